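---
title: "Domain-curated ortholog alignments and evolutionary tolerance calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-curated ortholog alignments and evolutionary tolerance calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(orthotol)
```

## The problem

Most missense variants reported for clinically relevant genes are variants
of uncertain significance (VUS): catalogued substitutions with no
established interpretation. For a protein with a deep, well-curated set of
orthologs, evolution itself is an assay: a substitution repeatedly accepted
across orthologous sequences is evidence of tolerance, while a residue kept
invariant across hundreds of millions of years of divergence is evidence
that change there is not tolerated.

That argument is only as good as the alignment behind it. Two failure modes
dominate in practice. First, paralogs: after a gene duplication, the two
copies evolve under different constraints, and a column that mixes both
copies reports the union of their constraints — automated variant predictors
built on bulk homolog searches routinely suffer from exactly this
contamination. Second, misalignment: multidomain proteins align poorly end
to end, and a misplaced block manufactures spurious "substitutions" at
otherwise conserved positions. `orthotol` packages the counter-measures:
ortholog clade selection against designated paralog exemplars on a gene
tree, and domain-wise re-curation of the full-length alignment, followed by
rule-based classification of variants.

## The classification rules

For a variant `ref`→`alt` at reference position `p`, the classifier looks at
the alignment column of `p` and decides, in order:

1. **Signal gate.** If the column has residue depth below `min_depth`, or a
   gap fraction above `max_gap_fraction`, the verdict is `UNALIGNABLE`:
   there is not enough evolutionary signal to say anything. This category
   can be folded into `UNINTERPRETABLE` for three-way accounting
   (`merge_unalignable`, or `--paper_compat` on the command line).
2. **Observed substitution.** If `alt` occurs in the column, each carrier
   sequence is checked at the adjoining reference positions
   (`p ± adjacency_window`): a carrier *certifies* the substitution only if
   it matches the reference at every one of them (a gap or masked residue
   there counts as a mismatch — a changed local context cannot certify
   anything). At least one certifying carrier gives `TOLERANT`; if every
   carrier also differs next door, the substitution may be compensated by
   its context and the verdict is `UNINTERPRETABLE`.
3. **Unobserved substitution.** In the default `strict` mode this is
   `INTOLERANT` outright: across a deep ortholog set, absence of a residue
   at a column is read as evolutionary prohibition, including at variable
   columns (a position can tolerate some exchanges and still forbid the
   queried one). The alternative `conservation` mode reserves `INTOLERANT`
   for invariant columns and columns whose majority residue frequency
   reaches `conservation_threshold`, returning `UNINTERPRETABLE` at variable
   columns — the stricter, more literal reading of "not seen at a highly
   conserved position". Both modes are first-class because the underlying
   rule text genuinely admits both readings; `strict` is the default because
   the worked examples that motivated the rules all call unobserved
   substitutions at variable positions intolerant.

Verdicts are categorical by design; no pathogenicity score is produced.

```{r}
aln <- protein_msa(c(REF = "TEG", a = "TKG", b = "TNG", c = "TEG",
                     d = "TEG", e = "TEG", f = "TEG", g = "TEG",
                     h = "TEG", i = "TEG"))
map <- build_reference_map(aln, "REF")
classify_variant(aln, map, "E2K")
```

## Curation pipeline

`curate_alignment()` chains the steps a careful analyst would perform by
hand:

1. **Ambiguity removal.** Sequences containing residues from
   `ambiguous_set` are dropped entirely. The default set is
   `{B, Z, X, J, *}` — the IUPAC ambiguity codes and stop. Selenocysteine
   (`U`) and pyrrolysine (`O`) are *not* ambiguous: they are genuine, if
   rare, residues. The set is configurable because reasonable curators
   differ on this point.
2. **Partition.** The domain coordinate table (1-based inclusive spans,
   e.g. PROSITE rule matches) tiles the reference into `domain` segments
   and the `initial` / `interdomain` / `terminal` stretches between them.
   For *k* separated domains with flanks on both sides this yields
   2*k* + 1 segments — 15 for the seven-domain table shipped in
   `inst/extdata/dicer1_domains.tsv` over a 1922-residue reference.
3. **Slice.** Each segment takes the columns of its reference positions
   plus interior insertion columns. Insertion columns *between* segments
   are attached to the left segment (and leading insertions to the first):
   any consistent convention works, but this one makes the slices tile
   every alignment column, which in turn makes reassembly lossless for
   every retained row — a property the package tests exhaustively.
4. **Coverage filter.** A row whose non-gap, non-masked residue count in a
   segment is less than `min_segment_coverage` (default 0.5) of the
   segment's reference columns is discarded *in that segment*. The default
   discards half-missing domain copies without punishing modest
   truncations; the reference itself can never be discarded.
5. **Realignment.** The surviving segment rows are degapped and realigned,
   either by an external command template (e.g.
   `mafft --quiet {in} > {out}`) or by the built-in center-star aligner
   (below). Realignment is constrained to be content-preserving: output
   rows are rewritten with the original residues position by position, so
   only gap placement can change.
6. **Indel-proximity masking.** Residues within `indel_mask_window`
   (default 2) columns of a gap in their own row are replaced by the mask
   mark `x` and become invisible to conservation counting. This automates
   the manual practice of distrusting residues adjacent to indels, where
   alignment placement is least reliable. The window is symmetric and
   deliberately small; 0 disables masking. Terminal gap runs are treated
   like internal ones — conservative, since residues at a truncation edge
   are equally likely to be misplaced. The reference row is never masked.
7. **Reassembly.** Segments are concatenated. Under the default
   `gap_fill` policy a row discarded in one segment is padded with gaps
   there and reported, so a sequence unusable in one domain still
   contributes evidence in the others; `drop_policy = "global"` removes
   such rows everywhere, the stricter reading of "discard incomplete
   sequences".

Every removal, flag, gap-fill and masking action lands in a report table
with a reason, so a curation run is auditable after the fact.

## The built-in aligner

Segments are short and their rows are, by construction, orthologous — a
heavy progressive aligner is not required to be *available* for the package
to work. The built-in route aligns every row globally to the segment's
reference subsequence (Needleman–Wunsch with affine gaps in the Gotoh
formulation, BLOSUM62 scoring, gap costs `open + k·extend` with defaults
10 and 1) and merges the pairwise alignments center-star style under
"once a gap, always a gap". Numerical choices are pinned down so output is
bit-stable: DP ties prefer the diagonal, then the vertical, then the
horizontal move; gap-state ties prefer reopening from a match over
switching gap direction; sequences merge in input order. The gap-cost
convention (a length-1 gap costs `open + extend`) matches
`Biostrings::pairwiseAlignment`, which the test suite uses as an
independent implementation to verify scores exactly. Residues without a
BLOSUM62 entry (`U`, `O`, the mask mark) are scored as `X`.

## Clade selection

`select_ortholog_clade()` assumes the analyst can name at least one paralog
exemplar leaf (the outgroup role). An unrooted tree is first rooted on the
branch subtending the exemplars' most recent common ancestor. The selection
is then the largest clade containing the reference leaf and no exemplar —
found by walking rootwards from the reference, which is equivalent to
exhaustive clade enumeration (tested against it on all small random trees)
because clades containing a fixed leaf are nested. With `min_support`, a
clade whose subtending branch support falls below the threshold is skipped
in favour of the largest supported nested clade; branches with *no* support
label are treated as uninformative rather than unsupported, since absence
of a label cannot demonstrate weakness. No default threshold is imposed:
topology alone decides unless the caller says otherwise.

A second, optional filter (`exclude_species_with_paralog()`) removes
sequences from species that still possess the paralog, for lineages where
function may be partitioned between the two copies; with the gene tree and
a species map this expresses "keep only orthologs from proteomes that lost
the paralog".

## Coordinates

Reference positions are 1-based inclusive everywhere a user sees them
(domain tables, variant tokens, reports), matching HGVS and annotation
databases. Alignment columns are also 1-based, matching R indexing and the
containers of the R sequence ecosystem; `reference_map` converts in both
directions and refuses masked reference rows. Variants may be written
compactly (`E1705K`) or as HGVS-p (`p.Glu1705Lys`); nonsense and frameshift
tokens are rejected as out of scope rather than silently scored.

## The synthetic generator

`fixture_spec()` / `generate_msa()` emulate the statistical shape of a
curated single-gene ortholog panel: a mix of invariant columns and variable
columns with small residue pools (weights favouring the reference residue),
occasional short deletions, single-row insertion columns, truncated rows,
rows carrying ambiguity codes, and a separable paralog clade whose rows
re-draw a fraction of columns from pools disjoint from the ortholog pools.
Defaults (40 rows, 120 positions, 60% invariant columns, 10% indel rate,
10% truncation, 5% ambiguity, 4 paralog rows at 40% divergence) were chosen
once as a realistic small ortholog panel with all the failure modes the
pipeline must handle, and are not tuned thereafter. One integer seed drives
the whole fixture through an isolated RNG scope (`withr::with_seed`), so
fixtures are bit-identical across sessions and platforms.

What the generator does *not* emulate: substitution-rate matrices, branch
lengths, site-rate heterogeneity, or covarying columns. Passing tests on
these fixtures therefore demonstrate the *mechanics* of curation and
classification — not that the biological premises hold on any real
protein family. Ground-truth verdicts for generated variants come from a
straight-line re-statement of the decision rules kept separate from the
classifier's code path, so generator and classifier cannot share a bug by
construction.

## Verification choices and problem sizes

The package's checks favour exhaustive small cases over sampled large ones:
rule-oracle equivalence on 10,000 randomized (alignment ≤ 8 × 30, variant,
configuration) triples; pairwise aligner scores against an independent
affine-gap implementation on peptides up to length 12; clade selection
against full clade enumeration on trees up to 12 leaves; reassembly and
coordinate-map round trips verified position-by-position on generated
fixtures. Strict-mode classification properties (row-permutation
invariance, evidence monotonicity when a clean carrier is appended,
duplication invariance) are exercised on over a thousand randomized
perturbation trials. Duplication invariance is asserted away from the
signal-gate margin: duplicating a row cannot change which residues are
present, but it can legitimately move a column's depth or gap fraction
across the `min_depth` / `max_gap_fraction` thresholds, so the
presence-based invariance claim only applies where the gate is not
borderline.

## Known limitations

- The curation pipeline presupposes a trustworthy reference sequence and
  domain table; domain detection is out of scope.
- Masking and coverage thresholds are surrogates for expert judgement; the
  defaults are sensible, not sacred, and are surfaced in every interface.
- Carriers are counted at the sequence level: two sequences from the same
  species count twice. Under presence-based rules this is harmless, but
  users merging near-duplicate proteomes should deduplicate upstream.
- `curate_alignment()` is idempotent on alignments whose masking pattern is
  stable under realignment (e.g. truncation-only fixtures); when masked
  residues sit next to interior indels, re-curation can shift gap placement
  slightly because masks score as `X` on the second pass.
- Tree inference, bootstrap computation and variant-database retrieval stay
  external by design; the package consumes their outputs.
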