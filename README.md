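# orthotol

Domain-curated ortholog alignments for classifying missense variants as
evolutionarily tolerant or intolerant.

## What it is for

Most catalogued missense variants in clinically relevant genes are variants
of uncertain significance (VUS). For a protein with many sequenced
orthologs, evolution is a natural mutagenesis screen: a substitution
repeatedly accepted among orthologs argues for tolerance; a position held
invariant across deep divergence argues that substitutions there are
damaging. The catch is that this inference is only as strong as the
alignment behind it — paralog contamination and domain-scale misalignment
are the two classic ways to get it wrong, and both are common in the bulk
homolog sets used by automated predictors.

`orthotol` is aimed at analysts curating a single gene family by hand, the
way one would for a multidomain protein such as Dicer1. It provides:

- **Ortholog clade selection** from a gene tree: root on designated paralog
  exemplars, take the largest clade containing the reference and no
  paralog, optionally drop species that still possess the paralog.
- **Domain-wise alignment curation**: partition the reference into domain
  and non-domain segments from a coordinate table (e.g. PROSITE spans),
  discard per-segment incomplete rows, realign each segment (built-in
  center-star aligner or any external command such as MAFFT), mask residues
  adjacent to indels, and reassemble a refined full-length MSA with a full
  audit report.
- **Variant classification** from per-column conservation. For `ref→alt`
  at reference position *p*:
  1. columns with depth `< min_depth` or gap fraction
     `> max_gap_fraction` → `UNALIGNABLE`;
  2. `alt` observed in the column → `TOLERANT` if at least one carrier
     matches the reference at every adjoining position (`p ± w`), else
     `UNINTERPRETABLE` (every carrier also changed its local context);
  3. `alt` unobserved → `INTOLERANT` (strict mode; a conservation mode
     restricts this to invariant/highly conserved columns).
- **A seeded synthetic-data generator** producing ortholog MSAs, matching
  gene trees and variant sets with ground-truth verdicts, so the whole
  pipeline is testable offline.
- **A command line** (`curate`, `clade`, `classify`, `simulate`, `report`).

## Worked example

Partition a 1922-residue reference with the shipped seven-domain table
(helicase, PAZ, RNase III and dsRNA-binding domains of human Dicer1):

```r
library(orthotol)
dom  <- read_domain_table(system.file("extdata", "dicer1_domains.tsv",
                                      package = "orthotol"))
segs <- partition_reference(dom, 1922L)
head(segs, 4)
#>          kind                        name start end
#> 1     initial                     initial     1  50
#> 2      domain Helicase ATP-binding domain    51 227
#> 3 interdomain               interdomain_1   228 432
#> 4      domain  Helicase C-terminal domain   433 602
nrow(segs)
#> [1] 15
```

The seven annotated domains plus their flanking and interdomain stretches
tile the protein into 15 segments, each of which is realigned
independently during curation.

Simulate an ortholog panel, curate it over two domains, and classify a
variant batch:

```r
fx  <- generate_msa(fixture_spec(seed = 42))
res <- curate_alignment(fx$alignment, "REF",
         read_domain_table(text = "name\trule_id\tstart\tend\ncoreA\t.\t20\t60\ncoreB\t.\t75\t110"))
vars <- generate_variants(fx, 25, seed = 7)
out  <- classify_batch(res$alignment, res$map, vars$variant)
out$summary
#>        tolerant      intolerant uninterpretable     unalignable           error
#>               7              11               5               2               0
head(out$table[, c("pos", "ref", "alt", "verdict", "rule", "depth", "observed_set")], 3)
#>   pos ref alt         verdict                    rule depth observed_set
#> 1  42   Q   L        TOLERANT  observed_clean_context    41          L,Q
#> 2  92   H   G UNINTERPRETABLE co_substitution_context    40          G,H
#> 3  15   P   G      INTOLERANT       unobserved_strict    40      H,K,N,P
```

Row 1: `L` is observed at position 42 in a carrier whose neighbours match
the reference, so `Q42L` is evolutionarily allowable. Row 2: `G` occurs at
position 92 only in sequences that also changed an adjoining position, so
`H92G` cannot be interpreted — the context shift may compensate. Row 3:
`G` is never seen at position 15 across the panel, so `P15G` is called
intolerant. The same operations are available from a shell:

```sh
orthotol simulate --dir run --seed 42
orthotol curate   --msa run/alignment.fasta --domains domains.tsv --ref REF --out run/refined.fasta
orthotol classify --msa run/refined.fasta --ref REF --variants run/variants.tsv --out run/calls.tsv
orthotol report   --table run/calls.tsv --domains domains.tsv
```

See the vignette (`vignettes/domain-curated-variant-classification.Rmd`)
for the model, the parameter defaults and their rationale, and known
limitations.

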