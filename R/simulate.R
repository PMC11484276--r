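## Seeded synthetic ortholog MSAs, gene trees and variant sets with ground
## truth, emulating the structure of a curated single-gene ortholog dataset:
## a mix of invariant and variable columns, occasional indels, truncated
## (incomplete) rows, rows carrying ambiguity codes, and a divergent paralog
## clade. Ground-truth verdicts come from a straight-line rule evaluator
## kept deliberately separate from the classification code path.

#' Specify a synthetic ortholog-MSA fixture
#'
#' Defaults describe a modest ortholog panel: 40 sequences over 120
#' reference positions, 60% of columns invariant, variable columns drawing
#' from pools of 2-4 residues with geometric-ish weights, a 10% per-row
#' chance of a short deletion, 10% of rows truncated, 5% of rows carrying an
#' ambiguity code, and 4 paralog rows with 40% of their columns re-drawn
#' from a disjoint residue pool.
#'
#' @param n_rows Ortholog rows including the reference.
#' @param L Reference length (columns before insertions).
#' @param invariant_frac Fraction of columns that are invariant.
#' @param pool_sizes Possible sizes of variable-column residue pools.
#' @param indel_rate Per-row probability of a deletion run.
#' @param n_insertions Number of single-row insertion columns added.
#' @param truncation_fraction Fraction of non-reference rows truncated.
#' @param ambiguous_rate Fraction of non-reference rows given an ambiguity
#'   code.
#' @param paralog_rows Number of paralog contaminant rows appended.
#' @param paralog_divergence Fraction of columns re-drawn in paralog rows.
#' @param seed Integer seed; same seed, same fixture, bit for bit.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_rows = 40L, L = 120L, invariant_frac = 0.6,
                         pool_sizes = 2:4, indel_rate = 0.1,
                         n_insertions = 2L, truncation_fraction = 0.1,
                         ambiguous_rate = 0.05, paralog_rows = 4L,
                         paralog_divergence = 0.4, seed = 1L) {
  stopifnot(n_rows >= 2L, L >= 10L, invariant_frac >= 0, invariant_frac <= 1,
            all(pool_sizes >= 2L), indel_rate >= 0, indel_rate <= 1,
            truncation_fraction >= 0, truncation_fraction <= 1,
            ambiguous_rate >= 0, ambiguous_rate <= 1, paralog_rows >= 0,
            paralog_divergence >= 0, paralog_divergence <= 1)
  structure(list(n_rows = as.integer(n_rows), L = as.integer(L),
                 invariant_frac = invariant_frac, pool_sizes = pool_sizes,
                 indel_rate = indel_rate, n_insertions = as.integer(n_insertions),
                 truncation_fraction = truncation_fraction,
                 ambiguous_rate = ambiguous_rate,
                 paralog_rows = as.integer(paralog_rows),
                 paralog_divergence = paralog_divergence,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

## sample() treats a length-1 numeric vector as 1:n; these helpers never do
.pick_n <- function(x, n) x[sample.int(length(x), n)]
.pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Generate a synthetic ortholog MSA with ground truth
#'
#' Row 1 (`REF`) is the ungapped reference carrying the designated reference
#' residue at every position. Ortholog rows follow the per-column design;
#' paralog rows re-draw a fixture-defined fraction of columns from residues
#' disjoint from the column's ortholog pool, guaranteeing separability.
#'
#' @param spec A [fixture_spec()].
#' @return List with `alignment` (`protein_msa`), `map` (reference map) and
#'   `truth`: per-column design (`column_kind`, `column_pool`), per-row
#'   annotations (`row_kind`, `truncated`, `ambiguous`), emitted residue
#'   sets per reference position (`observed`), and `insertion_columns`.
#' @export
generate_msa <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, .generate_msa_impl(spec))
}

.generate_msa_impl <- function(spec) {
  L <- spec$L
  n_orth <- spec$n_rows
  ids <- c("REF", sprintf("orth%02d", seq_len(n_orth - 1L)),
           if (spec$paralog_rows > 0L) sprintf("para%02d", seq_len(spec$paralog_rows)))
  n_all <- length(ids)

  n_inv <- round(spec$invariant_frac * L)
  kind <- rep("variable", L)
  kind[sample.int(L, n_inv)] <- "invariant"
  pool <- vector("list", L)
  for (p in seq_len(L)) {
    if (kind[p] == "invariant") {
      pool[[p]] <- sample(CANONICAL_AA, 1L)
    } else {
      k <- sample(spec$pool_sizes, 1L)
      pool[[p]] <- sample(CANONICAL_AA, k)
    }
  }
  ## column weights favour the first (reference) residue of the pool
  weights <- lapply(pool, function(pl) {
    w <- 0.5 ^ (seq_along(pl) - 1L)
    w / sum(w)
  })

  m <- matrix("", nrow = n_all, ncol = L, dimnames = list(ids, NULL))
  m["REF", ] <- vapply(pool, `[[`, "", 1L)
  for (i in seq_len(n_orth - 1L) + 1L) {
    m[i, ] <- vapply(seq_len(L), function(p)
      sample(pool[[p]], 1L, prob = weights[[p]]), "")
  }
  row_kind <- c("reference", rep("ortholog", n_orth - 1L),
                rep("paralog", spec$paralog_rows))
  if (spec$paralog_rows > 0L) {
    for (i in seq_len(spec$paralog_rows) + n_orth) {
      m[i, ] <- vapply(seq_len(L), function(p)
        sample(pool[[p]], 1L, prob = weights[[p]]), "")
      redraw <- sample.int(L, round(spec$paralog_divergence * L))
      for (p in redraw) {
        alt_pool <- setdiff(CANONICAL_AA, pool[[p]])
        m[i, p] <- sample(alt_pool, 1L)
      }
    }
  }

  ## deletions: short gap runs in ortholog/paralog rows
  for (i in 2L:n_all) {
    if (stats::runif(1L) < spec$indel_rate) {
      len <- sample(1:3, 1L)
      at <- sample.int(L - len, 1L)
      m[i, at:(at + len - 1L)] <- GAP_CHAR
    }
  }
  ## truncations: leading or trailing stretch gapped
  truncated <- rep(FALSE, n_all)
  cand <- 2L:n_all
  n_trunc <- round(spec$truncation_fraction * (n_all - 1L))
  if (n_trunc > 0L) {
    tr <- .pick_n(cand, n_trunc)
    for (i in tr) {
      frac <- stats::runif(1L, 0.3, 0.6)
      len <- max(1L, round(frac * L))
      if (stats::runif(1L) < 0.5) m[i, seq_len(len)] <- GAP_CHAR
      else m[i, (L - len + 1L):L] <- GAP_CHAR
      truncated[i] <- TRUE
    }
  }
  ## ambiguity codes
  ambiguous <- rep(FALSE, n_all)
  n_amb <- round(spec$ambiguous_rate * (n_all - 1L))
  if (n_amb > 0L) {
    am <- .pick_n(setdiff(cand, which(truncated)), min(n_amb, sum(!truncated[cand])))
    for (i in am) {
      nz <- which(m[i, ] != GAP_CHAR)
      m[i, .pick1(nz)] <- sample(c("B", "Z", "X", "J"), 1L)
      ambiguous[i] <- TRUE
    }
  }
  ## insertion columns: a single non-reference row holds a residue
  ins_after <- integer(0)
  if (spec$n_insertions > 0L) {
    ins_after <- sort(.pick_n(seq_len(L - 1L), spec$n_insertions))
    newm <- matrix(GAP_CHAR, nrow = n_all,
                   ncol = L + length(ins_after), dimnames = list(ids, NULL))
    ## column p of m lands at p + number of insertions before it
    tgt <- seq_len(L) + vapply(seq_len(L), function(p) sum(ins_after < p), 0L)
    newm[, tgt] <- m
    ins_cols <- setdiff(seq_len(ncol(newm)), tgt)
    for (j in ins_cols) {
      row <- .pick1(2L:n_all)
      newm[row, j] <- sample(CANONICAL_AA, 1L)
    }
    m <- newm
  } else {
    ins_cols <- integer(0)
  }

  aln <- m
  class(aln) <- c("protein_msa", class(matrix()))
  map <- build_reference_map(aln, "REF")
  observed <- lapply(seq_len(L), function(p) {
    chars <- m[, column_of(map, p)]
    sort(unique(chars[chars %in% CANONICAL_AA]))
  })
  truth <- list(column_kind = kind, column_pool = pool,
                row_kind = stats::setNames(row_kind, ids),
                truncated = stats::setNames(truncated, ids),
                ambiguous = stats::setNames(ambiguous, ids),
                observed = observed,
                insertion_columns = ins_cols)
  list(alignment = aln, map = map, truth = truth)
}

## Straight-line ground-truth rule evaluator, independent of
## classify_variant: explicit loops over the column and carriers.
#' @keywords internal
.truth_verdict <- function(m, ref_id, map, pos, ref_aa, alt_aa, cfg) {
  col <- map$pos_to_col[pos]
  n <- nrow(m)
  chars <- m[, col]
  depth <- 0L
  gaps <- 0L
  seen <- character(0)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "-") gaps <- gaps + 1L
    else if (ch != "x") { depth <- depth + 1L; seen <- c(seen, ch) }
  }
  if (depth < cfg$min_depth || gaps / n > cfg$max_gap_fraction)
    return("UNALIGNABLE")
  if (alt_aa %in% seen) {
    ok <- FALSE
    for (i in seq_len(n)) {
      if (chars[i] != alt_aa) next
      clean <- TRUE
      for (d in seq_len(cfg$adjacency_window)) {
        for (p2 in c(pos - d, pos + d)) {
          if (p2 < 1L || p2 > map$L) next
          c2 <- map$pos_to_col[p2]
          if (m[i, c2] != m[ref_id, c2]) clean <- FALSE
        }
      }
      if (clean) ok <- TRUE
    }
    return(if (ok) "TOLERANT" else "UNINTERPRETABLE")
  }
  if (cfg$mode == "strict") return("INTOLERANT")
  tab <- table(seen)
  if (length(tab) == 1L || max(tab) / depth >= cfg$conservation_threshold)
    return("INTOLERANT")
  "UNINTERPRETABLE"
}

#' Draw random variants with ground-truth verdicts
#'
#' Positions and alternate residues are sampled from the fixture; roughly
#' half the draws use residues observed somewhere in the column (candidates
#' for tolerance) and half unobserved residues. Expected verdicts are
#' computed by the internal straight-line rule evaluator, not by
#' [classify_variant()].
#'
#' @param msa Result of [generate_msa()].
#' @param n Number of variants.
#' @param seed Integer seed.
#' @param cfg A [classify_config()] the truth is computed under.
#' @return Data.frame with columns `variant`, `pos`, `ref`, `alt`,
#'   `expected`.
#' @export
generate_variants <- function(msa, n, seed, cfg = classify_config()) {
  m <- unclass(msa$alignment)
  map <- msa$map
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      pos <- sample.int(map$L, 1L)
      col <- map$pos_to_col[pos]
      ref_aa <- m[map$ref_id, col]
      chars <- m[, col]
      observed <- setdiff(unique(chars[chars %in% CANONICAL_AA]), ref_aa)
      alt <- NA_character_
      if (length(observed) > 0L && stats::runif(1L) < 0.5) {
        alt <- sample(observed, 1L)
      } else {
        unobs <- setdiff(CANONICAL_AA, c(unique(chars), ref_aa))
        if (length(unobs) == 0L) unobs <- setdiff(CANONICAL_AA, ref_aa)
        alt <- sample(unobs, 1L)
      }
      data.frame(variant = paste0(ref_aa, pos, alt), pos = pos,
                 ref = ref_aa, alt = alt,
                 expected = .truth_verdict(m, map$ref_id, map, pos,
                                           ref_aa, alt, cfg),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a gene tree matching a fixture
#'
#' Ortholog rows form one clade and paralog rows a sister clade, mirroring a
#' duplication that predates the sampled species. Topologies within each
#' clade are random but fully determined by the seed.
#'
#' @param spec A [fixture_spec()].
#' @return An `ape::phylo` tree whose tips are the fixture row ids.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed + 1L, {
    orth <- c("REF", sprintf("orth%02d", seq_len(spec$n_rows - 1L)))
    para <- if (spec$paralog_rows > 0L)
      sprintf("para%02d", seq_len(spec$paralog_rows)) else character(0)
    nt <- if (length(para) > 0L)
      sprintf("(%s,%s);", .random_subtree(orth), .random_subtree(para))
    else sprintf("%s;", .random_subtree(orth))
    read_newick(text = nt)
  })
}

## random binary Newick over labels (no branch lengths), seed-deterministic
.random_subtree <- function(labels) {
  if (length(labels) == 1L) return(labels)
  k <- sample.int(length(labels) - 1L, 1L)
  pick <- sample(labels)
  left <- pick[seq_len(k)]
  right <- pick[-seq_len(k)]
  sprintf("(%s,%s)", .random_subtree(left), .random_subtree(right))
}

#' Write a complete simulated dataset to disk
#'
#' Writes aligned FASTA, Newick tree, species map TSV, variants TSV and a
#' truth JSON next to each other.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param n_variants Number of variants to draw.
#' @param cfg [classify_config()] used for ground-truth verdicts.
#' @return Invisible named vector of file paths.
#' @export
simulate_dataset <- function(spec, dir, n_variants = 50L,
                             cfg = classify_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  msa <- generate_msa(spec)
  tree <- generate_tree(spec)
  vars <- generate_variants(msa, n_variants, spec$seed + 2L, cfg)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             tree = file.path(dir, "tree.nwk"),
             species = file.path(dir, "species.tsv"),
             variants = file.path(dir, "variants.tsv"),
             truth = file.path(dir, "truth.json"))
  write_alignment(msa$alignment, paths[["alignment"]])
  ape::write.tree(tree, paths[["tree"]])
  ids <- rownames(msa$alignment)
  utils::write.table(
    data.frame(id = ids, species = paste0("species_", seq_along(ids))),
    paths[["species"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(label = vars$variant, variant = vars$variant),
    paths[["variants"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(spec),
         row_kind = as.list(msa$truth$row_kind),
         expected = stats::setNames(as.list(vars$expected), vars$variant)),
    paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
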