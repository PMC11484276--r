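# Independent oracles used to cross-check the package implementation.
# These are deliberately written as plain loops / library calls, not as
# calls into the code paths they verify.

# Straight-line re-statement of the tolerance decision rules, operating on
# a bare character matrix.
oracle_verdict <- function(mat, ref_row, pos, alt, cfg) {
  ref_cols <- which(mat[ref_row, ] != "-")
  L <- length(ref_cols)
  col <- ref_cols[pos]
  n <- nrow(mat)

  residues <- character(0)
  gaps <- 0L
  for (i in seq_len(n)) {
    ch <- mat[i, col]
    if (ch == "-") {
      gaps <- gaps + 1L
    } else if (ch != "x") {
      residues <- c(residues, ch)
    }
  }
  if (length(residues) < cfg$min_depth) return("UNALIGNABLE")
  if (gaps / n > cfg$max_gap_fraction) return("UNALIGNABLE")

  if (alt %in% residues) {
    any_clean <- FALSE
    for (i in seq_len(n)) {
      if (mat[i, col] != alt) next
      clean <- TRUE
      for (p2 in (pos - cfg$adjacency_window):(pos + cfg$adjacency_window)) {
        if (p2 == pos || p2 < 1L || p2 > L) next
        c2 <- ref_cols[p2]
        if (mat[i, c2] != mat[ref_row, c2]) clean <- FALSE
      }
      if (clean) any_clean <- TRUE
    }
    if (any_clean) return("TOLERANT") else return("UNINTERPRETABLE")
  }

  if (cfg$mode == "strict") return("INTOLERANT")
  tab <- table(residues)
  if (length(tab) == 1L) return("INTOLERANT")
  if (max(tab) / length(residues) >= cfg$conservation_threshold)
    return("INTOLERANT")
  "UNINTERPRETABLE"
}

# Independent affine-gap global alignment score via Biostrings.
oracle_nw_score <- function(a, b, open = 10, ext = 1) {
  suppressWarnings(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = blosum62(),
    gapOpening = open, gapExtension = ext,
    type = "global", scoreOnly = TRUE))
}

# Exhaustive clade enumeration on a rooted tree: every internal node's tip
# set plus every singleton; the answer is the largest candidate containing
# the reference and no paralog.
oracle_clade <- function(tree, ref, paralogs) {
  ntip <- length(tree$tip.label)
  cands <- as.list(tree$tip.label)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    cands[[length(cands) + 1L]] <- ape::extract.clade(tree, node)$tip.label
  }
  best <- character(0)
  for (tips in cands) {
    if (!(ref %in% tips)) next
    if (any(paralogs %in% tips)) next
    if (length(tips) > length(best)) best <- tips
  }
  best
}

# Brute-force per-column distance to the nearest gap in the same row.
oracle_mask <- function(mat, window, ref_row = NULL) {
  out <- mat
  for (i in seq_len(nrow(mat))) {
    if (!is.null(ref_row) && rownames(mat)[i] == ref_row) next
    gaps <- which(mat[i, ] == "-")
    if (length(gaps) == 0L) next
    for (j in seq_len(ncol(mat))) {
      if (mat[i, j] == "-" || mat[i, j] == "x") next
      if (min(abs(gaps - j)) <= window) out[i, j] <- "x"
    }
  }
  out
}

# Brute-force interval scan: label every reference position, then count
# maximal runs of equal labels.
oracle_segment_count <- function(domains, L) {
  lab <- rep("none", L)
  for (i in seq_len(nrow(domains)))
    lab[domains$start[i]:domains$end[i]] <- paste0("d", i)
  runs <- rle(lab)
  length(runs$lengths)
}
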