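# In-code fixtures. The random alignment builder here is intentionally
# independent of the package's synthetic-data generator: plain matrix
# sampling, used to feed the rule-oracle and property tests.

random_alignment <- function(n_rows = NULL, n_pos = NULL,
                             gap_p = 0.15, mask_p = 0.05,
                             alphabet = c("A", "C", "D", "E", "K", "N")) {
  if (is.null(n_rows)) n_rows <- sample(4:8, 1)
  if (is.null(n_pos)) n_pos <- sample(5:30, 1)
  ids <- c("REF", paste0("s", seq_len(n_rows - 1)))
  m <- matrix("", n_rows, n_pos, dimnames = list(ids, NULL))
  m["REF", ] <- sample(alphabet, n_pos, replace = TRUE)
  for (i in 2:n_rows) {
    for (j in seq_len(n_pos)) {
      u <- runif(1)
      m[i, j] <- if (u < gap_p) "-"
        else if (u < gap_p + mask_p) "x"
        else if (u < gap_p + mask_p + 0.5) m["REF", j]
        else sample(alphabet, 1)
    }
  }
  m
}

as_msa <- function(mat) {
  protein_msa(setNames(apply(mat, 1, paste, collapse = ""), rownames(mat)))
}

random_classify_config <- function() {
  classify_config(
    mode = sample(c("strict", "conservation"), 1),
    conservation_threshold = runif(1, 0.5, 1),
    adjacency_window = sample(1:2, 1),
    max_gap_fraction = runif(1, 0.2, 0.8),
    min_depth = sample(1:6, 1))
}

# A 16-row, 14-position alignment engineered so that the substitution E>K at
# position 7 is witnessed only by carriers whose domain copy is too
# incomplete to survive per-segment coverage filtering: observed residues at
# the position are {E, K, N} before curation and {E} after.
flip_fixture <- function() {
  full <- "MAYVLTEGHKLWDS"          # reference; E at position 7
  rows <- c(REF = full)
  for (i in 1:13) rows[paste0("orth", i)] <- full
  rows[["carrierK"]] <- "MAY--TKG---WDS"  # K at 7, clean at 6 and 8
  rows[["carrierN"]] <- "MAY--TNG---WDS"  # N at 7
  aln <- protein_msa(rows)
  domains <- read_domain_table(text = "name\trule_id\tstart\tend\ncore\t.\t4\t11")
  list(alignment = aln, domains = domains, pos = 7L)
}
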