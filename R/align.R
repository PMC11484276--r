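## Built-in segment aligner: global pairwise Gotoh (BLOSUM62, affine gap
## costs) merged center-star style around the reference subsequence, plus
## support for delegating to an external aligner command (e.g. mafft).

.blosum62_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' Fetched from Biostrings and cached. Residues without a matrix entry
#' (U, O and the mask mark) are scored as 'X'.
#'
#' @return Numeric substitution matrix.
#' @export
blosum62 <- function() {
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$m <- e$BLOSUM62
  }
  .blosum62_cache$m
}

.residue_indices <- function(chars, alphabet) {
  idx <- match(chars, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx
}

#' Global pairwise alignment of two peptides
#'
#' Needleman-Wunsch with affine gaps (Gotoh); a gap of length k costs
#' `gap_open + k * gap_extend`. Deterministic tie-breaking: diagonal, then
#' up, then left.
#'
#' @param a,b Ungapped residue strings.
#' @param gap_open,gap_extend Gap cost parameters (positive costs).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @return List with `score`, and gapped strings `a_aln`, `b_aln`.
#' @export
nw_align <- function(a, b, gap_open = 10, gap_extend = 1, matrix = NULL) {
  if (is.null(matrix)) matrix <- blosum62()
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  alpha <- rownames(matrix)
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  res <- .nw_align_cpp(.residue_indices(ac, alpha), .residue_indices(bc, alpha),
                       matrix, gap_open, gap_extend)
  a_aln <- ifelse(res$a_idx == 0L, GAP_CHAR, ac[pmax(res$a_idx, 1L)])
  b_aln <- ifelse(res$b_idx == 0L, GAP_CHAR, bc[pmax(res$b_idx, 1L)])
  list(score = res$score,
       a_aln = paste(a_aln, collapse = ""),
       b_aln = paste(b_aln, collapse = ""))
}

## Insertion profile of one pairwise alignment relative to the center:
## number of center-gap columns after center residue k, k = 0..nc.
.center_insertions <- function(a_idx, nc) {
  ins <- integer(nc + 1L)
  k <- 0L
  for (v in a_idx) {
    if (v == 0L) ins[k + 1L] <- ins[k + 1L] + 1L else k <- v
  }
  ins
}

## Rebuild one row on the master coordinate system. cols: list of
## (a_idx, s_chars) pairwise columns; master_ins: insertions per center slot.
.project_row <- function(a_idx, s_chars, master_ins, nc) {
  out <- character(0)
  k <- 0L
  buf <- character(0)  # inserted residues pending for slot k
  flush <- function(out, buf, k) {
    pad <- master_ins[k + 1L] - length(buf)
    c(out, buf, rep(GAP_CHAR, pad))
  }
  for (t in seq_along(a_idx)) {
    if (a_idx[t] == 0L) {
      buf <- c(buf, s_chars[t])
    } else {
      out <- flush(out, buf, k)
      buf <- character(0)
      k <- a_idx[t]
      out <- c(out, s_chars[t])
    }
  }
  out <- flush(out, buf, k)
  ## remaining center residues beyond the last aligned one cannot occur in a
  ## global alignment, but guard anyway
  paste(out, collapse = "")
}

#' Center-star multiple alignment around a designated center sequence
#'
#' Every sequence is globally aligned to the center; the pairwise alignments
#' are merged under "once a gap, always a gap": the master alignment reserves,
#' between consecutive center residues, the maximum number of insertion
#' columns any pairwise alignment required there. Sequences are processed in
#' input order and ties in the pairwise DP are broken deterministically, so
#' the output is bit-stable.
#'
#' @param seqs Named character vector of ungapped sequences (mask marks
#'   allowed; scored as 'X').
#' @param center_id Name of the center sequence (typically the reference).
#' @param gap_open,gap_extend Affine gap costs.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @return A `protein_msa` in input row order.
#' @export
center_star_align <- function(seqs, center_id, gap_open = 10, gap_extend = 1,
                              matrix = NULL) {
  if (is.null(matrix)) matrix <- blosum62()
  stopifnot(!is.null(names(seqs)), center_id %in% names(seqs))
  if (any(nchar(seqs) == 0L))
    stop("cannot align empty sequences: ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  if (length(seqs) == 1L) return(protein_msa(seqs))
  alpha <- rownames(matrix)
  center <- seqs[[center_id]]
  cc <- strsplit(center, "", fixed = TRUE)[[1L]]
  nc <- length(cc)
  ci <- .residue_indices(cc, alpha)

  others <- setdiff(names(seqs), center_id)
  pw <- lapply(others, function(id) {
    sc <- strsplit(seqs[[id]], "", fixed = TRUE)[[1L]]
    r <- .nw_align_cpp(ci, .residue_indices(sc, alpha), matrix,
                       gap_open, gap_extend)
    s_chars <- ifelse(r$b_idx == 0L, GAP_CHAR, sc[pmax(r$b_idx, 1L)])
    list(a_idx = r$a_idx, s_chars = s_chars)
  })
  names(pw) <- others

  master_ins <- integer(nc + 1L)
  for (p in pw)
    master_ins <- pmax(master_ins, .center_insertions(p$a_idx, nc))

  rows <- stats::setNames(vector("character", length(seqs)), names(seqs))
  ## center row: gaps in every insertion block
  blocks <- character(0)
  for (k in 0:nc) {
    blocks <- c(blocks, rep(GAP_CHAR, master_ins[k + 1L]),
                if (k < nc) cc[k + 1L])
  }
  rows[[center_id]] <- paste(blocks, collapse = "")
  for (id in others)
    rows[[id]] <- .project_row(pw[[id]]$a_idx, pw[[id]]$s_chars, master_ins, nc)
  protein_msa(rows)
}

#' Specify how segments are realigned
#'
#' @param method `"center_star"` for the built-in aligner or `"external"` for
#'   a shell command template.
#' @param gap_open,gap_extend Affine gap costs (built-in aligner).
#' @param command Command template containing `{in}` and `{out}` placeholders
#'   operating on FASTA files, e.g. `"mafft --quiet {in} > {out}"`.
#' @return An `aligner_spec` list.
#' @export
aligner_spec <- function(method = c("center_star", "external"),
                         gap_open = 10, gap_extend = 1, command = NULL) {
  method <- match.arg(method)
  if (method == "external" && (is.null(command) ||
      !grepl("{in}", command, fixed = TRUE) ||
      !grepl("{out}", command, fixed = TRUE)))
    stop("external aligner needs a command template with {in} and {out}",
         call. = FALSE)
  structure(list(method = method, gap_open = gap_open,
                 gap_extend = gap_extend, command = command),
            class = "aligner_spec")
}

.run_external_aligner <- function(seqs, command) {
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  ## external tools do not know the mask mark; send 'X' and restore after
  send <- chartr("x", "X", seqs)
  writeLines(paste0(">", names(send), "\n", send), fin)
  cmd <- gsub("{out}", shQuote(fout),
              gsub("{in}", shQuote(fin), command, fixed = TRUE), fixed = TRUE)
  status <- suppressWarnings(
    system2("sh", c("-c", shQuote(cmd)), stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0L)
    stop("external aligner failed (exit ", code, "): ",
         paste(utils::tail(status, 5L), collapse = " | "), call. = FALSE)
  if (!file.exists(fout) || file.size(fout) == 0L)
    stop("external aligner produced no output", call. = FALSE)
  read_alignment(fout)
}

#' Realign the sequences of one segment
#'
#' Degapped segment rows are realigned either by the built-in center-star
#' aligner (centered on the reference) or by an external command. Whatever
#' the route, each output row is rewritten with the original input characters
#' in order, so realignment can change gap placement but never residue
#' content, and mask marks survive external tools.
#'
#' @param seqs Named character vector of ungapped sequences including the
#'   reference.
#' @param ref_id Name of the reference sequence.
#' @param aligner An [aligner_spec()].
#' @return A `protein_msa` over the same ids.
#' @export
realign_segment <- function(seqs, ref_id, aligner = aligner_spec()) {
  stopifnot(inherits(aligner, "aligner_spec"), ref_id %in% names(seqs))
  if (length(seqs) == 1L) return(protein_msa(seqs))
  aln <- if (aligner$method == "center_star") {
    center_star_align(seqs, ref_id, aligner$gap_open, aligner$gap_extend)
  } else {
    .run_external_aligner(seqs, aligner$command)
  }
  if (!setequal(rownames(aln), names(seqs)))
    stop("aligner dropped or renamed sequences", call. = FALSE)
  ## restore original residue characters position by position
  m <- unclass(aln)[names(seqs), , drop = FALSE]
  for (i in seq_along(seqs)) {
    orig <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    nz <- which(m[i, ] != GAP_CHAR)
    if (length(nz) != length(orig))
      stop("aligner altered residue content of '", names(seqs)[i], "'",
           call. = FALSE)
    m[i, nz] <- orig
  }
  out <- m
  class(out) <- c("protein_msa", class(matrix()))
  out
}
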