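## Sequence and alignment I/O with validation and sequence-level QC.
##
## Unaligned collections are plain data.frames (class "protein_seqs") with
## columns id, residues, species, description. Alignments are character
## matrices of single residues (class "protein_msa") with row names as ids:
## the natural container for the column-wise operations every later stage
## performs. Parsing of the FASTA container itself is delegated to
## Biostrings; this module owns validation and the residue alphabet.

DEFAULT_SPECIES_REGEX <- "\\[([^][]+)\\][^][]*$"

.as_fasta_input <- function(file, text) {
  if (!is.null(text)) {
    tf <- tempfile(fileext = ".fasta")
    writeLines(text, tf)
    return(tf)
  }
  if (!file.exists(file)) stop("FASTA file not found: ", file, call. = FALSE)
  file
}

.split_header <- function(nm) {
  nm <- trimws(nm)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(nchar(nm) > nchar(id), trimws(substring(nm, nchar(id) + 1L)), "")
  list(id = id, description = desc)
}

.species_from_description <- function(desc, regex = DEFAULT_SPECIES_REGEX) {
  m <- regmatches(desc, regexec(regex, desc))
  vapply(m, function(x) if (length(x) >= 2L) x[2L] else NA_character_, character(1))
}

.check_ids <- function(ids) {
  if (any(!nzchar(ids))) stop("empty sequence id in FASTA header", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  invisible(ids)
}

## Uppercase residue letters but preserve the lowercase mask mark.
.normalise_case <- function(s) {
  up <- toupper(s)
  masked <- gregexpr("x", s, fixed = TRUE)
  vapply(seq_along(s), function(i) {
    pos <- masked[[i]]
    si <- up[i]
    if (pos[1L] != -1L)
      for (p in pos) substr(si, p, p) <- "x"
    si
  }, character(1))
}

.check_alphabet <- function(strings, ids, allowed, what) {
  bad_re <- paste0("[^", gsub("([*\\]\\^\\-])", "\\\\\\1", paste(allowed, collapse = "")), "]")
  for (i in seq_along(strings)) {
    hit <- regexpr(bad_re, strings[i], perl = TRUE)
    if (hit != -1L) {
      stop(sprintf("invalid character '%s' at position %d of %s '%s'",
                   substr(strings[i], hit, hit), hit, what, ids[i]), call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Construct a protein sequence collection
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param residues Character vector of ungapped residue strings (uppercase
#'   canonical amino acids plus `B Z X J U O *`).
#' @param species Optional species labels (`NA` when unknown).
#' @param description Optional free-text descriptions.
#' @return A `protein_seqs` data.frame.
#' @export
protein_seqs <- function(id, residues, species = NA_character_, description = "") {
  id <- as.character(id); residues <- as.character(residues)
  .check_ids(id)
  if (any(!nzchar(residues)))
    stop("empty sequence record: ", paste(id[!nzchar(residues)], collapse = ", "),
         call. = FALSE)
  if (any(grepl("-", residues, fixed = TRUE)))
    stop("gap characters are not allowed in unaligned sequences (ids: ",
         paste(id[grepl("-", residues, fixed = TRUE)], collapse = ", "), ")",
         call. = FALSE)
  .check_alphabet(residues, id, RESIDUE_ALPHABET, "sequence")
  out <- data.frame(id = id, residues = residues,
                    species = rep_len(as.character(species), length(id)),
                    description = rep_len(as.character(description), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_seqs", "data.frame")
  out
}

#' Read unaligned protein sequences from FASTA
#'
#' The id is the first whitespace-delimited header token; the remainder is
#' kept as the description, from which a species label is extracted with
#' `species_regex` (default: text inside the last square brackets, NCBI
#' style). Residue letters are uppercased. Gap characters are rejected: use
#' [read_alignment()] for aligned FASTA.
#'
#' @param file Path to a FASTA file.
#' @param text Optional FASTA text given directly instead of a file.
#' @param species_regex Regex with one capture group applied to descriptions.
#' @return A `protein_seqs` data.frame.
#' @export
read_fasta <- function(file = NULL, text = NULL, species_regex = DEFAULT_SPECIES_REGEX) {
  path <- .as_fasta_input(file, text)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records found", call. = FALSE)
  hdr <- .split_header(names(set))
  strings <- .normalise_case(as.character(set))
  if (any(grepl(MASK_CHAR, strings, fixed = TRUE)))
    stop("mask mark 'x' is only legal in alignments, found in unaligned input",
         call. = FALSE)
  protein_seqs(hdr$id, strings,
               species = .species_from_description(hdr$description, species_regex),
               description = hdr$description)
}

#' Write unaligned protein sequences to FASTA
#'
#' @param seqs A `protein_seqs` data.frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file) {
  stopifnot(inherits(seqs, "protein_seqs"))
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- ifelse(nzchar(seqs$description),
                       paste(seqs$id, seqs$description), seqs$id)
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

#' Construct an alignment from gapped strings
#'
#' @param strings Named character vector of equal-length gapped rows
#'   (`-` for gaps, lowercase `x` for masked residues).
#' @return A `protein_msa` character matrix (rows = sequences, columns =
#'   alignment columns, row names = ids).
#' @export
protein_msa <- function(strings) {
  ids <- names(strings)
  if (is.null(ids)) stop("alignment rows must be named", call. = FALSE)
  .check_ids(ids)
  if (length(strings) < 1L) stop("alignment needs at least one row", call. = FALSE)
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L) {
    off <- paste(sprintf("%s (%d)", ids, lens), collapse = ", ")
    stop("ragged alignment, row lengths differ: ", off, call. = FALSE)
  }
  if (lens[1L] == 0L) stop("alignment rows are empty", call. = FALSE)
  .check_alphabet(strings, ids, c(RESIDUE_ALPHABET, GAP_CHAR, MASK_CHAR),
                  "alignment row")
  m <- matrix(unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE),
              nrow = length(strings), byrow = TRUE,
              dimnames = list(ids, NULL))
  class(m) <- c("protein_msa", class(m))
  m
}

#' Read an aligned FASTA file
#'
#' @inheritParams read_fasta
#' @return A `protein_msa` matrix; descriptions and parsed species labels are
#'   attached as attributes `description` and `species`.
#' @export
read_alignment <- function(file = NULL, text = NULL,
                           species_regex = DEFAULT_SPECIES_REGEX) {
  path <- .as_fasta_input(file, text)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records found", call. = FALSE)
  hdr <- .split_header(names(set))
  strings <- stats::setNames(.normalise_case(as.character(set)), hdr$id)
  aln <- protein_msa(strings)
  attr(aln, "description") <- stats::setNames(hdr$description, hdr$id)
  attr(aln, "species") <- stats::setNames(
    .species_from_description(hdr$description, species_regex), hdr$id)
  aln
}

#' Write an alignment to aligned FASTA
#'
#' @param aln A `protein_msa`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_alignment <- function(aln, file) {
  stopifnot(inherits(aln, "protein_msa"))
  strings <- msa_strings(aln)
  desc <- attr(aln, "description")
  nm <- names(strings)
  if (!is.null(desc)) {
    d <- desc[nm]
    nm <- ifelse(!is.na(d) & nzchar(d), paste(nm, d), nm)
  }
  set <- Biostrings::BStringSet(unname(strings))
  names(set) <- nm
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

#' Collapse a `protein_msa` back to gapped strings
#'
#' @param aln A `protein_msa`.
#' @return Named character vector of gapped rows.
#' @export
msa_strings <- function(aln) {
  stopifnot(inherits(aln, "protein_msa"))
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

#' Remove gaps (and optionally mask marks) from alignment rows
#'
#' Mask marks stand in for single residues, so by default they are kept so
#' that degapping an aligned row has the same length as the underlying
#' sequence.
#'
#' @param aln A `protein_msa` or a character vector of gapped strings.
#' @param drop_mask Also remove mask marks (`FALSE` by default).
#' @return Named character vector of ungapped strings.
#' @export
degap <- function(aln, drop_mask = FALSE) {
  strings <- if (inherits(aln, "protein_msa")) msa_strings(aln) else aln
  pat <- if (drop_mask) "[-x]" else "-"
  stats::setNames(gsub(pat, "", strings), names(strings))
}

#' Drop sequences containing ambiguous residues
#'
#' A sequence is removed iff it contains at least one residue from
#' `ambiguous_set`; each removal is logged with the offending residue. The
#' operation preserves input order and is idempotent.
#'
#' @param seqs A `protein_seqs` data.frame.
#' @param ambiguous_set Character vector of single-letter codes treated as
#'   ambiguous ([default_ambiguous_set()] unless overridden).
#' @return List with elements `kept` and `removed` (both `protein_seqs`) and
#'   `log` (data.frame of id and first offending residue).
#' @export
drop_ambiguous <- function(seqs, ambiguous_set = default_ambiguous_set()) {
  stopifnot(inherits(seqs, "protein_seqs"))
  if (length(ambiguous_set) == 0L) {
    log <- data.frame(id = character(0), residue = character(0),
                      stringsAsFactors = FALSE)
    return(list(kept = seqs, removed = seqs[0, ], log = log))
  }
  re <- paste0("[", gsub("([*\\]\\^\\-])", "\\\\\\1",
                         paste(ambiguous_set, collapse = "")), "]")
  hit <- regexpr(re, seqs$residues, perl = TRUE)
  bad <- hit != -1L
  log <- data.frame(
    id = seqs$id[bad],
    residue = substr(seqs$residues[bad], hit[bad], hit[bad]),
    stringsAsFactors = FALSE)
  list(kept = seqs[!bad, ], removed = seqs[bad, ], log = log)
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("protein_msa: %d sequences x %d columns\n", nrow(x), ncol(x)))
  show <- utils::head(msa_strings(x), 6L)
  if (ncol(x) > 60L) show <- paste0(substr(show, 1L, 60L), "...")
  for (i in seq_along(show)) cat(sprintf("  %-20s %s\n", names(show)[i], show[i]))
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
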