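## Mapping between 1-based reference positions and alignment columns.
##
## Variants are stated on the reference protein (e.g. human Dicer1) while
## conservation lives in alignment columns; this map is the bridge. Columns
## are 1-based, like everything else in R.

#' Build a reference-position / alignment-column map
#'
#' @param aln A `protein_msa` containing the reference row.
#' @param ref_id Row id of the reference sequence.
#' @return A `reference_map` list with `ref_id`, `pos_to_col` (integer vector
#'   of length `L`), `col_to_pos` (integer vector of length `n_cols`, `NA` at
#'   reference-gap columns), `L` and `n_cols`.
#' @export
build_reference_map <- function(aln, ref_id) {
  stopifnot(inherits(aln, "protein_msa"))
  if (!ref_id %in% rownames(aln))
    stop("reference id '", ref_id, "' is not a row of the alignment", call. = FALSE)
  row <- unclass(aln)[ref_id, ]
  if (any(row == MASK_CHAR))
    stop("reference row '", ref_id, "' contains mask marks; the reference must never be masked",
         call. = FALSE)
  pos_to_col <- which(row != GAP_CHAR)
  L <- length(pos_to_col)
  if (L == 0L) stop("reference row is all gaps", call. = FALSE)
  col_to_pos <- rep(NA_integer_, length(row))
  col_to_pos[pos_to_col] <- seq_len(L)
  structure(list(ref_id = ref_id, pos_to_col = as.integer(pos_to_col),
                 col_to_pos = col_to_pos, L = L, n_cols = length(row)),
            class = "reference_map")
}

#' Alignment column of a reference position
#'
#' @param map A `reference_map`.
#' @param pos 1-based reference position(s).
#' @return Integer column index (1-based), vectorised over `pos`.
#' @export
column_of <- function(map, pos) {
  stopifnot(inherits(map, "reference_map"))
  if (any(pos < 1L | pos > map$L))
    stop(sprintf("reference position %s out of range 1..%d",
                 paste(pos[pos < 1L | pos > map$L], collapse = ","), map$L),
         call. = FALSE)
  map$pos_to_col[pos]
}

#' Reference position at an alignment column
#'
#' @param map A `reference_map`.
#' @param col 1-based column index (vectorised).
#' @return Integer reference position, or `NA` where the reference has a gap.
#' @export
position_of <- function(map, col) {
  stopifnot(inherits(map, "reference_map"))
  if (any(col < 1L | col > map$n_cols))
    stop(sprintf("column %s out of range 1..%d",
                 paste(col[col < 1L | col > map$n_cols], collapse = ","),
                 map$n_cols), call. = FALSE)
  map$col_to_pos[col]
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf("reference_map: '%s', %d residues over %d columns\n",
              x$ref_id, x$L, x$n_cols))
  invisible(x)
}
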