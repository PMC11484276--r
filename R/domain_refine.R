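## Domain-wise curation of a full-length ortholog MSA: partition the
## reference into domain and non-domain segments, slice the alignment,
## drop incomplete rows per segment, mask residues adjacent to indels,
## realign each segment and reassemble the refined full-length MSA.

#' Read a domain coordinate table
#'
#' TSV with header columns `name`, `rule_id`, `start`, `end`; coordinates are
#' 1-based inclusive reference positions (e.g. PROSITE rule spans). Rows are
#' returned sorted by start, and overlapping domains are an error.
#'
#' @param file Path to the TSV.
#' @param text Optional TSV text given directly.
#' @return Data.frame of class `domain_table`.
#' @export
read_domain_table <- function(file = NULL, text = NULL) {
  d <- if (!is.null(text)) {
    utils::read.delim(text = text, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(file, stringsAsFactors = FALSE)
  }
  need <- c("name", "rule_id", "start", "end")
  if (!all(need %in% names(d)))
    stop("domain table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- d[, need]
  ## tolerate thousands separators as printed in annotation tables
  d$start <- as.integer(gsub(",", "", d$start, fixed = TRUE))
  d$end <- as.integer(gsub(",", "", d$end, fixed = TRUE))
  if (any(is.na(d$start)) || any(is.na(d$end)))
    stop("non-numeric domain coordinates", call. = FALSE)
  bad <- d$start > d$end | d$start < 1L
  if (any(bad))
    stop("invalid domain span (start > end or start < 1): ",
         paste(d$name[bad], collapse = ", "), call. = FALSE)
  d <- d[order(d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  if (nrow(d) > 1L) {
    for (i in seq_len(nrow(d) - 1L)) {
      if (d$end[i] >= d$start[i + 1L])
        stop(sprintf("overlapping domains: '%s' (%d-%d) and '%s' (%d-%d)",
                     d$name[i], d$start[i], d$end[i],
                     d$name[i + 1L], d$start[i + 1L], d$end[i + 1L]),
             call. = FALSE)
    }
  }
  class(d) <- c("domain_table", "data.frame")
  d
}

#' Tile the reference with domain and non-domain segments
#'
#' Produces a contiguous, non-overlapping partition of positions `1..L`:
#' each domain becomes a `domain` segment; the stretch before the first
#' domain (if any) is `initial`, stretches between non-abutting domains are
#' `interdomain`, and the stretch after the last domain is `terminal`. For
#' k mutually non-abutting domains with the first start > 1 and last end < L
#' this yields 2k + 1 segments.
#'
#' @param domains A `domain_table` (or data.frame with name/start/end).
#' @param L Reference length in residues.
#' @return Data.frame of class `segment_table` with columns `kind`, `name`,
#'   `start`, `end`.
#' @export
partition_reference <- function(domains, L) {
  L <- as.integer(L)
  if (nrow(domains) == 0L)
    return(structure(data.frame(kind = "initial", name = "initial",
                                start = 1L, end = L, stringsAsFactors = FALSE),
                     class = c("segment_table", "data.frame")))
  domains <- domains[order(domains$start), , drop = FALSE]
  if (any(domains$end > L))
    stop(sprintf("domain '%s' ends at %d, beyond reference length %d",
                 domains$name[which(domains$end > L)[1L]],
                 max(domains$end), L), call. = FALSE)
  segs <- list()
  cursor <- 1L
  n_inter <- 0L
  for (i in seq_len(nrow(domains))) {
    s <- domains$start[i]; e <- domains$end[i]
    if (s > cursor) {
      if (cursor == 1L) {
        segs[[length(segs) + 1L]] <- list("initial", "initial", cursor, s - 1L)
      } else {
        n_inter <- n_inter + 1L
        segs[[length(segs) + 1L]] <- list("interdomain",
                                          paste0("interdomain_", n_inter),
                                          cursor, s - 1L)
      }
    }
    segs[[length(segs) + 1L]] <- list("domain", domains$name[i], s, e)
    cursor <- e + 1L
  }
  if (cursor <= L)
    segs[[length(segs) + 1L]] <- list("terminal", "terminal", cursor, L)
  out <- data.frame(kind = vapply(segs, `[[`, "", 1L),
                    name = vapply(segs, `[[`, "", 2L),
                    start = vapply(segs, function(x) as.integer(x[[3L]]), 1L),
                    end = vapply(segs, function(x) as.integer(x[[4L]]), 1L),
                    stringsAsFactors = FALSE)
  ## duplicate domain names (repeated annotation rules) made unique
  dup <- duplicated(out$name) | duplicated(out$name, fromLast = TRUE)
  if (any(dup & out$kind == "domain")) {
    ix <- which(out$kind == "domain" & dup)
    out$name[ix] <- paste0(out$name[ix], "_", ave(out$start[ix], out$name[ix],
                                                  FUN = seq_along))
  }
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Extract the alignment slice of one segment
#'
#' The slice spans the columns of the segment's reference positions,
#' carrying along insertion (reference-gap) columns interior to the span.
#' With `include_trailing_insertions = TRUE` (the pipeline default) insertion
#' columns following the segment's last reference column are attached to
#' this (left) segment — and leading insertion columns before the first
#' reference column are attached to the first segment — so that the slices
#' of a full partition tile every alignment column and reassembly is
#' lossless for every row.
#'
#' @param aln A `protein_msa`.
#' @param map Its `reference_map`.
#' @param seg One row of a `segment_table` (list or data.frame row with
#'   `start`, `end`).
#' @param include_trailing_insertions See description.
#' @return A `protein_msa` slice; ids of rows that are all-gap within the
#'   slice are recorded in attribute `all_gap_ids`.
#' @export
slice_alignment <- function(aln, map, seg, include_trailing_insertions = TRUE) {
  stopifnot(inherits(aln, "protein_msa"), inherits(map, "reference_map"))
  start <- as.integer(seg$start); end <- as.integer(seg$end)
  if (start < 1L || end > map$L || start > end)
    stop(sprintf("segment %d-%d outside reference 1..%d", start, end, map$L),
         call. = FALSE)
  c1 <- column_of(map, start)
  c2 <- column_of(map, end)
  if (include_trailing_insertions) {
    if (start == 1L) c1 <- 1L
    c2 <- if (end == map$L) map$n_cols else column_of(map, end + 1L) - 1L
  }
  m <- unclass(aln)[, c1:c2, drop = FALSE]
  sub <- m
  class(sub) <- c("protein_msa", class(matrix()))
  all_gap <- rownames(sub)[rowSums(m != GAP_CHAR) == 0L]
  attr(sub, "all_gap_ids") <- all_gap
  attr(sub, "col_range") <- c(c1, c2)
  sub
}

#' Drop rows with insufficient coverage of a segment
#'
#' A row is removed iff its count of non-gap, non-masked residues in the
#' slice, divided by the number of reference-occupied columns of the slice,
#' falls below `min_segment_coverage`. The reference row is never removed
#' (its ratio is always at least 1).
#'
#' @param seg_aln A segment `protein_msa` containing the reference row.
#' @param min_segment_coverage Fraction in `[0, 1]`.
#' @param ref_id Reference row id.
#' @return List with `kept` (`protein_msa`) and `removed_ids`.
#' @export
filter_incomplete <- function(seg_aln, min_segment_coverage, ref_id) {
  stopifnot(inherits(seg_aln, "protein_msa"), ref_id %in% rownames(seg_aln),
            min_segment_coverage >= 0, min_segment_coverage <= 1)
  m <- unclass(seg_aln)
  n_ref_cols <- sum(m[ref_id, ] != GAP_CHAR)
  cov <- rowSums(m != GAP_CHAR & m != MASK_CHAR) / n_ref_cols
  drop <- cov < min_segment_coverage
  drop[ref_id] <- FALSE
  if (all(drop)) stop("coverage filter would empty the segment", call. = FALSE)
  kept <- m[!drop, , drop = FALSE]
  class(kept) <- c("protein_msa", class(matrix()))
  list(kept = kept, removed_ids = rownames(m)[drop])
}

#' Mask residues adjacent to indels
#'
#' In each row, any residue within `window` columns of a gap character in
#' that same row is replaced by the mask mark `x`; masked residues are
#' invisible to conservation counting downstream. The reference row is never
#' masked. `window = 0` disables masking.
#'
#' @param seg_aln A `protein_msa`.
#' @param window Non-negative number of columns.
#' @param ref_id Reference row id (exempt from masking), or `NULL`.
#' @return The masked `protein_msa`.
#' @export
mask_near_indels <- function(seg_aln, window, ref_id = NULL) {
  stopifnot(inherits(seg_aln, "protein_msa"), window >= 0)
  if (window == 0) return(seg_aln)
  m <- unclass(seg_aln)
  nc <- ncol(m)
  for (i in seq_len(nrow(m))) {
    if (!is.null(ref_id) && rownames(m)[i] == ref_id) next
    isgap <- m[i, ] == GAP_CHAR
    if (!any(isgap) || all(isgap)) next
    ## distance from every column to the nearest gap column in this row
    d <- .dist_to_true(isgap)
    mask <- !isgap & d <= window & m[i, ] != MASK_CHAR
    m[i, mask] <- MASK_CHAR
  }
  out <- m
  class(out) <- c("protein_msa", class(matrix()))
  attributes(out)$all_gap_ids <- attr(seg_aln, "all_gap_ids")
  out
}

## distance (in positions) from each element to the nearest TRUE; Inf if none
.dist_to_true <- function(flag) {
  n <- length(flag)
  d <- rep(Inf, n)
  last <- -Inf
  for (j in seq_len(n)) {
    if (flag[j]) last <- j
    d[j] <- j - last
  }
  nxt <- Inf
  for (j in rev(seq_len(n))) {
    if (flag[j]) nxt <- j
    d[j] <- min(d[j], nxt - j)
  }
  d
}

#' Reassemble segment alignments into a full-length alignment
#'
#' Segments are concatenated horizontally in order. A row missing from some
#' segment (discarded by QC there) is, under `drop_policy = "gap_fill"`,
#' padded with gaps across that segment and reported; under
#' `drop_policy = "global"` the row is removed from the whole assembly.
#'
#' @param segments List of `protein_msa` objects in segment order, each
#'   containing the reference row.
#' @param ref_id Reference row id.
#' @param drop_policy `"gap_fill"` or `"global"`.
#' @return A `protein_msa`; attribute `gap_filled` is a data.frame of
#'   (id, segment_index) pairs that were padded.
#' @export
reassemble <- function(segments, ref_id, drop_policy = c("gap_fill", "global")) {
  drop_policy <- match.arg(drop_policy)
  stopifnot(length(segments) >= 1L)
  for (s in segments)
    if (!ref_id %in% rownames(s))
      stop("reference row missing from a segment alignment", call. = FALSE)
  id_sets <- lapply(segments, rownames)
  if (drop_policy == "global") {
    ids <- Reduce(intersect, id_sets)
    if (length(ids) == 0L)
      stop("no sequence survives every segment under drop_policy = 'global'",
           call. = FALSE)
    ## preserve first segment's ordering
    ids <- id_sets[[1L]][id_sets[[1L]] %in% ids]
  } else {
    ids <- Reduce(union, id_sets)
    ids <- unique(c(id_sets[[1L]], ids))
  }
  filled <- list()
  blocks <- lapply(seq_along(segments), function(k) {
    m <- unclass(segments[[k]])
    out <- matrix(GAP_CHAR, nrow = length(ids), ncol = ncol(m),
                  dimnames = list(ids, NULL))
    present <- intersect(ids, rownames(m))
    out[present, ] <- m[present, , drop = FALSE]
    absent <- setdiff(ids, rownames(m))
    if (length(absent) > 0L)
      filled[[length(filled) + 1L]] <<- data.frame(id = absent, segment = k,
                                                   stringsAsFactors = FALSE)
    out
  })
  m <- do.call(cbind, blocks)
  out <- m
  class(out) <- c("protein_msa", class(matrix()))
  attr(out, "gap_filled") <- if (length(filled) > 0L) do.call(rbind, filled)
    else data.frame(id = character(0), segment = integer(0))
  ## the result must admit a reference map
  build_reference_map(out, ref_id)
  out
}

#' Curation configuration
#'
#' @param min_segment_coverage Minimum fraction of a segment's reference
#'   columns a row must cover to be kept there (default 0.5: discards
#'   half-missing domain copies without punishing modest truncations).
#' @param indel_mask_window Columns masked on each side of an indel
#'   (default 2; 0 disables).
#' @param ambiguous_set Residues that disqualify a whole sequence.
#' @param aligner An [aligner_spec()].
#' @param drop_policy `"gap_fill"` (default: a row unusable in one domain
#'   still contributes evidence elsewhere) or `"global"`.
#' @return A `curation_config` list.
#' @export
curation_config <- function(min_segment_coverage = 0.5,
                            indel_mask_window = 2L,
                            ambiguous_set = default_ambiguous_set(),
                            aligner = aligner_spec(),
                            drop_policy = c("gap_fill", "global")) {
  stopifnot(min_segment_coverage >= 0, min_segment_coverage <= 1,
            indel_mask_window >= 0)
  structure(list(min_segment_coverage = min_segment_coverage,
                 indel_mask_window = as.integer(indel_mask_window),
                 ambiguous_set = ambiguous_set,
                 aligner = aligner,
                 drop_policy = match.arg(drop_policy)),
            class = "curation_config")
}

#' Run the full domain-wise curation pipeline on an alignment
#'
#' Steps: drop rows with ambiguous residues; partition the reference into
#' segments; slice each segment; drop incomplete rows per segment; realign
#' the segment (center-star on the reference, or external aligner); mask
#' residues near indels; reassemble the full-length alignment.
#'
#' @param aln Full-length `protein_msa` containing the reference row.
#' @param ref_id Reference row id.
#' @param domains A `domain_table`.
#' @param config A [curation_config()].
#' @return List with `alignment` (refined `protein_msa`), `map` (its
#'   `reference_map`), `segments` (`segment_table`) and `report` (data.frame
#'   of id, segment, action, reason).
#' @export
curate_alignment <- function(aln, ref_id, domains, config = curation_config()) {
  stopifnot(inherits(aln, "protein_msa"))
  map <- build_reference_map(aln, ref_id)
  report <- list()
  note <- function(id, segment, action, reason)
    report[[length(report) + 1L]] <<- data.frame(
      id = id, segment = segment, action = action, reason = reason,
      stringsAsFactors = FALSE)

  ## sequence-level QC: ambiguity removal
  seqs <- protein_seqs(rownames(aln), degap(aln, drop_mask = TRUE))
  qc <- drop_ambiguous(seqs, config$ambiguous_set)
  if (nrow(qc$log) > 0L) {
    if (ref_id %in% qc$log$id)
      stop("reference sequence contains ambiguous residues", call. = FALSE)
    for (i in seq_len(nrow(qc$log)))
      note(qc$log$id[i], "(whole sequence)", "removed",
           paste0("ambiguous residue '", qc$log$residue[i], "'"))
    keep <- setdiff(rownames(aln), qc$log$id)
    m <- unclass(aln)[keep, , drop = FALSE]
    aln <- m
    class(aln) <- c("protein_msa", class(matrix()))
    map <- build_reference_map(aln, ref_id)
  }

  segs <- partition_reference(domains, map$L)
  refined <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    seg <- segs[k, ]
    sl <- slice_alignment(aln, map, seg)
    for (id in attr(sl, "all_gap_ids"))
      if (id != ref_id) note(id, seg$name, "flagged", "all-gap in segment")
    fl <- filter_incomplete(sl, config$min_segment_coverage, ref_id)
    for (id in fl$removed_ids)
      note(id, seg$name, "removed",
           sprintf("segment coverage < %.2f", config$min_segment_coverage))
    ungapped <- degap(fl$kept)
    nonempty <- ungapped[nchar(ungapped) > 0L | names(ungapped) == ref_id]
    re <- realign_segment(nonempty, ref_id, config$aligner)
    re <- mask_near_indels(re, config$indel_mask_window, ref_id)
    n_masked <- sum(unclass(re) == MASK_CHAR)
    if (n_masked > 0L)
      note("(segment)", seg$name, "masked",
           sprintf("%d residues within %d columns of an indel", n_masked,
                   config$indel_mask_window))
    refined[[k]] <- re
  }
  out <- reassemble(refined, ref_id, config$drop_policy)
  gf <- attr(out, "gap_filled")
  if (nrow(gf) > 0L)
    for (i in seq_len(nrow(gf)))
      note(gf$id[i], segs$name[gf$segment[i]], "gap_filled",
           "discarded in this segment only")
  report_df <- if (length(report) > 0L) do.call(rbind, report)
    else data.frame(id = character(0), segment = character(0),
                    action = character(0), reason = character(0))
  list(alignment = out, map = build_reference_map(out, ref_id),
       segments = segs, report = report_df)
}
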