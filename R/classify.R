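## Evolutionary tolerance classification of missense variants from
## per-column conservation in a curated ortholog alignment.
##
## Decision rules, evaluated in order for a variant ref_aa>alt_aa at a
## reference position:
##   1. too little signal at the column (depth below min_depth, or gap
##      fraction above max_gap_fraction)                -> UNALIGNABLE
##   2. alt_aa observed in the column: if at least one carrier matches the
##      reference at every adjoining position            -> TOLERANT
##      if every carrier also differs at an adjoining
##      position (co-substitution caveat)               -> UNINTERPRETABLE
##   3. alt_aa unobserved: strict mode                  -> INTOLERANT
##      conservation mode: invariant column or majority
##      frequency >= threshold -> INTOLERANT, else      -> UNINTERPRETABLE

VERDICTS <- c("TOLERANT", "INTOLERANT", "UNINTERPRETABLE", "UNALIGNABLE")

#' Parse a protein-level missense variant token
#'
#' Accepts the compact one-letter form (`E1705K`) and the HGVS-p three-letter
#' form with optional `p.` prefix (`p.Glu1705Lys`). Nonsense (`Ter`, `*`,
#' `X`), frameshift and synonymous tokens are rejected: only single-residue
#' substitutions are classifiable.
#'
#' @param token Variant string.
#' @param label Optional external identifier carried along.
#' @return A `variant_call` list with `pos`, `ref_aa`, `alt_aa`, `label`.
#' @export
parse_variant <- function(token, label = NA_character_) {
  tk <- trimws(token)
  tk <- sub("^p\\.", "", tk)
  tk <- gsub("[()]", "", tk)
  r1 <- regmatches(tk, regexec("^([A-Za-z*])([0-9]+)([A-Za-z*])$", tk))[[1L]]
  r3 <- regmatches(tk, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|\\*)$", tk))[[1L]]
  if (length(r1) == 4L) {
    r <- r1
    ref <- toupper(r[2L]); alt <- toupper(r[4L]); pos <- as.integer(r[3L])
  } else if (length(r3) == 4L) {
    r <- r3
    three <- function(x) {
      if (x == "*") return("*")
      x <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
      if (x == "Ter") return("*")
      if (is.na(AA_THREE_TO_ONE[x]))
        stop("unknown amino-acid code '", x, "' in variant '", token, "'",
             call. = FALSE)
      unname(AA_THREE_TO_ONE[x])
    }
    if (grepl("fs$|Fs$", tk))
      stop("frameshift variants are not supported: '", token, "'", call. = FALSE)
    ref <- three(r[2L]); alt <- three(r[4L]); pos <- as.integer(r[3L])
  } else if (grepl("fs", tk)) {
    stop("frameshift variants are not supported: '", token, "'", call. = FALSE)
  } else {
    stop("cannot parse variant token '", token, "'", call. = FALSE)
  }
  if (ref == "*" || alt == "*")
    stop("nonsense variants are not supported: '", token, "'", call. = FALSE)
  if (!ref %in% CANONICAL_AA || !alt %in% CANONICAL_AA)
    stop("non-canonical residue in variant '", token, "'", call. = FALSE)
  if (ref == alt)
    stop("'", token, "' is not a substitution (reference and alternate residues are equal)",
         call. = FALSE)
  structure(list(pos = pos, ref_aa = ref, alt_aa = alt, label = label),
            class = "variant_call")
}

#' Residue profile of one alignment column
#'
#' Gap characters and mask marks are excluded from the residue counts; they
#' are tallied separately.
#'
#' @param aln A `protein_msa`.
#' @param col 1-based column index.
#' @return A `column_profile` list: `col`, `counts` (named integer vector),
#'   `gap_count`, `masked_count`, `depth`, `observed_set`, `majority_freq`.
#' @export
column_profile <- function(aln, col) {
  stopifnot(inherits(aln, "protein_msa"))
  if (col < 1L || col > ncol(aln))
    stop(sprintf("column %d out of range 1..%d", col, ncol(aln)), call. = FALSE)
  chars <- unclass(aln)[, col]
  gap_count <- sum(chars == GAP_CHAR)
  masked_count <- sum(chars == MASK_CHAR)
  res <- chars[chars != GAP_CHAR & chars != MASK_CHAR]
  counts <- if (length(res) > 0L) table(res) else integer(0)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[order(names(counts))]
  depth <- sum(counts)
  structure(list(col = as.integer(col), counts = counts,
                 gap_count = gap_count, masked_count = masked_count,
                 depth = depth,
                 observed_set = names(counts),
                 majority_freq = if (depth > 0L) max(counts) / depth else 0),
            class = "column_profile")
}

#' Classification configuration
#'
#' @param mode `"strict"` (an unobserved alternate residue is intolerant
#'   regardless of column variability — the default) or `"conservation"`
#'   (unobserved residues are intolerant only at invariant or highly
#'   conserved columns, uninterpretable elsewhere).
#' @param conservation_threshold Majority frequency above which a column
#'   counts as highly conserved in conservation mode (default 0.95).
#' @param adjacency_window Reference positions checked on each side for the
#'   co-substitution caveat (default 1: immediate neighbours).
#' @param max_gap_fraction Columns with a larger gap fraction are
#'   unalignable (default 0.5).
#' @param min_depth Minimum residue depth for a verdict (default 10).
#' @return A `classify_config` list.
#' @export
classify_config <- function(mode = c("strict", "conservation"),
                            conservation_threshold = 0.95,
                            adjacency_window = 1L,
                            max_gap_fraction = 0.5,
                            min_depth = 10L) {
  mode <- match.arg(mode)
  stopifnot(conservation_threshold > 0, conservation_threshold <= 1,
            adjacency_window >= 1, max_gap_fraction >= 0,
            max_gap_fraction <= 1, min_depth >= 1)
  structure(list(mode = mode,
                 conservation_threshold = conservation_threshold,
                 adjacency_window = as.integer(adjacency_window),
                 max_gap_fraction = max_gap_fraction,
                 min_depth = as.integer(min_depth)),
            class = "classify_config")
}

#' Classify one missense variant against a curated alignment
#'
#' @param aln A `protein_msa`.
#' @param map Its `reference_map`.
#' @param v A `variant_call` (or token string parsed on the fly).
#' @param cfg A [classify_config()].
#' @return A `variant_classification` list: `verdict`, `rule`, `variant`,
#'   `profile`, `carriers`, `passing_carriers`, `gap_fraction`.
#' @export
classify_variant <- function(aln, map, v, cfg = classify_config()) {
  stopifnot(inherits(aln, "protein_msa"), inherits(map, "reference_map"))
  if (is.character(v)) v <- parse_variant(v)
  stopifnot(inherits(v, "variant_call"))
  if (v$pos < 1L || v$pos > map$L)
    stop(sprintf("variant position %d outside reference 1..%d", v$pos, map$L),
         call. = FALSE)
  col <- column_of(map, v$pos)
  m <- unclass(aln)
  ref_char <- m[map$ref_id, col]
  if (ref_char != v$ref_aa)
    stop(sprintf("variant/reference mismatch at position %d: reference has %s, variant states %s",
                 v$pos, ref_char, v$ref_aa), call. = FALSE)

  prof <- column_profile(aln, col)
  gap_fraction <- prof$gap_count / nrow(m)
  result <- function(verdict, rule, carriers = character(0),
                     passing = character(0)) {
    structure(list(verdict = verdict, rule = rule, variant = v,
                   profile = prof, carriers = carriers,
                   passing_carriers = passing, gap_fraction = gap_fraction),
              class = "variant_classification")
  }

  ## rule 1: enough evolutionary signal at the column?
  if (prof$depth < cfg$min_depth || gap_fraction > cfg$max_gap_fraction)
    return(result("UNALIGNABLE", "insufficient_signal"))

  if (v$alt_aa %in% prof$observed_set) {
    ## rule 2: observed substitution; co-substitution caveat per carrier
    carriers <- rownames(m)[m[, col] == v$alt_aa]
    nbr_pos <- setdiff(seq(v$pos - cfg$adjacency_window,
                           v$pos + cfg$adjacency_window), v$pos)
    nbr_pos <- nbr_pos[nbr_pos >= 1L & nbr_pos <= map$L]
    nbr_cols <- if (length(nbr_pos) > 0L) column_of(map, nbr_pos) else integer(0)
    passing <- carriers[vapply(carriers, function(id) {
      all(m[id, nbr_cols] == m[map$ref_id, nbr_cols])
    }, logical(1))]
    if (length(passing) > 0L)
      return(result("TOLERANT", "observed_clean_context", carriers, passing))
    return(result("UNINTERPRETABLE", "co_substitution_context", carriers))
  }

  ## rule 3: unobserved substitution
  if (cfg$mode == "strict")
    return(result("INTOLERANT", "unobserved_strict"))
  if (length(prof$observed_set) == 1L ||
      prof$majority_freq >= cfg$conservation_threshold)
    return(result("INTOLERANT", "unobserved_conserved"))
  result("UNINTERPRETABLE", "unobserved_variable")
}

#' Classify a batch of variants
#'
#' Items that fail to parse or mismatch the reference are reported per item
#' (verdict `ERROR`) without aborting the batch.
#'
#' @param aln A `protein_msa`.
#' @param map Its `reference_map`.
#' @param variants Character vector of tokens, list of `variant_call`s, or a
#'   data.frame with columns `label` and `variant`.
#' @param cfg A [classify_config()].
#' @param merge_unalignable Fold `UNALIGNABLE` into `UNINTERPRETABLE` in the
#'   summary (three-way accounting).
#' @return List with `table` (one row per input variant: label, pos, ref,
#'   alt, verdict, rule, depth, gap_fraction, observed_set, carrier_count,
#'   passing_carriers, error) and `summary` (named counts).
#' @export
classify_batch <- function(aln, map, variants, cfg = classify_config(),
                           merge_unalignable = FALSE) {
  items <- .as_variant_list(variants)
  rows <- lapply(items, function(it) {
    base <- data.frame(label = it$label, pos = NA_integer_,
                       ref = NA_character_, alt = NA_character_,
                       verdict = NA_character_, rule = NA_character_,
                       depth = NA_integer_, gap_fraction = NA_real_,
                       observed_set = NA_character_,
                       carrier_count = NA_integer_,
                       passing_carriers = NA_integer_,
                       error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      v <- if (inherits(it$call, "variant_call")) it$call
        else parse_variant(it$token, it$label)
      cl <- classify_variant(aln, map, v, cfg)
      base$pos <- v$pos; base$ref <- v$ref_aa; base$alt <- v$alt_aa
      base$verdict <- cl$verdict; base$rule <- cl$rule
      base$depth <- cl$profile$depth
      base$gap_fraction <- cl$gap_fraction
      base$observed_set <- paste(cl$profile$observed_set, collapse = ",")
      base$carrier_count <- length(cl$carriers)
      base$passing_carriers <- length(cl$passing_carriers)
      base
    }, error = function(e) {
      base$verdict <- "ERROR"
      base$error <- conditionMessage(e)
      base
    })
    res
  })
  tab <- if (length(rows) > 0L) do.call(rbind, rows)
    else data.frame(label = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    verdict = character(0), rule = character(0),
                    depth = integer(0), gap_fraction = numeric(0),
                    observed_set = character(0), carrier_count = integer(0),
                    passing_carriers = integer(0), error = character(0),
                    stringsAsFactors = FALSE)
  vd <- tab$verdict
  if (merge_unalignable)
    vd[vd == "UNALIGNABLE"] <- "UNINTERPRETABLE"
  lev <- c(VERDICTS, "ERROR")
  if (merge_unalignable) lev <- setdiff(lev, "UNALIGNABLE")
  summary <- vapply(lev, function(x) sum(vd == x, na.rm = TRUE), integer(1))
  names(summary) <- tolower(names(summary))
  list(table = tab, summary = summary)
}

.as_variant_list <- function(variants) {
  if (is.data.frame(variants)) {
    if (!all(c("label", "variant") %in% names(variants)))
      stop("variant data.frame needs columns label, variant", call. = FALSE)
    return(lapply(seq_len(nrow(variants)), function(i)
      list(token = variants$variant[i], label = variants$label[i], call = NULL)))
  }
  if (is.character(variants)) {
    lbl <- if (!is.null(names(variants))) names(variants)
      else rep(NA_character_, length(variants))
    return(lapply(seq_along(variants), function(i)
      list(token = variants[[i]], label = lbl[i], call = NULL)))
  }
  lapply(variants, function(v) {
    if (inherits(v, "variant_call")) list(token = NA, label = v$label, call = v)
    else list(token = as.character(v), label = NA_character_, call = NULL)
  })
}

#' Read a variant list file
#'
#' Either a TSV with header columns `label` and `variant`, or bare
#' one-token-per-line text (no header).
#'
#' @param file Path.
#' @return Data.frame with columns `label`, `variant`.
#' @export
read_variants <- function(file) {
  first <- readLines(file, n = 1L)
  if (grepl("\t", first) && grepl("variant", first, ignore.case = TRUE)) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (!all(c("label", "variant") %in% names(d)))
      stop("variant TSV must have columns label, variant", call. = FALSE)
    return(d[, c("label", "variant")])
  }
  tokens <- trimws(readLines(file))
  tokens <- tokens[nzchar(tokens)]
  data.frame(label = tokens, variant = tokens, stringsAsFactors = FALSE)
}

#' @export
print.variant_classification <- function(x, ...) {
  v <- x$variant
  cat(sprintf("%s%d%s: %s (%s)\n", v$ref_aa, v$pos, v$alt_aa, x$verdict, x$rule))
  cat(sprintf("  column %d: depth %d, observed {%s}, gap fraction %.2f\n",
              x$profile$col, x$profile$depth,
              paste(x$profile$observed_set, collapse = ","), x$gap_fraction))
  if (length(x$carriers) > 0L)
    cat(sprintf("  carriers: %d (%d with reference-matching context)\n",
                length(x$carriers), length(x$passing_carriers)))
  invisible(x)
}
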