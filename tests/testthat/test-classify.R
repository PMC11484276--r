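test_that("variant tokens parse in one-letter and HGVS-p forms", {
  v <- parse_variant("E1705K")
  expect_equal(v$pos, 1705L)
  expect_equal(v$ref_aa, "E")
  expect_equal(v$alt_aa, "K")

  v3 <- parse_variant("p.Met1808Leu")
  expect_equal(list(v3$pos, v3$ref_aa, v3$alt_aa), list(1808L, "M", "L"))
  expect_equal(parse_variant("Tyr124His")$alt_aa, "H")

  expect_error(parse_variant("E1705E"), "not a substitution")
  expect_error(parse_variant("p.Glu1705Ter"), "nonsense")
  expect_error(parse_variant("M1808fs"), "frameshift")
  expect_error(parse_variant("banana"), "cannot parse")
})

test_that("column profiles exclude gaps and masks from residue counts", {
  aln <- protein_msa(c(a = "E", b = "E", c = "E", d = "-"))
  p <- column_profile(aln, 1L)
  expect_equal(unname(p$counts["E"]), 3L)
  expect_equal(p$gap_count, 1L)
  expect_equal(p$depth, 3L)
  expect_equal(p$majority_freq, 1.0)

  aln2 <- protein_msa(c(a = "E", b = "K", c = "x", d = "N"))
  p2 <- column_profile(aln2, 1L)
  expect_equal(p2$masked_count, 1L)
  expect_setequal(p2$observed_set, c("E", "K", "N"))
  expect_equal(p2$depth + p2$gap_count + p2$masked_count, 4L)

  # random columns against a naive tally
  set.seed(107)
  for (trial in 1:20) {
    mat <- random_alignment()
    j <- sample(ncol(mat), 1)
    p3 <- column_profile(as_msa(mat), j)
    chars <- mat[, j]
    expect_equal(p3$gap_count, sum(chars == "-"))
    expect_equal(p3$masked_count, sum(chars == "x"))
    expect_equal(p3$depth, sum(chars != "-" & chars != "x"))
  }
})

shallow_cfg <- function(...) classify_config(min_depth = 2, ...)

test_that("decision rules: invariant, observed-clean, co-substitution, unalignable", {
  # invariant column, unobserved alternate: intolerant
  inv <- protein_msa(c(REF = "TEG", a = "TEG", b = "TEG", c = "TEG"))
  map <- build_reference_map(inv, "REF")
  expect_equal(classify_variant(inv, map, "E2K", shallow_cfg())$verdict,
               "INTOLERANT")

  # observed alternate with a reference-matching context: tolerant
  obs <- protein_msa(c(REF = "TEG", a = "TKG", b = "TNG", c = "TEG"))
  mo <- build_reference_map(obs, "REF")
  cl <- classify_variant(obs, mo, "E2K", shallow_cfg())
  expect_equal(cl$verdict, "TOLERANT")
  expect_equal(cl$carriers, "a")
  expect_equal(cl$passing_carriers, "a")

  # the only carrier also differs at an adjoining position: uninterpretable
  co <- protein_msa(c(REF = "TEG", a = "TKA", b = "TEG", c = "TEG"))
  mc <- build_reference_map(co, "REF")
  expect_equal(classify_variant(co, mc, "E2K", shallow_cfg())$verdict,
               "UNINTERPRETABLE")
  # a gap at the adjoining position also disqualifies the carrier
  cog <- protein_msa(c(REF = "TEG", a = "TK-", b = "TEG", c = "TEG"))
  mg <- build_reference_map(cog, "REF")
  expect_equal(classify_variant(cog, mg, "E2K", shallow_cfg())$verdict,
               "UNINTERPRETABLE")

  # thin or gappy columns are unalignable, not classified
  thin <- protein_msa(c(REF = "TEG", a = "T-G", b = "T-G", c = "T-G"))
  mt <- build_reference_map(thin, "REF")
  expect_equal(classify_variant(thin, mt, "E2K", shallow_cfg())$verdict,
               "UNALIGNABLE")
})

test_that("a single clean carrier certifies only its own substitution", {
  # one sequence carries C at the queried position with a clean context;
  # H is never observed there: C tolerated, H not (strict mode)
  rows <- c(REF = "AYD", p1 = "ACD", p2 = "AYD", p3 = "AYD", p4 = "AYD")
  aln <- protein_msa(rows)
  map <- build_reference_map(aln, "REF")
  expect_equal(classify_variant(aln, map, "Y2C", shallow_cfg())$verdict,
               "TOLERANT")
  expect_equal(classify_variant(aln, map, "Y2H", shallow_cfg())$verdict,
               "INTOLERANT")
})

test_that("conservation mode separates conserved from variable columns", {
  vr <- protein_msa(c(REF = "TEG", a = "TKG", b = "TNG", c = "TDG",
                      d = "TEG", e = "TKG"))
  mv <- build_reference_map(vr, "REF")
  # unobserved alternate at a variable column
  expect_equal(
    classify_variant(vr, mv, "E2W", shallow_cfg(mode = "conservation"))$verdict,
    "UNINTERPRETABLE")
  expect_equal(classify_variant(vr, mv, "E2W", shallow_cfg())$verdict,
               "INTOLERANT")
  # highly conserved column: intolerant in both modes
  hc <- protein_msa(c(REF = "TEG", a = "TEG", b = "TEG", c = "TEG",
                      d = "TEG", e = "TKG"))
  mh <- build_reference_map(hc, "REF")
  expect_equal(
    classify_variant(hc, mh, "E2W",
                     shallow_cfg(mode = "conservation",
                                 conservation_threshold = 0.8))$verdict,
    "INTOLERANT")
})

test_that("variant/reference mismatches and bad positions are errors", {
  aln <- protein_msa(c(REF = "TEG", a = "TEG"))
  map <- build_reference_map(aln, "REF")
  expect_error(classify_variant(aln, map, "K2E", shallow_cfg()), "mismatch")
  expect_error(classify_variant(aln, map, "E9K", shallow_cfg()), "outside")
})

test_that("batch classification preserves order, collects errors, sums up", {
  aln <- protein_msa(c(REF = "TEG", a = "TKG", b = "TEG", c = "TEG"))
  map <- build_reference_map(aln, "REF")
  res <- classify_batch(aln, map, c("E2K", "E2W", "Q9R", "junk"),
                        shallow_cfg())
  expect_equal(nrow(res$table), 4L)
  expect_equal(res$table$verdict, c("TOLERANT", "INTOLERANT", "ERROR", "ERROR"))
  expect_equal(sum(res$summary), 4L)
  expect_equal(unname(res$summary["error"]), 2L)

  empty <- classify_batch(aln, map, character(0), shallow_cfg())
  expect_equal(nrow(empty$table), 0L)
  expect_true(all(empty$summary == 0L))

  # duplicates are counted twice
  dup <- classify_batch(aln, map, c("E2K", "E2K"), shallow_cfg())
  expect_equal(unname(dup$summary["tolerant"]), 2L)

  # unalignable folding for three-way accounting
  thin <- protein_msa(c(REF = "TEG", a = "T-G", b = "T-G", c = "T-G"))
  mt <- build_reference_map(thin, "REF")
  merged <- classify_batch(thin, mt, "E2K", shallow_cfg(),
                           merge_unalignable = TRUE)
  expect_false("unalignable" %in% names(merged$summary))
  expect_equal(unname(merged$summary["uninterpretable"]), 1L)
})

test_that("verdicts are invariant under row permutation and duplication", {
  set.seed(113)
  for (trial in 1:30) {
    mat <- random_alignment()
    cfg <- shallow_cfg()
    pos <- sample(sum(mat["REF", ] != "-"), 1)
    ref_aa <- mat["REF", which(mat["REF", ] != "-")[pos]]
    alt <- sample(setdiff(c("A", "C", "D", "E", "K", "N"), ref_aa), 1)
    aln <- as_msa(mat)
    map <- build_reference_map(aln, "REF")
    v <- parse_variant(paste0(ref_aa, pos, alt))
    base <- classify_variant(aln, map, v, cfg)$verdict

    perm <- mat[sample(nrow(mat)), , drop = FALSE]
    aln_p <- as_msa(perm)
    expect_equal(classify_variant(aln_p, build_reference_map(aln_p, "REF"),
                                  v, cfg)$verdict, base)
  }
})
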