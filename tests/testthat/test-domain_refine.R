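dicer_domains <- function() {
  read_domain_table(system.file("extdata", "dicer1_domains.tsv",
                                package = "orthotol"))
}

test_that("domain table reading: sorting, validation, overlap detection", {
  d <- dicer_domains()
  expect_equal(nrow(d), 7L)
  expect_equal(d$name[1], "Helicase ATP-binding domain")
  expect_equal(d$rule_id[1], "PRU00541")
  expect_equal(d$start[1], 51L)
  expect_equal(d$end[1], 227L)
  expect_equal(max(d$end), 1914L)

  expect_error(
    read_domain_table(text = "name\trule_id\tstart\tend\nA\t.\t10\t20\nB\t.\t15\t30"),
    "overlap.*A.*B")
  expect_error(
    read_domain_table(text = "name\trule_id\tstart\tend\nA\t.\t20\t10"),
    "start > end|invalid")

  shuffled <- "name\trule_id\tstart\tend\nB\t.\t40\t60\nA\t.\t5\t20\nC\t.\t70\t90"
  expect_equal(read_domain_table(text = shuffled)$name, c("A", "B", "C"))
})

test_that("the seven-domain table over a full-length reference tiles into 15 segments", {
  segs <- partition_reference(dicer_domains(), 1922L)
  expect_equal(nrow(segs), 15L)
  expect_equal(segs$kind[1], "initial")
  expect_equal(c(segs$start[1], segs$end[1]), c(1L, 50L))
  expect_equal(segs$kind[2], "domain")
  expect_equal(segs$name[2], "Helicase ATP-binding domain")
  expect_equal(c(segs$start[2], segs$end[2]), c(51L, 227L))
  expect_equal(segs$kind[15], "terminal")
  # exact tiling of 1..L
  expect_equal(segs$start[1], 1L)
  expect_equal(segs$end[15], 1922L)
  expect_true(all(segs$start[-1] == head(segs$end, -1) + 1L))
})

test_that("degenerate partitions: single spanning domain, domain beyond L", {
  one <- read_domain_table(text = "name\trule_id\tstart\tend\nwhole\t.\t1\t100")
  segs <- partition_reference(one, 100L)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$kind, "domain")
  expect_error(partition_reference(one, 99L), "beyond")
})

test_that("segment counts match an interval-scan oracle on random domain sets", {
  set.seed(31)
  for (trial in 1:30) {
    L <- sample(50:200, 1)
    k <- sample(1:6, 1)
    bounds <- sort(sample(L, 2 * k))
    dom <- data.frame(name = paste0("d", 1:k), rule_id = ".",
                      start = bounds[seq(1, 2 * k, 2)],
                      end = bounds[seq(2, 2 * k, 2)])
    # drop abutting/overlapping pairs the sampler may produce
    keep <- rep(TRUE, k)
    for (i in seq_len(k - 1)) if (dom$start[i + 1] <= dom$end[i] + 1) keep[i + 1] <- FALSE
    dom <- dom[keep, ]
    segs <- partition_reference(dom, L)
    expect_equal(nrow(segs), oracle_segment_count(dom, L))
    expect_equal(sum(segs$end - segs$start + 1L), L)  # tiling, no overlap
    # 2k+1 law when flanks exist and domains are non-abutting
    if (dom$start[1] > 1 && dom$end[nrow(dom)] < L)
      expect_equal(nrow(segs), 2L * nrow(dom) + 1L)
  }
})

test_that("slice_alignment carries interior insertions and flags all-gap rows", {
  aln <- protein_msa(c(REF = "MK-VD", a = "MKRVD", b = "M---D"))
  map <- build_reference_map(aln, "REF")
  seg <- list(start = 2L, end = 3L)
  sl <- slice_alignment(aln, map, seg, include_trailing_insertions = FALSE)
  expect_equal(unname(msa_strings(sl)["REF"]), "K-V")
  expect_equal(unname(msa_strings(sl)["a"]), "KRV")
  expect_equal(attr(sl, "all_gap_ids"), "b")

  # slice of the whole reference is the whole alignment
  whole <- slice_alignment(aln, map, list(start = 1L, end = 4L))
  expect_equal(msa_strings(whole), msa_strings(aln))
})

test_that("slices of a full partition reassemble to the original alignment", {
  fx <- generate_msa(fixture_spec(seed = 41, n_rows = 12, L = 60,
                                  paralog_rows = 2, n_insertions = 3))
  aln <- fx$alignment
  map <- fx$map
  dom <- data.frame(name = c("d1", "d2"), rule_id = ".",
                    start = c(10L, 40L), end = c(25L, 50L))
  segs <- partition_reference(dom, map$L)
  slices <- lapply(seq_len(nrow(segs)), function(k)
    slice_alignment(aln, map, segs[k, ]))
  # column tiling with trailing-insertion attachment is exact
  widths <- vapply(slices, ncol, 1L)
  expect_equal(sum(widths), map$n_cols)
  rebuilt <- reassemble(slices, "REF")
  expect_equal(msa_strings(rebuilt), msa_strings(aln))
  # degapping the reference across concatenated slices gives the reference
  expect_equal(unname(degap(rebuilt)["REF"]), unname(degap(aln)["REF"]))
})

test_that("coverage filter drops rows below threshold, never the reference", {
  aln <- protein_msa(c(REF = "MKVDE", a = "M----", b = "MKVDE"))
  res <- filter_incomplete(aln, 0.5, "REF")
  expect_equal(res$removed_ids, "a")
  expect_equal(rownames(res$kept), c("REF", "b"))

  res0 <- filter_incomplete(aln, 0, "REF")
  expect_equal(length(res0$removed_ids), 0L)

  # planted truncations in a generated fixture are exactly what gets removed
  fx <- generate_msa(fixture_spec(seed = 53, n_rows = 20, L = 60,
                                  paralog_rows = 0, indel_rate = 0,
                                  truncation_fraction = 0.25,
                                  ambiguous_rate = 0, n_insertions = 0))
  truncated <- names(which(fx$truth$truncated))
  res2 <- filter_incomplete(fx$alignment, 0.75, "REF")
  expect_setequal(res2$removed_ids, truncated)
})

test_that("indel-proximity masking matches a brute-force distance transform", {
  aln <- protein_msa(c(REF = "AKKVDA", a = "AK--VD"))
  out <- mask_near_indels(aln, 1L, "REF")
  expect_equal(unname(msa_strings(out)["a"]), "Ax--xD")
  expect_equal(unname(msa_strings(out)["REF"]), "AKKVDA")
  expect_equal(msa_strings(mask_near_indels(aln, 0L, "REF")),
               msa_strings(aln))

  set.seed(61)
  for (trial in 1:20) {
    mat <- random_alignment(mask_p = 0)
    w <- sample(0:4, 1)
    got <- mask_near_indels(as_msa(mat), w, "REF")
    expect_equal(unclass(got)[rownames(mat), ], oracle_mask(mat, w, "REF"),
                 ignore_attr = TRUE)
  }
})

test_that("reassemble gap-fills rows discarded in a single segment", {
  s1 <- protein_msa(c(REF = "MK", a = "MK", b = "MK"))
  s2 <- protein_msa(c(REF = "VD", b = "VD"))          # 'a' failed QC here
  s3 <- protein_msa(c(REF = "EW", a = "EW", b = "EW"))
  out <- reassemble(list(s1, s2, s3), "REF", drop_policy = "gap_fill")
  expect_equal(unname(msa_strings(out)["a"]), "MK--EW")
  expect_equal(attr(out, "gap_filled")$id, "a")
  expect_equal(attr(out, "gap_filled")$segment, 2L)

  glob <- reassemble(list(s1, s2, s3), "REF", drop_policy = "global")
  expect_setequal(rownames(glob), c("REF", "b"))
})

test_that("realignment changes gaps, never residues, across the pipeline", {
  fx <- generate_msa(fixture_spec(seed = 71, n_rows = 15, L = 70,
                                  paralog_rows = 0, ambiguous_rate = 0))
  dom <- read_domain_table(text = "name\trule_id\tstart\tend\nd1\t.\t15\t40")
  res <- curate_alignment(fx$alignment, "REF", dom,
                          curation_config(indel_mask_window = 0))
  removed <- unique(res$report$id[res$report$action == "removed"])
  gap_filled <- unique(res$report$id[res$report$action == "gap_filled"])
  intact <- setdiff(rownames(res$alignment), c(removed, gap_filled))
  orig <- degap(fx$alignment)
  refined <- degap(res$alignment)
  for (id in intact) expect_equal(refined[[id]], orig[[id]])
})
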