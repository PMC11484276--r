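test_that("newick reading preserves leaves and rejects duplicates", {
  tr <- read_newick(text = "((a,b),c);")
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  expect_error(read_newick(text = "((a,b),a);"), "duplicate.*a")

  # write/read round trip preserves topology (bipartitions)
  set.seed(97)
  tr2 <- ape::rtree(10)
  tf <- tempfile(fileext = ".nwk")
  ape::write.tree(tr2, tf)
  back <- read_newick(tf)
  expect_equal(suppressWarnings(as.numeric(ape::dist.topo(tr2, back))), 0)
})

test_that("ortholog clade selection on forced topologies", {
  tr <- read_newick(text = "((ref,a),(p1,p2));")
  expect_setequal(select_ortholog_clade(tr, "ref", c("p1", "p2")),
                  c("ref", "a"))

  tr2 <- read_newick(text = "(ref,p1);")
  expect_warning(sel <- select_ortholog_clade(tr2, "ref", "p1"),
                 "reference leaf itself")
  expect_equal(sel, "ref")

  expect_error(select_ortholog_clade(tr, "zz", "p1"), "not in tree")
  expect_error(select_ortholog_clade(tr, "ref", character(0)), "non-empty")
  expect_error(select_ortholog_clade(tr, "ref", "ref"), "cannot be a paralog")
})

test_that("selection matches exhaustive clade enumeration on random trees", {
  set.seed(103)
  for (trial in 1:60) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    ref <- "t1"
    paralogs <- paste0("t", sample(2:n, sample(1:3, 1)))
    got <- suppressWarnings(select_ortholog_clade(tr, ref, paralogs))
    want <- oracle_clade(tr, ref, paralogs)
    expect_setequal(got, want)
    expect_true(ref %in% got)
    expect_length(intersect(got, paralogs), 0)
  }
})

test_that("support threshold never enlarges the selected clade", {
  # supports: clade (ref,a,b) has support 40, nested (ref,a) has 95
  tr <- read_newick(text = "(((ref,a)95,b)40,(p1,p2)99)root;")
  full <- select_ortholog_clade(tr, "ref", c("p1", "p2"))
  expect_setequal(full, c("ref", "a", "b"))
  supported <- select_ortholog_clade(tr, "ref", c("p1", "p2"), min_support = 80)
  expect_setequal(supported, c("ref", "a"))
  # monotonicity across thresholds
  sizes <- vapply(c(0, 40, 80, 96), function(ms)
    length(suppressWarnings(
      select_ortholog_clade(tr, "ref", c("p1", "p2"), min_support = ms))), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("unrooted trees are rooted on the paralog outgroup first", {
  tr <- ape::unroot(read_newick(text = "((ref,(a,b)),(p1,p2));"))
  expect_false(ape::is.rooted(tr))
  got <- select_ortholog_clade(tr, "ref", c("p1", "p2"))
  expect_setequal(got, c("ref", "a", "b"))
})

test_that("species-level paralog exclusion removes exactly the flagged ids", {
  ids <- c("h_ref", "fly_d1", "worm_d1")
  sp <- c(h_ref = "Homo sapiens", fly_d1 = "Drosophila melanogaster",
          worm_d1 = "Caenorhabditis elegans")
  out <- exclude_species_with_paralog(ids, sp, "Drosophila melanogaster")
  expect_equal(out$kept, c("h_ref", "worm_d1"))
  expect_equal(out$removed, "fly_d1")

  expect_equal(exclude_species_with_paralog(ids, sp, character(0))$kept, ids)
  expect_error(exclude_species_with_paralog(c(ids, "zz"), sp, "x"), "zz")

  # planted dual-paralog species in the generated fixture world
  fx_ids <- c(paste0("orth", 1:5), "REF")
  fx_sp <- setNames(paste0("sp", c(1, 2, 3, 2, 4, 0)), fx_ids)
  dual <- c("sp2")
  out2 <- exclude_species_with_paralog(fx_ids, fx_sp, dual)
  expect_setequal(out2$removed, c("orth2", "orth4"))
})

test_that("generated trees recover the planted ortholog/paralog split", {
  for (seed in c(5, 17, 29)) {
    spec <- fixture_spec(seed = seed, n_rows = 10, paralog_rows = 3)
    tr <- generate_tree(spec)
    sel <- select_ortholog_clade(tr, "REF", paste0("para0", 1:3))
    expect_setequal(sel, c("REF", sprintf("orth%02d", 1:9)))
    # determinism
    expect_identical(ape::write.tree(generate_tree(spec)), ape::write.tree(tr))
  }
})
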