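make_bm <- function(rows, sizes = NULL) {
  band_matrix(do.call(rbind, rows),
              strain_ids = names(rows),
              sizes = sizes)
}

test_that("band distances implement the three coefficients", {
  expect_equal(band_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(band_distance(c(1, 1, 0, 0), c(0, 0, 1, 1), "jaccard"), 1)
  expect_equal(band_distance(c(1, 1, 0, 0), c(0, 0, 1, 1), "dice"), 1)
  expect_equal(band_distance(c(1, 1, 0, 0), c(1, 0, 1, 0), "jaccard"), 2 / 3)
  expect_equal(band_distance(c(1, 1, 0, 0), c(1, 0, 1, 0), "dice"), 0.5)
  expect_equal(band_distance(c(1, 1, 0, 0), c(1, 0, 1, 0), "simple_matching"),
               0.5)
  expect_error(band_distance(c(1, 0), c(1, 0, 1)), "equal length")
  expect_warning(d0 <- band_distance(c(0, 0), c(0, 0), "jaccard"), "empty")
  expect_equal(d0, 0)
})

test_that("coefficients are symmetric and identify identical patterns", {
  set.seed(111)
  for (coef in c("jaccard", "dice", "simple_matching")) {
    for (i in 1:10) {
      a <- stats::rbinom(12, 1, 0.5); b <- stats::rbinom(12, 1, 0.5)
      if (sum(a) == 0) a[1] <- 1
      if (sum(b) == 0) b[1] <- 1
      expect_equal(band_distance(a, b, coef), band_distance(b, a, coef))
      expect_equal(band_distance(a, a, coef), 0)
      if (any(a != b)) expect_gt(band_distance(a, b, coef), 0)
    }
  }
})

test_that("size filtering keeps bands strictly above the threshold", {
  bm <- make_bm(list(s1 = c(1, 1), s2 = c(1, 0)), sizes = c(1200, 500))
  kept <- filter_bands(bm, 1000)
  expect_equal(ncol(kept$presence), 1L)
  expect_equal(kept$sizes, 1200)
  # boundary: exactly 1000 bp is dropped under the strict rule
  bm2 <- make_bm(list(s1 = c(1, 1)), sizes = c(1000, 1200))
  expect_equal(ncol(filter_bands(bm2, 1000)$presence), 1L)
  expect_equal(ncol(filter_bands(bm2, 1000, strict = FALSE)$presence), 2L)
  expect_identical(filter_bands(bm, 0), bm)
  no_sizes <- make_bm(list(s1 = c(1, 1)))
  expect_error(filter_bands(no_sizes, 1000), "no fragment sizes")
  expect_warning(filter_bands(bm, 5000), "below the size threshold")
})

test_that("strains emptied by filtering are kept and flagged", {
  bm <- make_bm(list(s1 = c(1, 1), s2 = c(0, 1)), sizes = c(2000, 800))
  expect_warning(kept <- filter_bands(bm, 1000), "s2")
  expect_equal(rownames(kept$presence), c("s1", "s2"))
})

test_that("UPGMA joins two leaves at half their distance", {
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- upgma(d)
  expect_equal(tree$merge_heights, 1.5)
  expect_equal(unname(tree_cophenetic(tree, c("A", "B"))[1, 2]), 3)
})

test_that("UPGMA agglomerates a three-leaf matrix by hand-derivable heights", {
  ids <- c("A", "B", "C")
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, dimnames = list(ids, ids))
  tree <- upgma(d)
  expect_equal(tree$newick, "((A:1,B:1):2,C:3);")
  expect_equal(tree$merge_heights, c(1, 3))
})

test_that("identical patterns give a zero-length cherry", {
  d <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- upgma(d)
  expect_equal(min(tree$merge_heights), 0)
  expect_true(ape::is.ultrametric(tree$phylo))
})

test_that("bad distance matrices are rejected", {
  d <- matrix(c(0, NA, NA, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(upgma(d), "free of NA")
  d2 <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(upgma(d2), "nonnegative")
  expect_error(upgma(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "at least two")
})

test_that("UPGMA trees are ultrametric and match average-linkage hclust", {
  set.seed(121)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    ids <- sprintf("s%02d", seq_len(n))
    m <- matrix(stats::runif(n * n), n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(ids, ids)
    tree <- upgma(d)
    # ultrametric within tolerance
    depths <- ape::node.depth.edgelength(tree$phylo)
    leaf_depths <- depths[seq_len(n)]
    expect_lt(diff(range(leaf_depths)), 1e-9)
    # independent route: stats::hclust average linkage cophenetic
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(tree_cophenetic(tree, ids),
                 as.matrix(stats::cophenetic(hc))[ids, ids],
                 tolerance = 1e-9)
  }
})

test_that("pattern counting groups identical rows and lists pairs", {
  bm <- make_bm(list(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 1, 1)))
  pat <- distinct_patterns(bm)
  expect_equal(pat$n_patterns, 2L)
  expect_equal(nrow(pat$undistinguishable_pairs), 1L)
  expect_equal(unname(pat$undistinguishable_pairs[1, ]), c("a", "b"))

  all_diff <- make_bm(list(a = c(1, 0), b = c(0, 1), c = c(1, 1)))
  expect_equal(distinct_patterns(all_diff)$n_patterns, 3L)
  one <- make_bm(list(a = c(1, 0)))
  expect_equal(distinct_patterns(one)$n_patterns, 1L)
})

test_that("pattern counts are invariant under row and column permutation", {
  set.seed(131)
  pres <- matrix(stats::rbinom(8 * 10, 1, 0.5), nrow = 8,
                 dimnames = list(letters[1:8], NULL))
  base_n <- distinct_patterns(band_matrix(pres))$n_patterns
  for (i in 1:5) {
    rp <- sample(8); cp <- sample(10)
    perm <- pres[rp, cp]
    expect_equal(distinct_patterns(band_matrix(perm))$n_patterns, base_n)
  }
})

test_that("band matrices round-trip through CSV with a size row", {
  pres <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 2,
                 dimnames = list(c("s1", "s2"), c("b1", "b2", "b3")))
  path <- tempfile(fileext = ".csv")
  tab <- rbind(size = c(1500, 900, 2000), pres)
  utils::write.csv(tab, path)
  bm <- read_band_matrix(path)
  storage.mode(pres) <- "integer"
  expect_equal(bm$presence, pres)
  expect_equal(bm$sizes, c(1500, 900, 2000))
  expect_equal(ncol(filter_bands(bm, 1000)$presence), 2L)
})
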