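test_that("single-sequence scan finds and types ambiguous sites", {
  none <- scan_sequence("ACGT")
  expect_equal(none$census$n_variable, 0L)
  expect_equal(nrow(none$sites), 0L)

  two <- scan_sequence("AYGR")
  expect_equal(two$sites$position, c(2L, 4L))
  expect_equal(two$sites$morphism, c("SND", "SND"))
  expect_equal(two$census$n_transitions, 2L)
  expect_equal(two$census$n_transversions, 0L)

  mix <- scan_sequence("AWSN")
  expect_equal(mix$sites$position, 2:4)
  expect_equal(mix$sites$morphism, c("SND", "SND", "SNP"))
  expect_equal(mix$sites$substitution[1:2],
               c("transversion", "transversion"))
  expect_true(is.na(mix$sites$substitution[3]))
})

test_that("illegal characters are rejected with their position", {
  expect_error(scan_sequence("ACXG"), "position 3")
})

test_that("alignment scan unions expansions and flags indel columns", {
  expect_equal(scan_alignment(c(a = "ACGT", b = "ACGT"))$census$n_variable, 0L)

  one <- scan_alignment(c(a = "ACYT", b = "ACCT"))
  expect_equal(one$sites$position, 3L)
  expect_equal(one$sites$code, "Y")
  expect_equal(one$sites$morphism, "SND")

  gap <- scan_alignment(c(a = "AC-T", b = "ACGT"))
  expect_equal(gap$census$n_indel_columns, 1L)
  expect_equal(gap$census$n_variable, 0L)
  expect_equal(gap$census$n_indel_events, 1L)
})

test_that("length mismatches name the offending ids", {
  expect_error(scan_alignment(c(ok = "ACGT", bad = "ACG")), "bad")
})

test_that("a gap run in one sequence is a single indel event", {
  cen <- scan_alignment(c(a = "A---CG", b = "ATTTCG"))
  expect_equal(cen$census$n_indel_columns, 3L)
  expect_equal(cen$census$n_indel_events, 1L)
})

test_that("scan of a singleton alignment equals the sequence scan", {
  set.seed(21)
  for (i in 1:10) {
    s <- random_ambiguous_seq(60, sample(0:8, 1))
    a <- scan_sequence(s)
    b <- scan_alignment(stats::setNames(s, "x"))
    expect_equal(a$sites, b$sites)
    expect_equal(a$census[setdiff(names(a$census), "per_sequence_counts")],
                 b$census[setdiff(names(b$census), "per_sequence_counts")])
  }
})

test_that("census counts are conserved on random inputs", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:4, 1)
    L <- sample(30:80, 1)
    seqs <- vapply(seq_len(n), function(j)
      random_ambiguous_seq(L, sample(0:10, 1)), character(1))
    names(seqs) <- paste0("s", seq_len(n))
    cen <- scan_alignment(seqs)$census
    expect_equal(cen$n_variable, cen$n_SND + cen$n_SNT + cen$n_SNP)
    expect_equal(cen$n_SND, cen$n_transitions + cen$n_transversions)
  }
})

test_that("block detection applies the run rule", {
  b <- detect_blocks(c(10L, 12L, 15L, 100L, 101L, 300L),
                     max_gap = 10, min_block_sites = 2)
  expect_equal(b$label, c("I", "II"))
  expect_equal(b$start, c(10L, 100L))
  expect_equal(b$end, c(15L, 101L))
  expect_equal(b$site_count, c(3L, 2L))

  expect_equal(nrow(detect_blocks(integer(0))), 0L)
  single <- detect_blocks(50L, min_block_sites = 1)
  expect_equal(single[, c("start", "end")],
               data.frame(start = 50L, end = 50L))
  expect_error(detect_blocks(c(5L, 3L)), "increasing")
})

test_that("blocks are disjoint, ordered, and never exceed the site count", {
  set.seed(41)
  for (i in 1:15) {
    pos <- sort(sample.int(500, sample(3:40, 1)))
    b <- detect_blocks(pos, max_gap = sample(1:20, 1),
                       min_block_sites = sample(1:3, 1))
    if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    expect_lte(sum(b$site_count), length(pos))
    expect_true(all(b$start <= b$end))
  }
})

test_that("pairwise divergence follows the two site models", {
  expect_equal(pairwise_census("ACGT", "ACGT"), 0)
  expect_equal(pairwise_census("ACGT", "ACGT", "incompatibility"), 0)
  expect_equal(pairwise_census("AY", "AC"), 0.25)
  expect_equal(pairwise_census("AY", "AC", "incompatibility"), 0)
  expect_equal(pairwise_census("AG", "AT"), 0.5)
  expect_equal(pairwise_census("AG", "AT", "incompatibility"), 0.5)
  expect_error(pairwise_census("ACG", "AC"), "equal length")
})

test_that("both models reduce to Hamming p-distance without ambiguity", {
  set.seed(51)
  for (i in 1:20) {
    L <- sample(10:60, 1)
    a <- random_ambiguous_seq(L, 0)
    b <- random_ambiguous_seq(L, 0)
    ham <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(pairwise_census(a, b), ham)
    expect_equal(pairwise_census(a, b, "incompatibility"), ham)
  }
})
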