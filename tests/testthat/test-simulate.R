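test_that("chimera simulation plants exactly the requested differences", {
  same <- simulate_chimera(100, n_diff_sites = 0, seed = 1)
  expect_equal(same$alleles[["allele1"]], same$alleles[["allele2"]])

  for (k in c(1, 7, 23)) {
    sim <- simulate_chimera(150, n_diff_sites = k, seed = k)
    a <- strsplit(sim$alleles[["allele1"]], "")[[1]]
    b <- strsplit(sim$alleles[["allele2"]], "")[[1]]
    expect_equal(sum(a != b), k)
    expect_equal(which(a != b), sim$truth$position)
  }
})

test_that("a transition bias of one yields only transitions", {
  sim <- simulate_chimera(200, n_diff_sites = 30, transition_bias = 1,
                          seed = 5)
  types <- mapply(function(r, a) substitution_type(c(r, a)),
                  sim$truth$ref, sim$truth$alt)
  expect_true(all(types == "transition"))
  # and bias 0 only transversions
  sim0 <- simulate_chimera(200, n_diff_sites = 30, transition_bias = 0,
                           seed = 5)
  types0 <- mapply(function(r, a) substitution_type(c(r, a)),
                   sim0$truth$ref, sim0$truth$alt)
  expect_true(all(types0 == "transversion"))
})

test_that("planted sites respect block and loop confinement", {
  blocks <- list(c(20, 30), c(60, 70))
  sim <- simulate_chimera(100, n_diff_sites = 10, block_spec = blocks,
                          seed = 9)
  expect_true(all(sim$truth$position %in% c(20:30, 60:70)))
  expect_error(simulate_chimera(100, n_diff_sites = 30,
                                block_spec = list(c(10, 15)), seed = 1),
               "too small")
  loops <- c(5, 9, 14, 22, 31)
  sim2 <- simulate_chimera(50, n_diff_sites = 3, loop_positions = loops,
                           seed = 4)
  expect_true(all(sim2$truth$position %in% loops))
})

test_that("planted blocks are recovered by block detection", {
  blocks <- list(c(40, 48), c(120, 130))
  sim <- simulate_chimera(200, n_diff_sites = 12, block_spec = blocks,
                          seed = 13)
  cons <- call_consensus(sim$alleles)$consensus
  found <- detect_blocks(scan_sequence(cons), max_gap = 15,
                         min_block_sites = 2)
  covered <- unlist(lapply(seq_len(nrow(found)), function(i)
    found$start[i]:found$end[i]))
  expect_true(all(sim$truth$position %in% covered))
  expect_true(all(covered %in% c(40:48, 120:130)))
})

test_that("loop-planted sites give a loop fraction of one", {
  db <- paste0("((((", strrep(".", 12), "))))")
  struct <- parse_dotbracket(db)
  loops <- which(is.na(struct$pair_map))
  sim <- simulate_chimera(struct$length, n_diff_sites = 5,
                          loop_positions = loops, seed = 17)
  cons <- call_consensus(sim$alleles)$consensus
  sites <- scan_sequence(cons)$sites$position
  expect_equal(site_context(struct, sites)$loop_fraction, 1)
})

test_that("repeat arrays are inert without time or mutation", {
  anc <- c("ACGTACGT", "ACGTACGT")
  expect_equal(evolve_repeat_array(anc, 0, seed = 1), anc)
  out <- evolve_repeat_array(anc, 50, mutation_rate = 0,
                             regime = "birth_death", seed = 2)
  expect_true(all(out %in% anc))
  expect_gte(length(out), 1L)
})

test_that("strong conversion fixes the array on one variant", {
  set.seed(141)
  anc <- c(random_ambiguous_seq(40, 0), random_ambiguous_seq(40, 0))
  mono <- vapply(1:60, function(s) {
    out <- evolve_repeat_array(anc, 60, mutation_rate = 0,
                               conversion_rate = 1, seed = s)
    length(unique(out)) == 1L
  }, logical(1))
  expect_gt(mean(mono), 0.95)
})

test_that("consensus calling shows or suppresses minority peaks at h", {
  eq <- call_consensus(c("ACGT", "ACGA"), h = 0.3)
  expect_equal(eq$consensus, "ACGW")
  expect_equal(eq$majority_called, integer(0))

  skew <- call_consensus(c("ACGT", "ACGA"), weights = c(0.9, 0.1), h = 0.3)
  expect_equal(skew$consensus, "ACGT")
  expect_equal(skew$majority_called, 4L)

  single <- call_consensus("ACGT")
  expect_equal(single$consensus, "ACGT")
  expect_equal(single$majority_called, integer(0))
  expect_error(call_consensus(c("AC", "ACG")), "equal length")
})

test_that("simulations are byte-identical under the same seed", {
  a <- simulate_chimera(80, n_diff_sites = 6, seed = 99)
  b <- simulate_chimera(80, n_diff_sites = 6, seed = 99)
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_chimera(80, n_diff_sites = 6, seed = 100)))
  r1 <- evolve_repeat_array(c("ACGTAC", "ACGTAC"), 30, regime = "birth_death",
                            seed = 7)
  r2 <- evolve_repeat_array(c("ACGTAC", "ACGTAC"), 30, regime = "birth_death",
                            seed = 7)
  expect_identical(r1, r2)
  f1 <- simulate_fingerprints(10, 20, 3, 0.1, seed = 3)
  f2 <- simulate_fingerprints(10, 20, 3, 0.1, seed = 3)
  expect_identical(f1, f2)
})

test_that("fingerprint groups are recovered when noise-free", {
  fp <- simulate_fingerprints(12, 25, 4, within_group_flip_prob = 0,
                              seed = 19)
  pat <- distinct_patterns(fp$matrix)
  expect_equal(pat$n_patterns, 4L)
  # class memberships match the planted grouping
  for (cl in pat$classes)
    expect_equal(length(unique(fp$groups[cl])), 1L)

  all_own <- simulate_fingerprints(8, 30, 8, 0, seed = 23)
  expect_equal(distinct_patterns(all_own$matrix)$n_patterns, 8L)
  expect_error(simulate_fingerprints(5, 0, 2, 0, seed = 1), "n_bands")
  expect_error(simulate_fingerprints(5, 10, 9, 0, seed = 1), "n_groups")
  expect_error(simulate_fingerprints(5, 10, 2, 0.6, seed = 1), "flip_prob")
})

test_that("the coding-cohort fixture carries its planted summary exactly", {
  fix <- simulate_pul4_like(seed = 42)
  expect_length(fix$consensus, 37L)
  expect_equal(unique(nchar(fix$consensus)), 380L)
  expect_equal(nrow(fix$truth), 70L)
  cen <- scan_alignment(fix$consensus)$census
  expect_equal(cen$n_variable, 70L)
  expect_equal(cen$n_SNT + cen$n_SNP, 0L)
  tab <- summarize_coding(fix$consensus, fix$frame)
  expect_equal(tab$n_affected_union, 14L)
  expect_true(all(vapply(fix$consensus, min_allele_count, integer(1)) == 2L))
  # every strain's two alleles are resolutions of its own consensus
  for (s in sample(names(fix$alleles), 5)) {
    expect_true(is_resolution(fix$alleles[[s]][["A"]], fix$consensus[[s]]))
    expect_true(is_resolution(fix$alleles[[s]][["B"]], fix$consensus[[s]]))
  }
})
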