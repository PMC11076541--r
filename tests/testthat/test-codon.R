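test_that("segment positions map onto the ORF codon grid", {
  fr <- coding_frame(754)
  m <- map_to_codons(c(1L, 3L, 4L), fr)
  expect_equal(m$codon_index, c(252L, 252L, 253L))
  expect_equal(m$codon_position, c(1L, 3L, 1L))
})

test_that("codon positions cycle and codon indices never decrease", {
  for (start in c(1L, 2L, 3L, 754L, 755L)) {
    m <- map_to_codons(1:30, coding_frame(start))
    expect_true(all(m$codon_position %in% 1:3))
    # positions advance 1,2,3,1,2,3,... and the codon index steps up
    # exactly at each wrap
    expect_true(all(diff(m$codon_position) %in% c(1L, -2L)))
    expect_equal(diff(m$codon_index), as.integer(diff(m$codon_position) < 0))
  }
})

test_that("codon classification separates silent from coding changes", {
  syn <- classify_codon("GGY")
  expect_equal(syn$effect, "synonymous")
  expect_setequal(syn$resolutions, c("GGC", "GGT"))
  expect_equal(syn$amino_acids, "G")

  non <- classify_codon("RAT")
  expect_equal(non$effect, "nonsynonymous")
  expect_setequal(non$amino_acids, c("D", "N"))

  expect_equal(classify_codon("ATG")$effect, "none")
  expect_equal(classify_codon("A-G")$effect, "unresolvable")
})

test_that("the alternative yeast nuclear code reassigns CTG", {
  std <- classify_codon("CTG", "standard")
  alt <- classify_codon("CTG", "alt_yeast")
  expect_equal(std$amino_acids, "L")
  expect_equal(alt$amino_acids, "S")
  # YTG: CTG/TTG is synonymous (both Leu) under the standard code but
  # nonsynonymous (Ser/Leu) in the CUG-Ser clade code
  expect_equal(classify_codon("YTG", "standard")$effect, "synonymous")
  expect_equal(classify_codon("YTG", "alt_yeast")$effect, "nonsynonymous")
})

test_that("synonymity is invariant under resolution order", {
  set.seed(91)
  for (i in 1:10) {
    codon <- paste(sample(ALL_CODES, 3, replace = TRUE), collapse = "")
    eff <- classify_codon(codon)
    expect_setequal(eff$resolutions, oracle_resolutions(codon))
    expect_equal(eff$effect, oracle_codon_effect(codon))
  }
})

test_that("coding summaries pool variability onto the reference grid", {
  both <- summarize_coding(c(a = "GGCGAT", b = "GGTGAT"), coding_frame(1))
  expect_equal(both$n_affected_union, 0L)
  expect_equal(both$effects$effect_union, "synonymous")
  expect_equal(both$n_codons_total, 2L)

  one <- summarize_coding(c(x = "RAT"), coding_frame(1))
  expect_equal(one$n_affected_union, 1L)
  expect_equal(one$n_affected_per_sequence, 1L)

  silent <- summarize_coding(c(x = "ATGAAA"), coding_frame(1))
  expect_equal(silent$n_affected_union, 0L)
  expect_equal(nrow(silent$effects), 0L)
})

test_that("partial codons at the segment edges are excluded and listed", {
  # 9 residues from ORF position 2: ORF positions 2..10, so the first
  # codon lacks its first base and the fourth codon has only its first
  tab <- summarize_coding(c(x = "AYGTTTGAA"), coding_frame(2))
  expect_equal(tab$n_codons_total, 2L)
  expect_equal(length(tab$excluded_partial), 2L)
})

test_that("union and per-sequence tallies can disagree", {
  # each isolate is unambiguous; pooled they differ nonsynonymously at
  # codon 1 (GAT Asp vs AAT Asn)
  tab <- summarize_coding(c(a = "GAT", b = "AAT"), coding_frame(1))
  expect_equal(tab$n_affected_union, 1L)
  expect_equal(tab$n_affected_per_sequence, 0L)
})

test_that("third-position fraction reflects the variable-site placement", {
  # one third-position SND (GGY) and one first-position SND (RAT)
  tab <- summarize_coding(c(x = "GGYRAT"), coding_frame(1))
  expect_equal(tab$third_position_fraction, 0.5)
})
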