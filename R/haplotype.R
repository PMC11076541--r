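# Haplotype resolutions of an ambiguity-coded consensus, divergence bounds,
# minimum allele counts and OTU-threshold splitting.

#' Enumerate the haplotype resolutions of an ambiguity-coded consensus
#'
#' Every sequence compatible with an ambiguity-coded consensus (one base
#' chosen from each site's expansion) is a possible haplotype of the
#' underlying copy family. The number of resolutions is the product of the
#' per-site expansion sizes (2^k for a consensus with k dimorphic sites and
#' no higher morphisms); explicit enumeration is capped, but the count,
#' the maximum pairwise divergence (k ambiguous sites can all differ, so
#' k / length) and the minimum allele count are always returned exactly.
#'
#' @param seq Gap-free consensus (any shape accepted by [scan_sequence()]).
#' @param cap Maximum number of resolutions to list explicitly
#'   (default 2^20). Above the cap `haplotypes` is `NULL` and
#'   `enumerated` is `FALSE`.
#' @return An object of class `haplotype_space` with fields `source_id`,
#'   `n_ambiguous_sites`, `n_haplotypes`, `enumerated`, `haplotypes`,
#'   `max_pairwise_divergence`, `min_allele_count`, `length`.
#' @examples
#' enumerate_haplotypes("RY")   # AC, AT, GC, GT
#' @export
enumerate_haplotypes <- function(seq, cap = 2^20) {
  seqs <- as_residue_set(seq)
  residues <- seqs[[1]]
  id <- names(seqs)[1]
  if (grepl("-", residues, fixed = TRUE))
    stop("haplotype enumeration requires a gap-free sequence", call. = FALSE)
  exps <- site_expansions(residues)
  sizes <- lengths(exps)
  k <- sum(sizes > 1L)
  L <- length(exps)
  n <- prod(sizes)
  enumerated <- n <= cap
  haps <- NULL
  if (enumerated) {
    var_idx <- which(sizes > 1L)
    if (length(var_idx) == 0L) {
      haps <- residues
    } else {
      grid <- expand.grid(exps[var_idx], stringsAsFactors = FALSE)
      m <- base::matrix(rep(residue_chars(residues), each = nrow(grid)),
                        nrow = nrow(grid))
      m[, var_idx] <- as.matrix(grid)
      haps <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
  }
  structure(list(
    source_id = id,
    length = L,
    n_ambiguous_sites = k,
    n_haplotypes = n,
    enumerated = enumerated,
    haplotypes = haps,
    max_pairwise_divergence = k / L,
    min_allele_count = max(sizes)
  ), class = "haplotype_space")
}

#' @export
print.haplotype_space <- function(x, ...) {
  cat("haplotype_space of '", x$source_id, "' (", x$length, " nt)\n",
      "  ambiguous sites: ", x$n_ambiguous_sites,
      ";  resolutions: ", format(x$n_haplotypes, big.mark = ","),
      if (!x$enumerated) " (not listed: above cap)" else "", "\n",
      "  max pairwise divergence: ",
      sprintf("%.4f", x$max_pairwise_divergence),
      " (denominator ", x$length, " non-gap sites)\n",
      "  minimum allele count: ", x$min_allele_count, "\n", sep = "")
  invisible(x)
}

#' Is a sequence a resolution of an ambiguity-coded consensus?
#'
#' Membership test that does not require explicit enumeration: `hap` is a
#' resolution of `consensus` iff at every position its base lies in the
#' consensus code's expansion.
#'
#' @param hap Unambiguous candidate sequence.
#' @param consensus Ambiguity-coded consensus of the same length.
#' @return Logical.
#' @export
is_resolution <- function(hap, consensus) {
  hap <- as_residue_set(hap)[[1]]
  consensus <- as_residue_set(consensus)[[1]]
  if (nchar(hap) != nchar(consensus)) return(FALSE)
  hb <- residue_chars(hap)
  ce <- site_expansions(consensus)
  all(mapply(function(b, e) b %in% e, hb, ce))
}

#' Minimum number of alleles compatible with a consensus
#'
#' A site at which m nucleotides alternate requires at least m distinct
#' copies of the locus; the largest per-site expansion is therefore a lower
#' bound on the allele count. A consensus with only SND sites implies at
#' least two alleles; SNT/SNP sites push the bound to three or four.
#'
#' @param seq Consensus sequence (gaps ignored).
#' @return Integer lower bound (1 for an unambiguous sequence).
#' @examples
#' min_allele_count("AYGR")  # 2
#' min_allele_count("AVGT")  # 3
#' @export
min_allele_count <- function(seq) {
  residues <- as_residue_set(seq)[[1]]
  sizes <- lengths(site_expansions(residues))
  max(c(1L, sizes))
}

#' Would one genome's resolutions split across OTUs at a similarity threshold?
#'
#' Metabarcoding pipelines cluster reads into OTUs at a fixed similarity
#' threshold (commonly 97%). If the resolutions of a single genome's
#' consensus can be less similar to each other than the threshold, the
#' genome's own copies land in different OTUs and taxon diversity is
#' overestimated. Similarity is 1 minus p-distance (no evolutionary
#' correction), with the non-gap length as denominator.
#'
#' @param seq Consensus sequence.
#' @param threshold Similarity threshold in (0, 1), e.g. 0.97.
#' @return List with `threshold`, `max_pairwise_divergence`,
#'   `min_similarity`, `splits` (logical) and `margin`
#'   (`min_similarity - threshold`; negative means the genome splits).
#' @examples
#' otu_split(strrep("ACGTACGTACYTACGTACGT", 20), threshold = 0.97)
#' @export
otu_split <- function(seq, threshold = 0.97) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  hs <- enumerate_haplotypes(seq, cap = 0)  # counts/bounds only
  min_sim <- 1 - hs$max_pairwise_divergence
  list(threshold = threshold,
       max_pairwise_divergence = hs$max_pairwise_divergence,
       min_similarity = min_sim,
       splits = min_sim < threshold,
       margin = min_sim - threshold)
}
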