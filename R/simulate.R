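# Seeded generators of chimeric-genome alleles, evolving repeat arrays,
# majority-peak consensus calls and strain-structured band matrices.
# These provide ground truth for the scanning, haplotype, codon and
# clustering modules.

.TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSION_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                               C = c("A", "G"), T = c("A", "G"))

random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

.resolve_positions <- function(length, k, block_spec = NULL,
                               loop_positions = NULL) {
  candidates <- seq_len(length)
  if (!is.null(loop_positions)) candidates <- sort(unique(as.integer(loop_positions)))
  if (!is.null(block_spec)) {
    if (is.data.frame(block_spec))
      block_spec <- lapply(seq_len(nrow(block_spec)), function(i)
        c(block_spec$start[i], block_spec$end[i]))
    in_blocks <- sort(unique(unlist(lapply(block_spec, function(b)
      seq.int(b[1], b[2])))))
    if (min(in_blocks) < 1L || max(in_blocks) > length)
      stop("block_spec extends outside the sequence", call. = FALSE)
    candidates <- intersect(candidates, in_blocks)
  }
  if (length(candidates) < k)
    stop("block/loop specification too small for ", k, " planted sites",
         call. = FALSE)
  sort(sample(candidates, k))
}

#' Simulate the divergent alleles of a chimeric genome
#'
#' Generates an ancestral sequence and `n_alleles` copies that differ at
#' planted substitution sites, emulating a genome that carries divergent
#' copies of a locus (e.g. after hybridisation). Substitutions are
#' transition-biased; planted sites can be confined to intervals
#' (variability blocks) or to an explicit position set (e.g. hairpin-loop
#' positions).
#'
#' @param length Sequence length in nt.
#' @param n_alleles Number of allele sequences (>= 1; the first allele is
#'   the unchanged ancestor).
#' @param n_diff_sites Exact number of planted variable sites; if `NULL`,
#'   drawn as Binomial(`length`, `allele_divergence`).
#' @param allele_divergence Expected per-site difference fraction between
#'   ancestral alleles (used when `n_diff_sites` is `NULL`).
#' @param transition_bias Probability a planted substitution is a
#'   transition (default 0.7, the bias typical of the dimorphic sites in
#'   these barcodes).
#' @param block_spec Optional list of `c(start, end)` intervals (or data
#'   frame with `start`/`end`) confining planted sites.
#' @param loop_positions Optional explicit candidate position set.
#' @param seed Integer seed; all randomness derives from it.
#' @return List with `alleles` (named character vector), `truth` (data
#'   frame `position`, `ref`, `alt`, `substitution`, `carriers`) and
#'   `ancestor`.
#' @examples
#' sim <- simulate_chimera(100, n_diff_sites = 5, seed = 1)
#' nrow(sim$truth)  # 5
#' @export
simulate_chimera <- function(length, n_alleles = 2, n_diff_sites = NULL,
                             allele_divergence = 0.05,
                             transition_bias = 0.7, block_spec = NULL,
                             loop_positions = NULL, seed = 1) {
  stopifnot(length >= 1, n_alleles >= 1,
            transition_bias >= 0, transition_bias <= 1)
  set.seed(seed)
  ancestor <- random_dna(length)
  k <- if (is.null(n_diff_sites))
    stats::rbinom(1, length, allele_divergence) else as.integer(n_diff_sites)
  positions <- if (k > 0)
    .resolve_positions(length, k, block_spec, loop_positions) else integer(0)

  anc_chars <- residue_chars(ancestor)
  ref <- anc_chars[positions]
  alt <- vapply(ref, function(b) {
    if (stats::runif(1) < transition_bias) .TRANSITION_PARTNER[[b]]
    else sample(.TRANSVERSION_PARTNERS[[b]], 1)
  }, character(1))
  subst <- if (k > 0) mapply(function(r, a) substitution_type(c(r, a)),
                             ref, alt) else character(0)

  alleles <- stats::setNames(rep(ancestor, n_alleles),
                             paste0("allele", seq_len(n_alleles)))
  carriers <- character(k)
  if (n_alleles > 1 && k > 0) {
    chars <- lapply(seq_len(n_alleles), function(i) anc_chars)
    for (s in seq_len(k)) {
      who <- if (n_alleles == 2) 2L else
        sort(sample(2:n_alleles, sample.int(n_alleles - 1L, 1)))
      for (w in who) chars[[w]][positions[s]] <- alt[s]
      carriers[s] <- paste(who, collapse = ",")
    }
    alleles[] <- vapply(chars, paste, character(1), collapse = "")
  }
  truth <- data.frame(position = positions, ref = unname(ref),
                      alt = unname(alt), substitution = unname(subst),
                      carriers = carriers, stringsAsFactors = FALSE)
  list(alleles = alleles, truth = truth, ancestor = ancestor)
}

#' Evolve a repeat array under homogenisation or birth-and-death dynamics
#'
#' Per generation, every repeat mutates per site at `mutation_rate`; with
#' probability `duplication_rate` a random repeat is duplicated; with
#' probability `deletion_rate` a random repeat is deleted (the array never
#' drops below one member); with probability `conversion_rate` a random
#' repeat is overwritten by a copy of another (gene conversion, the
#' homogenising force). The `regime` presets contrast the two hypotheses
#' for rRNA repeat evolution: `"homogenise"` (conversion active, no
#' birth/death) keeps the array internally identical; `"birth_death"`
#' (duplication/deletion active, no conversion) lets repeats diverge
#' within one genome.
#'
#' @param ancestors Character vector of equal-length starting repeats.
#' @param generations Number of generations (>= 0).
#' @param mutation_rate Per-site per-generation substitution probability.
#' @param regime `"birth_death"`, `"homogenise"`, or `NULL` to use the
#'   explicit rates only.
#' @param duplication_rate,deletion_rate,conversion_rate Per-generation
#'   event probabilities; regime presets are
#'   duplication = deletion = 0.05 (birth_death) and conversion = 0.5
#'   (homogenise), overridable.
#' @param seed Integer seed.
#' @return Character vector of final repeats.
#' @export
evolve_repeat_array <- function(ancestors, generations,
                                mutation_rate = 1e-3,
                                regime = NULL,
                                duplication_rate = NULL,
                                deletion_rate = NULL,
                                conversion_rate = NULL,
                                seed = 1) {
  stopifnot(generations >= 0, mutation_rate >= 0, length(ancestors) >= 1)
  if (length(unique(nchar(ancestors))) != 1L)
    stop("ancestor repeats must be equal length", call. = FALSE)
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("birth_death", "homogenise"))
    if (is.null(duplication_rate))
      duplication_rate <- if (regime == "birth_death") 0.05 else 0
    if (is.null(deletion_rate))
      deletion_rate <- if (regime == "birth_death") 0.05 else 0
    if (is.null(conversion_rate))
      conversion_rate <- if (regime == "homogenise") 0.5 else 0
  } else {
    if (is.null(duplication_rate)) duplication_rate <- 0
    if (is.null(deletion_rate)) deletion_rate <- 0
    if (is.null(conversion_rate)) conversion_rate <- 0
  }
  set.seed(seed)
  repeats <- lapply(unname(ancestors), residue_chars)
  L <- length(repeats[[1]])
  bases <- c("A", "C", "G", "T")
  for (g in seq_len(generations)) {
    for (r in seq_along(repeats)) {
      n_mut <- stats::rbinom(1, L, mutation_rate)
      if (n_mut > 0) {
        at <- sample.int(L, n_mut)
        repeats[[r]][at] <- vapply(repeats[[r]][at], function(b)
          sample(setdiff(bases, b), 1), character(1))
      }
    }
    if (stats::runif(1) < duplication_rate)
      repeats[[length(repeats) + 1L]] <- repeats[[sample.int(length(repeats), 1)]]
    if (length(repeats) > 1L && stats::runif(1) < deletion_rate)
      repeats[[sample.int(length(repeats), 1)]] <- NULL
    if (length(repeats) > 1L && stats::runif(1) < conversion_rate) {
      ij <- sample.int(length(repeats), 2)
      repeats[[ij[1]]] <- repeats[[ij[2]]]
    }
  }
  vapply(repeats, paste, character(1), collapse = "")
}

#' Call an ambiguity-coded consensus with the majority-peak rule
#'
#' Emulates how a Sanger amplicon consensus is written down: at each site
#' the repeats/alleles contribute weighted "peaks"; the consensus shows an
#' ambiguity code over the majority base and every minority base whose
#' weight reaches the calling threshold `h`; minority bases below `h` are
#' suppressed and only the majority base is written, with the position
#' flagged as majority-called (a known minor variant hidden by the call).
#'
#' @param repeats Equal-length unambiguous sequences.
#' @param weights Nonnegative weights, one per repeat (normalised
#'   internally; default equal).
#' @param h Minor-peak calling threshold in (0, 1] (default 0.3).
#' @return List with `consensus` (string), `majority_called` (integer
#'   positions where a positive-weight base was suppressed), and
#'   `displayed` (list of per-site displayed base sets).
#' @examples
#' call_consensus(c("ACGT", "ACGA"))$consensus                    # "ACGW"
#' call_consensus(c("ACGT", "ACGA"), weights = c(0.9, 0.1))       # "ACGT"
#' @export
call_consensus <- function(repeats, weights = NULL, h = 0.3) {
  stopifnot(length(repeats) >= 1, h > 0, h <= 1)
  if (length(unique(nchar(repeats))) != 1L)
    stop("repeats must be equal length", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(repeats))
  if (length(weights) != length(repeats) || any(weights < 0) ||
      sum(weights) == 0)
    stop("weights must be nonnegative, one per repeat", call. = FALSE)
  weights <- weights / sum(weights)
  chars <- lapply(unname(repeats), residue_chars)
  L <- nchar(repeats[[1]])
  out <- character(L)
  flagged <- integer(0)
  displayed <- vector("list", L)
  for (p in seq_len(L)) {
    col <- vapply(chars, `[[`, character(1), p)
    w <- tapply(weights, col, sum)
    major <- names(w)[order(-w, names(w))][1]
    show <- sort(unique(c(major, names(w)[w >= h])))
    if (length(show) < length(w)) flagged <- c(flagged, p)
    displayed[[p]] <- show
    out[p] <- encode_consensus(show)
  }
  list(consensus = paste(out, collapse = ""),
       majority_called = flagged, displayed = displayed)
}

#' Simulate strain-structured binary fingerprints
#'
#' Draws one uniform random band prototype per group, assigns strains to
#' groups round-robin, and flips each member band independently with the
#' within-group noise probability — ground truth for pattern counting and
#' UPGMA clustering.
#'
#' @param n_strains,n_bands,n_groups Dimensions; `n_groups <= n_strains`,
#'   `n_bands >= 1`.
#' @param within_group_flip_prob Band flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return List with `matrix` (a [band_matrix()]) and `groups` (named
#'   integer vector, the true group of each strain).
#' @export
simulate_fingerprints <- function(n_strains, n_bands, n_groups,
                                  within_group_flip_prob = 0, seed = 1) {
  if (n_bands < 1L) stop("n_bands must be >= 1", call. = FALSE)
  if (n_groups > n_strains) stop("n_groups must be <= n_strains", call. = FALSE)
  if (within_group_flip_prob < 0 || within_group_flip_prob >= 0.5)
    stop("within_group_flip_prob must lie in [0, 0.5)", call. = FALSE)
  set.seed(seed)
  proto <- base::matrix(stats::rbinom(n_groups * n_bands, 1, 0.5),
                        nrow = n_groups)
  groups <- rep_len(seq_len(n_groups), n_strains)
  pres <- proto[groups, , drop = FALSE]
  if (within_group_flip_prob > 0) {
    flips <- base::matrix(stats::rbinom(n_strains * n_bands, 1,
                                        within_group_flip_prob),
                          nrow = n_strains)
    pres <- (pres + flips) %% 2L
  }
  ids <- sprintf("strain%02d", seq_len(n_strains))
  list(matrix = band_matrix(pres, strain_ids = ids),
       groups = stats::setNames(groups, ids))
}
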