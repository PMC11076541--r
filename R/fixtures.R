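# A paper-shaped synthetic fixture: a set of strains each carrying two
# alleles of a 380 nt coding segment, with a controlled union of dimorphic
# sites and a controlled number of amino-acid-changing codons. Purely
# synthetic stand-in data for demonstration and end-to-end testing; no
# real isolate sequences are included.

# nonsynonymous templates: codon, position of planted site, ref, alt
# (all transition SNDs in first or second codon position, stop-free)
.NONSYN_TEMPLATES <- list(
  list(codon = c("G", "A", "T"), pos = 1L, alt = "A"),  # GAT Asp / AAT Asn
  list(codon = c("C", "G", "T"), pos = 1L, alt = "T"),  # CGT Arg / TGT Cys
  list(codon = c("A", "A", "A"), pos = 2L, alt = "G"),  # AAA Lys / AGA Arg
  list(codon = c("G", "C", "A"), pos = 2L, alt = "T")   # GCA Ala / GTA Val (tv)
)

# first-two-base contexts whose third position is fourfold degenerate
.FOURFOLD_PREFIX <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' Simulate a chimeric-genome coding-segment cohort
#'
#' Generates a cohort of strains, each carrying two alleles of one coding
#' segment, engineered so that the *union* of the per-strain dimorphic
#' (SND) sites has an exact, known size and a known number of the affected
#' codons are amino-acid-changing. Sites occupy distinct codons: most sit
#' in third codon positions with synonymous alternatives (transition-
#' biased, with a minority of fourfold-degenerate transversions); the
#' designated nonsynonymous codons carry first- or second-position
#' substitutions. Each strain is heterozygous at a random subset of the
#' site pool (every site is carried by at least one strain), and each
#' strain's consensus is produced by [call_consensus()] at equal allele
#' weights.
#'
#' Defaults mirror the summary statistics of a published *Metschnikowia
#' pulcherrima* PUL4 amplicon survey in shape only (37 strains, 380 nt
#' segment anchored at ORF position 754, 70 union SND sites of which 14
#' codons are amino-acid-changing); the sequences themselves are random.
#'
#' @param seed Integer seed.
#' @param n_strains Number of strains (default 37).
#' @param length Segment length in nt (default 380).
#' @param n_union_sites Exact size of the cross-strain union of variable
#'   sites (default 70).
#' @param n_nonsyn_codons Number of amino-acid-changing codons among them
#'   (default 14).
#' @param orf_start 1-based ORF position of the segment's first residue
#'   (default 754).
#' @param carry_prob Probability that a strain is heterozygous at any
#'   given pool site (default 0.3); every site is forced into at least
#'   one strain.
#' @param h Minor-peak calling threshold passed to [call_consensus()].
#' @return List with `consensus` (named character vector, one ambiguity-
#'   coded sequence per strain), `alleles` (list of 2-vectors per strain),
#'   `reference`, `frame` (a [coding_frame()]), and `truth` (data frame
#'   `position`, `ref`, `alt`, `substitution`, `codon_index`,
#'   `codon_position`, `effect`).
#' @export
simulate_pul4_like <- function(seed = 1, n_strains = 37, length = 380,
                               n_union_sites = 70, n_nonsyn_codons = 14,
                               orf_start = 754, carry_prob = 0.3, h = 0.3) {
  stopifnot(n_nonsyn_codons <= n_union_sites)
  set.seed(seed)
  frame <- coding_frame(orf_start)
  map <- map_to_codons(seq_len(length), frame)
  by_codon <- split(map$position, map$codon_index)
  complete <- names(by_codon)[lengths(by_codon) == 3L]
  if (length(complete) < n_union_sites)
    stop("segment too short for ", n_union_sites, " sites in distinct codons",
         call. = FALSE)

  ref_chars <- residue_chars(random_dna(length))
  chosen <- sample(complete, n_union_sites)
  nonsyn_codons <- chosen[seq_len(n_nonsyn_codons)]
  syn_codons <- chosen[-seq_len(n_nonsyn_codons)]

  n_tv_syn <- round(0.15 * length(syn_codons))  # minority of transversions
  tv_syn <- if (n_tv_syn > 0) sample(syn_codons, n_tv_syn) else character(0)

  positions <- integer(0); ref <- character(0); alt <- character(0)
  effect <- character(0)
  for (ci in syn_codons) {
    pos <- by_codon[[ci]]
    if (ci %in% tv_syn) {
      # fourfold-degenerate third position, A/T transversion
      prefix <- residue_chars(sample(.FOURFOLD_PREFIX, 1))
      ref_chars[pos[1:2]] <- prefix
      ref_chars[pos[3]] <- "A"
      positions <- c(positions, pos[3]); ref <- c(ref, "A"); alt <- c(alt, "T")
    } else {
      # NNC/NNT third position: transition, synonymous for every prefix
      r <- sample(c("C", "T"), 1)
      ref_chars[pos[3]] <- r
      positions <- c(positions, pos[3]); ref <- c(ref, r)
      alt <- c(alt, .TRANSITION_PARTNER[[r]])
    }
    effect <- c(effect, "synonymous")
  }
  for (ci in nonsyn_codons) {
    pos <- by_codon[[ci]]
    tpl <- .NONSYN_TEMPLATES[[sample.int(length(.NONSYN_TEMPLATES), 1)]]
    ref_chars[pos] <- tpl$codon
    positions <- c(positions, pos[tpl$pos])
    ref <- c(ref, tpl$codon[tpl$pos]); alt <- c(alt, tpl$alt)
    effect <- c(effect, "nonsynonymous")
  }
  ord <- order(positions)
  positions <- positions[ord]; ref <- ref[ord]; alt <- alt[ord]
  effect <- effect[ord]
  reference <- paste(ref_chars, collapse = "")

  # site -> carrying strains; every site in at least one strain
  carriers <- lapply(seq_along(positions), function(i) {
    who <- which(stats::runif(n_strains) < carry_prob)
    if (length(who) == 0L) who <- sample.int(n_strains, 1)
    who
  })
  strain_ids <- sprintf("S%02d", seq_len(n_strains))
  alleles <- vector("list", n_strains); names(alleles) <- strain_ids
  consensus <- character(n_strains); names(consensus) <- strain_ids
  for (s in seq_len(n_strains)) {
    b_chars <- ref_chars
    mine <- vapply(carriers, function(w) s %in% w, logical(1))
    b_chars[positions[mine]] <- alt[mine]
    a <- reference; b <- paste(b_chars, collapse = "")
    alleles[[s]] <- c(A = a, B = b)
    consensus[s] <- call_consensus(c(a, b), h = h)$consensus
  }
  site_map <- map_to_codons(positions, frame)
  truth <- data.frame(
    position = positions, ref = ref, alt = alt,
    substitution = mapply(function(r, a) substitution_type(c(r, a)), ref, alt),
    codon_index = site_map$codon_index,
    codon_position = site_map$codon_position,
    effect = effect,
    n_carriers = lengths(carriers),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(consensus = consensus, alleles = alleles, reference = reference,
       frame = frame, truth = truth)
}

#' Union site census and codon-effect summary of a strain cohort
#'
#' The worked-example analysis for a cohort of ambiguity-coded coding-
#' segment consensus sequences (such as the GenBank-deposited PUL4
#' amplicons of a published survey, once fetched and aligned): scans the
#' union of all strains' variable sites, reports the census (count and
#' percentage of variable sites, SND/SNT/SNP breakdown, ti/tv) and the
#' codon-effect table anchored at the given ORF position.
#'
#' @param seqs Equal-length consensus sequences (named character vector,
#'   FASTA path, or `DNAStringSet`).
#' @param orf_start 1-based ORF position of the segment's first residue.
#' @param code_table Genetic code (see [get_code_table()]).
#' @return List with `census` (a `diversity_census`), `codons` (a
#'   `codon_effect_table`), and `min_allele_counts` (named integer vector
#'   per strain).
#' @export
pul4_census <- function(seqs, orf_start = 754, code_table = "standard") {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_ambiguous_fasta(seqs)
  seqs <- as_residue_set(seqs)
  census <- scan_alignment(seqs)
  codons <- summarize_coding(seqs, coding_frame(orf_start, code_table))
  list(census = census, codons = codons,
       min_allele_counts = vapply(seqs, min_allele_count, integer(1)))
}
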