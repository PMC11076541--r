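# Per-position variability census of ambiguity-coded sequences and
# pre-aligned sequence sets; block detection; pairwise divergence.

site_expansions <- function(residues) {
  lapply(residue_chars(residues), function(ch) IUPAC_EXPANSION[[ch]])
}

.empty_sites <- function() {
  data.frame(position = integer(0), observed = character(0),
             code = character(0), morphism = character(0),
             substitution = character(0), is_indel_column = logical(0),
             majority_called = logical(0), stringsAsFactors = FALSE)
}

.build_census <- function(seqs, union_sets, gap_any) {
  L <- length(union_sets)
  sizes <- lengths(union_sets)
  variable <- sizes > 1L
  positions <- which(variable)

  morphism <- vapply(union_sets[positions], classify_morphism, character(1))
  substitution <- vapply(union_sets[positions], function(u)
    if (length(u) == 2L) substitution_type(u) else NA_character_, character(1))

  sites <- data.frame(
    position = positions,
    observed = vapply(union_sets[positions], paste, character(1), collapse = "/"),
    code = vapply(union_sets[positions], encode_consensus, character(1)),
    morphism = morphism,
    substitution = substitution,
    is_indel_column = gap_any[positions],
    majority_called = rep(NA, length(positions)),
    stringsAsFactors = FALSE
  )

  n_indel_columns <- sum(gap_any)
  n_nonindel <- L - n_indel_columns
  n_variable_nonindel <- sum(variable & !gap_any)
  pct <- if (n_nonindel > 0) 100 * n_variable_nonindel / n_nonindel else NA_real_

  per_seq <- vapply(seqs, function(r) {
    sum(lengths(site_expansions(r)) > 1L)
  }, integer(1))

  # one indel event per maximal run of gap characters per sequence
  n_indel_events <- sum(vapply(seqs, function(r) {
    g <- residue_chars(r) == "-"
    sum(g & !c(FALSE, g[-length(g)]))
  }, integer(1)))

  census <- list(
    n_sites_total = L,
    n_variable = sum(variable),
    n_variable_nonindel = n_variable_nonindel,
    pct_variable = pct,
    pct_variable_headline = if (is.na(pct)) NA_real_ else round_half_away(pct),
    pct_denominator = n_nonindel,
    n_SND = sum(morphism == "SND"),
    n_SNT = sum(morphism == "SNT"),
    n_SNP = sum(morphism == "SNP"),
    n_transitions = sum(substitution == "transition", na.rm = TRUE),
    n_transversions = sum(substitution == "transversion", na.rm = TRUE),
    n_indel_columns = n_indel_columns,
    n_indel_events = n_indel_events,
    per_sequence_counts = as.list(per_seq)
  )
  structure(list(sites = sites, census = census, n_sequences = length(seqs)),
            class = "diversity_census")
}

#' @export
print.diversity_census <- function(x, ...) {
  c_ <- x$census
  cat("Variability census over ", x$n_sequences, " sequence(s), ",
      c_$n_sites_total, " positions\n", sep = "")
  cat("  variable sites: ", c_$n_variable,
      if (!is.na(c_$pct_variable))
        sprintf(" (%.2f%%, headline %d%%, denominator %d)",
                c_$pct_variable, as.integer(c_$pct_variable_headline),
                c_$pct_denominator) else "", "\n", sep = "")
  cat("  SND/SNT/SNP: ", c_$n_SND, "/", c_$n_SNT, "/", c_$n_SNP,
      "   ti/tv: ", c_$n_transitions, ":", c_$n_transversions, "\n", sep = "")
  cat("  indel columns: ", c_$n_indel_columns,
      " (", c_$n_indel_events, " events)\n", sep = "")
  invisible(x)
}

#' Census the variable sites of a single ambiguity-coded sequence
#'
#' Scans one amplicon consensus sequence and reports every position whose
#' IUPAC code expands to more than one base, classified as SND (two
#' alternating bases), SNT (three) or SNP (four), with transition or
#' transversion typing for SND sites.
#'
#' @param seq An [ambiguous_sequence()], or a single residue string.
#' @return A `diversity_census` object: `$sites` is a data frame with one
#'   row per variable position (`position`, `observed`, `code`, `morphism`,
#'   `substitution`, `is_indel_column`, `majority_called`); `$census` holds
#'   the totals (`n_variable`, `n_SND`, `n_SNT`, `n_SNP`, `n_transitions`,
#'   `n_transversions`, `pct_variable` at full precision and
#'   `pct_variable_headline` rounded half-away-from-zero to integer
#'   percent, indel counts, per-sequence ambiguous-site counts).
#' @examples
#' scan_sequence("AYGR")  # two SND sites, both transitions
#' @export
scan_sequence <- function(seq) {
  seqs <- as_residue_set(seq)
  if (length(seqs) != 1L)
    stop("scan_sequence expects a single sequence; use scan_alignment",
         call. = FALSE)
  exps <- site_expansions(seqs[[1]])
  gap_any <- lengths(exps) == 0L
  .build_census(seqs, exps, gap_any)
}

#' Census the variable columns of a pre-aligned sequence set
#'
#' For equal-length (pre-aligned) sequences, a column is variable when the
#' union of the per-sequence expansions (ambiguity codes expanded; gaps
#' excluded from the union but flagged) contains more than one base.
#' Columns in which any sequence carries a gap are counted separately as
#' indel columns and excluded from the percentage denominator; a maximal
#' run of gaps within one sequence is one indel event.
#'
#' @param seqs Named character vector, list of [ambiguous_sequence()]
#'   objects, or a `Biostrings::DNAStringSet`; all the same length.
#' @return A `diversity_census` object (see [scan_sequence()]).
#' @examples
#' scan_alignment(c(a = "ACYT", b = "ACCT"))  # one SND column at position 3
#' @export
scan_alignment <- function(seqs) {
  seqs <- as_residue_set(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[lens != lens[1]]
    stop("sequences are not equal length (not aligned); offending ids: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  L <- lens[[1]]
  exps_by_seq <- lapply(seqs, site_expansions)
  union_sets <- vector("list", L)
  gap_any <- logical(L)
  for (p in seq_len(L)) {
    col <- lapply(exps_by_seq, `[[`, p)
    gap_any[p] <- any(lengths(col) == 0L)
    union_sets[[p]] <- sort(unique(unlist(col)))
  }
  .build_census(seqs, union_sets, gap_any)
}

#' Detect blocks of clustered variable positions
#'
#' Variable positions in rRNA barcodes often concentrate in short blocks.
#' A block is a maximal run of variable positions in which consecutive
#' members are at most `max_gap` apart; runs with fewer than
#' `min_block_sites` members are discarded. Blocks are labelled with Roman
#' numerals in positional order.
#'
#' @param sites A `diversity_census`, its `$sites` data frame, or an
#'   integer vector of 1-based variable positions (must be sorted).
#' @param max_gap Maximum distance between consecutive member sites
#'   (default 10).
#' @param min_block_sites Minimum number of sites per reported block
#'   (default 2).
#' @return Data frame with columns `label`, `start`, `end`, `site_count`.
#' @examples
#' detect_blocks(c(10L, 12L, 15L, 100L, 101L, 300L))
#' @export
detect_blocks <- function(sites, max_gap = 10L, min_block_sites = 2L) {
  if (inherits(sites, "diversity_census")) sites <- sites$sites
  pos <- if (is.data.frame(sites)) sites$position else as.integer(sites)
  stopifnot(max_gap >= 0L, min_block_sites >= 1L)
  empty <- data.frame(label = character(0), start = integer(0),
                      end = integer(0), site_count = integer(0),
                      stringsAsFactors = FALSE)
  if (length(pos) == 0L) return(empty)
  if (is.unsorted(pos, strictly = TRUE))
    stop("site positions must be strictly increasing", call. = FALSE)
  run <- cumsum(c(1L, diff(pos) > max_gap))
  blocks <- lapply(split(pos, run), function(p)
    data.frame(start = min(p), end = max(p), site_count = length(p)))
  out <- do.call(rbind, blocks)
  out <- out[out$site_count >= min_block_sites, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$label <- as.character(utils::as.roman(seq_len(nrow(out))))
  rownames(out) <- NULL
  out[, c("label", "start", "end", "site_count")]
}

#' Pairwise divergence between two ambiguity-coded sequences
#'
#' Two models of per-site difference between equal-length sequences:
#' `expected_mismatch` treats each ambiguity code as a uniform distribution
#' over its expansion and averages, over non-gap sites, the probability
#' that independent draws from the two sites differ; `incompatibility`
#' scores a site 1 only when the two expansions share no base (the
#' sequences cannot be resolutions of a common copy there). Sites where
#' either sequence has a gap are excluded from the denominator.
#'
#' @param a,b Sequences (any shape accepted by [scan_sequence()]), equal
#'   length.
#' @param distance_model `"expected_mismatch"` or `"incompatibility"`.
#' @return A distance in `[0, 1]`.
#' @examples
#' pairwise_census("AY", "AC")                      # 0.25
#' pairwise_census("AY", "AC", "incompatibility")   # 0
#' @export
pairwise_census <- function(a, b,
                            distance_model = c("expected_mismatch",
                                               "incompatibility")) {
  distance_model <- match.arg(distance_model)
  a <- as_residue_set(a)[[1]]
  b <- as_residue_set(b)[[1]]
  if (nchar(a) != nchar(b))
    stop("sequences must be equal length (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  ea <- site_expansions(a)
  eb <- site_expansions(b)
  keep <- lengths(ea) > 0L & lengths(eb) > 0L
  if (!any(keep)) return(0)
  per_site <- mapply(function(x, y) {
    if (distance_model == "incompatibility") {
      as.numeric(length(intersect(x, y)) == 0L)
    } else {
      1 - length(intersect(x, y)) / (length(x) * length(y))
    }
  }, ea[keep], eb[keep])
  mean(per_site)
}
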