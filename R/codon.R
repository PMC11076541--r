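# Mapping variable sites into codons of a protein-coding segment and
# classifying dimorphic-site effects as synonymous or amino-acid-changing.

#' Resolve a genetic code table
#'
#' `"standard"` (NCBI table 1) is the default; `"alt_yeast"` (NCBI table
#' 12, CTG read as Ser) is offered because *Metschnikowia* belongs to the
#' CUG-Ser clade. Numeric NCBI table ids are passed through to
#' [Biostrings::getGeneticCode()].
#'
#' @param code_table `"standard"`, `"alt_yeast"`, or an NCBI table id.
#' @return Named character vector mapping codons to one-letter residues.
#' @export
get_code_table <- function(code_table = "standard") {
  id <- switch(as.character(code_table),
               standard = "1", alt_yeast = "12", as.character(code_table))
  Biostrings::getGeneticCode(id)
}

#' Define the reading frame of an analysed coding segment
#'
#' @param orf_start_position 1-based position of the segment's first
#'   residue within the ORF (e.g. 754 for a segment starting at the 754th
#'   nucleotide of a gene).
#' @param code_table Genetic code (see [get_code_table()]).
#' @return An object of class `coding_frame`.
#' @export
coding_frame <- function(orf_start_position, code_table = "standard") {
  stopifnot(is.numeric(orf_start_position), orf_start_position >= 1)
  structure(list(orf_start_position = as.integer(orf_start_position),
                 code_table = code_table,
                 code = get_code_table(code_table)),
            class = "coding_frame")
}

#' Map segment positions to ORF codon coordinates
#'
#' For a segment whose first residue is the `orf_start_position`-th
#' nucleotide of the ORF, segment position p lies in codon
#' `ceiling((orf_start_position + p - 1) / 3)` at codon position
#' `((orf_start_position + p - 2) mod 3) + 1`.
#'
#' @param positions Integer vector of 1-based segment positions (or a
#'   `diversity_census` whose variable-site positions are used).
#' @param frame A [coding_frame()].
#' @return Data frame with `position`, `codon_index`, `codon_position`.
#' @examples
#' map_to_codons(1:4, coding_frame(754))
#' @export
map_to_codons <- function(positions, frame) {
  if (inherits(positions, "diversity_census"))
    positions <- positions$sites$position
  stopifnot(inherits(frame, "coding_frame"))
  g <- frame$orf_start_position + as.integer(positions) - 1L
  data.frame(position = as.integer(positions),
             codon_index = as.integer(ceiling(g / 3)),
             codon_position = as.integer(((g - 1L) %% 3L) + 1L))
}

#' Classify the effect of ambiguity within one codon
#'
#' Enumerates all unambiguous resolutions of a three-symbol ambiguity
#' codon, translates them, and classifies the codon: `none` when no
#' position is ambiguous, `synonymous` when at least two resolutions all
#' encode the same residue, `nonsynonymous` when the resolutions encode
#' more than one residue.
#'
#' @param codon Three IUPAC symbols (string or character vector), no gaps.
#' @param code_table Genetic code (see [get_code_table()]), or an already
#'   resolved named code vector.
#' @return List of class `codon_effect`: `codon`,
#'   `variable_positions_in_codon`, `resolutions`, `amino_acids`, `effect`.
#' @examples
#' classify_codon("GGY")$effect  # "synonymous"
#' classify_codon("RAT")$effect  # "nonsynonymous"
#' @export
classify_codon <- function(codon, code_table = "standard") {
  code <- if (is.character(code_table) && length(code_table) > 1L)
    code_table else get_code_table(code_table)
  chars <- if (length(codon) == 3L) toupper(codon) else
    residue_chars(as_residue_set(codon)[[1]])
  if (length(chars) != 3L)
    stop("a codon must contain exactly 3 symbols", call. = FALSE)
  if (any(chars == "-"))
    return(structure(list(codon = paste(chars, collapse = ""),
                          variable_positions_in_codon = integer(0),
                          resolutions = character(0),
                          amino_acids = character(0),
                          effect = "unresolvable"),
                     class = "codon_effect"))
  exps <- lapply(chars, expand_code)
  grid <- expand.grid(exps, stringsAsFactors = FALSE)
  resolutions <- do.call(paste0, grid)
  aas <- unique(unname(code[resolutions]))
  var_pos <- which(lengths(exps) > 1L)
  effect <- if (length(var_pos) == 0L) "none"
    else if (length(aas) > 1L) "nonsynonymous" else "synonymous"
  structure(list(codon = paste(chars, collapse = ""),
                 variable_positions_in_codon = var_pos,
                 resolutions = resolutions,
                 amino_acids = sort(aas),
                 effect = effect),
            class = "codon_effect")
}

#' @export
print.codon_effect <- function(x, ...) {
  cat("codon ", x$codon, ": ", x$effect,
      if (length(x$amino_acids))
        paste0(" {", paste(x$amino_acids, collapse = ","), "}"),
      "\n", sep = "")
  invisible(x)
}

#' Codon-level effect summary of a coding segment
#'
#' Pools the variable sites of one or more equal-length coding sequences
#' onto the codon grid given by `frame` and classifies every complete
#' codon. Two tallies of "affected" (nonsynonymous) codons are reported:
#' the union tally classifies the cross-sequence union codon (all
#' alternatives pooled onto one reference, as a figure stacking variants
#' above a reference sequence would show), and the per-sequence tally
#' counts codons that are nonsynonymous within at least one isolate's own
#' sequence. Codons only partially inside the segment are excluded from
#' all denominators and listed; codons containing a gap are excluded as
#' unresolvable.
#'
#' @param seqs Equal-length coding sequences (any shape accepted by
#'   [scan_alignment()]).
#' @param frame A [coding_frame()].
#' @return An object of class `codon_effect_table`: `$effects` (one row
#'   per complete codon with any variability: `codon_index`,
#'   `union_codon`, `variable_positions`, `amino_acids`, `effect_union`,
#'   `effect_any_sequence`), `$n_codons_total`, `$n_affected_union`,
#'   `$n_affected_per_sequence`, `$pct_affected_union`,
#'   `$third_position_fraction`, `$excluded_partial`,
#'   `$excluded_unresolvable`.
#' @examples
#' summarize_coding(c(a = "GGCGAT", b = "GGTGAT"), coding_frame(1))
#' @export
summarize_coding <- function(seqs, frame) {
  stopifnot(inherits(frame, "coding_frame"))
  seqs <- as_residue_set(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("coding sequences must be equal length; offending ids: ",
         paste(names(seqs)[lens != lens[1]], collapse = ", "), call. = FALSE)
  L <- lens[[1]]
  map <- map_to_codons(seq_len(L), frame)
  by_codon <- split(map$position, map$codon_index)
  complete <- names(by_codon)[lengths(by_codon) == 3L]
  excluded_partial <- as.integer(setdiff(names(by_codon), complete))

  exps_by_seq <- lapply(seqs, site_expansions)
  union_chars <- vapply(seq_len(L), function(p) {
    u <- sort(unique(unlist(lapply(exps_by_seq, `[[`, p))))
    if (length(u) == 0L) "-" else encode_consensus(u)
  }, character(1))
  seq_chars <- lapply(seqs, residue_chars)

  code <- frame$code
  rows <- list(); unresolvable <- integer(0)
  n_affected_union <- 0L; n_affected_perseq <- 0L; n_total <- 0L
  for (ci in complete) {
    pos <- by_codon[[ci]]
    eff_union <- classify_codon(union_chars[pos], code)
    per_seq_effects <- vapply(seq_chars, function(sc)
      classify_codon(sc[pos], code)$effect, character(1))
    if (eff_union$effect == "unresolvable" ||
        any(per_seq_effects == "unresolvable")) {
      unresolvable <- c(unresolvable, as.integer(ci))
      next
    }
    n_total <- n_total + 1L
    any_nonsyn_seq <- any(per_seq_effects == "nonsynonymous")
    if (eff_union$effect == "nonsynonymous")
      n_affected_union <- n_affected_union + 1L
    if (any_nonsyn_seq)
      n_affected_perseq <- n_affected_perseq + 1L
    if (eff_union$effect != "none") {
      rows[[length(rows) + 1L]] <- data.frame(
        codon_index = as.integer(ci),
        segment_start = pos[1],
        union_codon = eff_union$codon,
        variable_positions = paste(eff_union$variable_positions_in_codon,
                                   collapse = ","),
        n_resolutions = length(eff_union$resolutions),
        amino_acids = paste(eff_union$amino_acids, collapse = ","),
        effect_union = eff_union$effect,
        effect_any_sequence = if (any_nonsyn_seq) "nonsynonymous"
          else if (any(per_seq_effects == "synonymous")) "synonymous"
          else "none",
        stringsAsFactors = FALSE)
    }
  }
  effects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(codon_index = integer(0), segment_start = integer(0),
               union_codon = character(0), variable_positions = character(0),
               n_resolutions = integer(0), amino_acids = character(0),
               effect_union = character(0), effect_any_sequence = character(0),
               stringsAsFactors = FALSE)
  effects <- effects[order(effects$codon_index), , drop = FALSE]
  rownames(effects) <- NULL

  # variable sites (union) and their codon positions, complete codons only
  var_pos <- which(vapply(seq_len(L), function(p)
    length(expand_code(union_chars[p])) > 1L, logical(1)))
  var_map <- map[map$position %in% var_pos &
                 map$codon_index %in% as.integer(complete), , drop = FALSE]
  third_frac <- if (nrow(var_map)) mean(var_map$codon_position == 3L)
    else NA_real_

  structure(list(
    effects = effects,
    n_codons_total = n_total,
    n_affected_union = n_affected_union,
    n_affected_per_sequence = n_affected_perseq,
    pct_affected_union = if (n_total) 100 * n_affected_union / n_total
      else NA_real_,
    third_position_fraction = third_frac,
    excluded_partial = excluded_partial,
    excluded_unresolvable = unresolvable
  ), class = "codon_effect_table")
}

#' @export
print.codon_effect_table <- function(x, ...) {
  cat("codon effect table: ", x$n_codons_total, " complete codons\n",
      "  nonsynonymous (union of isolates): ", x$n_affected_union,
      sprintf(" (%.1f%%)", x$pct_affected_union), "\n",
      "  nonsynonymous (within >=1 isolate): ",
      x$n_affected_per_sequence, "\n", sep = "")
  if (!is.na(x$third_position_fraction))
    cat(sprintf("  variable sites at third codon positions: %.1f%%\n",
                100 * x$third_position_fraction))
  invisible(x)
}
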