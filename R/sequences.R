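#' Construct an ambiguity-coded sequence record
#'
#' A light container for one amplicon consensus sequence: an id, the
#' residues (IUPAC alphabet, `-` allowed for aligned input) and a 1-based
#' coordinate offset locating the first residue in a named reference frame
#' (e.g. position within an ORF).
#'
#' @param residues Single string over the IUPAC nucleotide alphabet.
#' @param id Sequence identifier.
#' @param offset 1-based position of the first residue in the reference
#'   coordinate system (default 1).
#' @return An object of class `ambiguous_sequence`.
#' @examples
#' ambiguous_sequence("ACYGR", id = "demo")
#' @export
ambiguous_sequence <- function(residues, id = "seq", offset = 1L) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("U", "T", residues, ignore.case = TRUE))
  if (nchar(residues) < 1L)
    stop("sequence '", id, "' is empty", call. = FALSE)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_EXPANSION))
  if (length(bad))
    stop("illegal character '", chars[bad[1]], "' at position ", bad[1],
         " of sequence '", id, "'", call. = FALSE)
  if (!is.numeric(offset) || offset < 1)
    stop("offset must be >= 1", call. = FALSE)
  structure(list(id = as.character(id), residues = residues,
                 offset = as.integer(offset)),
            class = "ambiguous_sequence")
}

#' @export
print.ambiguous_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  head <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat("ambiguous_sequence '", x$id, "' (", n, " nt, offset ", x$offset, ")\n",
      "  ", head, "\n", sep = "")
  invisible(x)
}

# Coerce the accepted input shapes (ambiguous_sequence, named character
# vector, Biostrings XStringSet, list of either) to a named character vector
# of validated residue strings.
as_residue_set <- function(seqs) {
  if (inherits(seqs, "ambiguous_sequence")) seqs <- list(seqs)
  if (methods::is(seqs, "XStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.list(seqs)) {
    ids <- vapply(seqs, function(s)
      if (inherits(s, "ambiguous_sequence")) s$id else NA_character_,
      character(1))
    res <- vapply(seqs, function(s)
      if (inherits(s, "ambiguous_sequence")) s$residues else as.character(s),
      character(1))
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      names(res) <- ifelse(is.na(ids), paste0("seq", seq_along(res)), ids)
    else names(res) <- names(seqs)
    seqs <- res
  }
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  # validate & normalise through the constructor
  out <- vapply(seq_along(seqs), function(i)
    ambiguous_sequence(seqs[[i]], id = names(seqs)[i])$residues, character(1))
  stats::setNames(out, names(seqs))
}

residue_chars <- function(residues) strsplit(residues, "", fixed = TRUE)[[1]]

#' Read ambiguity-coded sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a named
#' character vector with `U` mapped to `T` and validation of every symbol.
#'
#' @param path Path to a (plain or aligned) FASTA file.
#' @return Named character vector of upper-case residue strings.
#' @export
read_ambiguous_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    stop("FASTA file contains no sequences: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  as_residue_set(stats::setNames(as.character(set), ids))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (or any shape accepted by the scan
#'   functions) of residue strings.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ambiguous_fasta <- function(seqs, path) {
  seqs <- as_residue_set(seqs)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

# round half away from zero, the convention used for headline percentages
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
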