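
# IUPAC nucleotide ambiguity codes and their expansions over {A,C,G,T}.
# The gap character '-' is carried as a distinct non-nucleotide code with an
# empty expansion; it is never treated as a fifth base.
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"),
  `-` = character(0)
)

# reverse lookup: sorted expansion -> symbol
.IUPAC_ENCODE <- local({
  keys <- vapply(IUPAC_EXPANSION, function(x) paste(sort(x), collapse = ""),
                 character(1))
  stats::setNames(names(IUPAC_EXPANSION), keys)
})

.normalize_symbol <- function(symbol) {
  s <- toupper(symbol)
  s[s == "U"] <- "T"
  s
}

#' Expand an IUPAC nucleotide code to its defining base set
#'
#' Maps each IUPAC ambiguity symbol to the set of nucleotides it stands for,
#' e.g. `Y` (a C/T dimorphism) to `c("C", "T")`. Input is case-insensitive
#' and `U` is accepted as a synonym of `T` so that RNA-alphabet sequences
#' (e.g. rRNA-derived barcodes) can be scanned directly. The gap character
#' `-` is a legal code with an empty expansion.
#'
#' @param symbol A single character: one of `A C G T U R Y S W K M B D H V N -`
#'   (any case).
#' @param context Optional string naming where the symbol came from
#'   (sequence id, position); used in error messages only.
#' @return Character vector of bases from `A C G T` (empty for the gap).
#' @examples
#' expand_code("Y")  # "C" "T"
#' expand_code("N")  # all four bases
#' @seealso [encode_consensus()] for the inverse operation.
#' @export
expand_code <- function(symbol, context = NULL) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nchar(symbol) == 1L)
  s <- .normalize_symbol(symbol)
  exp <- IUPAC_EXPANSION[[s]]
  if (is.null(exp)) {
    where <- if (is.null(context)) "" else paste0(" (", context, ")")
    stop("unknown IUPAC nucleotide symbol '", symbol, "'", where, call. = FALSE)
  }
  exp
}

#' Encode a nucleotide set as its IUPAC consensus symbol
#'
#' Inverse of [expand_code()]: a nonempty subset of `{A,C,G,T}` is mapped to
#' the unique IUPAC symbol whose expansion it is (`{C,T}` to `Y`, the full
#' set to `N`).
#'
#' @param nucs Character vector of bases (duplicates tolerated, any case,
#'   `U` read as `T`). Must be nonempty after de-duplication.
#' @return A single upper-case IUPAC symbol.
#' @examples
#' encode_consensus(c("C", "T"))  # "Y"
#' @export
encode_consensus <- function(nucs) {
  nucs <- unique(.normalize_symbol(nucs))
  if (length(nucs) == 0L)
    stop("cannot encode an empty nucleotide set", call. = FALSE)
  if (!all(nucs %in% c("A", "C", "G", "T")))
    stop("nucleotide set may only contain A, C, G, T; got: ",
         paste(nucs, collapse = ","), call. = FALSE)
  .IUPAC_ENCODE[[paste(sort(nucs), collapse = "")]]
}

#' Classify the morphism of a site from its nucleotide set
#'
#' Sites at which copies of a locus within one genome disagree show up as
#' ambiguity codes in amplicon consensus sequencing. The number of
#' alternating nucleotides classifies the site: one base is `invariant`, two
#' alternating bases are a single-nucleotide dimorphism (`SND`), three a
#' trimorphism (`SNT`), and four a tetramorphism (`SNP` in this usage).
#'
#' @param nucs Nonempty character vector of bases from `{A,C,G,T}`.
#' @return One of `"invariant"`, `"SND"`, `"SNT"`, `"SNP"`.
#' @examples
#' classify_morphism(c("C", "T"))       # "SND"
#' classify_morphism(c("A", "C", "G"))  # "SNT"
#' @export
classify_morphism <- function(nucs) {
  nucs <- unique(.normalize_symbol(nucs))
  if (length(nucs) == 0L || !all(nucs %in% c("A", "C", "G", "T")))
    stop("morphism is defined for nonempty subsets of {A,C,G,T}", call. = FALSE)
  c("invariant", "SND", "SNT", "SNP")[length(nucs)]
}

#' Transition or transversion?
#'
#' Classifies an unordered pair of distinct nucleotides: purine-purine
#' (`{A,G}`) and pyrimidine-pyrimidine (`{C,T}`) exchanges are transitions;
#' the four purine-pyrimidine pairs are transversions.
#'
#' @param pair Character vector containing exactly two distinct bases.
#' @return `"transition"` or `"transversion"`.
#' @examples
#' substitution_type(c("A", "G"))  # "transition"
#' substitution_type(c("A", "T"))  # "transversion"
#' @export
substitution_type <- function(pair) {
  pair <- unique(.normalize_symbol(pair))
  if (length(pair) != 2L || !all(pair %in% c("A", "C", "G", "T")))
    stop("substitution type is defined for pairs of two distinct bases",
         call. = FALSE)
  key <- paste(sort(pair), collapse = "")
  if (key %in% c("AG", "CT")) "transition" else "transversion"
}
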