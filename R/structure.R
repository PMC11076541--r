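# Secondary-structure context of variable sites: dot-bracket parsing,
# loop/stem annotation, wobble-pairing neutrality.

#' Parse a dot-bracket secondary structure
#'
#' Stack-matches a single-tier dot-bracket string (characters `(`, `)` and
#' `.`; pseudoknots unsupported) into a symmetric pair map.
#'
#' @param s Dot-bracket string.
#' @return Object of class `secondary_structure`: `dotbracket`, `length`,
#'   `pair_map` (integer vector, `NA` where unpaired).
#' @examples
#' parse_dotbracket("((..))")
#' @export
parse_dotbracket <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad))
    stop("illegal structure character '", chars[bad[1]], "' at position ",
         bad[1], call. = FALSE)
  n <- length(chars)
  pair_map <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L)
        stop("unbalanced structure: unmatched ')' at position ", i,
             call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair_map[i] <- j
      pair_map[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced structure: unmatched '(' at position ", stack[1],
         call. = FALSE)
  structure(list(dotbracket = s, length = n, pair_map = pair_map),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("secondary_structure (", x$length, " nt, ",
      sum(!is.na(x$pair_map)) / 2, " pairs)\n  ", x$dotbracket, "\n",
      sep = "")
  invisible(x)
}

#' Serialize a pair map back to dot-bracket
#' @param struct A `secondary_structure`.
#' @return Dot-bracket string.
#' @export
format_dotbracket <- function(struct) {
  stopifnot(inherits(struct, "secondary_structure"))
  out <- rep(".", struct$length)
  paired <- which(!is.na(struct$pair_map))
  out[paired] <- ifelse(struct$pair_map[paired] > paired, "(", ")")
  paste(out, collapse = "")
}

#' Read a Vienna-format structure file
#'
#' Expects an optional FASTA-style header line, a sequence line and a
#' dot-bracket structure line (energy annotations after whitespace are
#' dropped).
#'
#' @param path File path.
#' @return List with `id`, `sequence` and `structure`
#'   (a `secondary_structure`).
#' @export
read_vienna <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  id <- "structure"
  if (length(lines) && startsWith(lines[1], ">")) {
    id <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 2L)
    stop("Vienna file needs a sequence line and a structure line: ", path,
         call. = FALSE)
  seq <- toupper(gsub("U", "T", trimws(lines[1]), ignore.case = TRUE))
  db <- strsplit(trimws(lines[2]), "\\s+")[[1]][1]
  struct <- parse_dotbracket(db)
  if (nchar(seq) != struct$length)
    stop("sequence and structure lengths differ in ", path, call. = FALSE)
  list(id = id, sequence = seq, structure = struct)
}

#' Loop/stem context of a set of sites
#'
#' Labels each given position `loop` (unpaired) or `paired` and reports
#' the fraction of the sites that fall in loops. Variable blocks of rRNA
#' barcodes sitting entirely in hairpin loops give a loop fraction of 1.
#'
#' @param struct A `secondary_structure`.
#' @param sites Integer vector of 1-based positions (may be empty).
#' @return List with `context` (data frame `position`, `context`,
#'   `partner`), `loop_fraction` (`NA` when `sites` is empty) and
#'   `n_sites`.
#' @examples
#' site_context(parse_dotbracket("((..))"), c(3, 4))$loop_fraction  # 1
#' @export
site_context <- function(struct, sites) {
  stopifnot(inherits(struct, "secondary_structure"))
  sites <- as.integer(sites)
  if (length(sites) && (min(sites) < 1L || max(sites) > struct$length))
    stop("site position out of range 1..", struct$length, call. = FALSE)
  partner <- struct$pair_map[sites]
  ctx <- ifelse(is.na(partner), "loop", "paired")
  list(context = data.frame(position = sites, context = ctx,
                            partner = partner, stringsAsFactors = FALSE),
       loop_fraction = if (length(sites)) mean(ctx == "loop") else NA_real_,
       n_sites = length(sites))
}

# legal RNA pairs on the DNA alphabet (T stands for U): Watson-Crick + G.U
.LEGAL_PAIRS <- c("AT", "TA", "GC", "CG", "GT", "TG")

#' Wobble-neutrality of a variable site within a helix
#'
#' A substitution at a paired site can be structurally neutral when every
#' alternative base still forms a legal pair (Watson-Crick or G·U wobble)
#' with the partner position. Under the default `partner_rule = "any"`, a
#' base is acceptable when it pairs with at least one base of the
#' partner's expansion; the stricter `"all"` rule demands that every
#' combination of site base and partner base be legal.
#'
#' @param seq Sequence (same length as the structure).
#' @param struct A `secondary_structure`.
#' @param position 1-based site position.
#' @param partner_rule `"any"` (existential, default) or `"all"`.
#' @return `"neutral"`, `"disruptive"`, or `"unpaired"`.
#' @examples
#' s <- parse_dotbracket("((..))")
#' wobble_check("GYAARC", s, 2)  # "neutral"
#' wobble_check("GMAAGC", s, 2)  # "disruptive": A with G is not a legal pair
#' @export
wobble_check <- function(seq, struct, position, partner_rule = c("any", "all")) {
  partner_rule <- match.arg(partner_rule)
  stopifnot(inherits(struct, "secondary_structure"))
  residues <- as_residue_set(seq)[[1]]
  if (nchar(residues) != struct$length)
    stop("sequence and structure lengths differ", call. = FALSE)
  position <- as.integer(position)
  if (position < 1L || position > struct$length)
    stop("position out of range", call. = FALSE)
  j <- struct$pair_map[position]
  if (is.na(j)) return("unpaired")
  here <- expand_code(substr(residues, position, position),
                      context = paste("position", position))
  there <- expand_code(substr(residues, j, j),
                       context = paste("position", j))
  if (length(here) == 0L || length(there) == 0L) return("unpaired")
  ok_one <- function(b) {
    legal <- paste0(b, there) %in% .LEGAL_PAIRS
    if (partner_rule == "any") any(legal) else all(legal)
  }
  if (all(vapply(here, ok_one, logical(1)))) "neutral" else "disruptive"
}

#' Wobble-neutral fraction of the paired variable sites
#'
#' Convenience summary over a site set: fraction of paired sites that are
#' wobble-neutral under [wobble_check()].
#'
#' @inheritParams wobble_check
#' @param sites Integer positions of variable sites.
#' @return List with per-site `status`, `loop_fraction`, and
#'   `wobble_neutral_fraction` (over paired sites; `NA` if none paired).
#' @export
structure_site_report <- function(seq, struct, sites,
                                  partner_rule = c("any", "all")) {
  partner_rule <- match.arg(partner_rule)
  ctx <- site_context(struct, sites)
  status <- vapply(as.integer(sites), function(p)
    wobble_check(seq, struct, p, partner_rule), character(1))
  paired <- status != "unpaired"
  list(status = data.frame(position = as.integer(sites), status = status,
                           stringsAsFactors = FALSE),
       loop_fraction = ctx$loop_fraction,
       wobble_neutral_fraction = if (any(paired))
         mean(status[paired] == "neutral") else NA_real_)
}
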