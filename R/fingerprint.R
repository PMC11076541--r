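# Binary band-pattern (RAPD / mtDNA-RFLP) analytics: filtering, distance
# coefficients, deterministic UPGMA with Newick output, pattern counting.

#' Construct a binary band-presence matrix
#'
#' @param presence Logical or 0/1 matrix, strains in rows, bands in
#'   columns.
#' @param strain_ids Row ids (default from rownames).
#' @param band_ids Column ids (default from colnames or `band1`, ...).
#' @param sizes Optional numeric vector of fragment sizes in bp, one per
#'   band.
#' @return Object of class `band_matrix`.
#' @export
band_matrix <- function(presence, strain_ids = rownames(presence),
                        band_ids = colnames(presence), sizes = NULL) {
  presence <- as.matrix(presence)
  mode(presence) <- "integer"
  if (nrow(presence) < 1L || ncol(presence) < 1L)
    stop("band matrix needs at least one strain and one band", call. = FALSE)
  if (!all(presence %in% c(0L, 1L)))
    stop("band matrix entries must be 0/1", call. = FALSE)
  if (is.null(strain_ids)) strain_ids <- paste0("strain", seq_len(nrow(presence)))
  if (is.null(band_ids)) band_ids <- paste0("band", seq_len(ncol(presence)))
  if (anyDuplicated(strain_ids) || anyDuplicated(band_ids))
    stop("duplicate strain or band ids", call. = FALSE)
  if (!is.null(sizes) && length(sizes) != ncol(presence))
    stop("sizes must have one entry per band", call. = FALSE)
  dimnames(presence) <- list(strain_ids, band_ids)
  structure(list(presence = presence, sizes = sizes), class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat("band_matrix: ", nrow(x$presence), " strains x ", ncol(x$presence),
      " bands", if (!is.null(x$sizes)) " (with fragment sizes)", "\n",
      sep = "")
  invisible(x)
}

#' Read a band matrix from CSV/TSV
#'
#' Strains in rows (first column = strain id), bands in columns. An
#' optional row named `size` (or `size_bp`) carries fragment sizes in bp.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return A [band_matrix()].
#' @export
read_band_matrix <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  sizes <- NULL
  size_row <- tolower(rownames(df)) %in% c("size", "size_bp", "bp")
  if (any(size_row)) {
    sizes <- as.numeric(df[which(size_row)[1], ])
    df <- df[!size_row, , drop = FALSE]
  }
  band_matrix(as.matrix(df), sizes = sizes)
}

#' Filter bands by fragment size
#'
#' Keeps bands strictly larger than `min_size_bp` (set
#' `strict = FALSE` to keep bands of exactly the threshold size too), the
#' rule used when only fragments above a size cutoff (e.g. 1 kb) are
#' scored. Strains are retained even when left without any band; such
#' strains are reported in a warning.
#'
#' @param matrix A [band_matrix()] with `sizes`.
#' @param min_size_bp Size threshold in bp.
#' @param strict Keep only bands with size > threshold (default `TRUE`).
#' @return A filtered [band_matrix()].
#' @export
filter_bands <- function(matrix, min_size_bp, strict = TRUE) {
  stopifnot(inherits(matrix, "band_matrix"))
  if (min_size_bp > 0 && is.null(matrix$sizes))
    stop("size filtering requested but the band matrix has no fragment sizes",
         call. = FALSE)
  if (min_size_bp <= 0 || is.null(matrix$sizes)) return(matrix)
  keep <- if (strict) matrix$sizes > min_size_bp else
    matrix$sizes >= min_size_bp
  if (!any(keep)) {
    warning("all bands fall below the size threshold; empty band set")
    keep[which.max(matrix$sizes)] <- FALSE  # keep none; build 0-col matrix
    pres <- matrix$presence[, keep, drop = FALSE]
    return(structure(list(presence = pres, sizes = matrix$sizes[keep]),
                     class = "band_matrix"))
  }
  pres <- matrix$presence[, keep, drop = FALSE]
  empty <- rownames(pres)[rowSums(pres) == 0L]
  if (length(empty))
    warning("strains with no bands after filtering: ",
            paste(empty, collapse = ", "))
  band_matrix(pres, sizes = matrix$sizes[keep])
}

#' Distance between two binary band patterns
#'
#' Similarity coefficients for presence/absence fingerprints: Jaccard
#' (shared / union), Dice (2 shared / (sum of band counts); the common
#' choice for dominant markers such as RAPD) and simple matching
#' (agreements / length, counting shared absences). Distance is
#' 1 - similarity.
#'
#' @param a,b Equal-length 0/1 (or logical) vectors.
#' @param coefficient `"dice"` (default), `"jaccard"` or
#'   `"simple_matching"`.
#' @return Distance in `[0, 1]`.
#' @examples
#' band_distance(c(1, 1, 0, 0), c(1, 0, 1, 0), "jaccard")  # 2/3
#' @export
band_distance <- function(a, b,
                          coefficient = c("dice", "jaccard",
                                          "simple_matching")) {
  coefficient <- match.arg(coefficient)
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    stop("band vectors must be equal length", call. = FALSE)
  both <- sum(a == 1L & b == 1L)
  either <- sum(a == 1L | b == 1L)
  sim <- switch(coefficient,
    jaccard = if (either == 0L) NA_real_ else both / either,
    dice = if (sum(a) + sum(b) == 0L) NA_real_
           else 2 * both / (sum(a) + sum(b)),
    simple_matching = sum(a == b) / length(a))
  if (is.na(sim)) {
    warning("both patterns empty; distance defined as 0 under ", coefficient)
    return(0)
  }
  1 - sim
}

#' All-pairs band distance matrix
#'
#' @param matrix A [band_matrix()].
#' @param coefficient See [band_distance()].
#' @return Symmetric numeric matrix with zero diagonal and strain ids as
#'   dimnames.
#' @export
band_distance_matrix <- function(matrix,
                                 coefficient = c("dice", "jaccard",
                                                 "simple_matching")) {
  coefficient <- match.arg(coefficient)
  stopifnot(inherits(matrix, "band_matrix"))
  pres <- matrix$presence
  n <- nrow(pres)
  d <- base::matrix(0, n, n, dimnames = list(rownames(pres), rownames(pres)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- band_distance(pres[i, ], pres[j, ], coefficient)
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair group method with arithmetic mean: repeatedly merges
#' the closest pair of clusters, placing the new node at half the merge
#' distance, and updates distances by the size-weighted average of the
#' members. Ties are broken deterministically: ids are ordered
#' lexicographically at the start and the tied pair with the lowest
#' (row, column) index in that ordering merges first. The result is an
#' ultrametric rooted tree serialized as Newick with branch lengths.
#'
#' @param d Symmetric distance matrix with ids as dimnames (or a
#'   [stats::dist]).
#' @return Object of class `upgma_tree`: `newick` (string), `ids`,
#'   `merge_heights`, and `phylo` (an [ape::phylo] tree).
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$newick  # ((A:1,B:1):2,C:3);
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2L)
    stop("UPGMA needs at least two ids", call. = FALSE)
  if (any(is.na(d)) || any(d < 0))
    stop("distance matrix must be nonnegative and free of NA", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(d)))
  ord <- order(ids)
  d <- d[ord, ord, drop = FALSE]
  ids <- ids[ord]

  n <- length(ids)
  newick <- ids           # partial Newick per active cluster
  height <- rep(0, n)     # current height of each active cluster
  size <- rep(1L, n)
  active <- seq_len(n)
  merge_heights <- numeric(0)
  while (length(active) > 1L) {
    m <- length(active)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dij <- d[active[i], active[j]]
      if (dij < best_d - 1e-15) { best_d <- dij; best <- c(i, j) }
    }
    i <- active[best[1]]; j <- active[best[2]]
    h <- best_d / 2
    merge_heights <- c(merge_heights, h)
    newick[i] <- sprintf("(%s:%s,%s:%s)", newick[i],
                         format(h - height[i], digits = 15),
                         newick[j], format(h - height[j], digits = 15))
    height[i] <- h
    # size-weighted average distance update
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- (size[i] * d[i, k] + size[j] * d[j, k]) /
        (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    active <- active[active != j]
  }
  nwk <- paste0(newick[active], ";")
  structure(list(newick = nwk, ids = ids, merge_heights = merge_heights,
                 phylo = ape::read.tree(text = nwk)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree over ", length(x$ids), " ids (root height ",
      format(max(x$merge_heights)), ")\n  ", x$newick, "\n", sep = "")
  invisible(x)
}

#' Write a tree to a Newick file
#' @param tree An `upgma_tree` or Newick string.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  nwk <- if (inherits(tree, "upgma_tree")) tree$newick else as.character(tree)
  writeLines(nwk, path)
  invisible(path)
}

#' Group strains by identical band patterns
#'
#' Strains with bitwise-identical presence rows are indistinguishable by
#' the fingerprint; this groups them, counts the distinct patterns, and
#' lists the undistinguishable pairs.
#'
#' @param matrix A [band_matrix()].
#' @return List with `n_patterns`, `classes` (list of strain-id vectors)
#'   and `undistinguishable_pairs` (two-column character matrix).
#' @export
distinct_patterns <- function(matrix) {
  stopifnot(inherits(matrix, "band_matrix"))
  pres <- matrix$presence
  key <- apply(pres, 1, paste, collapse = "")
  classes <- split(rownames(pres), key)
  names(classes) <- NULL
  classes <- classes[order(vapply(classes, `[`, character(1), 1))]
  pairs <- do.call(rbind, lapply(classes, function(members) {
    if (length(members) < 2L) return(NULL)
    t(utils::combn(sort(members), 2))
  }))
  if (is.null(pairs)) pairs <- base::matrix(character(0), ncol = 2)
  list(n_patterns = length(classes), classes = classes,
       undistinguishable_pairs = pairs)
}
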