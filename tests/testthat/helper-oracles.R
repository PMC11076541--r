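# Independent oracles and random-case generators used across the suite.

BASES <- c("A", "C", "G", "T")
AMBIG2 <- c("R", "Y", "S", "W", "K", "M")
AMBIG34 <- c("B", "D", "H", "V", "N")
ALL_CODES <- c(BASES, AMBIG2, AMBIG34)

# random ambiguity-coded sequence with exactly k ambiguous sites
random_ambiguous_seq <- function(L, k, codes = c(AMBIG2, AMBIG34)) {
  chars <- sample(BASES, L, replace = TRUE)
  if (k > 0) {
    at <- sample.int(L, k)
    chars[at] <- sample(codes, k, replace = TRUE)
  }
  paste(chars, collapse = "")
}

# brute-force resolution list via Biostrings' own IUPAC table (independent
# of the package's expansion machinery)
oracle_resolutions <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  exps <- lapply(chars, function(ch) strsplit(map[[ch]], "", fixed = TRUE)[[1]])
  grid <- expand.grid(exps, stringsAsFactors = FALSE)
  do.call(paste0, grid)
}

# brute-force maximum pairwise Hamming p-distance over all resolutions
# (row-vectorised inner comparison; callers keep the resolution count small)
oracle_max_divergence <- function(seq) {
  haps <- oracle_resolutions(seq)
  L <- nchar(seq)
  if (length(haps) == 1L) return(0)
  m <- do.call(rbind, strsplit(haps, "", fixed = TRUE))
  best <- 0L
  for (i in seq_len(nrow(m) - 1L)) {
    rest <- m[(i + 1L):nrow(m), , drop = FALSE]
    diffs <- rowSums(rest != matrix(m[i, ], nrow(rest), L, byrow = TRUE))
    best <- max(best, max(diffs))
  }
  best / L
}

# random ambiguity-coded sequence whose resolution count stays brute-force
# sized: at most two sites carry 3- or 4-fold codes, the rest are two-fold
random_bruteforce_seq <- function(L, k) {
  chars <- sample(BASES, L, replace = TRUE)
  if (k > 0) {
    at <- sample.int(L, k)
    n_wide <- min(k, sample(0:2, 1))
    codes <- c(sample(AMBIG34, n_wide, replace = TRUE),
               sample(AMBIG2, k - n_wide, replace = TRUE))
    chars[at] <- sample(codes)
  }
  paste(chars, collapse = "")
}

# brute-force codon effect by enumeration + Biostrings::translate
oracle_codon_effect <- function(codon) {
  res <- oracle_resolutions(codon)
  aas <- unique(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(res), no.init.codon = TRUE)))
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  n_var <- sum(nchar(Biostrings::IUPAC_CODE_MAP[chars]) > 1)
  if (n_var == 0L) "none"
  else if (length(aas) > 1L) "nonsynonymous" else "synonymous"
}

# random ultrametric tree as a cophenetic distance matrix: random
# agglomeration at strictly increasing heights
random_ultrametric_matrix <- function(n) {
  ids <- sprintf("t%02d", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  clusters <- as.list(seq_len(n))
  h <- 0
  while (length(clusters) > 1L) {
    h <- h + stats::runif(1, 0.05, 1)
    pick <- sample.int(length(clusters), 2)
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    D[a, b] <- 2 * h
    D[b, a] <- 2 * h
    clusters[[pick[1]]] <- c(a, b)
    clusters[[pick[2]]] <- NULL
  }
  D
}

# cophenetic matrix of an upgma_tree, aligned to the given id order
tree_cophenetic <- function(tree, ids) {
  cp <- ape::cophenetic.phylo(tree$phylo)
  cp[ids, ids]
}
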