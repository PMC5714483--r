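# Shared low-level sequence helpers.

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x) {
  !is.na(x) & nzchar(x) & !grepl("[^ACGT]", x)
}

#' Split equal-length sequences into a character matrix
#'
#' One row per sequence, one column per position.
#' @param seqs character vector of equal-length strings
#' @return character matrix of dim `c(length(seqs), nchar(seqs[1]))`
#' @keywords internal
#' @noRd
seq_char_matrix <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(character(0), nrow = 0, ncol = 0))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences must all have the same length")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = len, byrow = TRUE)
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b DNA strings of equal length
#' @return non-negative integer count of mismatching positions
#' @export
#' @examples
#' hamming("ACGTA", "TGCAT")
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): sequences have unequal lengths")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Minimum pairwise Hamming distance of a sequence set
#'
#' Scans all unordered pairs. Used to validate sample-index sets (which must
#' differ pairwise by at least 2 nt) and TAG catalogs (pairwise distance >= 3
#' is required before 1-mismatch tag matching may be enabled).
#'
#' @param seqs character vector of >= 2 equal-length DNA strings
#' @return the minimum Hamming distance over all unordered pairs
#' @export
#' @examples
#' min_pairwise_hamming(c("AAAAA", "AATTT", "GGCCA"))
min_pairwise_hamming <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least two sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences have unequal lengths")
  m <- seq_char_matrix(seqs)
  n <- nrow(m)
  len <- ncol(m)
  # accumulate an n x n mismatch-count matrix one position at a time
  d <- matrix(0L, n, n)
  for (k in seq_len(len)) {
    d <- d + outer(m[, k], m[, k], "!=")
  }
  min(d[upper.tri(d)])
}

# all unordered pairs with Hamming distance < min_dist, as a data.frame
hamming_violations <- function(seqs, min_dist) {
  m <- seq_char_matrix(seqs)
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (k in seq_len(ncol(m))) d <- d + outer(m[, k], m[, k], "!=")
  idx <- which(upper.tri(d) & d < min_dist, arr.ind = TRUE)
  data.frame(
    i = idx[, 1], j = idx[, 2],
    seq_i = seqs[idx[, 1]], seq_j = seqs[idx[, 2]],
    distance = d[idx],
    stringsAsFactors = FALSE
  )
}

#' Reverse-complement DNA strings
#'
#' Vectorised over its input; strict ACGT alphabet plus N.
#' @param x character vector of DNA strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(k) %% 1000L)
}
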