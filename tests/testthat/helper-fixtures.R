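# Shared fixtures and independent oracles, built in code at test time.

# tiny hand-built catalog with distance-3 tags (checked below in tests)
tiny_catalog <- function() {
  validate_catalog_df(data.frame(
    id = c("H2A_K34E", "H2A_K34Q", "H2B_del29-36"),
    histone = c("H2A", "H2A", "H2B"),
    allele = c("K34E", "K34Q", "del29-36"),
    residues = c("34", "34", paste(29:36, collapse = ",")),
    uptag = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"),
    downtag = c("TTTTTTTTTT", "ACACACACAC", "GTGTGTGTGT"),
    stringsAsFactors = FALSE
  ))
}

tiny_indices <- function() {
  validate_index_table(data.frame(
    sample_id = c("treated_rep1", "control_rep1"),
    index_seq = c("AATTT", "GGCCA"),
    condition = c("treated", "control"),
    replicate = c(1L, 1L),
    stringsAsFactors = FALSE
  ))
}

tiny_layout <- function() amplicon_layout(tag_length = 10L)

# brute-force all-pairs Hamming scan, independent of the package's
# matrix-based implementation
brute_min_hamming <- function(seqs) {
  best <- Inf
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) if (i < j) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    best <- min(best, sum(a != b))
  }
  best
}

# exhaustive two-sided exact test over all tables with the observed margins
brute_exact_test <- function(t, c, T_, C_) {
  K <- t + c; N <- T_ + C_
  xs <- max(0, T_ - (N - K)):min(T_, K)
  probs <- vapply(xs, function(x)
    choose(K, x) * choose(N - K, T_ - x) / choose(N, T_), numeric(1))
  obs <- probs[match(t, xs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# BH and Holm from their definitions
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  # q_(i) = min over cut indices j >= i of (m/j) * p_(j), clipped at 1
  qq <- vapply(seq_len(m), function(i)
    min(1, min(vapply(i:m, function(j) m / j * ranked[j], numeric(1)))),
    numeric(1))
  out <- numeric(m)
  out[ord] <- qq
  out
}

brute_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- vapply(seq_len(m), function(i)
    min(1, max(vapply(1:i, function(j) (m - j + 1) * ranked[j], numeric(1)))),
    numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# read pairs constructed from a layout, for demux/extract tests
make_read1 <- function(index, tag, layout = tiny_layout()) {
  paste0(strrep("A", layout$index_offset), index, layout$upstream_flank,
         tag, layout$downstream_flank)
}
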