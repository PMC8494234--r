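# shared fixtures, all generated in code

toy_genome <- function() genome_table(c("chr1", "chr2"), c(10000, 8000))

# a whitelist whose entries are mutually far apart (pairwise Hamming > 8)
toy_whitelist <- function() c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG",
                              "TTTTTTTTTT")

mutate_barcode <- function(bc, positions, to) {
  s <- strsplit(bc, "")[[1]]
  s[positions] <- to
  paste(s, collapse = "")
}

toy_fragments <- function() {
  data.table::data.table(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 100L, 500L, 30L),
    end = c(200L, 200L, 650L, 90L),
    barcode = c("AAAAAAAAAA", "AAAAAAAAAA", "CCCCCCCCCC", "CCCCCCCCCC"))
}

# exact collapsed posterior of a tiny binary LDA corpus by enumeration:
# returns per-token topic marginals (K x N)
enumerate_lda_posterior <- function(tok_doc, tok_word, D, V, K, a, b) {
  N <- length(tok_doc)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logp <- apply(grid, 1, function(z) {
    lp <- 0
    for (d in seq_len(D)) for (k in seq_len(K))
      lp <- lp + lgamma(a + sum(z[tok_doc == d] == k)) - lgamma(a)
    for (k in seq_len(K)) {
      nk <- sum(z == k)
      lp <- lp + lgamma(b * V) - lgamma(b * V + nk)
      for (w in seq_len(V))
        lp <- lp + lgamma(b + sum(z[tok_word == w] == k)) - lgamma(b)
    }
    lp
  })
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sapply(seq_len(N), function(i)
    sapply(seq_len(K), function(k) sum(p[grid[, i] == k])))
}

# brute-force valley oracle: boundary between two summits is the minimum
# position, ties resolved toward the summit midpoint (smaller on exact tie)
valley_oracle <- function(v, s1, s2) {
  between <- s1:s2
  cand <- between[v[between] == min(v[between])]
  cand[which.min(abs(cand - (s1 + s2) / 2))]
}

# brute-force slope-jump oracle for sorted outlier fractions: the index of
# the largest consecutive difference in the sorted values
slope_jump_oracle <- function(values) {
  s <- sort(values)
  which.max(diff(s))
}
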