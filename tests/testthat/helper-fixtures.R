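# Shared fixtures, all built in code.

# Tiny expression matrix with two conditions (n_a + n_b samples).
toy_matrix <- function(n_probes = 10, n_a = 4, n_b = 4, seed = 1,
                       conditions = c("A", "B")) {
  set.seed(seed)
  n <- n_a + n_b
  x <- matrix(rnorm(n_probes * n), n_probes, n,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n))))
  cond <- setNames(rep(conditions, c(n_a, n_b)), colnames(x))
  expression_matrix(x, cond)
}

# Planted two-block distance matrix (criterion fixture): two groups of
# `half`, within-block distances 0.1 +/- 0.01, between-block 1.0.
two_block_distance <- function(half = 20, seed = 1,
                               within = 0.1, between = 1.0, jitter = 0.01) {
  set.seed(seed)
  n <- 2 * half
  D <- matrix(between, n, n)
  for (blk in list(seq_len(half), half + seq_len(half))) {
    w <- matrix(within + runif(half^2, -jitter, jitter), half, half)
    w <- (w + t(w)) / 2
    D[blk, blk] <- w
  }
  diag(D) <- 0
  dimnames(D) <- list(sprintf("g%02d", seq_len(n)),
                      sprintf("g%02d", seq_len(n)))
  D
}

# Exact partition check: does any temperature's partition equal the two
# planted blocks?
recovers_two_blocks <- function(profile, half = 20) {
  any(apply(profile$membership, 1, function(lab) {
    length(unique(lab)) == 2 &&
      all(lab[seq_len(half)] == lab[1]) &&
      all(lab[half + seq_len(half)] == lab[half + 1]) &&
      lab[1] != lab[half + 1]
  }))
}

# Brute-force position-by-position degenerate motif scanner (oracle).
brute_motif_hits <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- length(positions)
  if (L < k) return(integer())
  hits <- integer()
  for (s in seq_len(L - k + 1)) {
    ok <- TRUE
    for (p in seq_len(k)) {
      if (!(chars[s + p - 1] %in% positions[[p]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
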