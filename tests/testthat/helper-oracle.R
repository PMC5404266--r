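# Shared fixtures and an independent brute-force re-implementation of the
# NPPS conditional-probability encoding, used as the oracle for the fast
# matrix-based encoder.

BASES <- c("A", "C", "G", "U")

random_windows <- function(n, l) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, l, replace = TRUE), collapse = ""), character(1L))
}

make_labeled_dataset <- function(pos_seqs, neg_seqs) {
  npps_dataset(c(pos_seqs, neg_seqs),
               label = rep(c("positive", "negative"),
                           c(length(pos_seqs), length(neg_seqs))))
}

# recount f and F from scratch for every query position: the slow oracle
brute_force_conditional <- function(train_seqs, query, xi, alpha = 0) {
  l <- nchar(query)
  n <- length(train_seqs)
  q <- strsplit(query, "")[[1L]]
  tr <- strsplit(train_seqs, "")
  vapply(seq_len(l - xi - 1L), function(k) {
    k2 <- k + xi + 1L
    pair_count <- sum(vapply(tr, function(s)
      s[k] == q[k] && s[k2] == q[k2], logical(1L)))
    single_count <- sum(vapply(tr, function(s) s[k2] == q[k2], logical(1L)))
    F_jk <- (pair_count + alpha) / (n + 16 * alpha)
    f_ik <- (single_count + alpha) / (n + 4 * alpha)
    if (f_ik == 0) 0 else F_jk / f_ik
  }, numeric(1L))
}

brute_force_encode <- function(pos_seqs, neg_seqs, query, xi, alpha = 0) {
  brute_force_conditional(pos_seqs, query, xi, alpha) -
    brute_force_conditional(neg_seqs, query, xi, alpha)
}

# two tight, well-separated Gaussian blobs for classifier tests
gaussian_blobs <- function(n_per_class, d = 2L, separation = 6, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * d, separation / 2), ncol = d),
             matrix(stats::rnorm(n_per_class * d, -separation / 2),
                    ncol = d))
  list(x = x, y = rep(c(1L, -1L), each = n_per_class))
}
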