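# Independent brute-force oracles, kept deliberately naive.

# D_n scan by exhaustive double loop over split positions and evaluation
# points (all observed values and points just below them, covering both
# one-sided limits of the step functions).
brute_dn <- function(control, case) {
  n1 <- length(control); n <- n1 + length(case)
  x <- c(control, case)
  ys <- sort(c(x, x - 1e-8))
  vapply(n1:(n - 1), function(m) {
    tail <- x[(m + 1):n]
    sup <- 0
    for (y in ys) {
      d <- abs(mean(tail <= y) - mean(control <= y))
      if (d > sup) sup <- d
    }
    sqrt(m * (n - m) / n) * sup
  }, numeric(1))
}

# probability-of-correct-ordering (rank-sum) AUC estimator
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  np <- sum(labels); nn <- sum(!labels)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# one Monte Carlo AUC measurement for a simulation cell
cell_auc <- function(n_half, mu, k, n_genes, dge_fraction = 0.15,
                     method = "wcps") {
  nd <- round(n_genes * dge_fraction)
  labels <- c(rep(TRUE, nd), rep(FALSE, n_genes - nd))
  f <- dge_methods()[[method]]
  scores <- vapply(seq_len(n_genes), function(j) {
    g <- generate_gene(n_half, n_half, if (labels[j]) k else 0,
                       if (labels[j]) mu else 0)
    f(g)
  }, numeric(1))
  rank_auc(scores, labels)
}
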