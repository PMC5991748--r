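# Shared fixtures and independent oracles used across the test files.

# A small labelled expression matrix (features x samples).
toy_expression <- function(n_features = 5, n_samples = 10, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_features * n_samples), n_features, n_samples)
    dimnames(m) <- list(sprintf("f%02d", seq_len(n_features)),
                        sprintf("s%02d", seq_len(n_samples)))
    m
  })
}

# O(n^3) brute-force topological overlap, straight from the formula.
tom_brute_force <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) shared <- shared + a[i, u] * a[u, j]
      tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Exhaustive upper-tail hypergeometric sum via binomial coefficients.
hyper_tail_exhaustive <- function(overlap, size_a, size_b, n) {
  kk <- seq(overlap, min(size_a, size_b))
  sum(choose(size_a, kk) * choose(n - size_a, size_b - kk)) /
    choose(n, size_b)
}

# All-pairs concordance AUC with ties counted one half.
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Standard soft-margin SVM (mean hinge + lam * ||w||^2, unpenalized bias)
# solved through its dual with kernlab's interior-point QP code.
qp_svm_oracle <- function(x, y, lam) {
  n <- ncol(x)
  kk <- crossprod(x)
  h <- (y %o% y) * kk / (2 * lam)
  sv <- kernlab::ipop(c = matrix(-1, n, 1), H = h,
                      A = matrix(y, 1, n), b = 0,
                      l = matrix(0, n, 1), u = matrix(1 / n, n, 1), r = 0,
                      sigf = 12, maxiter = 400)
  a <- kernlab::primal(sv)
  w <- as.numeric(x %*% (a * y)) / (2 * lam)
  f <- as.numeric(t(x) %*% w)
  interior <- a > 1e-7 & a < 1 / n - 1e-7
  b <- if (any(interior)) mean(y[interior] - f[interior]) else NA_real_
  list(w = w, b = b)
}

# Block-correlated cohort matching the module-recovery study conditions.
recovery_design <- function(seed = 1) {
  synthetic_design(
    n_features = 300,
    module_sizes = c(40, 35, 30, 25, 22, 20, 15, 10, 8, 5),
    rho_within = 0.7,
    n_ref = 90, n_rep = 90, n_norm = 34,
    disrupted_in_norm = c(8, 9, 10),
    de_features = numeric(0),
    seed = seed
  )
}
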