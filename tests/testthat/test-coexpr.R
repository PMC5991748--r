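test_that("correlation matrix matches the textbook formula and flags bad input", {
  m <- toy_expression(5, 10)
  cc <- correlation_matrix(m)
  # direct covariance / sd computation, feature pair by feature pair
  for (i in 1:5) {
    for (j in 1:5) {
      xi <- m[i, ] - mean(m[i, ])
      xj <- m[j, ] - mean(m[j, ])
      expect_equal(cc[i, j], sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)),
                   tolerance = 1e-12)
    }
  }
  m2 <- rbind(m, dup = m[1, ], neg = -m[1, ])
  cc2 <- correlation_matrix(m2)
  expect_equal(unname(cc2["dup", "f01"]), 1)
  expect_equal(unname(cc2["neg", "f01"]), -1)

  m3 <- m
  m3[2, ] <- 5
  expect_error(correlation_matrix(m3), "f02")
  expect_error(correlation_matrix(m[, 1:2]), "3 samples")
})

test_that("scale-free fit is exact on log-linear data and flags degeneracy", {
  # frequencies 64, 16, 4, 1 at k = 1, 2, 4, 8: log-freq linear in log-k
  k <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
  fit <- scale_free_fit(k, n_bins = 8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$slope, 0)

  flat <- scale_free_fit(rep(3, 50))
  expect_equal(flat$r_squared, 0)
  expect_true(flat$degenerate)

  # sample from the power-law model the fit index assumes
  kp <- withr::with_seed(5, (1 - runif(500))^(-1 / 1.5))
  expect_gte(scale_free_fit(kp)$r_squared, 0.8)
})

test_that("power selection follows the smallest-adequate rule with fallback", {
  co <- generate_cohorts(synthetic_design(
    n_features = 60, module_sizes = c(15, 10, 8), rho_within = 0.7,
    de_features = numeric(0), disrupted_in_norm = integer(0), seed = 2))
  pw <- pick_power(co$ref, powers = 1:8, fit_cut = 0.5)
  # independent brute-force scan over the same grid
  cc <- abs(correlation_matrix(co$ref))
  r2 <- sapply(1:8, function(p) {
    a <- cc^p
    diag(a) <- 0
    scale_free_fit(rowSums(a))$r_squared
  })
  ok <- which(r2 >= 0.5)
  if (length(ok)) {
    expect_equal(pw$beta, ok[1])
    expect_true(pw$reached_cut)
  } else {
    expect_equal(pw$beta, which.max(r2))
    expect_false(pw$reached_cut)
  }
  # unreachable cut -> argmax with the flag cleared
  pw2 <- pick_power(co$ref, powers = 1:8, fit_cut = 0.999)
  expect_false(pw2$reached_cut)
  expect_equal(pw2$beta, which.max(r2))
  expect_error(pick_power(co$ref, powers = numeric(0)), "ascending")
})

test_that("TOM matches closed forms and the brute-force oracle", {
  # isolated pair: TOM equals the adjacency itself
  a <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  expect_equal(tom_matrix(a)[1, 2], 0.4)
  # complete unit-weight graph: all overlaps are 1
  n <- 6
  cg <- matrix(1, n, n)
  expect_true(all(abs(tom_matrix(cg) - 1) < 1e-12))

  withr::with_seed(11, {
    for (rep in 1:10) {
      nn <- sample(3:10, 1)
      aa <- matrix(runif(nn * nn), nn, nn)
      aa <- (aa + t(aa)) / 2
      diag(aa) <- 0
      expect_equal(tom_matrix(aa), tom_brute_force(aa), tolerance = 1e-12)
    }
  })
  expect_error(tom_matrix(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("dendrogram cut recovers planted blocks and honors min size", {
  # two well-separated blocks, sizes 10 and 5, plus similarity noise
  n <- 15
  tom <- withr::with_seed(8, {
    t0 <- matrix(0.05 + runif(n * n) * 0.02, n, n)
    t0[1:10, 1:10] <- 0.8 + runif(100) * 0.05
    t0[11:15, 11:15] <- 0.8 + runif(25) * 0.05
    t0 <- (t0 + t(t0)) / 2
    diag(t0) <- 1
    t0
  })
  rownames(tom) <- colnames(tom) <- sprintf("f%02d", 1:n)
  part <- cluster_and_cut(tom, min_module_size = 3)
  expect_equal(unname(part$module[1:10]), rep(1L, 10))
  expect_equal(unname(part$module[11:15]), rep(2L, 5))
  expect_equal(part$color[1], "turquoise")
  expect_equal(max(part$module), 2)

  # a planted block of 2 falls below the min size and goes grey
  tom2 <- tom
  part2 <- cluster_and_cut(tom2[c(1:10, 11:12), c(1:10, 11:12)],
                           min_module_size = 3)
  expect_equal(unname(part2$module[11:12]), c(0L, 0L))
  expect_equal(part2$color[11], "grey")

  # flat similarity: one flagged module spanning everything
  flat <- matrix(0.5, 6, 6)
  diag(flat) <- 1
  expect_warning(pf <- cluster_and_cut(flat), "flat dendrogram")
  expect_true(all(pf$module == 1))
  expect_true(attr(pf, "degenerate"))

  expect_warning(p0 <- cluster_and_cut(flat[1:2, 1:2], min_module_size = 3),
                 "fewer features")
  expect_true(all(p0$module == 0))
})

test_that("module detection is deterministic and recovers planted modules", {
  co <- generate_cohorts(recovery_design(seed = 2))
  d1 <- detect_modules(co$ref)
  d2 <- detect_modules(co$ref)
  expect_identical(as_tibble(d1$partition), as_tibble(d2$partition))
  ari <- adjusted_rand_index(d1$partition$module, co$truth$module)
  expect_gte(ari, 0.9)
})

test_that("eigengenes explain module variance and orient consistently", {
  m <- toy_expression(6, 12, seed = 2)
  # module of identical features: eigengene explains everything
  ident <- rbind(a = m[1, ], b = m[1, ], c = m[1, ])
  part <- mirmod:::new_partition(c("a", "b", "c"), c(1, 1, 1))
  me <- module_eigengene(ident, part)
  expect_equal(me$prop_var_expl$prop_var_expl, 1, tolerance = 1e-12)
  expect_gt(cor(me$eigengenes[, "ME1"], ident["a", ]), 0.999)

  # sign-flipping all members re-orients the eigengene, pve unchanged
  me_flip <- module_eigengene(-ident, part)
  expect_equal(me_flip$prop_var_expl$prop_var_expl, 1, tolerance = 1e-12)
  expect_gt(cor(me_flip$eigengenes[, "ME1"], -ident["a", ]), 0.999)

  # SVD-based independent recomputation for a 5-member module
  mm <- m[1:5, ]
  part5 <- mirmod:::new_partition(rownames(mm), rep(1, 5))
  me5 <- module_eigengene(mm, part5)
  zs <- t(scale(t(mm)))
  sv <- svd(zs)
  eg <- sv$v[, 1]
  if (mean(cor(t(mm), eg)) < 0) eg <- -eg
  expect_equal(abs(cor(me5$eigengenes[, "ME1"], eg)), 1, tolerance = 1e-10)
  expect_equal(me5$prop_var_expl$prop_var_expl,
               mean(cor(t(mm), eg)^2), tolerance = 1e-10)
})

test_that("kME and kIM follow their definitions", {
  m <- toy_expression(6, 15, seed = 3)
  m[2, ] <- m[1, ]
  m[3, ] <- m[1, ] + rnorm(15, sd = 1e-6)
  part <- mirmod:::new_partition(rownames(m), c(1, 1, 1, 2, 2, 0))
  net <- build_network(m, beta = 2)
  kk <- kme_and_kim(m, net, part)
  expect_equal(unname(kk$kme[1:3, "ME1"]), rep(1, 3), tolerance = 1e-4)
  expect_equal(kk$kim$kim[kk$kim$module == 0], 0)
  # manual row-sum over own-module columns
  a <- net$adjacency
  diag(a) <- 0
  expect_equal(kk$kim$kim[1], sum(a[1, 2:3]))
  expect_equal(kk$kim$kim[4], a[4, 5])
})

test_that("thresholded edge lists respect the cutoff and quantile rules", {
  co <- generate_cohorts(synthetic_design(
    n_features = 30, module_sizes = c(10, 8), rho_within = 0.8,
    de_features = numeric(0), disrupted_in_norm = integer(0), seed = 6))
  net <- build_network(co$ref, beta = 4)
  ed <- network_edges(net, cutoff = 0.2)
  expect_true(all(ed$weight >= 0.2))
  off <- net$tom[upper.tri(net$tom)]
  expect_equal(nrow(ed), sum(off >= 0.2))
  edq <- network_edges(net, quantile = 0.9)
  expect_equal(nrow(edq), sum(off >= quantile(off, 0.9)))
})
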