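test_that("observed density statistics match hand computation", {
  m <- toy_expression(4, 12, seed = 21)
  # identical members: everything saturates at 1
  ident <- rbind(a = m[1, ], b = m[1, ], c = m[1, ])
  ds <- observed_density_stats(ident, c("a", "b", "c"), beta = 6)
  expect_equal(ds$mean_cor, 1, tolerance = 1e-12)
  expect_equal(ds$mean_adj, 1, tolerance = 1e-12)
  expect_equal(ds$prop_var_expl, 1, tolerance = 1e-12)
  expect_equal(ds$mean_kme, 1, tolerance = 1e-12)

  # 4-member toy vs manual correlation averages
  ds4 <- observed_density_stats(m, rownames(m), beta = 3)
  cc <- cor(t(m))
  manual_cor <- mean(cc[upper.tri(cc)])
  expect_equal(ds4$mean_cor, manual_cor, tolerance = 1e-10)
  expect_equal(ds4$mean_adj, mean(abs(cc[upper.tri(cc)])^3),
               tolerance = 1e-10)

  # pairwise-independent members at large n: near-zero statistics
  big <- toy_expression(4, 4000, seed = 22)
  dsi <- observed_density_stats(big, rownames(big), beta = 1)
  expect_lt(abs(dsi$mean_cor), 0.05)
  expect_lt(abs(dsi$prop_var_expl - 1 / 4), 0.08)

  expect_error(observed_density_stats(m, c("f01", "nope"), 2), "nope")
})

test_that("connectivity statistics are exact under self-comparison", {
  m <- toy_expression(6, 20, seed = 31)
  cs <- observed_connectivity_stats(m, m, rownames(m), beta = 4)
  expect_equal(cs$cor_kim, 1, tolerance = 1e-12)
  expect_equal(cs$cor_kme, 1, tolerance = 1e-12)
  expect_equal(cs$cor_cor, 1, tolerance = 1e-12)

  # direct recomputation with independently written formulas
  m2 <- toy_expression(6, 20, seed = 32)
  cs2 <- observed_connectivity_stats(m, m2, rownames(m), beta = 4)
  cc_r <- cor(t(m))
  cc_t <- cor(t(m2))
  adj <- function(cc) {
    a <- abs(cc)^4
    diag(a) <- 0
    a
  }
  expect_equal(cs2$cor_kim,
               cor(rowSums(adj(cc_r)), rowSums(adj(cc_t))),
               tolerance = 1e-10)
  expect_equal(cs2$cor_cor,
               cor(cc_r[upper.tri(cc_r)], cc_t[upper.tri(cc_t)]),
               tolerance = 1e-10)
  expect_error(observed_connectivity_stats(m, m2, rownames(m)[1:2], 2),
               "at least 3")
})

test_that("the combined statistic pass agrees with the two public functions", {
  m_ref <- toy_expression(8, 25, seed = 41)
  m_test <- toy_expression(8, 25, seed = 42)
  members <- rownames(m_ref)[2:6]
  all7 <- mirmod:::module_stats_all(m_ref, m_test, members, beta = 5)
  d <- observed_density_stats(m_test, members, 5)
  cs <- observed_connectivity_stats(m_ref, m_test, members, 5)
  expect_equal(unname(all7[c("mean_cor", "mean_adj", "prop_var_expl",
                             "mean_kme")]),
               unname(unlist(d)), tolerance = 1e-12)
  expect_equal(unname(all7[c("cor_kim", "cor_kme", "cor_cor")]),
               unname(unlist(cs)), tolerance = 1e-12)
})

test_that("permutation null standardizes and flags degeneracy correctly", {
  m_ref <- toy_expression(12, 15, seed = 51)
  m_test <- toy_expression(12, 15, seed = 52)

  stat <- function(rr, tt, mem) mean(cor(t(tt[mem, ]))[upper.tri(diag(4))])
  pn <- permutation_null(m_ref, m_test, 4, stat, observed = 0.3,
                         n_perm = 50, seed = 5)
  # independent reimplementation of the same permutation loop
  manual <- local({
    ids <- sort(rownames(m_test))
    vals <- numeric(50)
    mirmod:::with_seed(5, {
      for (i in 1:50) {
        mem <- sample(ids, 4)
        vals[i] <- stat(m_ref, m_test, mem)
      }
    })
    vals
  })
  expect_equal(pn$mean, mean(manual), tolerance = 1e-12)
  expect_equal(pn$sd, sd(manual), tolerance = 1e-12)
  expect_equal(pn$z, (0.3 - mean(manual)) / sd(manual), tolerance = 1e-12)

  # observed equal to the permutation mean gives Z = 0
  pn0 <- permutation_null(m_ref, m_test, 4, stat, observed = pn$mean,
                          n_perm = 50, seed = 5)
  expect_equal(pn0$z, 0, tolerance = 1e-12)

  # constant statistic: flagged degenerate, never infinite
  const <- function(rr, tt, mem) 1
  pnc <- permutation_null(m_ref, m_test, 4, const, observed = 2,
                          n_perm = 20, seed = 1)
  expect_true(pnc$degenerate)
  expect_true(is.na(pnc$z))
  pnc0 <- permutation_null(m_ref, m_test, 4, const, observed = 1,
                           n_perm = 20, seed = 1)
  expect_equal(pnc0$z, 0)
  expect_error(permutation_null(m_ref, m_test, 99, const, 1, 20, 1),
               "exceeds")
})

test_that("Z_summary combines the medians per its definition", {
  z <- c(z_mean_cor = 2, z_mean_adj = 2, z_prop_var_expl = 2,
         z_mean_kme = 2, z_cor_kim = 2, z_cor_kme = 2, z_cor_cor = 2)
  expect_equal(zsummary(z)$z_summary, 2)
  z2 <- c(z_mean_cor = 1, z_mean_adj = 2, z_prop_var_expl = 3,
          z_mean_kme = 4, z_cor_kim = 0, z_cor_kme = 0, z_cor_cor = 0)
  out <- zsummary(z2)
  expect_equal(out$z_density, 2.5)
  expect_equal(out$z_connectivity, 0)
  expect_equal(out$z_summary, 1.25)
  expect_equal(zsummary(setNames(rep(0, 7), names(z)))$z_summary, 0)
  z_na <- z
  z_na["z_cor_cor"] <- NA_real_
  expect_true(is.na(zsummary(z_na)$z_summary))
})

test_that("module classification applies the activated-biomarker rule", {
  cls <- classify_modules(z_vs_rep = c(3, -1, 11, 1, -0.2),
                          z_vs_norm = c(-0.5, -0.5, 4, 0.5, 3))
  expect_equal(cls$class, c("preserved", "activated", "strong", "weak",
                            "activated"))
  # disrupted vs norm AND reproducible vs rep -> biomarker
  expect_true(cls$activated_biomarker[1])
  # disrupted even vs the technical replicate -> excluded
  expect_false(cls$activated_biomarker[2])
  expect_false(any(cls$activated_biomarker[3:5]))
})

test_that("self-preservation yields strong positive Z for real modules", {
  d <- synthetic_design(n_features = 60, module_sizes = c(12, 8),
                        rho_within = 0.7, de_features = numeric(0),
                        disrupted_in_norm = integer(0), seed = 61)
  co <- generate_cohorts(d)
  part <- mirmod:::new_partition(co$truth$feature_id, co$truth$module)
  pres <- module_preservation(co$ref, co$ref, part, beta = 6,
                              n_perm = 100, seed = 7)
  expect_equal(pres$report$cor_kim, rep(1, 2), tolerance = 1e-12)
  expect_equal(pres$report$cor_cor, rep(1, 2), tolerance = 1e-12)
  expect_true(all(pres$report$z_summary >= 2))
})

test_that("preservation Z is invariant to feature and sample ordering", {
  d <- synthetic_design(n_features = 40, module_sizes = c(10, 6),
                        rho_within = 0.7, de_features = numeric(0),
                        disrupted_in_norm = integer(0), seed = 71)
  co <- generate_cohorts(d)
  part <- mirmod:::new_partition(co$truth$feature_id, co$truth$module)
  base <- module_preservation(co$ref, co$rep, part, beta = 4,
                              n_perm = 30, seed = 3)
  perm_rows <- withr::with_seed(1, sample(nrow(co$ref)))
  perm_cols <- withr::with_seed(2, c(1, 1 + sample(ncol(co$ref) - 1)))
  shuf <- module_preservation(co$ref[perm_rows, perm_cols],
                              co$rep, part, beta = 4,
                              n_perm = 30, seed = 3)
  expect_equal(base$report$z_summary, shuf$report$z_summary,
               tolerance = 1e-9)
})
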