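test_that("the normalized Laplacian matches its closed forms", {
  feats <- c("a", "b", "c")
  l0 <- build_laplacian(tibble::tibble(from = character(0),
                                       to = character(0)), feats)
  expect_equal(unname(l0), diag(3))

  l1 <- build_laplacian(tibble::tibble(from = "a", to = "b", weight = 1),
                        feats)
  expect_equal(unname(l1[1:2, 1:2]), matrix(c(1, -1, -1, 1), 2))
  expect_equal(unname(l1[3, ]), c(0, 0, 1))

  # quadratic-form identity on a small weighted graph
  edges <- tibble::tibble(from = c("a", "a", "b", "c"),
                          to = c("b", "c", "c", "d"),
                          weight = c(2, 1, 0.5, 3))
  feats4 <- c("a", "b", "c", "d")
  ll <- build_laplacian(edges, feats4)
  a <- matrix(0, 4, 4, dimnames = list(feats4, feats4))
  for (e in seq_len(nrow(edges))) {
    a[edges$from[e], edges$to[e]] <- edges$weight[e]
    a[edges$to[e], edges$from[e]] <- edges$weight[e]
  }
  d <- rowSums(a)
  x <- c(0.3, -1, 2, 0.5)
  direct <- 0
  for (e in seq_len(nrow(edges))) {
    i <- match(edges$from[e], feats4)
    j <- match(edges$to[e], feats4)
    direct <- direct +
      edges$weight[e] * (x[i] / sqrt(d[i]) - x[j] / sqrt(d[j]))^2
  }
  expect_equal(as.numeric(t(x) %*% ll %*% x), unname(direct),
               tolerance = 1e-12)

  expect_error(build_laplacian(tibble::tibble(from = "a", to = "b",
                                              weight = -1), feats),
               "nonnegative")
})

test_that("with no network term the fit matches a soft-margin QP oracle", {
  withr::with_seed(13, {
    for (trial in 1:3) {
      n <- 10
      d <- 4
      x <- matrix(rnorm(n * d), d, n,
                  dimnames = list(paste0("f", 1:d), paste0("s", 1:n)))
      y <- rep(c(1, -1), each = 5)
      x[1, y == 1] <- x[1, y == 1] + 2
      lam <- 0.05
      fit <- fit_netsvm(x, y, lambda_margin = lam, lambda_net = 0)
      z <- t(scale(t(x)))
      oracle <- qp_svm_oracle(z, y, lam)
      expect_lt(max(abs(fit$weights$weight - oracle$w)), 1e-4)
      if (!is.na(oracle$b)) expect_lt(abs(fit$bias - oracle$b), 1e-4)
      expect_true(fit$converged)
    }
  })
})

test_that("a strong network penalty ties the weights of connected features", {
  withr::with_seed(14, {
    x <- matrix(rnorm(60), 6, 10,
                dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  })
  y <- rep(c(1, -1), each = 5)
  x[1, y == 1] <- x[1, y == 1] + 1.5
  x[4, y == 1] <- x[4, y == 1] + 1.5
  lap <- build_laplacian(tibble::tibble(from = "f1", to = "f4", weight = 1),
                         features = rownames(x))
  fit <- fit_netsvm(x, y, laplacian = lap, lambda_margin = 0.01,
                    lambda_net = 1000)
  w <- setNames(fit$weights$weight, fit$weights$feature_id)
  expect_lt(abs(w["f1"] - w["f4"]), 1e-3)
})

test_that("separable toys are classified perfectly and inputs validated", {
  x <- matrix(c(1, 2, 3, 4, -1, -2, -3, -4), 2, 4,
              dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  y <- c(1, 1, -1, -1)
  fit <- fit_netsvm(x, y, lambda_margin = 0.01, lambda_net = 0)
  scores <- predict(fit, x)
  expect_equal(mean(scores[y == 1] > 0), 1)
  expect_equal(mean(scores[y == -1] <= 0), 1)
  # dual objective never decreases across solver iterations
  expect_false(is.unsorted(fit$dual_trace))

  expect_error(fit_netsvm(x, c(1, 1, 1, 1), lambda_margin = 0.1), "classes")
  x_bad <- x
  x_bad[1, 1] <- NA
  expect_error(fit_netsvm(x_bad, y, lambda_margin = 0.1), "finite")
})

test_that("node ranking orders by signed weight with lexicographic ties", {
  w <- tibble::tibble(feature_id = c("a", "b", "c"),
                      weight = c(0.2, -0.22, 0.1))
  r <- rank_nodes(w, k_up = 1, k_down = 1)
  expect_equal(r$up$feature_id, "a")
  expect_equal(r$down$feature_id, "b")
  r2 <- rank_nodes(tibble::tibble(feature_id = c("a", "b", "c"),
                                  weight = c(0.3, -0.29, 0.1)),
                   k_up = 2, k_down = 2, k_overall = 2)
  expect_setequal(r2$overall$weight, c(0.3, -0.29))
  # ties break on feature id
  r3 <- rank_nodes(tibble::tibble(feature_id = c("z", "m", "a"),
                                  weight = c(0.5, 0.5, 0.5)), k_up = 3)
  expect_equal(r3$up$feature_id, c("a", "m", "z"))
})

test_that("a gastric-cancer hub-weight table ranks its top hubs first", {
  # a published table of hub-miRNA SVM weights, gastric cancer vs normal
  up <- c("hsa-miR-424" = 0.2001, "hsa-miR-503" = 0.1984,
          "hsa-miR-224" = 0.1888, "hsa-miR-342" = 0.1794,
          "hsa-miR-767-5p" = 0.1586, "hsa-miR-577" = 0.1575,
          "hsa-miR-486" = 0.1570, "hsa-miR-10a" = 0.1545,
          "hsa-miR-545" = 0.1542, "hsa-miR-548d" = 0.1531,
          "hsa-miR-208" = 0.1529, "hsa-miR-223" = 0.1519,
          "hsa-miR-579" = 0.1485, "hsa-miR-635" = 0.1445,
          "hsa-miR-320" = 0.1439, "hsa-let-7i" = 0.1433,
          "hsa-miR-582" = 0.1383, "hsa-miR-326" = 0.1359,
          "hsa-miR-484" = 0.1353, "hsa-miR-451" = 0.1296)
  down <- c("hsa-miR-146a" = -0.2201, "hsa-miR-376a" = -0.2149,
            "hsa-miR-647" = -0.1615, "hsa-miR-650" = -0.1605,
            "hsa-miR-375" = -0.1514, "hsa-miR-504" = -0.1491,
            "hsa-miR-514" = -0.1467, "hsa-miR-625" = -0.1430,
            "hsa-miR-642" = -0.1392, "hsa-miR-517" = -0.1335,
            "hsa-miR-660" = -0.1277, "hsa-miR-365" = -0.1250,
            "hsa-miR-203" = -0.1231, "hsa-miR-133a" = -0.1231,
            "hsa-miR-299-5p" = -0.1225, "hsa-miR-661" = -0.1223,
            "hsa-miR-95" = -0.1213, "hsa-miR-629" = -0.1197,
            "hsa-miR-155" = -0.1146, "hsa-miR-551b" = -0.1143)
  all_w <- c(up, down)
  tbl <- tibble::tibble(feature_id = names(all_w), weight = unname(all_w))
  r <- rank_nodes(tbl, k_up = 20, k_down = 20, k_overall = 20)
  expect_equal(r$up$feature_id[1], "hsa-miR-424")
  expect_equal(r$down$feature_id[1], "hsa-miR-146a")
  expect_equal(r$up$weight[1], 0.2001)
  expect_equal(r$down$weight[1], -0.2201)
  # both members of the activated module sit among the top-20 up list
  expect_true(all(c("hsa-miR-486", "hsa-miR-451") %in% r$up$feature_id))
  # merged top-20: 13 up-regulated and 7 down-regulated
  expect_equal(sum(r$overall$weight > 0), 13)
  expect_equal(sum(r$overall$weight < 0), 7)
})

test_that("sub-network extraction induces exactly the selected nodes", {
  nodes <- tibble::tibble(feature_id = c("a", "b", "c"),
                          weight = c(0.5, -0.2, 0.1))
  none <- extract_subnetwork(tibble::tibble(from = "x", to = "y"), nodes)
  expect_equal(nrow(none$edges), 0)

  full <- tidyr::expand_grid(from = c("a", "b", "c", "d"),
                             to = c("a", "b", "c", "d")) |>
    dplyr::filter(from < to)
  sub <- extract_subnetwork(full, nodes)
  expect_equal(nrow(sub$edges), 3)

  withr::with_seed(15, {
    feats <- paste0("n", 1:8)
    edges <- tidyr::expand_grid(from = feats, to = feats) |>
      dplyr::filter(from < to) |>
      dplyr::slice_sample(prop = 0.4)
    sel <- tibble::tibble(feature_id = sample(feats, 4),
                          weight = rnorm(4))
    got <- extract_subnetwork(edges, sel)
    manual <- edges[edges$from %in% sel$feature_id &
                    edges$to %in% sel$feature_id, ]
    expect_equal(got$edges, manual)
  })

  # direction annotation and conflict flag against fold change
  lfc <- c(a = 1, b = 0.5, c = -1)
  sub2 <- extract_subnetwork(full, nodes, log2fc = lfc)
  expect_equal(sub2$nodes$direction, c("up", "down", "up"))
  expect_equal(sub2$nodes$direction_conflict, c(FALSE, TRUE, TRUE))
})

test_that("cross-validated metrics behave on signal, null, and optimism", {
  make_data <- function(seed, shift) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(6 * 40), 6, 40,
                  dimnames = list(paste0("f", 1:6), paste0("s", 1:40)))
      y <- rep(c(1, -1), each = 20)
      x[1:2, y == 1] <- x[1:2, y == 1] + shift
      list(x = x, y = y)
    })
  }
  strong <- make_data(16, 4)
  m <- evaluate_classifier(strong$x, strong$y, lambda_margin = 0.05,
                           lambda_net = 0, folds = 5, seed = 1)
  expect_gte(m$cv_sensitivity, 0.95)
  expect_gte(m$cv_specificity, 0.95)

  # under shuffled labels the held-out AUC hovers around chance; average a
  # few shuffles so the check reflects the null distribution, not one draw
  null_aucs <- sapply(1:5, function(s) {
    null_y <- withr::with_seed(170 + s, sample(strong$y))
    evaluate_classifier(strong$x, null_y, lambda_margin = 0.05,
                        lambda_net = 0, folds = 5, seed = 1)$cv_auc
  })
  expect_lt(abs(mean(null_aucs) - 0.5), 0.15)

  # apparent metrics are optimistic relative to CV on average
  diffs <- sapply(1:20, function(s) {
    dd <- make_data(100 + s, 0.8)
    mm <- evaluate_classifier(dd$x, dd$y, lambda_margin = 0.05,
                              lambda_net = 0, folds = 4, seed = s)
    mm$apparent_auc - mm$cv_auc
  })
  expect_gt(mean(diffs), 0)
  expect_error(evaluate_classifier(strong$x, strong$y, folds = 25),
               "folds")
})

test_that("top-ranked features recover the planted differential set", {
  d <- synthetic_design(
    n_features = 120, module_sizes = c(20, 15, 10, 5),
    rho_within = 0.7, disrupted_in_norm = integer(0),
    de_features = setNames(c(rep(1, 5), rep(-1, 5)),
                           sprintf("miR-%03d", c(1, 21, 36, 51, 60,
                                                 5, 25, 40, 55, 70))),
    seed = 18)
  co <- generate_cohorts(d)
  x_all <- dplyr::inner_join(co$ref, co$norm, by = "feature_id")
  y <- c(rep(1, 90), rep(-1, 34))
  net <- build_network(co$ref, beta = 6)
  lap <- build_laplacian(network_edges(net, quantile = 0.95),
                         features = x_all$feature_id)
  fit <- fit_netsvm(x_all, y, laplacian = lap, lambda_margin = 0.01,
                    lambda_net = 0.01)
  planted <- names(d$de_features)
  top <- rank_nodes(fit, k_overall = 2 * length(planted))$overall
  recall <- mean(planted %in% top$feature_id)
  expect_gte(recall, 0.8)
})
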