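make_signature <- function(X) {
  structure(X, class = c("signature_matrix", "matrix"))
}

test_that("projection recovers trivial closed-form solutions", {
  X <- tiny_beta(cbind(c(0.9, 0.1, 0.5, 0.2), c(0.1, 0.9, 0.2, 0.8)),
                 samples = c("A", "B"))
  sig <- make_signature(X)
  w <- project_one(X[, "A"], sig)
  expect_equal(unname(w), c(1, 0), tolerance = 1e-8)

  orth <- make_signature(tiny_beta(cbind(c(1, 0), c(0, 1)),
                                   samples = c("A", "B")))
  w2 <- project_one(c(cg01 = 0.3, cg02 = 0.7), orth)
  expect_equal(unname(w2), c(0.3, 0.7), tolerance = 1e-12)
})

test_that("nonnegative projection matches the pracma NNLS oracle", {
  skip_if_not_installed("pracma")
  set.seed(41)
  for (i in 1:25) {
    X <- matrix(runif(40), 10, 4,
                dimnames = list(sprintf("cg%02d", 1:10), LETTERS[1:4]))
    y <- runif(10)
    names(y) <- rownames(X)
    mine <- project_one(y, make_signature(X))
    oracle <- pracma::lsqnonneg(X, y)$x
    expect_equal(unname(mine), oracle, tolerance = 1e-6)
  }
})

test_that("simplex-constrained projection matches the grid-search oracle", {
  set.seed(42)
  grid <- simplex_grid()
  cfg <- projection_config(sum_constraint = "eq_one")
  for (i in 1:3) {
    panel <- planted_panel(n_probes = 500, n_sig = 25, precision = 200,
                           seed = 42 + i)
    st <- one_vs_rest_stats(panel$beta, panel$sheet)
    sel <- select_probes(st, "both", n_each = 20L)
    sig <- build_signature_matrix(panel$beta, panel$sheet, sel$union)
    mix <- generate_mixtures(panel$profiles, 2, noise_precision = 100,
                             seed = 50 + i)
    for (s in colnames(mix$beta)) {
      y <- mix$beta[rownames(sig), s]
      mine <- project_one(y, sig, cfg)
      expect_equal(sum(mine), 1, tolerance = 1e-8)
      oracle <- grid_project(y, unclass(sig), grid)
      expect_lt(max(abs(mine - oracle)), 0.02)
    }
  }
})

test_that("projection handles constraints, missing values and rank errors", {
  X <- tiny_beta(cbind(c(0.9, 0.1, 0.4), c(0.1, 0.9, 0.4)),
                 samples = c("A", "B"))
  sig <- make_signature(X)
  y <- 0.6 * X[, "A"] + 0.6 * X[, "B"]   # unconstrained sum 1.2
  w_free <- project_one(pmin(y, 1), sig)
  w_le <- project_one(pmin(y, 1), sig,
                      projection_config(sum_constraint = "le_one"))
  expect_lte(sum(w_le), 1 + 1e-8)
  expect_gte(sum(w_free), sum(w_le))

  # a missing probe is dropped pairwise, not fatal
  y2 <- X[, "A"]; y2[2] <- NA
  expect_equal(unname(project_one(y2, sig)), c(1, 0), tolerance = 1e-6)

  # too few probes left / collinear design are errors
  y3 <- X[, "A"]; y3[2:3] <- NA
  expect_error(project_one(y3, sig), "fewer non-missing")
  bad <- make_signature(tiny_beta(cbind(c(0.2, 0.4), c(0.2, 0.4)),
                                  samples = c("A", "B")))
  expect_error(project_one(c(cg01 = 0.3, cg02 = 0.5), bad),
               "rank-deficient")
})

test_that("solver beats every vertex of the constraint simplex", {
  set.seed(43)
  for (i in 1:5) {
    X <- matrix(runif(24), 6, 4,
                dimnames = list(sprintf("cg%d", 1:6), LETTERS[1:4]))
    y <- runif(6); names(y) <- rownames(X)
    w <- project_one(y, make_signature(X),
                     projection_config(sum_constraint = "eq_one"))
    obj <- function(v) sum((y - X %*% v)^2)
    for (k in 1:4) expect_lte(obj(w), obj(diag(4)[, k]) + 1e-10)
  }
})

test_that("noiseless mixtures are recovered exactly, sums near one", {
  panel <- planted_panel(n_probes = 1200, n_sig = 50, precision = Inf,
                         seed = 44)
  mix <- generate_mixtures(panel$profiles, 8, noise_precision = Inf,
                           seed = 45)
  est <- estimate_cell_counts(mix$beta, panel$beta, panel$sheet,
                              mode = "both")
  truth <- mix$truth$true_weights
  expect_equal(unclass(est)[, colnames(truth)], unclass(truth),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_true(all(abs(rowSums(est) - 1) < 1e-3))
})

test_that("'any' and 'both' estimates agree on synthetic mixtures", {
  panel <- planted_panel(n_probes = 2000, n_sig = 60, precision = 500,
                         seed = 46)
  mix <- generate_mixtures(panel$profiles, 12, noise_precision = 200,
                           seed = 47)
  e_any <- estimate_cell_counts(mix$beta, panel$beta, panel$sheet,
                                mode = "any")
  e_both <- estimate_cell_counts(mix$beta, panel$beta, panel$sheet,
                                 mode = "both")
  for (ct in colnames(e_any))
    expect_gt(cor(e_any[, ct], e_both[, ct]), 0.99)
})

test_that("parameter recovery at moderate noise stays accurate", {
  panel <- planted_panel(n_probes = 2000, n_sig = 60, precision = 500,
                         seed = 48)
  mix <- generate_mixtures(panel$profiles, 20, noise_precision = 200,
                           seed = 49)
  est <- estimate_cell_counts(mix$beta, panel$beta, panel$sheet,
                              mode = "both")
  per_ct <- mse(mix$truth$true_weights, est, by = "cell_type")
  expect_true(all(per_ct < 0.005))
})

test_that("an unmodelled similar cell type is absorbed by its neighbour", {
  panel <- planted_panel(n_probes = 1500, n_sig = 60, precision = 1e4,
                         seed = 50)
  prof <- panel$profiles
  # a monocyte-like profile: macrophage profile nudged slightly
  set.seed(51)
  mono <- pmin(pmax(prof$mean_beta[, "AlveolarMacrophage"] +
                      rnorm(nrow(prof$mean_beta), 0, 0.03), 0), 1)
  w_known <- c(AlveolarMacrophage = 0.1, Granulocyte = 0.3,
               Lymphocyte = 0.2, AEC = 0.1)
  y <- prof$mean_beta %*% w_known + 0.3 * mono
  mixture <- tiny_beta(pmin(pmax(y, 0), 1), probes = prof$probe_ids,
                       samples = "mix1")
  est <- estimate_cell_counts(mixture, panel$beta, panel$sheet,
                              mode = "both")
  expect_gt(est[1, "AlveolarMacrophage"], w_known["AlveolarMacrophage"] + 0.15)
})

test_that("aggregation sums supergroups exactly", {
  t1 <- proportion_table(tiny_beta(rbind(c(0.1, 0.05, 0.05, 0.8)),
                                   samples = c("T", "B", "NK", "Gran")),
                         "fraction")
  g <- c(T = "Lymphocyte", B = "Lymphocyte", NK = "Lymphocyte",
         Gran = "Granulocyte")
  agg <- aggregate_estimates(t1, g)
  expect_equal(unname(agg[1, "Lymphocyte"]), 0.2)

  set.seed(52)
  w <- matrix(runif(24), 6, 4,
              dimnames = list(paste0("s", 1:6), c("T", "B", "NK", "Gran")))
  agg2 <- aggregate_estimates(proportion_table(w, "fraction"), g)
  expect_equal(unname(agg2[, "Lymphocyte"]),
               unname(w[, "T"] + w[, "B"] + w[, "NK"]))
  expect_error(aggregate_estimates(proportion_table(w, "fraction"),
                                   g[1:3]), "cover")
  # identity grouping
  idg <- setNames(colnames(w), colnames(w))
  expect_equal(unclass(aggregate_estimates(proportion_table(w, "fraction"),
                                           idg)),
               w, ignore_attr = TRUE)
})
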