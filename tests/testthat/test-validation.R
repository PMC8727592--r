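test_that("flow rescaling reproduces printed compositions and sums to 100", {
  cf4 <- c(AlveolarMacrophage = 50.2, Lymphocyte = 5,
           Granulocyte = 13.6, AEC = 0.4)
  expect_equal(round(scale_flow_proportions(cf4), 1),
               c(AlveolarMacrophage = 72.5, Lymphocyte = 7.2,
                 Granulocyte = 19.7, AEC = 0.6))
  cf2 <- c(46.1, 7.4, 26.9, 2.4)
  expect_equal(round(unname(scale_flow_proportions(cf2)), 1),
               c(55.7, 8.9, 32.5, 2.9))
  # fixed point and exact-sum invariant
  expect_equal(scale_flow_proportions(c(25, 25, 25, 25)),
               c(25, 25, 25, 25))
  set.seed(61)
  for (i in 1:10) {
    v <- runif(4, 0, 60)
    expect_equal(sum(scale_flow_proportions(v)), 100, tolerance = 1e-9)
  }
  m <- rbind(a = c(10, 10), b = c(30, 10))
  expect_equal(rowSums(scale_flow_proportions(m)), c(a = 100, b = 100))
  expect_error(scale_flow_proportions(c(0, 0, 0)), "all-zero")
  expect_error(scale_flow_proportions(c(-1, 2)), ">= 0")
})

test_that("MSE matches hand-summed oracles on random tables", {
  set.seed(62)
  tr <- matrix(runif(24), 6, 4,
               dimnames = list(paste0("s", 1:6), LETTERS[1:4]))
  est <- tr + matrix(rnorm(24, 0, 0.05), 6, 4)
  est <- pmin(pmax(est, 0), 1)
  t_tab <- proportion_table(tr, "fraction")
  e_tab <- proportion_table(est, "fraction")
  expect_equal(mse(t_tab, e_tab, "overall"), mean((est - tr)^2))
  expect_equal(unname(mse(t_tab, e_tab, "subject")),
               unname(rowMeans((est - tr)^2)))
  expect_equal(unname(mse(t_tab, e_tab, "cell_type")),
               unname(colMeans((est - tr)^2)))
  # with equal cell-type counts, subject MSEs average to the overall MSE
  expect_equal(mean(mse(t_tab, e_tab, "subject")),
               mse(t_tab, e_tab, "overall"))
  expect_equal(unname(mse(t_tab, t_tab, "overall")), 0)
  # scale conversion: percent inputs give fraction-squared output
  expect_equal(mse(as_percent(t_tab), e_tab, "overall"),
               mse(t_tab, e_tab, "overall"))
  expect_error(mse(t_tab, proportion_table(tr[, 1:2], "fraction")),
               "share")
})

test_that("subject-level MSE reproduces the printed BAL discrepancy", {
  comp <- bal_composition(wide = TRUE)
  m <- mse(proportion_table(comp$flow_unscaled, "percent"),
           proportion_table(comp$dnam_any, "percent"), by = "subject")
  expect_equal(unname(round(m["CF1"], 2)), 0.06)
})

test_that("Bland-Altman bias and limits follow the direct formula", {
  tr <- matrix(runif(20, 0, 0.8), 5, 4,
               dimnames = list(paste0("s", 1:5), LETTERS[1:4]))
  same <- bland_altman(proportion_table(tr, "fraction"),
                       proportion_table(tr, "fraction"))
  ov <- same$summary[same$summary$cell_type == "overall", ]
  expect_equal(ov$bias, 0); expect_equal(ov$lower, 0); expect_equal(ov$upper, 0)

  shift <- bland_altman(proportion_table(tr, "fraction"),
                        proportion_table(tr + 0.1, "fraction"))
  ov <- shift$summary[shift$summary$cell_type == "overall", ]
  expect_equal(ov$bias, 0.1, tolerance = 1e-12)
  expect_equal(ov$sd, 0, tolerance = 1e-12)

  set.seed(63)
  est <- pmin(pmax(tr + rnorm(20, 0, 0.03), 0), 1)
  ba <- bland_altman(proportion_table(tr, "fraction"),
                     proportion_table(est, "fraction"))
  d <- as.vector(est - tr)
  ov <- ba$summary[ba$summary$cell_type == "overall", ]
  expect_equal(ov$bias, mean(d))
  expect_equal(ov$lower, mean(d) - 1.96 * sd(d))
  expect_equal(ov$upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba$pairs$mean, as.vector((tr + est) / 2))
})

test_that("invariant probes are found, monotone in thresholds, consistent", {
  b <- tiny_beta(rbind(rep(0.99, 6), rep(0.02, 6),
                       c(0.99, 0.99, 0.99, 0.99, 0.5, 0.5),
                       rep(0.5, 6)),
                 probes = c("hyperstable", "hypostable", "partial", "mid"))
  sheet <- ref_sheet(colnames(b), rep(c("A", "B", "C"), each = 2))
  mix <- tiny_beta(matrix(c(0.97, 0.03, 0.6, 0.5), 4, 1),
                   probes = rownames(b), samples = "m1")
  res <- invariant_probe_check(b, sheet, mix)
  expect_setequal(res$probes$probe_id, c("hyperstable", "hypostable"))
  expect_equal(unname(res$consistency["m1"]), 1)

  relaxed <- invariant_probe_check(b, sheet, mix, hi = 0.9, lo = 0.1)
  expect_true(all(res$probes$probe_id %in% relaxed$probes$probe_id))

  # mixtures of only the profiled types keep invariant probes consistent
  panel <- planted_panel(n_probes = 2000, n_sig = 20, precision = 300,
                         seed = 64)
  mixes <- generate_mixtures(panel$profiles, 6, noise_precision = 300,
                             seed = 65)
  chk <- invariant_probe_check(panel$beta, panel$sheet, mixes$beta)
  expect_gt(chk$n_probes, 0)
  expect_true(all(chk$consistency > 0.99))
})

test_that("pooling regression equals the closed-form OLS solution", {
  # degenerate cases
  b <- tiny_beta(matrix(rep(c(0.2, 0.4, 0.6, 0.8), 4), 4, 4))
  sheet <- ref_sheet(colnames(b), rep("A", 4), pool_size = c(1, 2, 3, 6))
  same <- suppressWarnings(pooling_variance_regression(b, sheet))
  expect_equal(same$slope, 0, tolerance = 1e-12)
  expect_gt(same$p_value, 0.9)

  set.seed(66)
  n <- 8L
  sizes <- c(1, 1, 2, 3, 4, 6, 8, 12)
  v_target <- 0.001 * sizes          # variance exactly linear in size
  cols <- vapply(v_target, function(v) {
    x <- seq(-1, 1, length.out = 50)
    0.5 + x * sqrt(v / var(x))
  }, numeric(50))
  b2 <- tiny_beta(cols)
  sheet2 <- ref_sheet(colnames(b2), rep("A", n), pool_size = sizes)
  perfect <- suppressWarnings(pooling_variance_regression(b2, sheet2))
  expect_equal(perfect$adj_r_squared, 1, tolerance = 1e-9)

  # random fixture vs closed-form simple regression
  vv <- apply(b2, 2, var) + runif(n, 0, 5e-4)
  b3 <- tiny_beta(vapply(vv, function(v) {
    x <- seq(-1, 1, length.out = 50); 0.5 + x * sqrt(v / var(x))
  }, numeric(50)))
  reg <- pooling_variance_regression(b3, sheet2)
  x <- sizes; y <- apply(b3, 2, var)
  slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(reg$slope, slope_cf, tolerance = 1e-9)
  r2 <- cor(x, y)^2
  adj_cf <- 1 - (1 - r2) * (n - 1) / (n - 2)
  expect_equal(reg$adj_r_squared, adj_cf, tolerance = 1e-9)
  tstat <- slope_cf / sqrt((sum((y - mean(y))^2) * (1 - r2) / (n - 2)) /
                             sum((x - mean(x))^2))
  expect_equal(reg$p_value, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-9)

  expect_error(pooling_variance_regression(b2[, 1:2], sheet2[1:2, ]),
               ">= 3")
})

test_that("classical MDS reproduces geometry and distances", {
  # three mutually equidistant samples -> equilateral configuration
  b <- tiny_beta(0.6 * diag(3))
  res <- classical_mds(b, top_n_variable = 3, n_dims = 2)
  d <- dist(res$coordinates)
  expect_equal(as.vector(d), rep(0.6 * sqrt(2), 3), tolerance = 1e-9)

  # duplicated sample -> coincident points
  b2 <- tiny_beta(cbind(c(0.1, 0.9, 0.4), c(0.1, 0.9, 0.4),
                        c(0.8, 0.2, 0.6)))
  res2 <- classical_mds(b2, top_n_variable = 3, n_dims = 2)
  expect_equal(res2$coordinates[1, ], res2$coordinates[2, ],
               tolerance = 1e-6)

  # full-dimension coordinates reconstruct the input distances
  set.seed(67)
  b3 <- tiny_beta(matrix(runif(250), 50, 5))
  res3 <- classical_mds(b3, top_n_variable = 50, n_dims = 4)
  expect_equal(as.vector(dist(res3$coordinates)),
               as.vector(dist(t(b3))), tolerance = 1e-6)
  expect_true(all(diff(res3$variance_explained) <= 1e-12))
  expect_error(classical_mds(b3[, 1:2]), ">= 3")
})

test_that("reference panels cluster by cell type in MDS space", {
  panel <- planted_panel(n_probes = 1000, n_sig = 40, precision = 500,
                         seed = 68)
  res <- classical_mds(panel$beta, top_n_variable = 500, n_dims = 3)
  cts <- panel$sheet$cell_type
  co <- res$coordinates
  within <- mean(sapply(unique(cts), function(ct)
    mean(dist(co[cts == ct, ]))))
  between <- mean(dist(co))
  expect_lt(within, between / 2)
})
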