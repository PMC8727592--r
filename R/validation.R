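#' Validation of proportion estimates against known compositions
#'
#' Tools for comparing methylation-based proportion estimates with known
#' mixture compositions or flow cytometry: rescaling flow proportions over
#' the profiled cell types, mean squared error by cell type or subject,
#' Bland-Altman agreement, an invariant-probe consistency check for
#' DNA-free contaminating cells, a pooling-variance regression, and a
#' classical MDS diagnostic.
#'
#' @name validation
NULL

#' Rescale flow-cytometry proportions over the profiled cell types
#'
#' Flow cytometry counts every event, including DNA-free cells (e.g. red
#' blood cells) invisible to methylation. Dividing each profiled cell type's
#' percentage by the sum over the profiled types re-expresses composition
#' over the DNA-contributing cells only ("scaled" vs "original").
#'
#' @param unscaled Numeric vector (one sample) or matrix (samples x cell
#'   types) of percentages, all >= 0 with a positive sum per sample.
#' @return Same shape, each sample rescaled to sum to 100.
#' @export
scale_flow_proportions <- function(unscaled) {
  scale1 <- function(v) {
    if (any(v < 0)) stop("proportions must be >= 0", call. = FALSE)
    s <- sum(v)
    if (s <= 0) stop("cannot rescale an all-zero composition", call. = FALSE)
    v / s * 100
  }
  if (is.matrix(unscaled)) t(apply(unscaled, 1L, scale1)) else scale1(unscaled)
}

align_pair <- function(truth, estimate) {
  to_mat <- function(x) if (inherits(x, "proportion_table"))
    unclass_prop(as_fraction(x)) else as.matrix(x)
  t_m <- to_mat(truth); e_m <- to_mat(estimate)
  if (!is.null(rownames(t_m)) && !is.null(rownames(e_m))) {
    if (!setequal(rownames(t_m), rownames(e_m)) ||
        !setequal(colnames(t_m), colnames(e_m)))
      stop("truth and estimate tables do not share sample/cell-type ids",
           call. = FALSE)
    e_m <- e_m[rownames(t_m), colnames(t_m), drop = FALSE]
  } else if (!identical(dim(t_m), dim(e_m))) {
    stop("truth and estimate tables differ in shape", call. = FALSE)
  }
  list(truth = t_m, estimate = e_m)
}

#' Mean squared error between true and estimated proportions
#'
#' Inputs given as [proportion_table()]s are converted to the fraction
#' scale, so the MSE is on the fraction-squared scale regardless of input
#' scale; plain matrices are used as supplied.
#'
#' @param truth,estimate Aligned proportion tables or matrices
#'   (samples x cell types).
#' @param by `"cell_type"` (one MSE per column), `"subject"` (one per row),
#'   or `"overall"`.
#' @return Named numeric vector (or scalar for `"overall"`).
#' @export
mse <- function(truth, estimate, by = c("cell_type", "subject", "overall")) {
  by <- match.arg(by)
  p <- align_pair(truth, estimate)
  sq <- (p$estimate - p$truth)^2
  switch(by,
         cell_type = colMeans(sq),
         subject = rowMeans(sq),
         overall = mean(sq))
}

#' Bland-Altman agreement between true and estimated proportions
#'
#' For each (sample, cell type) pair the difference `estimate - truth` is
#' plotted against the pair mean; agreement is summarized by the bias (mean
#' difference) and the 95% limits of agreement `bias +/- 1.96 sd(diff)`,
#' overall and per cell type.
#'
#' @inheritParams mse
#' @return List with `pairs` (data.frame: sample, cell_type, mean,
#'   difference) and `summary` (data.frame per cell type plus `"overall"`:
#'   bias, sd, lower, upper).
#' @export
bland_altman <- function(truth, estimate) {
  p <- align_pair(truth, estimate)
  samples <- rownames(p$truth) %||% as.character(seq_len(nrow(p$truth)))
  cts <- colnames(p$truth) %||% as.character(seq_len(ncol(p$truth)))
  pairs <- data.frame(
    sample_id = rep(samples, times = length(cts)),
    cell_type = rep(cts, each = length(samples)),
    mean = as.vector((p$truth + p$estimate) / 2),
    difference = as.vector(p$estimate - p$truth),
    stringsAsFactors = FALSE)
  summarize <- function(d) {
    bias <- mean(d)
    s <- if (length(d) > 1L) stats::sd(d) else 0
    c(bias = bias, sd = s, lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  }
  per_ct <- t(vapply(cts, function(ct)
    summarize(pairs$difference[pairs$cell_type == ct]), numeric(4L)))
  overall <- summarize(pairs$difference)
  summary <- data.frame(cell_type = c(cts, "overall"),
                        rbind(per_ct, overall), row.names = NULL,
                        stringsAsFactors = FALSE)
  list(pairs = pairs, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Identify invariant probes and check mixtures for foreign cell signal
#'
#' Probes whose per-cell-type mean beta is >= `hi` in every reference cell
#' type, or <= `lo` in every cell type, should stay fully methylated or
#' unmethylated in any mixture composed solely of those cell types. A
#' contaminating nucleated cell type would pull them toward intermediate
#' values; DNA-free cells (no methylation signal) would not. The per-mixture
#' consistency fraction is the share of invariant probes remaining on their
#' expected side of 0.5.
#'
#' @param reference_beta Probes x samples reference beta matrix.
#' @param sample_sheet Reference sample sheet.
#' @param mixture_beta Probes x samples mixture beta matrix.
#' @param hi,lo Thresholds for hyper- and hypo-stable probes.
#' @return List with `probes` (data.frame: probe_id, direction),
#'   `consistency` (named per-mixture fraction), and `n_probes`.
#' @export
invariant_probe_check <- function(reference_beta, sample_sheet, mixture_beta,
                                  hi = 0.95, lo = 0.05) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  sheet <- sample_sheet[sample_sheet$role == "reference" &
                          sample_sheet$sample_id %in% colnames(reference_beta), ]
  types <- unique(sheet$cell_type)
  means <- vapply(types, function(ct)
    rowMeans(reference_beta[, sheet$sample_id[sheet$cell_type == ct],
                            drop = FALSE], na.rm = TRUE),
    numeric(nrow(reference_beta)))
  hyper <- rowSums(means >= hi) == length(types)
  hypo <- rowSums(means <= lo) == length(types)
  probes <- data.frame(
    probe_id = c(rownames(reference_beta)[hyper],
                 rownames(reference_beta)[hypo]),
    direction = rep(c("hyper", "hypo"), c(sum(hyper), sum(hypo))),
    stringsAsFactors = FALSE)
  common <- intersect(probes$probe_id, rownames(mixture_beta))
  dir <- probes$direction[match(common, probes$probe_id)]
  consistency <- apply(mixture_beta[common, , drop = FALSE], 2L, function(v) {
    ok <- ifelse(dir == "hyper", v > 0.5, v < 0.5)
    mean(ok, na.rm = TRUE)
  })
  list(probes = probes, consistency = consistency,
       n_probes = nrow(probes))
}

#' Regress per-sample variance on pool size
#'
#' Computes each pooled sample's variance across all probes and fits an
#' ordinary least-squares regression of that variance on the number of
#' individuals in the pool. A flat relationship (slope ~ 0, small adjusted
#' R-squared, large p) indicates pools of different sizes are equally
#' representative of their cell type.
#'
#' @param beta Probes x samples beta matrix of pooled samples.
#' @param sample_sheet Sheet with `pool_size` for each column of `beta`.
#' @return List with `slope`, `adj_r_squared`, `p_value` (two-sided, on the
#'   slope), and the per-sample `data` used.
#' @export
pooling_variance_regression <- function(beta, sample_sheet) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ]
  if (nrow(sheet) < 3L || anyNA(sheet$sample_id))
    stop("need >= 3 samples with pool sizes", call. = FALSE)
  if (length(unique(sheet$pool_size)) < 2L)
    stop("pool sizes must vary", call. = FALSE)
  d <- data.frame(sample_id = sheet$sample_id,
                  pool_size = sheet$pool_size,
                  variance = apply(beta, 2L, stats::var, na.rm = TRUE))
  fit <- stats::lm(variance ~ pool_size, data = d)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  p <- sm$coefficients["pool_size", "Pr(>|t|)"]
  # constant response: zero slope with zero residual leaves t = 0/0
  if (!is.finite(p)) p <- if (abs(slope) < 1e-12) 1 else 0
  adj <- sm$adj.r.squared
  if (!is.finite(adj)) adj <- 0
  list(slope = slope, adj_r_squared = adj, p_value = p, data = d)
}

#' Classical multidimensional scaling of samples
#'
#' Euclidean distances between samples over the `top_n_variable` most
#' variable probes are double-centred and eigendecomposed
#' ([stats::cmdscale()]); leading coordinates and per-dimension variance
#' fractions are returned. Reference panels should separate into one
#' cluster per cell type.
#'
#' @param beta Probes x samples beta matrix (>= 3 samples).
#' @param top_n_variable Number of most-variable probes used.
#' @param n_dims Number of leading dimensions returned.
#' @return List with `coordinates` (samples x n_dims) and
#'   `variance_explained` (fraction of positive eigenvalue mass per
#'   dimension).
#' @export
classical_mds <- function(beta, top_n_variable = 1000L, n_dims = 3L) {
  if (ncol(beta) < 3L) stop("need >= 3 samples for MDS", call. = FALSE)
  v <- apply(beta, 1L, stats::var, na.rm = TRUE)
  keep <- utils::head(order(v, decreasing = TRUE),
                      min(top_n_variable, nrow(beta)))
  d <- stats::dist(t(beta[keep, , drop = FALSE]))
  n_dims <- min(n_dims, ncol(beta) - 1L)
  fit <- stats::cmdscale(d, k = n_dims, eig = TRUE)
  pos <- fit$eig[fit$eig > 0]
  list(coordinates = fit$points,
       variance_explained = fit$eig[seq_len(n_dims)] / sum(pos))
}
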