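#' Constrained-projection deconvolution (Houseman approach)
#'
#' A mixed-cell methylation profile is modelled as a weighted average of
#' purified cell-type profiles, `y = X w + e`, where `X` is the signature
#' matrix over discriminating probes. Cell-type proportions are the
#' least-squares solution constrained to the biologically meaningful region:
#' non-negative weights, optionally confined to (or below) the unit simplex.
#'
#' Because the number of cell types K is small, the convex quadratic program
#' is solved exactly by support enumeration: for every candidate support set
#' of non-zero weights the equality-constrained least-squares solution is
#' computed in closed form, infeasible candidates are discarded, and the
#' feasible candidate with the smallest residual sum of squares is returned.
#' The optimum of the QP has some support, so it is always among the
#' candidates; the solver is deterministic and involves no iteration or
#' random initialization. Cost is O(2^K) small linear solves per sample.
#'
#' @name deconvolution
NULL

#' Configuration for the constrained projection
#'
#' @param nonnegative Constrain weights to be >= 0 (default `TRUE`).
#' @param sum_constraint `"none"` (default, as in the classical
#'   reference-based estimators, which let the fitted sum float near 1),
#'   `"le_one"`, or `"eq_one"`.
#' @param tolerance Feasibility tolerance (> 0) for the returned weights.
#' @return A `projection_config` list.
#' @export
projection_config <- function(nonnegative = TRUE,
                              sum_constraint = c("none", "le_one", "eq_one"),
                              tolerance = 1e-8) {
  sum_constraint <- match.arg(sum_constraint)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  structure(list(nonnegative = nonnegative, sum_constraint = sum_constraint,
                 tolerance = tolerance), class = "projection_config")
}

# unconstrained LS on columns S of X
ls_subset <- function(X, y, S) {
  fit <- stats::lm.fit(X[, S, drop = FALSE], y)
  w <- fit$coefficients
  w[is.na(w)] <- 0
  w
}

# LS on columns S subject to sum(w) = 1 via KKT system
ls_subset_sum1 <- function(X, y, S) {
  Xs <- X[, S, drop = FALSE]
  k <- length(S)
  A <- rbind(cbind(crossprod(Xs), rep(1, k)), c(rep(1, k), 0))
  b <- c(crossprod(Xs, y), 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  sol[seq_len(k)]
}

rss <- function(X, y, w) { r <- y - X %*% w; sum(r * r) }

#' Project one sample onto the signature matrix
#'
#' Solves `argmin_w sum_probes (y - Xw)^2` under the configured
#' constraints. Probes with a missing value in `y` (or in any signature
#' column) are dropped pairwise from both sides before solving.
#'
#' @param sample_beta Named numeric vector of the sample's betas over the
#'   signature probes (aligned by name when named, by position otherwise).
#' @param signature A `signature_matrix` (probes x cell types).
#' @param config A [projection_config()].
#' @return Named weight vector over cell types satisfying the constraints
#'   within the configured tolerance.
#' @export
project_one <- function(sample_beta, signature,
                        config = projection_config()) {
  X <- unclass(signature)
  if (!is.null(names(sample_beta)) && !is.null(rownames(X))) {
    common <- intersect(rownames(X), names(sample_beta))
    X <- X[common, , drop = FALSE]
    y <- sample_beta[common]
  } else {
    if (length(sample_beta) != nrow(X))
      stop("sample vector and signature matrix differ in length",
           call. = FALSE)
    y <- sample_beta
  }
  keep <- !is.na(y) & stats::complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  k <- ncol(X)
  if (nrow(X) < k)
    stop("fewer non-missing probes (", nrow(X), ") than cell types (", k,
         ")", call. = FALSE)
  if (qr(X)$rank < k)
    stop("signature matrix is rank-deficient after dropping missing probes",
         call. = FALSE)

  tol <- config$tolerance
  cts <- colnames(X)

  if (!config$nonnegative) {
    w <- switch(config$sum_constraint,
                none = ls_subset(X, y, seq_len(k)),
                eq_one = ls_subset_sum1(X, y, seq_len(k)),
                le_one = {
                  w0 <- ls_subset(X, y, seq_len(k))
                  if (sum(w0) <= 1 + tol) w0
                  else ls_subset_sum1(X, y, seq_len(k))
                })
    names(w) <- cts
    return(w)
  }

  best <- NULL; best_rss <- Inf
  consider <- function(w_sub, S) {
    if (is.null(w_sub) || any(w_sub < -tol)) return()
    w <- numeric(k); w[S] <- pmax(w_sub, 0)
    r <- rss(X, y, w)
    if (r < best_rss - 1e-15 ||
        (r < best_rss + 1e-15 && is.null(best))) {
      best <<- w; best_rss <<- r
    }
  }
  subsets <- seq_len(2^k - 1L)
  if (config$sum_constraint == "none") consider(numeric(0), integer(0))
  for (s in subsets) {
    S <- which(bitwAnd(s, 2^(seq_len(k) - 1L)) > 0L)
    if (config$sum_constraint %in% c("none", "le_one")) {
      w_sub <- ls_subset(X, y, S)
      ok <- config$sum_constraint == "none" || sum(w_sub) <= 1 + tol
      if (ok) consider(w_sub, S)
    }
    if (config$sum_constraint %in% c("eq_one", "le_one"))
      consider(ls_subset_sum1(X, y, S), S)
  }
  if (is.null(best))
    stop("constraint set infeasible for this sample", call. = FALSE)
  names(best) <- cts
  best
}

#' Estimate cell-type proportions of mixture samples end-to-end
#'
#' Runs the full reference-based pipeline: restrict reference and mixture
#' data to common probes (after removing any QC-excluded probes from both),
#' compute one-vs-rest statistics on the reference panel, select signature
#' probes in the requested mode, build the signature matrix, and project
#' each mixture sample onto it.
#'
#' @param mixture_beta Probes x samples beta matrix of mixed samples.
#' @param reference_beta Probes x samples beta matrix of purified samples.
#' @param sample_sheet Sheet labelling the reference samples.
#' @param qc_exclusions Optional character vector of probe ids to drop from
#'   both matrices before selection (e.g. failing QC in either dataset).
#' @param mode Probe-selection mode, `"both"` or `"any"`.
#' @param config A [projection_config()].
#' @param n_any,n_each,p_threshold Passed to [select_probes()].
#' @return A fraction-scale [proportion_table()] (mixtures x cell types)
#'   with the selection metadata attached as attribute `selection`.
#' @export
estimate_cell_counts <- function(mixture_beta, reference_beta, sample_sheet,
                                 qc_exclusions = NULL,
                                 mode = c("both", "any"),
                                 config = projection_config(),
                                 n_any = 100L, n_each = 50L,
                                 p_threshold = 1e-8) {
  mode <- match.arg(mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (length(qc_exclusions)) {
    reference_beta <- reference_beta[
      !(rownames(reference_beta) %in% qc_exclusions), , drop = FALSE]
    mixture_beta <- mixture_beta[
      !(rownames(mixture_beta) %in% qc_exclusions), , drop = FALSE]
  }
  common <- stage("restrict_to_common_probes",
                  restrict_to_common_probes(reference_beta, mixture_beta))
  stats <- stage("one_vs_rest_stats",
                 one_vs_rest_stats(common$reference, sample_sheet))
  sel <- stage("select_probes",
               select_probes(stats, mode, n_any, n_each, p_threshold))
  sig <- stage("build_signature_matrix",
               build_signature_matrix(common$reference, sample_sheet,
                                      sel$union, sel$metadata))
  w <- t(vapply(colnames(common$mixture), function(s)
    stage("project_one",
          project_one(common$mixture[, s], sig, config)),
    numeric(ncol(sig))))
  out <- proportion_table(w, "fraction")
  attr(out, "selection") <- sel$metadata
  out
}

#' Aggregate estimated proportions into supergroups
#'
#' Sums weights within supergroups, e.g. T, B and NK cell proportions into a
#' single lymphocyte proportion for comparison with a panel that profiled
#' total lymphocytes.
#'
#' @param table A [proportion_table()].
#' @param grouping Named character vector mapping every cell type in
#'   `table` to its supergroup label.
#' @return A `proportion_table` over the supergroups, same scale.
#' @export
aggregate_estimates <- function(table, grouping) {
  stopifnot(inherits(table, "proportion_table"))
  w <- unclass_prop(table)
  miss <- setdiff(colnames(w), names(grouping))
  if (length(miss))
    stop("grouping does not cover cell type(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  groups <- unique(unname(grouping[colnames(w)]))
  agg <- vapply(groups, function(g) {
    members <- intersect(names(grouping)[grouping == g], colnames(w))
    rowSums(w[, members, drop = FALSE])
  }, numeric(nrow(w)))
  agg <- matrix(agg, nrow = nrow(w), dimnames = list(rownames(w), groups))
  proportion_table(agg, attr(table, "scale"))
}
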