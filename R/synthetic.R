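#' Synthetic methylation reference panels and mixtures
#'
#' The generator emulates the structure of a sorted-cell methylation study:
#' a small set of cell types with a shared bimodal background methylation
#' landscape, planted hyper-/hypo-methylated signature CpGs that separate one
#' cell type from the rest by at least `delta`, per-individual sorted samples
#' with beta-distributed measurement noise, equal-mass DNA pools (per-probe
#' means over individuals), and Dirichlet-weighted mixtures. A mixture may
#' additionally carry an "unprofiled" DNA-free fraction (red-blood-cell-like)
#' that dilutes the simulated flow-cytometry composition but, carrying no
#' DNA, leaves the methylation signal untouched.
#'
#' @name synthetic
NULL

default_cell_types <- c("AlveolarMacrophage", "Granulocyte",
                        "Lymphocyte", "AEC")

#' Generate ground-truth per-cell-type methylation profiles
#'
#' Background probes share a common mean across cell types drawn from an
#' equal mixture of Beta(0.5, 5) and Beta(5, 0.5), reproducing the bimodal
#' beta landscape of methylation arrays. For each cell type,
#' `n_signature_per_type` hypermethylated and as many hypomethylated probes
#' are planted: the cell type's own mean exceeds (hyper) or falls below
#' (hypo) every other cell type's mean by at least `delta`.
#'
#' @param n_probes Total probe count; must be at least
#'   `2 * n_signature_per_type * length(cell_types)`.
#' @param cell_types Ordered cell-type labels.
#' @param n_signature_per_type Planted signature probes per direction per
#'   cell type.
#' @param delta Minimum mean-beta separation of a planted probe, in (0, 0.9].
#' @param seed Integer seed; output is deterministic given it.
#' @return A `cell_type_profiles` list with elements `mean_beta` (probes x
#'   cell types, in `[0,1]`), `cell_types`, and `signature_map`
#'   (data.frame: `probe_id`, `cell_type`, `direction` hyper/hypo).
#' @export
generate_profiles <- function(n_probes,
                              cell_types = default_cell_types,
                              n_signature_per_type = 60L,
                              delta = 0.5, seed = 1L) {
  k <- length(cell_types)
  n_sig <- 2L * n_signature_per_type * k
  if (n_probes < n_sig)
    stop("n_probes must be >= ", n_sig, " to plant ",
         n_signature_per_type, " probes per direction per cell type",
         call. = FALSE)
  if (delta <= 0 || delta > 0.9)
    stop("delta must be in (0, 0.9]", call. = FALSE)
  set.seed(seed)

  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  mean_beta <- matrix(NA_real_, n_probes, k,
                      dimnames = list(probe_ids, cell_types))

  # background: one bimodal mean per probe, shared across cell types
  n_bg <- n_probes - n_sig
  hi <- stats::runif(n_probes) < 0.5
  bg <- ifelse(hi, stats::rbeta(n_probes, 5, 0.5),
               stats::rbeta(n_probes, 0.5, 5))
  mean_beta[] <- bg

  # planted signature probes occupy the leading rows, grouped by type
  pad <- 0.02  # keep means off the [0,1] boundary
  sig_rows <- seq_len(n_sig)
  map <- data.frame(probe_id = probe_ids[sig_rows],
                    cell_type = rep(cell_types,
                                    each = 2L * n_signature_per_type),
                    direction = rep(rep(c("hyper", "hypo"),
                                        each = n_signature_per_type), k),
                    stringsAsFactors = FALSE)
  for (i in sig_rows) {
    own <- map$cell_type[i]
    rest <- setdiff(cell_types, own)
    lo <- stats::runif(1L, pad, 1 - delta - 2 * pad)
    hi_m <- stats::runif(1L, lo + delta, 1 - pad)
    # the rest share one mean, so the probe discriminates exactly one type
    if (map$direction[i] == "hyper") {
      mean_beta[i, own] <- hi_m
      mean_beta[i, rest] <- lo
    } else {
      mean_beta[i, own] <- 1 - hi_m
      mean_beta[i, rest] <- 1 - lo
    }
  }

  structure(list(cell_types = cell_types, probe_ids = probe_ids,
                 mean_beta = mean_beta, signature_map = map,
                 delta = delta, seed = seed),
            class = "cell_type_profiles")
}

#' @export
print.cell_type_profiles <- function(x, ...) {
  cat("cell_type_profiles: ", length(x$probe_ids), " probes x ",
      length(x$cell_types), " cell types; ",
      nrow(x$signature_map), " planted signature probes (delta >= ",
      x$delta, ")\n", sep = "")
  invisible(x)
}

# Beta(m*s, (1-m)*s) noise around mean m; means clipped to [0.005, 0.995]
# so neither shape parameter degenerates. s = Inf returns the means.
rbeta_noise <- function(m, precision) {
  m <- pmin(pmax(m, 0.005), 0.995)
  if (!is.finite(precision)) return(m)
  out <- stats::rbeta(length(m), m * precision, (1 - m) * precision)
  out <- pmin(pmax(out, 0), 1)
  attributes(out) <- attributes(m)
  out
}

#' Simulate per-individual sorted-cell samples
#'
#' Each individual's beta at each probe is drawn from a beta distribution
#' centred on the cell-type mean `m` with variance `m(1-m)/(1+precision)`.
#'
#' @param profiles A `cell_type_profiles` object.
#' @param n_per_type Individuals per cell type.
#' @param precision Beta-distribution concentration (> 0); `Inf` gives
#'   noise-free samples equal to the cell-type means.
#' @param seed Integer seed.
#' @return List with `beta` (probes x individuals) and `sample_sheet`.
#' @export
sample_individuals <- function(profiles, n_per_type = 3L,
                               precision = 100, seed = 1L) {
  stopifnot(inherits(profiles, "cell_type_profiles"))
  if (precision <= 0) stop("precision must be > 0", call. = FALSE)
  set.seed(seed)
  k <- length(profiles$cell_types)
  ids <- paste0(rep(profiles$cell_types, each = n_per_type), "_ind",
                rep(seq_len(n_per_type), k))
  beta <- matrix(NA_real_, length(profiles$probe_ids), length(ids),
                 dimnames = list(profiles$probe_ids, ids))
  for (j in seq_along(ids)) {
    ct <- rep(profiles$cell_types, each = n_per_type)[j]
    beta[, j] <- rbeta_noise(profiles$mean_beta[, ct], precision)
  }
  sheet <- data.frame(sample_id = ids, role = "reference",
                      cell_type = rep(profiles$cell_types, each = n_per_type),
                      pool_size = 1L, batch = "sim",
                      stringsAsFactors = FALSE)
  list(beta = beta, sample_sheet = sheet)
}

#' Pool individual samples by equal-mass DNA combination
#'
#' Pooling equal masses of DNA averages methylation fractions, so a pool
#' column is the per-probe arithmetic mean of its member columns. All members
#' of a group must share a cell type.
#'
#' @param beta Probes x individuals beta matrix.
#' @param pooling Named list of character vectors of member sample ids; names
#'   become pool sample ids.
#' @param sample_sheet Sheet describing `beta`'s columns.
#' @return List with pooled `beta` and a pool-level `sample_sheet` whose
#'   `pool_size` is the summed member pool sizes.
#' @export
pool_samples <- function(beta, pooling, sample_sheet) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  if (is.null(names(pooling)))
    names(pooling) <- paste0("pool", seq_along(pooling))
  for (g in pooling) {
    if (!length(g)) stop("empty pooling group", call. = FALSE)
    if (!all(g %in% colnames(beta)))
      stop("pooling group member(s) not in beta: ",
           paste(setdiff(g, colnames(beta)), collapse = ", "), call. = FALSE)
  }
  types <- vapply(pooling, function(g) {
    ct <- unique(sample_sheet$cell_type[match(g, sample_sheet$sample_id)])
    if (length(ct) != 1L)
      stop("pooling group mixes cell types: ", paste(ct, collapse = ", "),
           call. = FALSE)
    ct
  }, character(1L))
  pooled <- vapply(pooling, function(g)
    rowMeans(beta[, g, drop = FALSE]), numeric(nrow(beta)))
  dimnames(pooled) <- list(rownames(beta), names(pooling))
  sizes <- vapply(pooling, function(g)
    sum(sample_sheet$pool_size[match(g, sample_sheet$sample_id)]),
    numeric(1L))
  sheet <- data.frame(sample_id = names(pooling), role = "reference",
                      cell_type = types, pool_size = as.integer(sizes),
                      batch = "sim", stringsAsFactors = FALSE,
                      row.names = NULL)
  list(beta = pooled, sample_sheet = sheet)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate mixed-cell samples with known composition
#'
#' The per-probe mixture mean is the weight-averaged cell-type mean,
#' `sum_k w_k m_k`; the observed beta is drawn around it with beta noise at
#' `noise_precision`. Each sample also receives an unprofiled (DNA-free,
#' red-blood-cell-like) fraction drawn uniformly from `unprofiled_range`:
#' it is recorded in the truth object — where it dilutes what a
#' flow-cytometry count of the physical sample would report — but never
#' enters the methylation signal.
#'
#' @param profiles A `cell_type_profiles` object.
#' @param n_mixtures Number of mixture samples.
#' @param dirichlet_alpha Dirichlet concentration vector (recycled to the
#'   number of cell types) used when `weights` is `NULL`.
#' @param weights Optional explicit n_mixtures x cell-types matrix of true
#'   weights; rows must be >= 0 and sum to 1 within 1e-6.
#' @param noise_precision Beta noise concentration; `Inf` for noise-free.
#' @param unprofiled_range Range of the per-sample unprofiled fraction,
#'   within `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `beta` (probes x mixtures) and `truth`, a list holding
#'   `true_weights` (a fraction-scale [proportion_table()]) and
#'   `unprofiled_fraction` (named per-sample vector).
#' @export
generate_mixtures <- function(profiles, n_mixtures = 12L,
                              dirichlet_alpha = c(4, 2, 1, 0.5),
                              weights = NULL,
                              noise_precision = 200,
                              unprofiled_range = c(0.1, 0.5),
                              seed = 1L) {
  stopifnot(inherits(profiles, "cell_type_profiles"))
  k <- length(profiles$cell_types)
  set.seed(seed)
  if (is.null(weights)) {
    alpha <- rep_len(dirichlet_alpha, k)
    weights <- rdirichlet(n_mixtures, alpha)
  } else {
    weights <- as.matrix(weights)
    if (ncol(weights) != k)
      stop("weights must have one column per cell type", call. = FALSE)
    if (any(weights < 0))
      stop("weights must be >= 0", call. = FALSE)
    if (any(abs(rowSums(weights) - 1) > 1e-6))
      stop("each weight row must sum to 1 within 1e-6", call. = FALSE)
    n_mixtures <- nrow(weights)
  }
  colnames(weights) <- profiles$cell_types
  rownames(weights) <- sprintf("mix%02d", seq_len(n_mixtures))

  means <- profiles$mean_beta %*% t(weights)  # probes x mixtures
  beta <- rbeta_noise(means, noise_precision)
  dimnames(beta) <- list(profiles$probe_ids, rownames(weights))

  if (any(unprofiled_range < 0) || any(unprofiled_range >= 1))
    stop("unprofiled_range must lie in [0, 1)", call. = FALSE)
  unprof <- stats::runif(n_mixtures, unprofiled_range[1L],
                         unprofiled_range[2L])
  names(unprof) <- rownames(weights)

  truth <- list(true_weights = proportion_table(weights, "fraction"),
                unprofiled_fraction = unprof)
  list(beta = beta, truth = truth)
}

#' Simulate a detection p-value matrix
#'
#' Each entry independently fails with probability `fail_rate`. Passing
#' entries are uniform on `[0, 0.005]`, failing entries uniform on
#' `(0.01, 1]`, so the conventional 0.01 threshold separates them cleanly.
#'
#' @param beta Beta matrix whose shape and dimnames the output copies.
#' @param fail_rate Per-entry failure probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Detection p-value matrix aligned with `beta`.
#' @export
simulate_detection_p <- function(beta, fail_rate = 0, seed = 1L) {
  if (fail_rate < 0 || fail_rate >= 1)
    stop("fail_rate must be in [0, 1)", call. = FALSE)
  set.seed(seed)
  n <- length(beta)
  fail <- stats::runif(n) < fail_rate
  p <- numeric(n)
  p[!fail] <- stats::runif(sum(!fail), 0, 0.005)
  p[fail] <- stats::runif(sum(fail), 0.01, 1)
  # open lower bound on the failing interval
  p[fail][p[fail] <= 0.01] <- 0.0100001
  matrix(p, nrow(beta), ncol(beta), dimnames = dimnames(beta))
}
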