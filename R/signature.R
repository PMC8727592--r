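#' One-vs-rest signature probe statistics
#'
#' For each cell type, each probe's reference betas are compared between
#' that type's samples and all other reference samples with a classical
#' equal-variance (pooled) two-group test. The F statistic is the square of
#' the pooled-variance t statistic and its p-value comes from the F
#' distribution with (1, n - 2) degrees of freedom, where n counts the
#' non-missing observations for that probe. `delta_beta` is the in-type mean
#' minus the rest mean. Probes with zero pooled variance get `f_stat = Inf`,
#' `p = 0` when the group means differ, else `f = 0`, `p = 1`.
#'
#' @param reference_beta Probes x samples beta matrix of reference
#'   (purified-cell) samples.
#' @param sample_sheet Sheet labelling each reference column with a cell
#'   type; every cell type needs >= 2 samples and the rest group >= 2.
#' @return data.frame with columns `cell_type`, `probe_id`, `f_stat`,
#'   `p_value`, `delta_beta`.
#' @export
one_vs_rest_stats <- function(reference_beta, sample_sheet) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  sheet <- sample_sheet[sample_sheet$role == "reference", ]
  sheet <- sheet[sheet$sample_id %in% colnames(reference_beta), ]
  types <- unique(sheet$cell_type)
  if (length(types) < 2L)
    stop("need at least 2 cell types among reference samples", call. = FALSE)
  counts <- table(sheet$cell_type)
  small <- names(counts)[counts < 2L]
  if (length(small))
    stop("cell type(s) with fewer than 2 reference samples: ",
         paste(small, collapse = ", "), call. = FALSE)

  beta <- reference_beta[, sheet$sample_id, drop = FALSE]
  res <- vector("list", length(types))
  for (t in seq_along(types)) {
    in_g <- sheet$cell_type == types[t]
    x <- beta[, in_g, drop = FALSE]
    y <- beta[, !in_g, drop = FALSE]
    n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
    m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
    ss1 <- rowSums((x - m1)^2, na.rm = TRUE)
    ss2 <- rowSums((y - m2)^2, na.rm = TRUE)
    df <- n1 + n2 - 2L
    sp2 <- (ss1 + ss2) / df
    se2 <- sp2 * (1 / n1 + 1 / n2)
    f <- (m1 - m2)^2 / se2
    p <- stats::pf(f, 1, df, lower.tail = FALSE)
    zero_var <- se2 <= 0 | !is.finite(se2)
    diff_mean <- abs(m1 - m2) > 0
    f[zero_var & diff_mean] <- Inf
    p[zero_var & diff_mean] <- 0
    f[zero_var & !diff_mean] <- 0
    p[zero_var & !diff_mean] <- 1
    res[[t]] <- data.frame(cell_type = types[t],
                           probe_id = rownames(beta),
                           f_stat = unname(f), p_value = unname(p),
                           delta_beta = unname(m1 - m2),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

# deterministic ranking: |delta| desc, then p asc, then probe id
rank_order <- function(df) {
  order(-abs(df$delta_beta), df$p_value, df$probe_id)
}

#' Select cell-type signature probes
#'
#' Candidates are first restricted to `p_value < p_threshold`; then, per
#' cell type, mode `"both"` takes the `n_each` most hypermethylated
#' (largest positive `delta_beta`) and `n_each` most hypomethylated (most
#' negative) probes, while mode `"any"` takes the `n_any` probes with the
#' largest `|delta_beta|` regardless of direction. Ties break by larger
#' `|delta_beta|`, then smaller p, then probe id. Shortfalls (fewer
#' significant candidates than requested) are permitted and recorded; a
#' cell type with no significant probe at all is an error.
#'
#' @param stats Output of [one_vs_rest_stats()].
#' @param mode `"both"` or `"any"`.
#' @param n_any Probes per cell type in mode `"any"`.
#' @param n_each Probes per direction per cell type in mode `"both"`.
#' @param p_threshold F-test p-value cut applied before ranking.
#' @return List with `per_type` (named list of per-cell-type probe id
#'   vectors), `union` (deduplicated union across cell types), `shortfall`
#'   (named counts of missing probes), and `metadata`.
#' @export
select_probes <- function(stats, mode = c("both", "any"),
                          n_any = 100L, n_each = 50L, p_threshold = 1e-8) {
  mode <- match.arg(mode)
  types <- unique(stats$cell_type)
  per_type <- list()
  shortfall <- integer(0)
  for (ct in types) {
    d <- stats[stats$cell_type == ct & stats$p_value < p_threshold, ]
    if (!nrow(d))
      stop("no probes significant at p < ", p_threshold,
           " for cell type '", ct, "'", call. = FALSE)
    if (mode == "any") {
      d <- d[rank_order(d), ]
      pick <- utils::head(d$probe_id, n_any)
      short <- n_any - length(pick)
    } else {
      hyper <- d[d$delta_beta > 0, ]
      hypo <- d[d$delta_beta < 0, ]
      hyper <- hyper[rank_order(hyper), ]
      hypo <- hypo[rank_order(hypo), ]
      pick <- c(utils::head(hyper$probe_id, n_each),
                utils::head(hypo$probe_id, n_each))
      short <- 2L * n_each - length(pick)
    }
    if (short > 0L)
      warning("cell type '", ct, "': ", short,
              " fewer significant probes than requested")
    per_type[[ct]] <- pick
    shortfall[ct] <- short
  }
  union <- unique(unlist(per_type, use.names = FALSE))
  list(per_type = per_type, union = union, shortfall = shortfall,
       metadata = list(mode = mode, n_any = n_any, n_each = n_each,
                       p_threshold = p_threshold,
                       per_type_counts = lengths(per_type),
                       union_size = length(union)))
}

#' Build the signature (design) matrix from selected probes
#'
#' Entry (probe, cell type) is the mean beta of that cell type's reference
#' samples at that probe — the design matrix of the constrained projection.
#'
#' @param reference_beta Probes x samples reference beta matrix.
#' @param sample_sheet Reference sample sheet.
#' @param selected_union Character vector of selected probe ids (e.g.
#'   `select_probes(...)$union`).
#' @param metadata Optional selection metadata to attach.
#' @return A `signature_matrix`: probes x cell types numeric matrix with a
#'   `metadata` attribute.
#' @export
build_signature_matrix <- function(reference_beta, sample_sheet,
                                   selected_union, metadata = NULL) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  sheet <- sample_sheet[sample_sheet$role == "reference" &
                          sample_sheet$sample_id %in% colnames(reference_beta), ]
  missing <- setdiff(selected_union, rownames(reference_beta))
  if (length(missing))
    stop("selected probe(s) absent from reference beta: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  types <- unique(sheet$cell_type)
  sig <- vapply(types, function(ct) {
    cols <- sheet$sample_id[sheet$cell_type == ct]
    rowMeans(reference_beta[selected_union, cols, drop = FALSE],
             na.rm = TRUE)
  }, numeric(length(selected_union)))
  sig <- matrix(sig, nrow = length(selected_union),
                dimnames = list(selected_union, types))
  structure(sig, metadata = metadata,
            class = c("signature_matrix", "matrix"))
}

#' @export
print.signature_matrix <- function(x, ...) {
  md <- attr(x, "metadata")
  cat("signature_matrix: ", nrow(x), " probes x ", ncol(x),
      " cell types", if (!is.null(md$mode)) paste0(" (mode '", md$mode, "')"),
      "\n", sep = "")
  invisible(x)
}

#' Write / read a signature matrix as CSV
#'
#' @param signature A `signature_matrix`.
#' @param path File path.
#' @param sep Field delimiter.
#' @export
write_signature_matrix <- function(signature, path, sep = ",") {
  df <- data.frame(probe_id = rownames(signature),
                   signif(unclass(signature), 15L), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_signature_matrix
#' @export
read_signature_matrix <- function(path, sep = ",") {
  x <- read_id_matrix(path, sep = sep)
  structure(x, metadata = NULL, class = c("signature_matrix", "matrix"))
}
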