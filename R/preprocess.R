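#' Quality control and normalization of beta matrices
#'
#' Filters follow standard methylation-array practice: samples whose mean
#' detection p-value exceeds the threshold are dropped first, then probes
#' are removed for (in first-cause order) detection failure in any retained
#' sample, a SNP at the CpG, sex-chromosome location, or cross-reactivity.
#' Normalization is cross-sample quantile normalization, optionally
#' stratified by probe design type.
#'
#' @name preprocessing
NULL

check_aligned <- function(beta, detp) {
  if (!identical(rownames(beta), rownames(detp)) ||
      !identical(colnames(beta), colnames(detp)))
    stop("beta and detection p matrices are not aligned by probe/sample ids",
         call. = FALSE)
}

#' Remove poor-quality samples by mean detection p-value
#'
#' @param beta Probes x samples beta matrix.
#' @param detp Aligned detection p-value matrix.
#' @param threshold Mean detection p-value above which a sample is removed.
#' @return List with filtered `beta` and `detp` and `samples_removed`, a
#'   data.frame of removed sample ids and their mean detection p.
#' @export
filter_samples_by_detection <- function(beta, detp, threshold = 0.01) {
  check_aligned(beta, detp)
  mean_p <- colMeans(detp, na.rm = TRUE)
  drop <- mean_p > threshold
  list(beta = beta[, !drop, drop = FALSE],
       detp = detp[, !drop, drop = FALSE],
       samples_removed = data.frame(sample_id = colnames(beta)[drop],
                                    mean_detection_p = unname(mean_p[drop]),
                                    stringsAsFactors = FALSE))
}

#' Remove failing and flagged probes
#'
#' A probe is removed if its detection p-value exceeds `threshold` in one or
#' more (retained) samples, or if the annotation flags it as having a SNP at
#' the CpG, mapping to a sex chromosome, or being cross-reactive. Each
#' removed probe is attributed to its first cause in that order. Probes
#' missing from the annotation are treated as unflagged and counted in
#' `unannotated`.
#'
#' @param beta Probes x samples beta matrix (sample filter already applied).
#' @param detp Aligned detection p-value matrix.
#' @param annotation Probe annotation data.frame (see
#'   [read_probe_annotation()]); `NULL` for no flags.
#' @param threshold Per-entry detection p-value threshold.
#' @return List with filtered `beta` and a `report` list: per-reason removal
#'   counts (`detection`, `snp`, `sex`, `cross_reactive`), `probes_removed`
#'   (data.frame probe_id, reason), `probes_retained`, `unannotated`.
#' @export
filter_probes <- function(beta, detp, annotation = NULL, threshold = 0.01) {
  check_aligned(beta, detp)
  probes <- rownames(beta)
  fail_det <- rowSums(detp > threshold, na.rm = TRUE) >= 1L

  flag <- function(col) {
    if (is.null(annotation)) return(rep(FALSE, length(probes)))
    i <- match(probes, annotation$probe_id)
    out <- annotation[[col]][i]
    out[is.na(out)] <- FALSE
    out
  }
  snp <- flag("snp_at_cpg")
  sex <- flag("on_sex_chromosome")
  xr <- flag("cross_reactive")
  unannotated <- if (is.null(annotation)) length(probes) else
    sum(!(probes %in% annotation$probe_id))

  reason <- rep(NA_character_, length(probes))
  reason[xr] <- "cross_reactive"
  reason[sex] <- "sex"
  reason[snp] <- "snp"
  reason[fail_det] <- "detection"   # first cause wins: assigned last
  drop <- !is.na(reason)

  report <- list(
    removed_by_reason = c(detection = sum(reason == "detection", na.rm = TRUE),
                          snp = sum(reason == "snp", na.rm = TRUE),
                          sex = sum(reason == "sex", na.rm = TRUE),
                          cross_reactive = sum(reason == "cross_reactive",
                                               na.rm = TRUE)),
    probes_removed = data.frame(probe_id = probes[drop],
                                reason = reason[drop],
                                stringsAsFactors = FALSE),
    probes_retained = sum(!drop),
    unannotated = unannotated)
  list(beta = beta[!drop, , drop = FALSE], report = report)
}

#' Run the full sample + probe QC chain
#'
#' Convenience wrapper: sample filter, then probe filter, returning a
#' combined QC report.
#'
#' @inheritParams filter_probes
#' @param sample_threshold Mean detection p threshold for samples.
#' @param probe_threshold Per-entry detection p threshold for probes.
#' @return List with filtered `beta` and a `report` combining both stages.
#' @export
run_qc <- function(beta, detp, annotation = NULL,
                   sample_threshold = 0.01, probe_threshold = 0.01) {
  s <- filter_samples_by_detection(beta, detp, sample_threshold)
  p <- filter_probes(s$beta, s$detp, annotation, probe_threshold)
  report <- c(list(samples_removed = s$samples_removed,
                   input_probes = nrow(beta),
                   input_samples = ncol(beta)),
              p$report)
  list(beta = p$beta, report = report)
}

#' Cross-sample quantile normalization
#'
#' Maps each sample's values onto the mean empirical quantile function
#' across samples (via [limma::normalizeQuantiles()]), so that after
#' normalization all samples share the same sorted value vector. With
#' `stratify_by_design = TRUE` and a `design_type` column in the annotation,
#' normalization is performed within each probe-chemistry stratum
#' separately, approximating design-aware (subset) quantile schemes.
#'
#' @param beta Probes x samples beta matrix (>= 2 samples; a single sample
#'   is returned unchanged with a warning).
#' @param stratify_by_design Normalize within design-type strata?
#' @param annotation Probe annotation providing `design_type` when
#'   stratifying.
#' @return Normalized beta matrix, same shape and dimnames, values in
#'   `[0, 1]`, within-sample rank order preserved.
#' @export
quantile_normalize <- function(beta, stratify_by_design = FALSE,
                               annotation = NULL) {
  if (ncol(beta) < 2L) {
    warning("fewer than 2 samples; returning data unchanged")
    return(beta)
  }
  if (stratify_by_design) {
    if (is.null(annotation) || is.null(annotation$design_type))
      stop("stratify_by_design needs an annotation with design_type",
           call. = FALSE)
    stratum <- annotation$design_type[match(rownames(beta),
                                            annotation$probe_id)]
    stratum[is.na(stratum)] <- "unknown"
    out <- beta
    for (s in unique(stratum)) {
      i <- stratum == s
      out[i, ] <- quantile_normalize(beta[i, , drop = FALSE])
    }
    return(out)
  }
  out <- limma::normalizeQuantiles(beta, ties = TRUE)
  out[] <- pmin(pmax(out, 0), 1)
  dimnames(out) <- dimnames(beta)
  out
}

#' Restrict two beta matrices to their common probes
#'
#' Both matrices are subset to the intersection of their probe ids, in the
#' first matrix's order, so reference and mixture data are comparable after
#' independent quality control.
#'
#' @param reference_beta,mixture_beta Beta matrices.
#' @return List of the two restricted matrices (`reference`, `mixture`).
#' @export
restrict_to_common_probes <- function(reference_beta, mixture_beta) {
  common <- intersect(rownames(reference_beta), rownames(mixture_beta))
  if (!length(common))
    stop("no probes in common between reference and mixture data",
         call. = FALSE)
  list(reference = reference_beta[common, , drop = FALSE],
       mixture = mixture_beta[common, , drop = FALSE])
}
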