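#' baldecon: reference-based cell-type deconvolution of methylation profiles
#'
#' Beta-value matrices are represented as plain numeric matrices with probe
#' ids as rownames and sample ids as colnames, the convention used throughout
#' methylation array analysis. Sample sheets and probe annotations are
#' data.frames. Proportions are held in a small `proportion_table` S3 class
#' that records whether values are on the fraction (0-1) or percent (0-100)
#' scale; all internal computation is on the fraction scale.
#'
#' @keywords internal
"_PACKAGE"

#' Validate a beta-value (or detection p-value) matrix
#'
#' Checks the invariants shared by beta and detection p-value matrices:
#' a numeric matrix with unique, non-missing probe rownames and sample
#' colnames, and all non-missing values within `[0, 1]`.
#'
#' @param x Numeric matrix, probes as rows, samples as columns.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown naming the
#'   first offending probe/sample.
#' @export
validate_beta_matrix <- function(x, what = "beta matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || anyNA(rownames(x)))
    stop(what, " must have probe ids as rownames", call. = FALSE)
  if (is.null(colnames(x)) || anyNA(colnames(x)))
    stop(what, " must have sample ids as colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(what, ": duplicate probe id '",
         rownames(x)[anyDuplicated(rownames(x))], "'", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(what, ": duplicate sample id '",
         colnames(x)[anyDuplicated(colnames(x))], "'", call. = FALSE)
  bad <- which(!is.na(x) & (x < 0 | x > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(x))
    stop(what, ": value ", x[bad[1L]], " outside [0,1] at probe '",
         rownames(x)[i[1L]], "', sample '", colnames(x)[i[2L]], "'",
         call. = FALSE)
  }
  invisible(x)
}

read_id_matrix <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          row.names = 1L, check.names = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = NA, stringsAsFactors = FALSE)
  notnum <- !vapply(df, is.numeric, logical(1L))
  if (any(notnum)) {
    col <- colnames(df)[which(notnum)[1L]]
    v <- df[[which(notnum)[1L]]]
    row <- rownames(df)[which(is.na(suppressWarnings(as.numeric(v))) &
                                !is.na(v))[1L]]
    stop("non-numeric value in column '", col, "'",
         if (!is.na(row)) paste0(", row '", row, "'"), call. = FALSE)
  }
  as.matrix(df)
}

#' Read a beta-value matrix from a delimited text file
#'
#' The first column must hold probe ids and the header row sample ids.
#' Missing values may be encoded as empty cells or `NA`. Values are validated
#' to lie in `[0, 1]`.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param sep Field delimiter, `","` or `"\t"`.
#' @return Numeric matrix (probes x samples) with dimnames.
#' @export
read_beta_matrix <- function(path, sep = ",") {
  x <- read_id_matrix(path, sep = sep)
  validate_beta_matrix(x, what = paste0("beta matrix '", basename(path), "'"))
  x
}

#' Write a beta-value matrix to a delimited text file
#'
#' @param x Validated beta matrix.
#' @param path Output path.
#' @param sep Field delimiter.
#' @param digits Significant digits retained; the default round-trips doubles.
#' @export
write_beta_matrix <- function(x, path, sep = ",", digits = 15L) {
  validate_beta_matrix(x)
  df <- data.frame(probe_id = rownames(x),
                   signif(x, digits), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a detection p-value matrix
#'
#' Same layout and `[0, 1]` contract as [read_beta_matrix()].
#' @inheritParams read_beta_matrix
#' @return Numeric matrix (probes x samples).
#' @export
read_detection_p <- function(path, sep = ",") {
  x <- read_id_matrix(path, sep = sep)
  validate_beta_matrix(x, what = paste0("detection p matrix '",
                                        basename(path), "'"))
  x
}

#' Read or validate a sample sheet
#'
#' A sample sheet assigns each array to a role (`"reference"` for purified
#' sorted-cell samples, `"mixture"` for mixed-cell samples), gives reference
#' samples a cell-type label, and records how many individuals were pooled
#' into the sample (`pool_size`, >= 1) plus a free-text batch label.
#'
#' @param path CSV with columns `sample_id`, `role`, `cell_type`,
#'   `pool_size`, `batch` (the last three optional on read).
#' @param sep Field delimiter.
#' @return data.frame with those five columns.
#' @export
read_sample_sheet <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to validate in place of a file.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "role")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(sheet$cell_type)) sheet$cell_type <- NA_character_
  if (is.null(sheet$pool_size)) sheet$pool_size <- 1L
  if (is.null(sheet$batch)) sheet$batch <- NA_character_
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  if (!all(sheet$role %in% c("reference", "mixture")))
    stop("sample sheet role must be 'reference' or 'mixture'", call. = FALSE)
  ref <- sheet$role == "reference"
  if (any(ref & (is.na(sheet$cell_type) | sheet$cell_type == "")))
    stop("every reference sample needs a cell_type", call. = FALSE)
  if (any(is.na(sheet$pool_size) | sheet$pool_size < 1))
    stop("pool_size must be >= 1", call. = FALSE)
  sheet[, c("sample_id", "role", "cell_type", "pool_size", "batch")]
}

write_sample_sheet <- function(sheet, path, sep = ",") {
  utils::write.table(sheet, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a probe annotation table
#'
#' @param path CSV with columns `probe_id` and any of `on_sex_chromosome`,
#'   `snp_at_cpg`, `cross_reactive` (logical or 0/1) and `design_type`.
#' @param sep Field delimiter.
#' @return data.frame with logical flag columns, defaults `FALSE`.
#' @export
read_probe_annotation <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  if (is.null(df$probe_id)) stop("probe annotation needs probe_id", call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id in annotation", call. = FALSE)
  for (fl in c("on_sex_chromosome", "snp_at_cpg", "cross_reactive")) {
    df[[fl]] <- if (is.null(df[[fl]])) FALSE else as.logical(df[[fl]])
    df[[fl]][is.na(df[[fl]])] <- FALSE
  }
  if (is.null(df$design_type)) df$design_type <- NA_character_
  df
}

#' Read a probe id list
#'
#' Plain text, one id per line; blank lines and lines starting with `#` are
#' ignored; duplicates are dropped.
#'
#' @param path Path to the list.
#' @return Character vector of unique probe ids (possibly empty).
#' @export
read_probe_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Construct a table of cell-type proportions
#'
#' @param weights Numeric matrix, samples as rows, cell types as columns,
#'   all entries >= 0 (NA allowed for unestimated entries).
#' @param scale `"fraction"` (0-1) or `"percent"` (0-100).
#' @return A `proportion_table`: the weight matrix with a `scale` attribute.
#' @export
proportion_table <- function(weights, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)) && nrow(weights) > 0L)
    rownames(weights) <- paste0("sample", seq_len(nrow(weights)))
  if (is.null(colnames(weights)))
    stop("proportion table needs cell-type colnames", call. = FALSE)
  if (any(weights < 0, na.rm = TRUE))
    stop("proportions must be >= 0", call. = FALSE)
  structure(weights, scale = scale, class = c("proportion_table", "matrix"))
}

#' @export
print.proportion_table <- function(x, ...) {
  cat("proportion_table (", attr(x, "scale"), " scale): ",
      nrow(x), " samples x ", ncol(x), " cell types\n", sep = "")
  print(unclass_prop(x), ...)
  invisible(x)
}

unclass_prop <- function(x) {
  attr(x, "scale") <- NULL
  class(x) <- "matrix"
  x
}

#' Convert a proportion table between fraction and percent scales
#'
#' @param x A `proportion_table`.
#' @return The table on the requested scale.
#' @export
as_fraction <- function(x) {
  stopifnot(inherits(x, "proportion_table"))
  if (attr(x, "scale") == "percent")
    x <- proportion_table(unclass_prop(x) / 100, "fraction")
  x
}

#' @rdname as_fraction
#' @export
as_percent <- function(x) {
  stopifnot(inherits(x, "proportion_table"))
  if (attr(x, "scale") == "fraction")
    x <- proportion_table(unclass_prop(x) * 100, "percent")
  x
}

#' Write cell-type proportions to a CSV file
#'
#' Samples are rows, cell types are columns, values on the requested scale.
#'
#' @param table A `proportion_table`.
#' @param path Output path.
#' @param scale Output scale, `"fraction"` or `"percent"`.
#' @param sep Field delimiter.
#' @export
write_proportions <- function(table, path, scale = c("fraction", "percent"),
                              sep = ",") {
  scale <- match.arg(scale)
  table <- if (scale == "fraction") as_fraction(table) else as_percent(table)
  w <- unclass_prop(table)
  df <- data.frame(sample_id = rownames(w), signif(w, 15L),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read cell-type proportions written by [write_proportions()]
#'
#' @param path Input path.
#' @param scale Scale the file is on.
#' @param sep Field delimiter.
#' @return A `proportion_table` on that scale.
#' @export
read_proportions <- function(path, scale = c("fraction", "percent"),
                             sep = ",") {
  scale <- match.arg(scale)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, na.strings = c("NA", ""))
  proportion_table(as.matrix(df), scale)
}
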