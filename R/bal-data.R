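#' Bundled BAL cell-composition example data
#'
#' Measured cell composition for six paediatric bronchoalveolar lavage
#' samples (five from children with cystic fibrosis, one control), as
#' percentages of four cell types: alveolar macrophages, lymphocytes,
#' granulocytes and alveolar epithelial cells. For each subject the table
#' holds the flow-cytometry composition over all counted events
#' (`flow_unscaled`; the remainder to 100% is mostly DNA-free red blood
#' cells), the same composition rescaled over the four profiled cell types
#' (`flow_scaled`), and methylation-based deconvolution estimates under the
#' `"any"` and `"both"` probe-selection modes (`dnam_any`, `dnam_both`).
#'
#' @param wide Return one matrix per measurement (`TRUE`) or the long
#'   data.frame (`FALSE`, default).
#' @return Long: data.frame with columns `subject`, `cell_type`,
#'   `flow_unscaled`, `flow_scaled`, `dnam_any`, `dnam_both` (percent).
#'   Wide: named list of subjects x cell-types percent matrices.
#' @examples
#' comp <- bal_composition(wide = TRUE)
#' scale_flow_proportions(comp$flow_unscaled["CF4", ])
#' @export
bal_composition <- function(wide = FALSE) {
  path <- system.file("extdata", "bal_composition.csv",
                      package = "baldecon", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!wide) return(df)
  subjects <- unique(df$subject)
  cts <- unique(df$cell_type)
  one <- function(col) {
    m <- matrix(df[[col]][order(match(df$subject, subjects),
                                match(df$cell_type, cts))],
                nrow = length(subjects), byrow = TRUE,
                dimnames = list(subjects, cts))
    m
  }
  lapply(stats::setNames(nm = c("flow_unscaled", "flow_scaled",
                                "dnam_any", "dnam_both")), one)
}
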