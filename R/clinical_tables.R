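#' Bundled clinical contingency counts of the breast-cancer validation cohort
#'
#' Per-variable counts of relapse vs no-relapse (n = 1056) for estrogen
#' receptor status, lymph-node status and tumour grade, as published for
#' the public validation cohort the pipeline targets. Used with
#' [univariable_or()] to compute the univariable odds ratios of relapse.
#'
#' @param path TSV source; defaults to the copy shipped with the package.
#' @return named list of counts matrices (levels x 2, columns no-relapse /
#'   relapse), one per clinical variable, ready for [univariable_or()].
#' @export
clinical_cohort_counts <- function(path = system.file(
  "extdata", "bc_cohort_clinical_counts.tsv", package = "gcnsurv")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
  lapply(split(df, df$variable), function(d) {
    m <- as.matrix(d[c("no_relapse", "relapse")])
    rownames(m) <- d$level
    m
  })
}
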