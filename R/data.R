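#' Published cross-validation profiles from the ideal-professor survey
#'
#' Cross-validated deviance profiles from a survey in which 100 first-year
#' business-economics students ranked five characteristics of an ideal
#' professor (clarity of exposition, material before lectures, midterm
#' scheduling, slides/material with the books, helpfulness) and seven
#' subject covariates were recorded. The underlying rankings are not
#' publicly deposited; what is available are the published model-selection
#' summaries: for each trunk size, the model deviance `D`, the case-wise
#' 10-fold cross-validation deviance `Dcv` and its standard error `SEcv`,
#' for both the one-split-only and the multiple-splitting search. They
#' serve as a worked example for [prune_select()]: with `c = 0.5` the
#' multiple-splitting profile selects model 4; with `c = 0` the
#' one-split-only profile selects model 3.
#'
#' @return A list with data frames `oso` and `ms` (columns `model`, `D`,
#'   `Dcv`, `SEcv`).
#' @examples
#' prof <- professor_cv_profiles()
#' prune_select(prof$ms, c = 0.5)
#' prune_select(prof$oso, c = 0)
#' @export
professor_cv_profiles <- function() {
  rd <- function(f) utils::read.delim(
    system.file("extdata", f, package = "btrtrunk", mustWork = TRUE))
  list(oso = rd("professor_cv_oso.tsv"), ms = rd("professor_cv_ms.tsv"))
}

#' Read rankings, paired comparisons or covariates from delimited text
#'
#' `read_rankings()` expects a header `judge,<obj1>,...,<objK>` with integer
#' ranks; `read_pairs()` a long table `judge,object_i,object_j,y`;
#' `read_covariates()` a header `judge,x1,...,xP`.
#'
#' @param file Path to a CSV file.
#' @param objects Optional object labels for `read_pairs()`.
#' @return A `btrt_rankings`, `btrt_pairs` or plain data frame.
#' @export
read_rankings <- function(file) {
  as_rankings(utils::read.csv(file, check.names = FALSE))
}

#' @rdname read_rankings
#' @export
read_pairs <- function(file, objects = NULL) {
  as_pairs(utils::read.csv(file), objects = objects)
}

#' @rdname read_rankings
#' @export
read_covariates <- function(file) {
  df <- utils::read.csv(file)
  if (!"judge" %in% names(df)) stop("covariates file must have a 'judge' column")
  df
}
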