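#' Paths to bundled example tables
#'
#' The package ships small plain-text example tables: published
#' keyword-level APC values and hashtag counts (transcribed printed table
#' columns), an event log, and \emph{synthetic} per-category annotation
#' reconstructions (the published sources print only total I-scale scores;
#' the bundled breakdowns are consistent with the rubric's worked examples
#' and sum to the printed totals — see
#' \code{inst/extdata/README.txt}).
#'
#' @param file file name within \code{extdata}, or NULL to list all
#'   available files.
#' @return a file path (or a character vector of file names).
#' @examples
#' infodemic_example()
#' read.csv(infodemic_example("table4_hashtags.csv"))
#' @export
infodemic_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "infodemic")))
  path <- system.file("extdata", file, package = "infodemic")
  if (path == "") stop("no such example file: ", file, call. = FALSE)
  path
}
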