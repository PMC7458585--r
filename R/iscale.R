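#' @name iscale-rubric
#' @title The infodemic scale (I-scale) rubric
#'
#' @description
#' An infodemic moniker is a term, query, hashtag or phrase that generates or
#' feeds misinformation, misinterpretation or discrimination online. Each
#' moniker is scored by a human annotator on five rubric categories, 0 to 2
#' points each, so the total I-scale score ranges from 0 to 10:
#'
#' \itemize{
#'   \item \emph{generic} — the term confuses through lack of specificity
#'     (1 pt: a scientific term prone to misunderstanding, e.g. "COVID" for
#'     "COVID-19"; 2 pts: a conflation of two scientific terms).
#'   \item \emph{misinformative} — the term feeds fake news (1 pt: points at
#'     individuals; 2 pts: spreads claims from unconfirmed sources).
#'   \item \emph{discriminatory} — the term ties the disease to a place or
#'     ethnicity (1 pt: a country; 2 pts: an ethnicity).
#'   \item \emph{deviant} — the term pushes an opinion or attitude rather
#'     than identifying the phenomenon.
#'   \item \emph{other} — reserved extra points for exceptionally serious
#'     cases (health or economic risk).
#' }
#'
#' Totals map to five severity classes: 0 = not infodemic, 1 = slightly,
#' 2–4 = moderately, 5–8 = highly, 9–10 = extremely infodemic.
#'
#' The package deliberately does \emph{not} infer category points from the
#' keyword text: point assignment is a human judgment, and the computable
#' contract here is validation, arithmetic and classification.
NULL

.iscale_categories <- c("generic", "misinformative", "discriminatory",
                        "deviant", "other")

.severity_levels <- c("not_infodemic", "slightly", "moderately",
                      "highly", "extremely")

#' Validate a table of moniker annotations
#'
#' Checks that every rubric category point is an integer in \{0, 1, 2\}, that
#' monikers are non-empty after trimming, and that monikers are unique after
#' case-folding (Google treats "corona" and "Corona" as one query).
#'
#' @param x a data.frame with columns \code{moniker}, \code{generic},
#'   \code{misinformative}, \code{discriminatory}, \code{deviant},
#'   \code{other}.
#' @return the validated data.frame, invisibly unchanged apart from
#'   whitespace-trimmed monikers.
#' @export
validate_annotations <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("moniker", .iscale_categories), names(x))
  if (length(missing_cols) > 0L)
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x$moniker <- trimws(as.character(x$moniker))
  if (any(is.na(x$moniker) | x$moniker == ""))
    stop("empty moniker at row(s): ",
         paste(which(is.na(x$moniker) | x$moniker == ""), collapse = ", "),
         call. = FALSE)
  for (cat in .iscale_categories) {
    v <- x[[cat]]
    bad <- is.na(v) | v != as.integer(v) | v < 0 | v > 2
    if (any(bad))
      stop(sprintf("%s out of range (must be an integer in {0,1,2}) at row(s): %s",
                   cat, paste(which(bad), collapse = ", ")), call. = FALSE)
    x[[cat]] <- as.integer(v)
  }
  folded <- tolower(x$moniker)
  if (anyDuplicated(folded)) {
    dups <- unique(folded[duplicated(folded)])
    stop("duplicate moniker(s) after case-folding: ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Map I-scale scores to severity classes
#'
#' The five classes partition the score range \{0, ..., 10\}:
#' 0 is not infodemic, 1 slightly, 2–4 moderately, 5–8 highly and
#' 9–10 extremely infodemic.
#'
#' @param score integer vector of I-scale totals in 0..10.
#' @return a factor with levels \code{not_infodemic}, \code{slightly},
#'   \code{moderately}, \code{highly}, \code{extremely}.
#' @examples
#' classify_severity(c(0, 1, 4, 8, 10))
#' @export
classify_severity <- function(score) {
  if (any(is.na(score) | score != as.integer(score) | score < 0 | score > 10))
    stop("score must be an integer in 0..10", call. = FALSE)
  cut(as.integer(score), breaks = c(-1, 0, 1, 4, 8, 10),
      labels = .severity_levels)
}

#' Score monikers on the infodemic scale
#'
#' Sums the five category points of each annotated moniker into a 0–10
#' I-scale score and attaches the severity class. Input order is preserved;
#' rows are independent.
#'
#' @param x an annotation data.frame (see [validate_annotations()]), one row
#'   per moniker.
#' @return an object of class \code{"iscale"}: a data.frame with columns
#'   \code{moniker}, \code{score}, \code{severity} plus the original
#'   category columns.
#' @examples
#' ann <- data.frame(moniker = c("COVID-19", "COVID"),
#'                   generic = c(0L, 1L), misinformative = 0L,
#'                   discriminatory = 0L, deviant = 0L, other = 0L)
#' iscale(ann)
#' @export
iscale <- function(x) {
  x <- validate_annotations(x)
  score <- as.integer(rowSums(x[.iscale_categories]))
  out <- data.frame(moniker = x$moniker, score = score,
                    severity = classify_severity(score),
                    x[.iscale_categories],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("iscale", "data.frame")
  out
}

#' @export
print.iscale <- function(x, ...) {
  cat(sprintf("I-scale scores for %d moniker(s)\n", nrow(x)))
  print.data.frame(x[c("moniker", "score", "severity")], row.names = FALSE,
                   ...)
  invisible(x)
}

#' @export
summary.iscale <- function(object, ...) {
  tab <- table(object$severity)
  cat("Severity class counts:\n")
  print(tab)
  cat(sprintf("Score range: %d-%d (median %g)\n",
              min(object$score), max(object$score),
              stats::median(object$score)))
  invisible(tab)
}

#' @export
coef.iscale <- function(object, ...) {
  stats::setNames(object$score, object$moniker)
}
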