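# CSV readers/writers for the pipeline's table dialects.
# All files are UTF-8, comma-separated, header-required; dates ISO-8601.

read_csv_strict <- function(path, required, stage) {
  if (!file.exists(path))
    stage_error(stage, sprintf("input file not found: %s", path))
  x <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stage_error(stage, sprintf(
      "cannot parse %s: %s", path, conditionMessage(e))))
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L)
    stage_error(stage, sprintf("%s lacks column(s): %s", path,
                               paste(miss, collapse = ", ")))
  if (nrow(x) == 0L)
    stage_error(stage, sprintf("%s has no data rows", path))
  x
}

#' Read a moniker annotation table
#'
#' Expects columns \code{moniker,generic,misinformative,discriminatory,
#' deviant,other}.
#' @param path CSV file path.
#' @return validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  validate_annotations(
    read_csv_strict(path, c("moniker", .iscale_categories), "iscale"))
}

#' Read search-volume series
#'
#' Expects columns \code{keyword,geo,date,value}; one \code{rsv_series} is
#' built per keyword-geography pair. Values must already be on the 0-100
#' scale unless \code{normalized = FALSE}, in which case they are raw
#' counts and each series is normalized on read.
#'
#' @param path CSV file path.
#' @param normalized whether values are already RSV (default TRUE).
#' @return named list of \code{rsv_series}, names \code{keyword|geo}.
#' @export
read_series <- function(path, normalized = TRUE) {
  x <- read_csv_strict(path, c("keyword", "geo", "date", "value"), "trends")
  x$date <- as.Date(x$date)
  pieces <- split(x, paste(x$keyword, x$geo, sep = "|"))
  lapply(pieces, function(p) {
    p <- p[order(p$date), ]
    if (normalized)
      rsv_series(p$keyword[1], p$geo[1], p$date, p$value)
    else
      normalize_rsv(p$value, keyword = p$keyword[1], geo = p$geo[1],
                    dates = p$date)
  })
}

#' Read an event log
#'
#' Expects columns \code{date,label,keyword}.
#' @param path CSV file path.
#' @return data.frame with parsed dates.
#' @export
read_events <- function(path) {
  x <- read_csv_strict(path, c("date", "label", "keyword"), "trends")
  x$date <- as.Date(x$date)
  if (any(is.na(x$date) | !nzchar(x$label)))
    stage_error("trends", "event log has missing dates or empty labels")
  x
}

#' Read a hashtag count table
#'
#' Expects columns \code{tag,count} (optional \code{group}).
#' @param path CSV file path.
#' @return data.frame ready for [shares()].
#' @export
read_hashtags <- function(path) {
  x <- read_csv_strict(path, c("tag", "count"), "hashtags")
  if (!"group" %in% names(x)) x$group <- "other"
  x
}

#' Read a keyword-level APC table
#'
#' Expects columns \code{keyword,total} (optional \code{ci_low,ci_high}),
#' e.g. a transcribed published ranking.
#' @param path CSV file path.
#' @return data.frame of APC estimates.
#' @export
read_apc_table <- function(path) {
  read_csv_strict(path, c("keyword", "total"), "trends")
}

#' Read a joined country panel
#'
#' Expects columns \code{country,interest,incidence}.
#' @param path CSV file path.
#' @return data.frame for [panel_pearson()].
#' @export
read_panel <- function(path) {
  x <- read_csv_strict(path, c("country", "interest", "incidence"),
                       "association")
  if (anyDuplicated(x$country))
    stage_error("association", paste0("duplicate country: ",
      paste(unique(x$country[duplicated(x$country)]), collapse = ", ")))
  x
}

write_csv_utf8 <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}
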