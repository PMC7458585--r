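#' Country-level correlation of search interest with disease incidence
#'
#' Tests whether countries with higher disease incidence (cases per million
#' people) show greater search interest. The Pearson coefficient and its
#' significance test are computed from first principles:
#' \deqn{r = \frac{\sum (x_i-\bar x)(y_i-\bar y)}
#'               {\sqrt{\sum (x_i-\bar x)^2 \sum (y_i-\bar y)^2}}, \quad
#'       t = r\sqrt{\frac{n-2}{1-r^2}},}
#' with a two-sided p-value from the Student-t distribution on n - 2
#' degrees of freedom.
#'
#' @param panel data.frame with columns \code{interest} and
#'   \code{incidence} (and optionally \code{country}), one row per country;
#'   n >= 3, both variables with nonzero variance.
#' @return an object of class \code{"panel_cor"} with components \code{r},
#'   \code{n}, \code{t_stat}, \code{p_value}, \code{df}. The p-value is kept
#'   at machine precision; printing displays "<.001" below that threshold.
#' @examples
#' p <- data.frame(interest = 1:5, incidence = 2 * (1:5) + 1)
#' panel_pearson(p)$r  # 1
#' @export
panel_pearson <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("interest", "incidence") %in% names(panel)))
  x <- as.numeric(panel$interest)
  y <- as.numeric(panel$incidence)
  n <- length(x)
  if (n < 3L) stop("need at least 3 countries", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in panel", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stop("zero variance in interest or incidence", call. = FALSE)
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  t_stat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  structure(list(r = r, n = n, t_stat = t_stat, p_value = p, df = n - 2L),
            class = "panel_cor")
}

#' @export
print.panel_cor <- function(x, ...) {
  pdisp <- if (x$p_value < 0.001) "<.001" else sprintf("=%.3f", x$p_value)
  cat(sprintf("Pearson correlation: R=%.2f (n=%d, t=%.2f on %d df, P%s)\n",
              x$r, x$n, x$t_stat, x$df, pdisp))
  invisible(x)
}

#' @export
coef.panel_cor <- function(object, ...) c(r = object$r)

#' Build a country panel from per-country RSV series and an incidence table
#'
#' Inner-joins per-country search series with an incidence table on the
#' country code. The interest measure is the mean RSV over the study window
#' by default; \code{measure = "apc"} uses the average peak volume instead.
#'
#' @param series_list named list of \code{rsv_series}, one per country
#'   (names or \code{geo} attributes are the country codes).
#' @param incidence data.frame with columns \code{country} and
#'   \code{incidence} (cases per million), countries unique.
#' @param measure \code{"mean_rsv"} (default) or \code{"apc"}.
#' @param window_days peak window used when \code{measure = "apc"}.
#' @return data.frame with columns \code{country}, \code{interest},
#'   \code{incidence}, suitable for [panel_pearson()].
#' @export
build_panel <- function(series_list, incidence, measure = c("mean_rsv", "apc"),
                        window_days = 7) {
  measure <- match.arg(measure)
  stopifnot(is.list(series_list), is.data.frame(incidence),
            all(c("country", "incidence") %in% names(incidence)))
  if (anyDuplicated(incidence$country))
    stop("duplicate country in incidence table: ",
         paste(unique(incidence$country[duplicated(incidence$country)]),
               collapse = ", "), call. = FALSE)
  geos <- names(series_list)
  if (is.null(geos))
    geos <- vapply(series_list, attr, character(1), "geo")
  common <- intersect(geos, incidence$country)
  if (length(common) == 0L)
    stop("no countries in common between series and incidence table",
         call. = FALSE)
  interest <- vapply(common, function(cc) {
    s <- series_list[[match(cc, geos)]]
    if (measure == "mean_rsv") mean(s$value)
    else apc(extract_peaks(s, window_days))$total
  }, numeric(1))
  data.frame(country = common, interest = as.numeric(interest),
             incidence = incidence$incidence[match(common,
                                                   incidence$country)],
             row.names = NULL)
}
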