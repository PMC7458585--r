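#' Construct a relative search-volume series
#'
#' A relative search volume (RSV) series is the normalized popularity index
#' published by search-trend services: integers from 0 (low) to 100 (the
#' period/region maximum) for one keyword in one geography, on strictly
#' increasing calendar dates.
#'
#' @param keyword search keyword the series describes.
#' @param geo geography code (e.g. ISO-3166 alpha-2, or "GLOBAL").
#' @param dates a \code{Date} vector (or coercible), strictly increasing.
#' @param values numeric vector, same length as \code{dates}, each in
#'   \[0, 100\].
#' @param normalized logical; \code{TRUE} when the values are already on the
#'   0–100 RSV scale (a nonzero normalized series must attain 100).
#' @return an object of class \code{"rsv_series"}: a data.frame with columns
#'   \code{date} and \code{value} and attributes \code{keyword}, \code{geo},
#'   \code{normalized}, \code{degenerate}.
#' @export
rsv_series <- function(keyword, geo, dates, values, normalized = TRUE) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(values), length(dates) >= 1L)
  if (any(diff(as.numeric(dates)) <= 0))
    stop("dates must be strictly increasing", call. = FALSE)
  if (any(is.na(values) | values < 0 | values > 100))
    stop("RSV values must lie in [0, 100]", call. = FALSE)
  degenerate <- all(values == 0)
  if (normalized && !degenerate && max(values) != 100)
    stop("a nonzero normalized series must attain 100", call. = FALSE)
  out <- data.frame(date = dates, value = values)
  structure(out, keyword = as.character(keyword), geo = as.character(geo),
            normalized = isTRUE(normalized), degenerate = degenerate,
            class = c("rsv_series", "data.frame"))
}

#' @export
print.rsv_series <- function(x, ...) {
  cat(sprintf("RSV series \"%s\" [%s]: %d observations, %s..%s%s\n",
              attr(x, "keyword"), attr(x, "geo"), nrow(x),
              min(x$date), max(x$date),
              if (attr(x, "degenerate")) " (degenerate: all zero)" else ""))
  invisible(x)
}

#' Normalize raw counts to the 0-100 RSV scale
#'
#' Maps each raw value v to \code{round_half_up(100 * v / max(raw))}, the
#' convention used by search-trend indices (integer output, period maximum
#' pinned at 100). An all-zero input returns all zeros and is flagged
#' degenerate. Normalization preserves value ordering and is idempotent on
#' already-normalized nonzero series.
#'
#' @param x non-negative numeric vector of raw counts, or an
#'   \code{rsv_series} holding raw counts.
#' @param keyword,geo,dates series metadata used when \code{x} is a bare
#'   numeric vector.
#' @return an \code{rsv_series} with integer values in \[0, 100\].
#' @examples
#' as.numeric(normalize_rsv(c(3, 7, 9))$value)  # 33 78 100
#' @export
normalize_rsv <- function(x, keyword = "query", geo = "GLOBAL",
                          dates = NULL) {
  if (inherits(x, "rsv_series")) {
    keyword <- attr(x, "keyword"); geo <- attr(x, "geo")
    dates <- x$date; x <- x$value
  }
  if (any(is.na(x) | x < 0))
    stop("raw counts must be non-negative", call. = FALSE)
  if (length(x) == 0L) stop("empty series", call. = FALSE)
  if (is.null(dates))
    dates <- seq(as.Date("2020-02-20"), by = "day", length.out = length(x))
  vals <- if (all(x == 0)) rep(0L, length(x))
          else as.integer(round_half_up(100 * x / max(x)))
  rsv_series(keyword, geo, dates, vals, normalized = TRUE)
}

#' Extract windowed peak observations
#'
#' Tiles the date range into consecutive windows of \code{window_days}
#' calendar days anchored at the first observation date (a trailing partial
#' window is kept) and records the maximum value in each non-empty window.
#' These windowed peaks are the observations underlying the average peak
#' volume estimator.
#'
#' @param series an \code{rsv_series}.
#' @param window_days window length in days (default 7).
#' @return data.frame with columns \code{geo}, \code{window_index} (1-based
#'   tile number) and \code{peak_value}.
#' @export
extract_peaks <- function(series, window_days = 7) {
  stopifnot(inherits(series, "rsv_series"),
            length(window_days) == 1L, window_days >= 1)
  tile <- floor(as.numeric(series$date - series$date[1]) / window_days)
  peaks <- tapply(series$value, tile, max)
  data.frame(geo = attr(series, "geo"),
             window_index = as.integer(names(peaks)) + 1L,
             peak_value = as.numeric(peaks), row.names = NULL)
}

#' Average peak volume (APC) with a Gaussian confidence interval
#'
#' Summarizes a keyword's search interest as the sum, over geographies, of
#' the per-geography mean of windowed peak RSV values. Because the total
#' sums across geographies it can exceed the per-series RSV ceiling of 100.
#' The confidence interval is Gaussian with independently propagated
#' per-geography variances: for geography g with n_g windowed peaks, mean
#' m_g and unbiased variance s_g^2 (taken as 0 when n_g = 1),
#' \deqn{APC = \sum_g m_g, \quad
#'       \mathrm{halfwidth} = z_{(1+level)/2}\sqrt{\sum_g s_g^2 / n_g},}
#' and the interval is \code{total +/- halfwidth}, floored at 0. With one
#' peak per geography the interval collapses to the point estimate.
#'
#' @param peaks data.frame of peak observations with columns \code{geo} and
#'   \code{peak_value} (as from [extract_peaks()], possibly row-bound over
#'   geographies).
#' @param level confidence level in (0, 1); default 0.95.
#' @param keyword keyword label carried into the estimate.
#' @return an object of class \code{"apc"} with components \code{keyword},
#'   \code{total}, \code{ci_low}, \code{ci_high}, \code{n_obs},
#'   \code{level}, and \code{per_geo} (per-geography means and variances).
#' @examples
#' pk <- data.frame(geo = "IT", peak_value = c(10, 10, 10))
#' apc(pk)  # total 10, degenerate CI [10, 10]
#' @export
apc <- function(peaks, level = 0.95, keyword = "query") {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L) stop("no peak observations", call. = FALSE)
  stopifnot(all(c("geo", "peak_value") %in% names(peaks)),
            all(peaks$peak_value >= 0),
            length(level) == 1L, level > 0, level < 1)
  g <- factor(peaks$geo, levels = unique(peaks$geo))
  n_g <- as.numeric(tapply(peaks$peak_value, g, length))
  m_g <- as.numeric(tapply(peaks$peak_value, g, mean))
  s2_g <- as.numeric(tapply(peaks$peak_value, g,
                            function(v) if (length(v) > 1L) stats::var(v) else 0))
  total <- sum(m_g)
  hw <- stats::qnorm((1 + level) / 2) * sqrt(sum(s2_g / n_g))
  structure(list(keyword = keyword, total = total,
                 ci_low = max(0, total - hw), ci_high = total + hw,
                 n_obs = nrow(peaks), level = level,
                 per_geo = data.frame(geo = levels(g), n = n_g, mean = m_g,
                                      var = s2_g)),
            class = "apc")
}

#' @export
print.apc <- function(x, digits = 2, ...) {
  cat(sprintf("APC for \"%s\": %.*f, %d%% CI [%.*f, %.*f] (%d peaks, %d geographies)\n",
              x$keyword, digits, x$total, round(100 * x$level),
              digits, x$ci_low, digits, x$ci_high,
              x$n_obs, nrow(x$per_geo)))
  invisible(x)
}

#' @export
coef.apc <- function(object, ...) c(total = object$total)

#' @export
confint.apc <- function(object, parm, level, ...) {
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("total",
                              sprintf("%g %%", c((1 - object$level) / 2,
                                                 (1 + object$level) / 2) * 100)))
  m
}

#' Detect breakout dates
#'
#' A breakout is a time point at which a query attains maximal relative
#' popularity, RSV = 100.
#'
#' @param series a normalized \code{rsv_series}.
#' @return \code{Date} vector of breakout dates in chronological order
#'   (empty for an all-zero series).
#' @export
detect_breakout <- function(series) {
  stopifnot(inherits(series, "rsv_series"))
  if (!isTRUE(attr(series, "normalized")))
    stop("series must be normalized to the 0-100 RSV scale", call. = FALSE)
  series$date[series$value == 100]
}

#' Detect spikes (thresholded local maxima)
#'
#' A spike is a strict local maximum — a value greater than both neighbors,
#' with endpoints compared to their single neighbor — at or above the given
#' RSV threshold. A flat series has no spikes; a monotone increasing series
#' spikes only at its last point. A single-observation series counts as a
#' spike when it meets the threshold.
#'
#' @param series an \code{rsv_series}.
#' @param threshold minimum RSV value for a spike, in (0, 100\].
#' @return data.frame with columns \code{date} and \code{value}.
#' @export
detect_spikes <- function(series, threshold = 50) {
  stopifnot(inherits(series, "rsv_series"),
            length(threshold) == 1L, threshold > 0, threshold <= 100)
  v <- series$value
  n <- length(v)
  is_max <- if (n == 1L) TRUE else {
    left  <- c(TRUE, v[-1] > v[-n])   # greater than left neighbor
    right <- c(v[-n] > v[-1], TRUE)   # greater than right neighbor
    left & right
  }
  keep <- is_max & v >= threshold
  data.frame(date = series$date[keep], value = v[keep], row.names = NULL)
}

#' Align spikes with a log of real-world events
#'
#' Matches each detected spike to the nearest logged event within a day
#' tolerance; when two events are equidistant the earlier event is chosen.
#' Only date alignment is performed — no causal attribution.
#'
#' @param spikes data.frame with a \code{date} column (as from
#'   [detect_spikes()]).
#' @param events data.frame with columns \code{date} and \code{label} (and
#'   optionally \code{keyword}).
#' @param tolerance_days maximum |spike date - event date| for a match
#'   (default 0: same day only).
#' @return list with \code{matches} (spike date/value, event date/label,
#'   signed day offset), \code{unmatched_spikes}, \code{unmatched_events}.
#' @export
align_events <- function(spikes, events, tolerance_days = 0) {
  stopifnot(is.data.frame(spikes), is.data.frame(events),
            tolerance_days >= 0)
  spikes$date <- as.Date(spikes$date)
  events$date <- as.Date(events$date)
  events <- events[order(events$date), , drop = FALSE]
  hit <- integer(0)
  rows <- vector("list", nrow(spikes))
  matched <- logical(nrow(spikes))
  for (i in seq_len(nrow(spikes))) {
    if (nrow(events) == 0L) break
    d <- abs(as.numeric(events$date - spikes$date[i]))
    j <- which.min(d)  # events date-sorted, so ties resolve to the earlier
    if (d[j] <= tolerance_days) {
      matched[i] <- TRUE
      hit <- union(hit, j)
      rows[[i]] <- data.frame(
        spike_date = spikes$date[i],
        spike_value = if ("value" %in% names(spikes)) spikes$value[i] else NA_real_,
        event_date = events$date[j], event_label = events$label[j],
        offset_days = as.numeric(events$date[j] - spikes$date[i]))
    }
  }
  list(matches = do.call(rbind, rows[matched]) %||%
         data.frame(spike_date = as.Date(character()),
                    spike_value = numeric(), event_date = as.Date(character()),
                    event_label = character(), offset_days = numeric()),
       unmatched_spikes = spikes[!matched, , drop = FALSE],
       unmatched_events = events[setdiff(seq_len(nrow(events)), hit), ,
                                 drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank keywords by APC total
#'
#' Orders estimates descending by total average peak volume, breaking ties
#' by ascending keyword, and returns the first \code{n}.
#'
#' @param estimates data.frame with columns \code{keyword} and \code{total}
#'   (extra columns are carried along), or a list of \code{"apc"} objects.
#' @param n number of top keywords to return (the whole table when larger).
#' @return the ranked data.frame, first \code{n} rows.
#' @export
rank_by_apc <- function(estimates, n = 10) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, logical(1), "apc"))) {
    estimates <- do.call(rbind, lapply(estimates, function(e)
      data.frame(keyword = e$keyword, total = e$total,
                 ci_low = e$ci_low, ci_high = e$ci_high, n_obs = e$n_obs)))
  }
  stopifnot(is.data.frame(estimates),
            all(c("keyword", "total") %in% names(estimates)),
            length(n) == 1L, n >= 1)
  ord <- order(-estimates$total, tolower(estimates$keyword),
               estimates$keyword)
  out <- estimates[ord, , drop = FALSE]
  row.names(out) <- NULL
  utils::head(out, n)
}

#' Aggregate APC estimates by I-scale severity class
#'
#' Sums keyword-level APC totals within each severity class and reports the
#' class share of the grand total. Because an analyst may prefer to exclude
#' scientifically neutral terms from the denominator, the share excluding
#' the not-infodemic class is reported alongside.
#'
#' Class confidence intervals use one of two methods: \code{"variance"}
#' (default) back-solves each keyword's Gaussian variance from its CI
#' half-width and propagates the sum — \code{total +/- z * sqrt(sum var)} —
#' while \code{"sum_of_bounds"} simply sums member CI bounds. The method
#' used is recorded in the result.
#'
#' @param estimates data.frame with columns \code{keyword}, \code{total} and
#'   optionally \code{ci_low}, \code{ci_high}; or a list of \code{"apc"}
#'   objects.
#' @param scores an \code{"iscale"} object or data.frame with columns
#'   \code{moniker} and \code{score} (or \code{severity}). Every estimate
#'   keyword must have exactly one score (matched case-insensitively).
#' @param ci_method \code{"variance"} or \code{"sum_of_bounds"}.
#' @param level confidence level assumed for the member CIs (default 0.95).
#' @return an object of class \code{"severity_summary"}: a data.frame with
#'   one row per severity class (\code{total_apc}, \code{share},
#'   \code{share_excl_not_infodemic}, \code{ci_low}, \code{ci_high},
#'   \code{n_keywords}, \code{members}), with the grand total and CI method
#'   as attributes.
#' @export
aggregate_by_severity <- function(estimates, scores,
                                  ci_method = c("variance", "sum_of_bounds"),
                                  level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, logical(1), "apc"))) {
    estimates <- do.call(rbind, lapply(estimates, function(e)
      data.frame(keyword = e$keyword, total = e$total,
                 ci_low = e$ci_low, ci_high = e$ci_high)))
  }
  stopifnot(is.data.frame(estimates),
            all(c("keyword", "total") %in% names(estimates)))
  if (is.data.frame(scores) && "severity" %in% names(scores)) {
    sev <- as.character(scores$severity)
  } else {
    sev <- as.character(classify_severity(scores$score))
  }
  key <- if ("moniker" %in% names(scores)) scores$moniker else scores$keyword
  idx <- match(tolower(trimws(estimates$keyword)), tolower(trimws(key)))
  if (anyNA(idx))
    stop("keyword(s) without an I-scale score: ",
         paste(estimates$keyword[is.na(idx)], collapse = ", "),
         call. = FALSE)
  cls <- factor(sev[idx], levels = .severity_levels)

  z <- stats::qnorm((1 + level) / 2)
  has_ci <- all(c("ci_low", "ci_high") %in% names(estimates))
  totals <- as.numeric(tapply(estimates$total, cls, sum, default = 0))
  nk <- as.integer(tapply(estimates$total, cls, length, default = 0))
  members <- lapply(split(estimates$keyword, cls), as.character)
  if (has_ci) {
    if (ci_method == "variance") {
      v <- ((estimates$ci_high - estimates$ci_low) / (2 * z))^2
      vsum <- as.numeric(tapply(v, cls, sum, default = 0))
      lo <- pmax(0, totals - z * sqrt(vsum))
      hi <- totals + z * sqrt(vsum)
    } else {
      lo <- as.numeric(tapply(estimates$ci_low, cls, sum, default = 0))
      hi <- as.numeric(tapply(estimates$ci_high, cls, sum, default = 0))
    }
  } else {
    lo <- hi <- rep(NA_real_, length(totals))
  }
  grand <- sum(totals)
  if (grand <= 0) stop("grand total APC is zero", call. = FALSE)
  grand_excl <- grand - totals[1L]  # minus the not-infodemic class
  out <- data.frame(severity = .severity_levels, total_apc = totals,
                    share = totals / grand,
                    share_excl_not_infodemic =
                      if (grand_excl > 0) totals / grand_excl else NA_real_,
                    ci_low = lo, ci_high = hi, n_keywords = nk,
                    members = I(members), row.names = NULL)
  out$share_excl_not_infodemic[1L] <- NA_real_
  structure(out, grand_total = grand, ci_method = ci_method, level = level,
            class = c("severity_summary", "data.frame"))
}

#' @export
print.severity_summary <- function(x, ...) {
  cat(sprintf("Severity-weighted APC summary (grand total %g, CI method \"%s\")\n",
              attr(x, "grand_total"), attr(x, "ci_method")))
  show <- data.frame(severity = x$severity, total_apc = x$total_apc,
                     share_pct = round_half_up(100 * x$share, 1),
                     ci = sprintf("[%.0f, %.0f]", x$ci_low, x$ci_high),
                     n_keywords = x$n_keywords)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}
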