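#' Simulate raw search-count series with injected spikes
#'
#' Generates, per geography, a raw (un-normalized) daily count series built
#' from a constant baseline, Gaussian noise, and event-driven spikes with a
#' triangular kernel: a spike of magnitude m on day d contributes
#' \code{m * max(0, 1 - |t - d| / width)} on day t, so the injected argmax
#' is exactly the spike day. Values are floored at 0. The generator is a
#' pure function of its arguments: a fixed seed yields byte-identical
#' output, and the injected ground truth is returned for recovery tests.
#'
#' This emulates the shape of search-interest traces around news events
#' (flat background punctuated by sharp, short-lived peaks). It does not
#' emulate resampling jitter across repeated trend-service extractions,
#' weekly seasonality, or long-term drift.
#'
#' @param n_days number of daily observations.
#' @param baseline background count level (>= 0).
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param spikes data.frame with columns \code{day} (1-based index within
#'   the series) and \code{magnitude} (> 0); may be empty.
#' @param geos character vector of geography codes.
#' @param seed integer RNG seed.
#' @param start_date first calendar date (default the study-window start,
#'   2020-02-20).
#' @param width triangular kernel half-width in days (default 5).
#' @param keyword keyword label attached to each series.
#' @return list with \code{series} (named list of raw \code{rsv_series}-like
#'   data.frames of date/value per geo, not yet normalized) and
#'   \code{truth} (the spike table used).
#' @export
sim_raw_series <- function(n_days, baseline = 10, noise_sd = 0,
                           spikes = data.frame(day = integer(),
                                               magnitude = numeric()),
                           geos = "GLOBAL", seed = 20200220,
                           start_date = as.Date("2020-02-20"), width = 5,
                           keyword = "synthetic-query") {
  stopifnot(n_days >= 1, baseline >= 0, noise_sd >= 0, width >= 1,
            is.data.frame(spikes),
            all(c("day", "magnitude") %in% names(spikes)) ||
              nrow(spikes) == 0L)
  if (nrow(spikes) > 0L) {
    stopifnot(all(spikes$day >= 1), all(spikes$day <= n_days),
              all(spikes$magnitude > 0))
  }
  dates <- seq(as.Date(start_date), by = "day", length.out = n_days)
  t_idx <- seq_len(n_days)
  signal <- rep(baseline, n_days)
  for (k in seq_len(nrow(spikes))) {
    signal <- signal + spikes$magnitude[k] *
      pmax(0, 1 - abs(t_idx - spikes$day[k]) / width)
  }
  series <- with_seed(seed, {
    out <- lapply(geos, function(g) {
      v <- pmax(0, signal + stats::rnorm(n_days, 0, noise_sd))
      df <- data.frame(date = dates, value = v)
      structure(df, keyword = keyword, geo = g, normalized = FALSE,
                degenerate = all(v == 0),
                class = c("rsv_series", "data.frame"))
    })
    names(out) <- geos
    out
  })
  list(series = series, truth = spikes)
}

#' Simulate a multinomial hashtag count table
#'
#' Draws one multinomial sample of the given total over the supplied tag
#' probabilities; counts always sum exactly to \code{total}.
#'
#' @param probs probability vector over tags (must sum to 1 within 1e-9).
#' @param total total number of posts to distribute (> 0).
#' @param seed integer RNG seed.
#' @param tags optional tag names (defaults to \code{tag1..tagK}).
#' @param groups optional group labels per tag (defaults to "other").
#' @return data.frame with columns \code{tag}, \code{count}, \code{group}.
#' @export
sim_hashtag_table <- function(probs, total, seed = 20200220,
                              tags = NULL, groups = NULL) {
  stopifnot(is.numeric(probs), length(probs) >= 1L, all(probs >= 0),
            total > 0)
  if (abs(sum(probs) - 1) > 1e-9)
    stop("probs must sum to 1", call. = FALSE)
  if (is.null(tags)) tags <- paste0("tag", seq_along(probs))
  if (is.null(groups)) groups <- rep("other", length(probs))
  stopifnot(length(tags) == length(probs), length(groups) == length(probs))
  counts <- with_seed(seed,
    as.integer(stats::rmultinom(1, size = total, prob = probs)))
  data.frame(tag = tags, count = counts, group = groups,
             stringsAsFactors = FALSE)
}

#' Population Pearson correlation of an exponentiated Gaussian pair
#'
#' For a standard bivariate normal pair with latent correlation \code{rho},
#' the Pearson correlation of the exponentiated (lognormal) pair is, in
#' closed form, \code{(exp(rho) - 1) / (exp(1) - 1)}. Positive linear
#' rescaling leaves it unchanged, so this is the exact ground truth of the
#' country-panel generator.
#'
#' @param rho latent normal-scale correlation in (-1, 1).
#' @return the population Pearson correlation of the transformed pair.
#' @seealso [calibrate_rho()] for the inverse.
#' @export
lognormal_pearson <- function(rho) {
  stopifnot(all(abs(rho) < 1))
  (exp(rho) - 1) / (exp(1) - 1)
}

#' Latent correlation needed to realize a target Pearson correlation
#'
#' Inverts [lognormal_pearson()]: returns the normal-scale \code{rho} such
#' that the exponentiated pair has the requested Pearson correlation.
#'
#' @param target_r desired Pearson correlation of the generated panel, in
#'   \code{(lognormal_pearson(-1), 1)}.
#' @return latent correlation in (-1, 1).
#' @examples
#' calibrate_rho(0.45)
#' lognormal_pearson(calibrate_rho(0.45))  # 0.45
#' @export
calibrate_rho <- function(target_r) {
  stopifnot(all(target_r < 1), all(target_r > lognormal_pearson(-1 + 1e-12)))
  log(1 + target_r * (exp(1) - 1))
}

#' Simulate a correlated country panel
#'
#' Draws a standard bivariate normal pair with latent correlation
#' \code{rho} (Cholesky construction), exponentiates both coordinates to
#' obtain positive skewed variables — search interest and incidence are
#' both non-negative and right-skewed across countries — and scales them
#' linearly. The exponential transform changes the linear correlation away
#' from \code{rho}; the realized population Pearson correlation
#' \code{lognormal_pearson(rho)} is attached as attribute \code{true_r}
#' (the honest recovery target).
#'
#' With \code{transform = "normal"} the Gaussian pair is kept on the linear
#' scale (shifted six standard deviations into the positive range and
#' clipped at 0, an event of negligible probability), so the population
#' Pearson correlation is \code{rho} itself and the sample correlation has
#' the light-tailed normal-theory sampling distribution — the right choice
#' when a test needs the classical \code{3 (1 - r^2) / sqrt(n)} error
#' bound, which the heavy-tailed lognormal pair does not obey.
#'
#' @param n_countries number of countries (>= 3).
#' @param rho latent normal-scale correlation in (-1, 1).
#' @param interest_scale,incidence_scale positive multipliers applied after
#'   the transform.
#' @param seed integer RNG seed.
#' @param transform \code{"exp"} (lognormal marginals, default) or
#'   \code{"normal"} (Gaussian marginals shifted positive).
#' @return data.frame with columns \code{country}, \code{interest},
#'   \code{incidence}; attribute \code{true_r} holds the population
#'   Pearson correlation of the generated pair.
#' @export
sim_country_panel <- function(n_countries, rho = 0,
                              interest_scale = 50, incidence_scale = 1000,
                              seed = 20200220,
                              transform = c("exp", "normal")) {
  transform <- match.arg(transform)
  stopifnot(interest_scale > 0, incidence_scale > 0)
  if (n_countries < 3) stop("need at least 3 countries", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  z <- with_seed(seed, matrix(stats::rnorm(2 * n_countries), ncol = 2))
  # Cholesky factor of the 2x2 correlation matrix
  z2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  if (transform == "exp") {
    xi <- exp(z[, 1]); yi <- exp(z2)
    true_r <- lognormal_pearson(rho)
  } else {
    xi <- pmax(0, z[, 1] + 6); yi <- pmax(0, z2 + 6)
    true_r <- rho
  }
  panel <- data.frame(
    country = sprintf("C%03d", seq_len(n_countries)),
    interest = interest_scale * xi,
    incidence = incidence_scale * yi)
  structure(panel, true_r = true_r, latent_rho = rho,
            transform = transform)
}

#' Simulate valid rubric annotations
#'
#' Draws category points uniformly from \{0, 1, 2\} for synthetic monikers,
#' or enumerates every one of the 3^5 = 243 rubric combinations exactly
#' once (\code{exhaustive = TRUE}), in which case \code{n} is ignored.
#'
#' @param n number of annotations.
#' @param seed integer RNG seed.
#' @param exhaustive enumerate all 243 category combinations instead of
#'   sampling.
#' @return annotation data.frame acceptable to [iscale()].
#' @export
sim_annotations <- function(n, seed = 20200220, exhaustive = FALSE) {
  cats <- .iscale_categories
  if (exhaustive) {
    grid <- expand.grid(rep(list(0:2), 5), KEEP.OUT.ATTRS = FALSE)
    names(grid) <- cats
    return(data.frame(moniker = sprintf("moniker-%03d", seq_len(nrow(grid))),
                      grid, stringsAsFactors = FALSE))
  }
  stopifnot(n >= 0)
  if (n == 0L) {
    out <- data.frame(moniker = character(0))
    for (cc in cats) out[[cc]] <- integer(0)
    return(out)
  }
  pts <- with_seed(seed,
    matrix(sample(0:2, 5 * n, replace = TRUE), ncol = 5,
           dimnames = list(NULL, cats)))
  data.frame(moniker = sprintf("moniker-%03d", seq_len(n)),
             as.data.frame(pts), stringsAsFactors = FALSE)
}
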