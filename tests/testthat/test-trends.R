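test_that("normalization scales to the 0-100 integer scale with half-up rounding", {
  expect_equal(normalize_rsv(c(50, 100, 25))$value, c(50L, 100L, 25L))
  expect_equal(normalize_rsv(c(2, 4, 1))$value, c(50L, 100L, 25L))
  # hand oracle: round(100 * c(3,7,9) / 9) half-up = 33, 78, 100
  expect_equal(normalize_rsv(c(3, 7, 9))$value, c(33L, 78L, 100L))
  expect_error(normalize_rsv(c(1, -2)), "non-negative")
  z <- normalize_rsv(c(0, 0, 0))
  expect_equal(z$value, c(0L, 0L, 0L))
  expect_true(attr(z, "degenerate"))
})

test_that("normalization preserves ordering and is idempotent", {
  set.seed(42)
  for (rep in 1:25) {
    raw <- stats::rpois(sample(5:60, 1), lambda = sample(c(2, 20, 500), 1))
    if (all(raw == 0)) raw[1] <- 1
    out <- normalize_rsv(raw)$value
    expect_equal(max(out), 100L)
    # order preservation: raw_i <= raw_j implies out_i <= out_j
    ord <- order(raw)
    expect_true(all(diff(out[ord]) >= 0))
    expect_equal(normalize_rsv(out)$value, out)  # idempotent
  }
})

test_that("windowed peak extraction tiles from the first date and keeps partial windows", {
  s <- make_series(c(0, 0, 100, 0, 0, 0, 0, 0, 50, 0, 0, 0, 0, 0))
  pk <- extract_peaks(s, window_days = 7)
  expect_equal(pk$peak_value, c(100, 50))
  expect_equal(pk$window_index, c(1L, 2L))
  const <- make_series(rep(10, 15), normalized = FALSE)
  expect_true(all(extract_peaks(const, 5)$peak_value == 10))
  # trailing partial window is kept: 15 days at window 7 -> 3 windows
  expect_equal(nrow(extract_peaks(const, 7)), 3L)
})

test_that("APC reduces to the mean for one geography and adds across geographies", {
  e1 <- apc(data.frame(geo = "IT", peak_value = c(10, 10, 10)))
  expect_equal(e1$total, 10)
  expect_equal(c(e1$ci_low, e1$ci_high), c(10, 10))  # zero variance
  e2 <- apc(data.frame(geo = rep(c("IT", "DE"), each = 2),
                       peak_value = c(5, 5, 7, 7)))
  expect_equal(e2$total, 12)
  expect_equal(c(e2$ci_low, e2$ci_high), c(12, 12))
  expect_error(apc(data.frame(geo = character(), peak_value = numeric())),
               "no peak")
  # single observation per geography: CI collapses to the point estimate
  e3 <- apc(data.frame(geo = c("A", "B"), peak_value = c(3, 4)))
  expect_equal(c(e3$ci_low, e3$total, e3$ci_high), c(7, 7, 7))
})

test_that("APC over k identical geographies is k times the single-geo mean", {
  set.seed(7)
  vals <- stats::rnorm(20, 50, 5)
  single <- apc(data.frame(geo = "X", peak_value = vals))
  for (k in c(2, 5)) {
    multi <- apc(data.frame(geo = rep(paste0("g", 1:k), each = 20),
                            peak_value = rep(vals, k)))
    expect_equal(multi$total, k * single$total)
  }
})

test_that("CI half-width shrinks as 1/sqrt(n) on i.i.d. peaks", {
  mean_hw <- function(n, reps = 300) {
    hw <- replicate(reps, {
      e <- apc(data.frame(geo = "X", peak_value = stats::rnorm(n, 50, 5)))
      (e$ci_high - e$ci_low) / 2
    })
    mean(hw)
  }
  set.seed(123)
  w <- vapply(c(25, 100, 400), mean_hw, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 0.15)
  expect_equal(w[2] / w[3], 2, tolerance = 0.15)
})

test_that("breakout detection returns every date at RSV 100, in order", {
  s <- make_series(c(10, 100, 30, 100, 5))
  expect_equal(detect_breakout(s), s$date[c(2, 4)])
  expect_length(detect_breakout(make_series(c(0, 0, 0))), 0)
  raw <- make_series(c(10, 20, 30), normalized = FALSE)
  expect_error(detect_breakout(raw), "normalized")
  # breakout after normalization of any nonzero raw series is non-empty
  set.seed(9)
  for (rep in 1:10) {
    raw_v <- stats::rpois(30, 15) + 1
    expect_gt(length(detect_breakout(normalize_rsv(raw_v))), 0)
  }
})

test_that("spikes are strict local maxima at or above the threshold", {
  s <- make_series(c(10, 70, 10), normalized = FALSE)
  sp <- detect_spikes(s, threshold = 50)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$value, 70)
  expect_equal(sp$date, s$date[2])
  # monotone increasing: only the right endpoint spikes
  mono <- make_series(1:6, normalized = FALSE)
  sp2 <- detect_spikes(mono, threshold = 1)
  expect_equal(sp2$date, mono$date[6])
  # flat series has no strict local maximum
  expect_equal(nrow(detect_spikes(make_series(rep(40, 8),
                                              normalized = FALSE), 10)), 0L)
  # below-threshold maxima are dropped
  expect_equal(nrow(detect_spikes(s, threshold = 80)), 0L)
})

test_that("event alignment matches nearest event within tolerance, earlier on ties", {
  spikes <- data.frame(date = as.Date("2020-04-17"), value = 100)
  events <- data.frame(date = as.Date("2020-04-17"),
                       label = "lab-origin statement")
  al <- align_events(spikes, events, tolerance_days = 0)
  expect_equal(nrow(al$matches), 1L)
  expect_equal(al$matches$event_label, "lab-origin statement")
  # nearest event outside tolerance stays unmatched
  al2 <- align_events(data.frame(date = as.Date("2020-03-10"), value = 60),
                      data.frame(date = as.Date("2020-03-14"), label = "e"),
                      tolerance_days = 2)
  expect_equal(nrow(al2$matches), 0L)
  expect_equal(nrow(al2$unmatched_spikes), 1L)
  expect_equal(nrow(al2$unmatched_events), 1L)
  # equidistant events: the earlier one is chosen
  al3 <- align_events(
    data.frame(date = as.Date("2020-04-10"), value = 90),
    data.frame(date = as.Date(c("2020-04-11", "2020-04-09")),
               label = c("later", "earlier")),
    tolerance_days = 1)
  expect_equal(al3$matches$event_label, "earlier")
})

test_that("ranking is descending by total with alphabetical tie-break", {
  est <- table1_estimates()
  top <- rank_by_apc(est, 10)
  expect_equal(top$keyword,
               c("coronavirus", "corona", "COVID", "virus", "corona virus",
                 "coronavirus Italy", "COVID-19", "coronavirus USA",
                 "coronavirus China", "coronavirus Germany"))
  tie <- data.frame(keyword = c("zeta", "alpha"), total = c(5, 5))
  expect_equal(rank_by_apc(tie, 2)$keyword, c("alpha", "zeta"))
  expect_equal(nrow(rank_by_apc(tie, 99)), 2L)
})

test_that("severity aggregation sums member totals and shares sum to one", {
  sev <- aggregate_by_severity(table1_estimates(), table1_scores())
  tot <- sev$total_apc[match(c("moderately", "highly"), sev$severity)]
  expect_equal(tot, c(1487, 992))
  expect_equal(sum(sev$total_apc), attr(sev, "grand_total"))
  expect_equal(sum(sev$share), 1, tolerance = 1e-9)
  # a lone keyword occupies its whole class
  one <- aggregate_by_severity(
    data.frame(keyword = "solo", total = 10, ci_low = 9, ci_high = 11),
    data.frame(moniker = "solo", score = 0))
  expect_equal(one$share[one$severity == "not_infodemic"], 1)
  expect_true(all(one$share[one$severity != "not_infodemic"] == 0))
  expect_error(
    aggregate_by_severity(data.frame(keyword = "ghost", total = 1),
                          data.frame(moniker = "other", score = 1)),
    "without an I-scale score")
})

test_that("class CI methods differ as documented on the published table", {
  est <- table1_estimates()
  sc <- table1_scores()
  v <- aggregate_by_severity(est, sc, ci_method = "variance")
  b <- aggregate_by_severity(est, sc, ci_method = "sum_of_bounds")
  i <- match("moderately", v$severity)
  # sum-of-bounds reproduces the summed printed bounds exactly
  expect_equal(c(b$ci_low[i], b$ci_high[i]), c(1246 + 45 + 29 + 20,
                                               1537 + 62 + 36 + 27))
  # variance propagation gives a narrower interval than summed bounds
  expect_gt(v$ci_low[i], b$ci_low[i] - 1e-9)
  expect_lt(v$ci_high[i], b$ci_high[i] + 1e-9)
  expect_identical(attr(v, "ci_method"), "variance")
})
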