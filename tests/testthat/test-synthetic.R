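test_that("series generator is deterministic and honors its noise-free contract", {
  spikes <- data.frame(day = 10, magnitude = 90)
  a <- sim_raw_series(30, baseline = 10, noise_sd = 0, spikes = spikes,
                      geos = c("IT", "DE"), seed = 99)
  b <- sim_raw_series(30, baseline = 10, noise_sd = 0, spikes = spikes,
                      geos = c("IT", "DE"), seed = 99)
  expect_identical(a, b)
  # noiseless, no spikes -> constant at baseline
  flat <- sim_raw_series(14, baseline = 7, noise_sd = 0)$series[[1]]
  expect_true(all(flat$value == 7))
  # injected argmax sits exactly on the spike day
  s <- a$series$IT
  expect_equal(which.max(s$value), 10L)
  # noisy runs with the same seed are still byte-identical
  n1 <- sim_raw_series(30, noise_sd = 4, seed = 123)$series[[1]]$value
  n2 <- sim_raw_series(30, noise_sd = 4, seed = 123)$series[[1]]$value
  expect_identical(n1, n2)
  expect_error(sim_raw_series(10, spikes = data.frame(day = 99,
                                                      magnitude = 5)))
})

test_that("breakout of a normalized noise-free series lands on the largest injected spike", {
  spikes <- data.frame(day = c(8, 20), magnitude = c(40, 90))
  raw <- sim_raw_series(30, baseline = 5, noise_sd = 0, spikes = spikes,
                        seed = 1)$series[[1]]
  rsv <- normalize_rsv(raw$value, dates = raw$date)
  expect_equal(detect_breakout(rsv), raw$date[20])
  sp <- detect_spikes(rsv, threshold = 40)
  expect_true(raw$date[20] %in% sp$date)
  expect_true(raw$date[8] %in% sp$date)
})

test_that("hashtag generator draws a single conserved multinomial", {
  one <- sim_hashtag_table(1.0, total = 100, seed = 4)
  expect_equal(one$count, 100L)
  big <- sim_hashtag_table(rep(0.25, 4), total = 4e6, seed = 4)
  expect_equal(sum(big$count), 4000000L)
  # binomial SD oracle: each count within 3 * sqrt(N p (1-p)) of N p
  expect_true(all(abs(big$count - 1e6) <= 3 * sqrt(4e6 * 0.25 * 0.75)))
  expect_error(sim_hashtag_table(c(0.5, 0.6), 10), "sum to 1")
  expect_identical(sim_hashtag_table(c(0.3, 0.7), 1000, seed = 8)$count,
                   sim_hashtag_table(c(0.3, 0.7), 1000, seed = 8)$count)
})

test_that("country-panel generator reports an exact calibrated ground truth", {
  # closed form: corr(e^X, e^Y) = (e^rho - 1)/(e - 1); check by simulation
  rho <- 0.6
  big <- sim_country_panel(200000, rho = rho, seed = 77)
  expect_equal(panel_pearson(big)$r, lognormal_pearson(rho),
               tolerance = 0.02)
  expect_equal(attr(big, "true_r"), lognormal_pearson(rho))
  # calibration inverts the transform's correlation distortion
  expect_equal(lognormal_pearson(calibrate_rho(0.45)), 0.45)
  # null case: sample r within 3/sqrt(n) of zero
  null <- sim_country_panel(4000, rho = 0, seed = 5)
  expect_lt(abs(panel_pearson(null)$r), 3 / sqrt(4000))
  expect_error(sim_country_panel(2, rho = 0), "at least 3")
  expect_error(sim_country_panel(10, rho = 1), "rho")
})

test_that("generated interest and incidence are positively ordered for positive rho", {
  p <- sim_country_panel(500, rho = 0.6, seed = 21)
  expect_gt(stats::cor(p$interest, p$incidence, method = "spearman"), 0)
  n <- sim_country_panel(500, rho = -0.6, seed = 21)
  expect_lt(stats::cor(n$interest, n$incidence, method = "spearman"), 0)
  # the shifted-normal transform keeps rho as the exact target
  g <- sim_country_panel(2000, rho = 0.45, seed = 3, transform = "normal")
  expect_equal(attr(g, "true_r"), 0.45)
  expect_true(all(g$interest >= 0) && all(g$incidence >= 0))
})

test_that("annotation generator yields valid rubrics and an exhaustive mode", {
  expect_equal(nrow(sim_annotations(0)), 0L)
  ann <- sim_annotations(50, seed = 2)
  expect_silent(validate_annotations(ann))
  ex <- sim_annotations(exhaustive = TRUE, n = 0)
  expect_equal(nrow(ex), 243L)
  expect_equal(anyDuplicated(ex[, -1]), 0L)
  expect_equal(sort(unique(iscale(ex)$score)), 0:10)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(555)
  before <- stats::runif(1)
  set.seed(555)
  invisible(sim_country_panel(10, rho = 0.2, seed = 1))
  invisible(sim_raw_series(5, noise_sd = 1, seed = 2))
  after <- stats::runif(1)
  expect_identical(before, after)
})
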