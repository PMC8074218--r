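study_times <- c(0.5, 1, 2, 4, 8, 24)

# Build a release_series whose corrected Qt equals a supplied curve exactly.
series_from_Qt <- function(Qt, time_h = study_times) {
  s <- release_series(time_h, rep(1, length(time_h)))
  s$Qt <- Qt
  s
}

test_that("the replaced-aliquot volume correction accumulates prior draws", {
  expect_equal(volume_correction(10), 10)            # single draw
  expect_equal(volume_correction(c(10, 10)), c(10, 10.2))
  expect_equal(volume_correction(c(5, 4, 3), aliquot_ml = 0), c(5, 4, 3))
  expect_error(volume_correction(c(1, 2), aliquot_ml = 50, vessel_ml = 50),
               "smaller")
  expect_error(volume_correction(c(-1, 2)), "non-negative")
  # additive homogeneity
  C <- c(3, 7, 2, 9)
  expect_equal(volume_correction(5 * C), 5 * volume_correction(C),
               tolerance = 1e-12)
})

test_that("release_series validates its sampling grid", {
  expect_error(release_series(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(release_series(c(0, 1), c(1, 2)), "positive")
  s <- release_series(study_times, rep(2, 6))
  expect_equal(s$Qt, volume_correction(rep(2, 6)))
})

test_that("each kinetic fitter recovers its own noiseless generator", {
  t <- study_times
  cases <- list(
    list(model = "zero_order", Qt = 26.2 + 1.54 * t,
         pars = c(k0 = 1.54, Q0 = 26.2)),
    list(model = "first_order", Qt = 10^(log10(100) - 0.01 * t),
         pars = c(k1 = 0.01, Q0 = 100)),
    list(model = "higuchi", Qt = 10 * sqrt(t),
         pars = c(kH = 10, Q0 = 0)),
    list(model = "korsmeyer_peppas", Qt = 5 * t^0.43,
         pars = c(kKP = 5, n = 0.43)))
  for (cs in cases) {
    fit <- fit_release(series_from_Qt(cs$Qt), cs$model)
    expect_equal(fit$r2, 1, tolerance = 1e-10)
    got <- unlist(fit$parameters)[names(cs$pars)]
    expect_equal(got, cs$pars, tolerance = 1e-10)
  }
})

test_that("model selection ranks by linearized R2 with the generator first", {
  t <- study_times
  sel <- select_release_model(series_from_Qt(26.2 + 1.54 * t))
  expect_equal(sel[[1L]]$model, "zero_order")
  expect_true(sel[[1L]]$best_model)
  expect_equal(sel[[1L]]$r2, 1, tolerance = 1e-10)
  r2s <- vapply(sel, `[[`, numeric(1L), "r2")
  expect_true(all(diff(r2s) <= 1e-12))

  sel_h <- select_release_model(series_from_Qt(10 * sqrt(t)))
  expect_equal(sel_h[[1L]]$model, "higuchi")
})

test_that("a constant series degenerates to a flat zero-order line", {
  sel <- select_release_model(series_from_Qt(rep(8, 6)))
  expect_equal(sel[[1L]]$model, "zero_order")  # tie broken by model order
  expect_equal(sel[[1L]]$parameters$k0, 0, tolerance = 1e-12)
})

test_that("log models drop non-positive points with a warning", {
  Qt <- c(0, 2, 4, 8, 16, 20)
  s <- series_from_Qt(Qt)
  expect_warning(fit <- fit_release(s, "first_order"), "dropped")
  expect_equal(fit$n_points, 5L)
  # too few usable points is an error
  s2 <- series_from_Qt(c(0, 0, 0, 0, 5, 6))
  expect_error(suppressWarnings(fit_release(s2, "korsmeyer_peppas")),
               "fewer than 3")
})

test_that("intercept can be constrained to the origin", {
  t <- study_times
  fit <- fit_release(series_from_Qt(10 * sqrt(t)), "higuchi",
                     intercept = FALSE)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$parameters$kH, 10, tolerance = 1e-10)
})

test_that("transport classification follows the sphere thresholds", {
  expect_equal(classify_transport(0.30), "Fickian")
  expect_equal(classify_transport(0.43), "Fickian")
  expect_equal(classify_transport(0.60), "non-Fickian")
  expect_equal(classify_transport(0.85), "Case II")
  expect_equal(classify_transport(1.2), "Super Case II")
  expect_equal(classify_transport(0.55, geometry = "film"), "non-Fickian")
  expect_error(classify_transport(0), "positive")
  # the KP fit carries its own classification
  fit <- fit_release(series_from_Qt(5 * study_times^0.43),
                     "korsmeyer_peppas")
  expect_equal(fit$transport, "Fickian")
})

test_that("release CSVs round-trip into series", {
  d <- data.frame(sample = rep(c("enc", "free"), each = 3),
                  medium = "rumen", pH = 5.6,
                  time_h = rep(c(1, 2, 4), 2),
                  concentration = c(5, 6, 7, 10, 11, 12))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(d, path, row.names = FALSE)
  series <- read_release_csv(path)
  expect_length(series, 2L)
  expect_equal(series[["enc:rumen"]]$Qt, volume_correction(c(5, 6, 7)))
  expect_equal(series[["free:rumen"]]$pH, 5.6)
})
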