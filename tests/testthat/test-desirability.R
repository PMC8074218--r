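test_that("individual desirability is the Derringer-Suich ramp", {
  expect_equal(individual_desirability(20, "maximize", 10, 20), 1)
  expect_equal(individual_desirability(10, "maximize", 10, 20), 0)
  expect_equal(individual_desirability(15, "maximize", 10, 20), 0.5)
  expect_equal(individual_desirability(25, "maximize", 10, 20), 1)  # clamp
  expect_equal(individual_desirability(15, "minimize", 10, 20), 0.5)
  expect_equal(individual_desirability(10, "minimize", 10, 20), 1)
  # weight exponent bends the ramp
  expect_equal(individual_desirability(15, "maximize", 10, 20, weight = 2),
               0.25)
  expect_error(individual_desirability(1, "maximize", 5, 5), "lower")
})

test_that("overall desirability is the weighted geometric mean", {
  expect_equal(overall_desirability(c(1, 1, 1, 1)), 1)
  expect_equal(overall_desirability(c(0.5, 0, 0.9)), 0)
  expect_equal(overall_desirability(c(0.25, 1)), 0.5)
  expect_equal(overall_desirability(c(0.25, 1), weights = c(2, 1)),
               (0.25^2)^(1 / 3))
  expect_error(overall_desirability(numeric(0)), "no desirabilities")
  expect_error(overall_desirability(1.5), "\\[0, 1\\]")
  # order-invariant and monotone in each component
  set.seed(3)
  for (i in 1:10) {
    d <- stats::runif(4)
    expect_equal(overall_desirability(d), overall_desirability(rev(d)))
    d2 <- d; d2[2L] <- min(1, d2[2L] + 0.1)
    expect_gte(overall_desirability(d2), overall_desirability(d))
  }
})

test_that("single-response LC maximization lands on the (+1, -1) corner", {
  qd <- quebracho_data()
  fit <- fit_quadratic(qd$design, qd$responses$LC, "LC")
  opt <- optimize_desirability(list(LC = fit),
                               desirability_spec(c(LC = "maximize")),
                               ccd_spec = qd$spec)
  expect_equal(unname(opt$coded), c(1, -1), tolerance = 1e-6)
  expect_equal(unname(opt$actual), c(1.5, 2), tolerance = 1e-6)
  # independent brute-force oracle over the same region
  oracle <- grid_argmax(as.list(coef(fit)))
  expect_equal(unname(opt$coded), unname(oracle), tolerance = 1e-6)
})

test_that("D for a single response equals its own d surface", {
  qd <- quebracho_data()
  fit <- fit_quadratic(qd$design, qd$responses$LC, "LC")
  g <- desirability_grid(list(LC = fit),
                         desirability_spec(c(LC = "maximize")),
                         resolution = 21L)
  expect_equal(g$D, g$d_LC, tolerance = 1e-12)
})

test_that("grid maximum agrees with the optimizer and is grid-stable", {
  qd <- quebracho_data()
  fits <- lapply(c(LC = "LC", EY = "EY"), function(nm)
    fit_quadratic(qd$design, qd$responses[[nm]], nm))
  spec <- desirability_spec(c(LC = "maximize", EY = "maximize"))
  opt <- optimize_desirability(fits, spec, resolution = 101L)
  g <- desirability_grid(fits, spec, resolution = 101L)
  expect_gte(opt$D + 1e-9, max(g$D))

  coarse <- optimize_desirability(fits, spec, resolution = 51L)
  fine <- optimize_desirability(fits, spec, resolution = 101L)
  cell <- 2 / 50
  expect_true(all(abs(coarse$coded - fine$coded) <= cell + 1e-9))
})

test_that("auto anchors hit both ends of each response over the region", {
  qd <- quebracho_data()
  fit <- fit_quadratic(qd$design, qd$responses$EE, "EE")
  g <- desirability_grid(list(EE = fit),
                         desirability_spec(c(EE = "maximize")),
                         resolution = 41L)
  expect_equal(max(g$d_EE), 1, tolerance = 1e-9)
  expect_equal(min(g$d_EE), 0, tolerance = 1e-9)
})

test_that("optimizer rejects inconsistent inputs", {
  qd <- quebracho_data()
  fit <- fit_quadratic(qd$design, qd$responses$LC, "LC")
  expect_error(
    optimize_desirability(list(LC = fit),
                          desirability_spec(c(LC = "maximize", EY = "maximize"))),
    "EY")
  expect_error(desirability_spec(c(LC = "biggest")), "maximize")
  expect_error(
    optimize_desirability(list(LC = fit),
                          desirability_spec(c(LC = "maximize"),
                                            bounds = c(1, -1))),
    "lo < hi")
})
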