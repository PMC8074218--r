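test_that("fit_quadratic matches an explicit normal-equations solve", {
  set.seed(42)
  des <- ccd_design(study_spec())
  coded <- as.matrix(des[c("coded_core_shell", "coded_md_ga")])
  for (i in 1:10) {
    y <- stats::rnorm(nrow(coded), mean = 50, sd = 5)
    fit <- fit_quadratic(des, y, "sim")
    oracle <- normal_equations_fit(coded, y)
    expect_equal(coef(fit)[names(oracle)], oracle, tolerance = 1e-10)
  }
})

test_that("noiseless synthetic surfaces are recovered exactly", {
  des <- ccd_design(study_spec())
  beta <- c(b0 = 12, b1 = 5, b2 = -0.2, b11 = -0.7, b22 = 0.2, b12 = -0.1)
  coded <- as.matrix(des[c("coded_core_shell", "coded_md_ga")])
  y <- beta["b0"] + beta["b1"] * coded[, 1] + beta["b2"] * coded[, 2] +
    beta["b11"] * coded[, 1]^2 + beta["b22"] * coded[, 2]^2 +
    beta["b12"] * coded[, 1] * coded[, 2]
  fit <- fit_quadratic(des, y, "exact")
  expect_equal(coef(fit)[names(beta)], beta, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("a constant response gives the constant intercept only", {
  des <- ccd_design(study_spec())
  fit <- fit_quadratic(des, rep(7.5, nrow(des)), "const")
  expect_equal(unname(coef(fit)["b0"]), 7.5, tolerance = 1e-12)
  expect_lt(max(abs(coef(fit)[-1L])), 1e-12)
})

test_that("the study LC fit reproduces the published coefficients", {
  qd <- quebracho_data()
  fit <- fit_quadratic(qd$design, qd$responses$LC, "LC")
  expect_equal(unname(coef(fit)["b0"]), 12.292, tolerance = 0.02)
  expect_equal(unname(coef(fit)["b1"]), 5.193, tolerance = 0.02 / 5.193)
  # prediction at the center is the intercept
  expect_equal(unname(predict(fit, c(0, 0))), unname(coef(fit)["b0"]))
  # prediction at a corner equals direct polynomial arithmetic
  b <- coef(fit)
  by_hand <- b[["b0"]] + b[["b1"]] - b[["b2"]] + b[["b11"]] + b[["b22"]] -
    b[["b12"]]
  expect_equal(unname(predict(fit, c(1, -1))), by_hand, tolerance = 1e-12)
})

test_that("adjusted R2 satisfies its defining identity", {
  qd <- quebracho_data()
  for (resp in c("LC", "EE", "EY", "TC")) {
    fit <- fit_quadratic(qd$design, qd$responses[[resp]], resp)
    N <- length(fit$y); p <- length(coef(fit))
    expect_equal(fit$r2_adj, 1 - (1 - fit$r2) * (N - 1) / (N - p),
                 tolerance = 1e-12)
    expect_lte(fit$r2_adj, fit$r2)
  }
})

test_that("lack-of-fit ANOVA decomposes the residual sum of squares", {
  qd <- quebracho_data()
  fit <- fit_quadratic(qd$design, qd$responses$LC, "LC")
  an <- fit$anova
  ss <- function(src) an$ss[an$source == src]
  df <- function(src) an$df[an$source == src]
  expect_equal(df("pure_error"), 4L)  # 5 center replicates
  expect_equal(ss("residual"), ss("lack_of_fit") + ss("pure_error"),
               tolerance = 1e-10)
  expect_equal(df("residual"), df("lack_of_fit") + df("pure_error"))
  expect_true(all(an$ss >= -1e-12))

  # noiseless quadratic data: nothing left for lack of fit
  coded <- as.matrix(qd$design[c("coded_core_shell", "coded_md_ga")])
  y0 <- 3 + 2 * coded[, 1] - coded[, 2]^2
  fit0 <- fit_quadratic(qd$design, y0, "exact")
  expect_lt(fit0$anova$ss[fit0$anova$source == "lack_of_fit"], 1e-18)
})

test_that("lack-of-fit is refused without replicated points", {
  spec <- study_spec()
  des <- ccd_design(ccd_spec(spec$factors, n_center = 1L))
  fit <- fit_quadratic(des, seq_len(nrow(des)) + 0.5, "y")
  expect_null(fit$anova)
  expect_error(lack_of_fit_anova(fit), "unavailable")
})

test_that("rank-deficient designs fail with the aliased terms named", {
  des <- data.frame(coded_a = c(-1, 1, -1, 1, 0, 0, 0),
                    coded_b = c(-1, 1, -1, 1, 0, 0, 0))  # b aliases a
  expect_error(fit_quadratic(des, stats::rnorm(7), "y"), "aliased")
})

test_that("significance marks follow the conventional thresholds", {
  expect_equal(unname(significance_marks(c(0.0005, 0.005, 0.03, 0.2))),
               c("***", "**", "*", ""))
  expect_error(significance_marks(1.2), "\\[0, 1\\]")
})

test_that("surface grids expose the fitted landscape", {
  qd <- quebracho_data()
  des <- qd$design
  const <- fit_quadratic(des, rep(2, nrow(des)), "const")
  g <- surface_grid(const, c(-1, 1), resolution = 2L)
  expect_equal(nrow(g), 4L)
  expect_equal(unname(g$predicted), rep(2, 4L), tolerance = 1e-12)

  lc <- fit_quadratic(des, qd$responses$LC, "LC")
  glc <- surface_grid(lc, c(-1, 1), resolution = 41L)
  top <- glc[which.max(glc$predicted), ]
  expect_equal(c(top$core_shell, top$md_ga), c(1, -1))

  # corrected-EY surface rises with the MD:GA axis at the core center
  ey <- fit_quadratic(des, qd$responses$EY, "EY")
  gey <- surface_grid(ey, c(-1, 1), resolution = 21L)
  slice <- gey[abs(gey$core_shell) < 1e-9, ]
  expect_true(all(diff(slice$predicted[order(slice$md_ga)]) > 0))
})
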