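#' @importFrom stats lm coef pf pt predict setNames var optim rnorm
NULL

# Term labels for the full second-order model in k coded factors:
# intercept, linear, pure quadratic, then pairwise interactions.
quadratic_terms <- function(k) {
  lab <- c("b0", paste0("b", seq_len(k)), paste0("b", seq_len(k), seq_len(k)))
  if (k >= 2L) {
    pairs <- utils::combn(k, 2L)
    lab <- c(lab, paste0("b", pairs[1L, ], pairs[2L, ]))
  }
  lab
}

# Model matrix of the full quadratic in coded factors (rows = design points).
quadratic_model_matrix <- function(coded) {
  coded <- as.matrix(coded)
  k <- ncol(coded)
  X <- cbind(1, coded, coded^2)
  if (k >= 2L) {
    pairs <- utils::combn(k, 2L)
    inter <- sapply(seq_len(ncol(pairs)), function(p)
      coded[, pairs[1L, p]] * coded[, pairs[2L, p]])
    X <- cbind(X, inter)
  }
  colnames(X) <- quadratic_terms(k)
  X
}

#' Fit the full second-order response-surface model
#'
#' Ordinary least squares of a response on the coded factors of a design:
#' intercept, linear, pure quadratic and pairwise interaction terms
#' (`1 + 2k + k(k-1)/2` coefficients). Coefficients are reported on the
#' coded scale; p-values are two-sided t tests with residual degrees of
#' freedom, uncorrected. The full model is always reported — no terms are
#' dropped for non-significance.
#'
#' @param design A `ccd_design` (or any data frame with `coded_*` columns).
#' @param y Response values, one per run, or the name of a column in
#'   `design`.
#' @param response_name Label for reports (defaults to the column name or
#'   the expression passed as `y`).
#' @return An object of class `quadratic_fit`: coefficients, standard
#'   errors, t and p values, significance marks, `r2`, `r2_adj`, the
#'   lack-of-fit ANOVA (when the design has replicated points), and the
#'   underlying `lm` fit.
#' @examples
#' qd <- quebracho_data()
#' fit <- fit_quadratic(qd$design, qd$responses$LC, "LC")
#' coef(fit)["b1"]  # 5.19
#' @export
fit_quadratic <- function(design, y, response_name = NULL) {
  coded <- coded_matrix(design)
  k <- ncol(coded)
  if (is.character(y) && length(y) == 1L) {
    if (is.null(response_name)) response_name <- y
    y <- design[[y]]
    if (is.null(y)) stop("response column not found in design", call. = FALSE)
  }
  if (is.null(response_name)) response_name <- deparse(substitute(y))
  y <- as.numeric(y)
  if (length(y) != nrow(coded))
    stop("response length ", length(y), " != ", nrow(coded), " runs",
         call. = FALSE)
  p <- 1L + 2L * k + k * (k - 1L) %/% 2L
  if (length(y) < p)
    stop("need at least ", p, " runs to fit ", p, " coefficients",
         call. = FALSE)
  X <- quadratic_model_matrix(coded)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("model matrix is rank-deficient; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(y = y, X[, -1L, drop = FALSE], check.names = FALSE)
  model <- lm(y ~ ., data = dat)
  # noiseless round-trip data legitimately hit summary.lm's perfect-fit
  # warning; everything reported here is still well defined
  sm <- withCallingHandlers(summary(model), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  est <- setNames(sm$coefficients[, 1L], colnames(X))
  se <- setNames(sm$coefficients[, 2L], colnames(X))
  tv <- setNames(sm$coefficients[, 3L], colnames(X))
  pv <- setNames(sm$coefficients[, 4L], colnames(X))

  fit <- structure(list(
    response_name = response_name,
    k = k, factor_names = colnames(coded),
    coefficients = est, standard_errors = se,
    t_values = tv, p_values = pv,
    marks = significance_marks(pv),
    r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
    sigma = sm$sigma, df_residual = model$df.residual,
    design_coded = coded, y = y, model = model),
    class = "quadratic_fit")
  fit$anova <- tryCatch(lack_of_fit_anova(fit),
                        error = function(e) NULL)
  fit
}

#' @export
coef.quadratic_fit <- function(object, ...) object$coefficients

#' Predict from a fitted response surface
#'
#' @param object A `quadratic_fit`.
#' @param newdata Coded point: numeric vector of length `k`, or a matrix /
#'   data frame with `k` columns.
#' @param ... Unused.
#' @return Predicted response value(s).
#' @export
predict.quadratic_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.matrix(newdata)) {
    if (length(newdata) != object$k)
      stop("coded point has length ", length(newdata),
           "; model has ", object$k, " factors", call. = FALSE)
    newdata <- matrix(newdata, nrow = 1L)
  }
  if (ncol(newdata) != object$k)
    stop("coded points have ", ncol(newdata), " columns; model has ",
         object$k, " factors", call. = FALSE)
  drop(quadratic_model_matrix(newdata) %*% object$coefficients)
}

#' Lack-of-fit ANOVA from replicated design points
#'
#' Splits the residual sum of squares into pure error (within groups of
#' runs at identical coded settings — the center replicates in a standard
#' CCD) and lack of fit, with an F test of lack of fit against pure error.
#'
#' @param fit A `quadratic_fit`.
#' @return An object of class `anova_table`: a data frame with rows for
#'   model, residual, lack-of-fit and pure-error (sum of squares, df, mean
#'   square, F, p).
#' @export
lack_of_fit_anova <- function(fit) {
  stopifnot(inherits(fit, "quadratic_fit"))
  coded <- fit$design_coded
  y <- fit$y
  key <- apply(coded, 1L, paste, collapse = "\r")
  groups <- split(y, key)
  n_distinct <- length(groups)
  N <- length(y)
  if (N - n_distinct < 1L)
    stop("no replicated design points: lack-of-fit ANOVA unavailable",
         call. = FALSE)
  p <- length(fit$coefficients)

  rss <- sum(fit$model$residuals^2)
  tss <- sum((y - mean(y))^2)
  ss_model <- tss - rss
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  ss_lof <- rss - ss_pe

  df_model <- p - 1L
  df_resid <- N - p
  df_pe <- N - n_distinct
  df_lof <- n_distinct - p

  ms_model <- ss_model / df_model
  ms_resid <- rss / df_resid
  ms_pe <- ss_pe / df_pe
  ms_lof <- if (df_lof > 0L) ss_lof / df_lof else NA_real_

  f_model <- ms_model / ms_resid
  p_model <- pf(f_model, df_model, df_resid, lower.tail = FALSE)
  if (df_lof > 0L && ms_pe > 0) {
    f_lof <- ms_lof / ms_pe
    p_lof <- pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
  } else {
    f_lof <- NA_real_
    p_lof <- NA_real_
  }

  tab <- data.frame(
    source = c("model", "residual", "lack_of_fit", "pure_error"),
    ss = c(ss_model, rss, ss_lof, ss_pe),
    df = c(df_model, df_resid, df_lof, df_pe),
    ms = c(ms_model, ms_resid, ms_lof, ms_pe),
    F = c(f_model, NA, f_lof, NA),
    p = c(p_model, NA, p_lof, NA))
  structure(tab, class = c("anova_table", "data.frame"))
}

#' Significance marks for p-values
#'
#' The conventional starring: `***` for p < 0.001, `**` for p < 0.01,
#' `*` for p < 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of marks.
#' @export
significance_marks <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
  out[is.na(p)] <- ""
  setNames(out, names(p))
}

#' Evaluate a fitted surface on a regular grid
#'
#' @param fit A `quadratic_fit`.
#' @param bounds Either a numeric vector `c(lo, hi)` applied to every coded
#'   factor, or a list of per-factor bounds.
#' @param resolution Grid points per axis.
#' @return Data frame with one coded column per factor plus `predicted`.
#' @export
surface_grid <- function(fit, bounds = c(-1, 1), resolution = 41L) {
  stopifnot(inherits(fit, "quadratic_fit"))
  if (!is.list(bounds)) bounds <- rep(list(bounds), fit$k)
  if (length(bounds) != fit$k)
    stop("need bounds for each of ", fit$k, " factors", call. = FALSE)
  axes <- lapply(bounds, function(b) {
    if (any(!is.finite(b))) stop("bounds must be finite", call. = FALSE)
    seq(b[1L], b[2L], length.out = resolution)
  })
  names(axes) <- fit$factor_names
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  grid$predicted <- predict(fit, as.matrix(grid))
  grid
}

#' @export
print.quadratic_fit <- function(x, digits = 3, ...) {
  cat("Second-order response-surface fit:", x$response_name, "\n")
  tab <- data.frame(
    estimate = round(x$coefficients, digits),
    std_error = round(x$standard_errors, digits),
    t = round(x$t_values, 2),
    p = signif(x$p_values, 2),
    sig = x$marks)
  print(tab)
  cat(sprintf("R2 %.3f  adjusted R2 %.3f  (n = %d)\n",
              x$r2, x$r2_adj, length(x$y)))
  if (!is.null(x$anova)) {
    lof <- x$anova[x$anova$source == "lack_of_fit", ]
    if (is.finite(lof$p))
      cat(sprintf("lack-of-fit p = %.3f\n", lof$p))
  }
  invisible(x)
}
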