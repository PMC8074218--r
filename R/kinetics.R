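release_models <- c("zero_order", "first_order", "higuchi",
                    "korsmeyer_peppas")

#' Cumulative sampling-volume correction
#'
#' In a dissolution test where each drawn aliquot is replaced with fresh
#' medium, the analyte removed in earlier draws must be added back to the
#' later measurements. The standard replaced-aliquot correction is
#' `Qt_i = C_i + (v/V) * sum_{j<i} C_j`, with `v` the aliquot volume and
#' `V` the vessel volume.
#'
#' @param concentration Measured concentration at each draw, in sampling
#'   order (>= 0).
#' @param aliquot_ml Aliquot volume `v` (mL); default 1.
#' @param vessel_ml Vessel volume `V` (mL); default 50. Must exceed `v`.
#' @return Corrected cumulative release `Qt`, same length and units as
#'   `concentration`.
#' @examples
#' volume_correction(c(10, 10), aliquot_ml = 1, vessel_ml = 50)  # 10, 10.2
#' @export
volume_correction <- function(concentration, aliquot_ml = 1,
                              vessel_ml = 50) {
  if (aliquot_ml >= vessel_ml)
    stop("aliquot volume must be smaller than vessel volume", call. = FALSE)
  if (aliquot_ml < 0) stop("aliquot volume must be >= 0", call. = FALSE)
  if (any(concentration < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  n <- length(concentration)
  prior <- c(0, cumsum(concentration))[seq_len(n)]
  concentration + (aliquot_ml / vessel_ml) * prior
}

#' Construct a release time series
#'
#' Bundles the sampling times, measured aliquot concentrations and vessel
#' geometry of an in-vitro release experiment, and applies the cumulative
#' sampling-volume correction.
#'
#' @param time_h Sampling times in hours, strictly increasing and positive.
#' @param concentration Measured concentration at each draw.
#' @param aliquot_ml,vessel_ml Aliquot and vessel volumes (mL).
#' @param sample Free-text sample label (e.g. "encapsulated").
#' @param medium Elution-medium label (e.g. "rumen").
#' @param pH Medium pH (informational).
#' @return An object of class `release_series` with the corrected
#'   cumulative release in `$Qt`.
#' @export
release_series <- function(time_h, concentration, aliquot_ml = 1,
                           vessel_ml = 50, sample = "", medium = "",
                           pH = NA_real_) {
  if (length(time_h) != length(concentration))
    stop("time and concentration lengths differ", call. = FALSE)
  if (any(time_h <= 0) || any(diff(time_h) <= 0))
    stop("times must be positive and strictly increasing", call. = FALSE)
  Qt <- volume_correction(concentration, aliquot_ml, vessel_ml)
  structure(list(time_h = time_h, concentration = concentration,
                 Qt = Qt, aliquot_ml = aliquot_ml, vessel_ml = vessel_ml,
                 sample = sample, medium = medium, pH = pH),
            class = "release_series")
}

#' @export
print.release_series <- function(x, ...) {
  cat("Release series", if (nzchar(x$sample)) paste0("'", x$sample, "'"),
      if (nzchar(x$medium)) paste0("in ", x$medium,
                                   if (is.finite(x$pH))
                                     sprintf(" (pH %.1f)", x$pH)), "\n")
  print(data.frame(time_h = x$time_h, concentration = x$concentration,
                   Qt = round(x$Qt, 4)))
  invisible(x)
}

# Linearization of each kinetic law: transform (x, y), then a straight-line
# fit y = slope * x + intercept. Base-10 logs where the printed model uses
# log; the power-law exponent is log-base invariant.
kinetic_transform <- function(model, time_h, Qt) {
  switch(model,
    zero_order = list(x = time_h, y = Qt, keep = rep(TRUE, length(Qt))),
    first_order = list(x = time_h, y = log10(Qt), keep = Qt > 0),
    higuchi = list(x = sqrt(time_h), y = Qt, keep = rep(TRUE, length(Qt))),
    korsmeyer_peppas = list(x = log10(time_h), y = log10(Qt),
                            keep = Qt > 0 & time_h > 0),
    stop("unknown model '", model, "'", call. = FALSE))
}

#' Fit one release-kinetics model
#'
#' Linearized least-squares fit of a cumulative-release curve to one of the
#' four classical laws: zero order (`Qt = Q0 + k0 t`), first order
#' (`log Qt = log Q0 - k1 t`, base-10), Higuchi (`Qt = Q0 + kH sqrt(t)`),
#' or Korsmeyer–Peppas (`Qt = kKP t^n`, fitted as `log Qt` on `log t`).
#' Points with non-positive `Qt` are dropped, with a warning, under the log
#' models.
#'
#' @param series A `release_series`, or a list with `time_h` and `Qt`.
#' @param model One of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"korsmeyer_peppas"`.
#' @param intercept Fit a free intercept (default). With `FALSE`, the
#'   zero-order and Higuchi lines are forced through the origin (`Q0 = 0`);
#'   ignored for the log-linear models, whose intercept is a model
#'   parameter.
#' @return An object of class `kinetic_fit`: `slope`, `intercept`, `r2` of
#'   the linearized fit, and model parameters on the natural scale
#'   (`k0`/`k1`/`kH`/`kKP`, `n`, `Q0`). For the first-order law the rate
#'   constant is reported as `k1 = -slope`, matching its printed form; the
#'   signed slope is always retained.
#' @examples
#' s <- release_series(c(0.5, 1, 2, 4, 8, 24), rep(1, 6))
#' s$Qt <- 10 * sqrt(s$time_h)  # exact Higuchi curve
#' fit_release(s, "higuchi")$parameters$kH  # 10
#' @export
fit_release <- function(series, model = release_models,
                        intercept = TRUE) {
  model <- match.arg(model)
  time_h <- series$time_h
  Qt <- series$Qt
  tr <- kinetic_transform(model, time_h, Qt)
  dropped <- sum(!tr$keep)
  if (dropped > 0L)
    warning(dropped, " non-positive point(s) dropped for ", model,
            call. = FALSE)
  x <- tr$x[tr$keep]; y <- tr$y[tr$keep]
  if (length(x) < 3L)
    stop("fewer than 3 usable points for ", model, call. = FALSE)
  free_int <- intercept || model %in% c("first_order", "korsmeyer_peppas")
  fit <- if (free_int) lm(y ~ x) else lm(y ~ x - 1)
  slope <- unname(coef(fit)[["x"]])
  b0 <- if (free_int) unname(coef(fit)[["(Intercept)"]]) else 0
  # R2 of the straight-line fit, computed directly; a zero-variance series
  # has no explainable variation and is reported as NA
  tss <- if (free_int) sum((y - mean(y))^2) else sum(y^2)
  rss <- sum(fit$residuals^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  params <- switch(model,
    zero_order = list(k0 = slope, Q0 = b0),
    first_order = list(k1 = -slope, Q0 = 10^b0),
    higuchi = list(kH = slope, Q0 = b0),
    korsmeyer_peppas = list(kKP = 10^b0, n = slope))

  out <- structure(list(model = model, slope = slope, intercept = b0,
                        r2 = r2, parameters = params,
                        n_points = length(x), n_dropped = dropped,
                        free_intercept = free_int),
                   class = "kinetic_fit")
  if (model == "korsmeyer_peppas" && is.finite(slope) && slope > 0)
    out$transport <- classify_transport(slope)
  out
}

#' @export
print.kinetic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s: y = %.*gx %+.*g,  R2 = %.4f\n", x$model,
              digits, x$slope, digits, x$intercept, x$r2))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$parameters),
                    unlist(x$parameters)), collapse = ", "), "\n")
  if (!is.null(x$transport)) cat("  transport:", x$transport, "\n")
  invisible(x)
}

#' Fit all release models and rank them
#'
#' Fits the four kinetic laws and ranks them by the R-squared of their
#' linearized fits (descending); ties are broken by the fixed model order
#' zero order, first order, Higuchi, Korsmeyer–Peppas (all four laws have
#' two parameters in their fitted form). Degenerate fits (e.g. a constant
#' series under the power law) are retained with their diagnostics rather
#' than dropped.
#'
#' @param series A `release_series`.
#' @param models Subset of models to fit (default all four).
#' @param intercept Passed to [fit_release()].
#' @return An object of class `release_selection`: list of `kinetic_fit`s
#'   in rank order; the first is flagged `best_model`.
#' @export
select_release_model <- function(series, models = release_models,
                                 intercept = TRUE) {
  models <- match.arg(models, several.ok = TRUE)
  fits <- lapply(models, function(m)
    tryCatch(suppressWarnings(fit_release(series, m, intercept)),
             error = function(e) NULL))
  names(fits) <- models
  ok <- !vapply(fits, is.null, logical(1L))
  if (sum(ok) < 2L)
    stop("series fittable by fewer than 2 models", call. = FALSE)
  fits <- fits[ok]
  r2 <- vapply(fits, function(f)
    if (is.finite(f$r2)) f$r2 else -Inf, numeric(1L))
  ord <- order(-r2, match(names(fits), release_models))
  fits <- fits[ord]
  for (i in seq_along(fits)) fits[[i]]$best_model <- i == 1L
  structure(fits, class = "release_selection")
}

#' @export
print.release_selection <- function(x, ...) {
  cat("Release-model ranking (by linearized R2):\n")
  for (f in x)
    cat(sprintf("  %s%-18s R2 = %.4f\n",
                if (isTRUE(f$best_model)) "* " else "  ", f$model, f$r2))
  invisible(x)
}

#' Classify the release transport mechanism
#'
#' Classification from the Korsmeyer–Peppas release exponent `n`. For
#' spherical particles the conventional thresholds are: `n <= 0.43` Fickian
#' diffusion, `0.43 < n < 0.85` anomalous (non-Fickian) transport,
#' `n ~ 0.85` Case II (polymer-relaxation controlled), `n > 0.85` Super
#' Case II. Thin films use 0.5 and 1.0 in place of 0.43 and 0.85.
#'
#' @param n Release exponent (> 0).
#' @param geometry `"sphere"` (default) or `"film"`.
#' @param tol Half-width of the band around the Case II threshold treated
#'   as Case II.
#' @return One of `"Fickian"`, `"non-Fickian"`, `"Case II"`,
#'   `"Super Case II"`.
#' @examples
#' classify_transport(0.30)  # Fickian
#' classify_transport(1.2)   # Super Case II
#' @export
classify_transport <- function(n, geometry = c("sphere", "film"),
                               tol = 0.01) {
  geometry <- match.arg(geometry)
  if (any(n <= 0)) stop("release exponent must be positive", call. = FALSE)
  lims <- switch(geometry, sphere = c(0.43, 0.85), film = c(0.5, 1.0))
  classify1 <- function(ni) {
    if (abs(ni - lims[2L]) <= tol) "Case II"
    else if (ni <= lims[1L]) "Fickian"
    else if (ni < lims[2L]) "non-Fickian"
    else "Super Case II"
  }
  vapply(n, classify1, character(1L))
}

#' Read release series from CSV
#'
#' Expects columns `sample`, `medium`, `pH`, `time_h`, `concentration`;
#' one series is built per `sample` x `medium` combination.
#'
#' @param path CSV path.
#' @param aliquot_ml,vessel_ml Volumes passed to [release_series()].
#' @return Named list of `release_series`.
#' @export
read_release_csv <- function(path, aliquot_ml = 1, vessel_ml = 50) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "medium", "time_h", "concentration")
  if (!all(req %in% names(d)))
    stop("release CSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  key <- paste(d$sample, d$medium, sep = ":")
  lapply(split(d, key), function(g) {
    g <- g[order(g$time_h), ]
    release_series(g$time_h, g$concentration, aliquot_ml, vessel_ml,
                   sample = g$sample[1L], medium = g$medium[1L],
                   pH = if ("pH" %in% names(g)) g$pH[1L] else NA_real_)
  })
}
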