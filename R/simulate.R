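# Run an expression under a fixed seed without disturbing the caller's RNG
# stream, so the simulators are pure functions of their spec.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a quadratic-surface simulation
#'
#' Defines the data-generating model behind the response-surface analysis:
#' a full second-order polynomial on the coded factors of a design, plus
#' additive Gaussian noise, optionally with replicate measurements per run.
#'
#' @param beta Named coefficient vector on the coded scale, names as in
#'   [fit_quadratic()] (`b0`, `b1`, ..., `b11`, ..., `b12`, ...); missing
#'   terms default to 0.
#' @param sigma Noise standard deviation (>= 0), response units.
#' @param design A `ccd_design` (or `ccd_spec`, which is expanded).
#' @param replicates Measurements per run (>= 1).
#' @param seed Integer seed fixing all draws.
#' @return An object of class `surface_sim_spec`.
#' @export
surface_sim_spec <- function(beta, sigma, design, replicates = 1L,
                             seed = 1L) {
  if (inherits(design, "ccd_spec")) design <- ccd_design(design)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  k <- ncol(coded_matrix(design))
  full <- setNames(numeric(length(quadratic_terms(k))), quadratic_terms(k))
  unknown <- setdiff(names(beta), names(full))
  if (length(unknown))
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  full[names(beta)] <- beta
  structure(list(beta = full, sigma = sigma, design = design,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "surface_sim_spec")
}

#' Simulate responses from a quadratic surface
#'
#' Evaluates the specified polynomial at every design point and adds
#' independent `N(0, sigma^2)` noise; replicates share the design point.
#' Two calls with the same spec return identical tables.
#'
#' @param spec A `surface_sim_spec`.
#' @return Data frame with `run_id`, `replicate`, the design's coded
#'   columns, `y_true` (noiseless surface) and `y` (observed).
#' @examples
#' sp <- surface_sim_spec(c(b0 = 10, b1 = 2), sigma = 0,
#'                        design = quebracho_spec(), seed = 7)
#' sim <- simulate_surface(sp)
#' all.equal(sim$y, sim$y_true)
#' @export
simulate_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_sim_spec"))
  coded <- coded_matrix(spec$design)
  mu <- drop(quadratic_model_matrix(coded) %*% spec$beta)
  n <- nrow(coded)
  idx <- rep(seq_len(n), times = spec$replicates)
  out <- data.frame(run_id = spec$design$run_id[idx],
                    replicate = rep(seq_len(spec$replicates), each = n))
  for (j in seq_len(ncol(coded)))
    out[[paste0("coded_", colnames(coded)[j])]] <- coded[idx, j]
  out$y_true <- mu[idx]
  out$y <- out$y_true +
    with_seed(spec$seed, rnorm(length(idx), 0, spec$sigma))
  out
}

#' Specify a release-curve simulation
#'
#' Emulates the in-vitro sampling scheme of a replaced-aliquot dissolution
#' test: a true cumulative-release curve from one of the four kinetic laws,
#' inverted through the volume correction to per-draw concentrations, with
#' multiplicative Gaussian measurement noise on each draw.
#'
#' @param model One of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"korsmeyer_peppas"`.
#' @param parameters Named list of true parameters: `k0`/`k1`/`kH`/`kKP`,
#'   `n`, and `Q0` where the law uses it (default `Q0 = 0`; the first-order
#'   law needs `Q0 > 0`).
#' @param time_h Sampling grid in hours (default the study's
#'   0.5, 1, 2, 4, 8, 24).
#' @param sigma Multiplicative noise SD as a fraction (e.g. 0.05 = 5%).
#' @param aliquot_ml,vessel_ml Sampling volumes (defaults 1 and 50 mL).
#' @param seed Integer seed.
#' @return An object of class `release_sim_spec`.
#' @export
release_sim_spec <- function(model = release_models, parameters,
                             time_h = c(0.5, 1, 2, 4, 8, 24),
                             sigma = 0, aliquot_ml = 1, vessel_ml = 50,
                             seed = 1L) {
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (any(time_h <= 0) || any(diff(time_h) <= 0))
    stop("times must be positive and strictly increasing", call. = FALSE)
  structure(list(model = model, parameters = parameters, time_h = time_h,
                 sigma = sigma, aliquot_ml = aliquot_ml,
                 vessel_ml = vessel_ml, seed = as.integer(seed)),
            class = "release_sim_spec")
}

# True cumulative release under each law.
kinetic_law <- function(model, parameters, time_h) {
  p <- parameters
  q0 <- if (is.null(p$Q0)) 0 else p$Q0
  switch(model,
    zero_order = q0 + p$k0 * time_h,
    first_order = {
      if (q0 <= 0) stop("first-order law needs Q0 > 0", call. = FALSE)
      10^(log10(q0) - p$k1 * time_h)
    },
    higuchi = q0 + p$kH * sqrt(time_h),
    korsmeyer_peppas = p$kKP * time_h^p$n)
}

# Inverse of volume_correction: per-draw concentrations that reproduce Qt.
invert_volume_correction <- function(Qt, aliquot_ml, vessel_ml) {
  r <- aliquot_ml / vessel_ml
  C <- numeric(length(Qt))
  acc <- 0
  for (i in seq_along(Qt)) {
    C[i] <- Qt[i] - r * acc
    acc <- acc + C[i]
  }
  C
}

#' Simulate a release series
#'
#' @param spec A `release_sim_spec`.
#' @return A `release_series` whose `concentration` carries the noisy
#'   per-draw measurements and whose `Qt` is the recomputed corrected
#'   cumulative release; the noiseless truth is attached as attributes
#'   `"Qt_true"` and `"concentration_true"`.
#' @examples
#' sp <- release_sim_spec("higuchi", list(kH = 10), sigma = 0)
#' s <- simulate_release(sp)
#' max(abs(s$Qt - 10 * sqrt(s$time_h)))  # ~0
#' @export
simulate_release <- function(spec) {
  stopifnot(inherits(spec, "release_sim_spec"))
  Qt_true <- kinetic_law(spec$model, spec$parameters, spec$time_h)
  C_true <- invert_volume_correction(Qt_true, spec$aliquot_ml,
                                     spec$vessel_ml)
  if (any(C_true < 0))
    stop("parameters imply negative draw concentrations", call. = FALSE)
  C <- C_true * (1 + with_seed(spec$seed,
                               rnorm(length(C_true), 0, spec$sigma)))
  C <- pmax(C, 0)
  s <- release_series(spec$time_h, C, spec$aliquot_ml, spec$vessel_ml,
                      sample = paste0("simulated_", spec$model))
  attr(s, "Qt_true") <- Qt_true
  attr(s, "concentration_true") <- C_true
  s
}
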