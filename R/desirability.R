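#' Individual desirability transform
#'
#' Derringer–Suich transform of a response value onto \[0, 1\]. For a
#' maximized response: 0 at or below `lower`, 1 at or above `upper`, and
#' `((y - lower)/(upper - lower))^weight` between. Minimization mirrors
#' this; `goal = "target"` rises to 1 at `target` and falls back to 0 at the
#' anchors on either side.
#'
#' @param y Response value(s).
#' @param goal One of `"maximize"`, `"minimize"`, `"target"`.
#' @param lower,upper Anchor values, `lower < upper`.
#' @param weight Positive exponent; larger values demand the response be
#'   closer to the ideal before the desirability rises.
#' @param target Target value for `goal = "target"`.
#' @return Desirability in \[0, 1\], same length as `y`.
#' @examples
#' individual_desirability(15, "maximize", lower = 10, upper = 20)  # 0.5
#' @export
individual_desirability <- function(y, goal = c("maximize", "minimize",
                                                "target"),
                                    lower, upper, weight = 1,
                                    target = NULL) {
  goal <- match.arg(goal)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("desirability anchors need lower < upper", call. = FALSE)
  if (weight <= 0) stop("weight must be positive", call. = FALSE)
  scale01 <- function(v) pmin(1, pmax(0, v))
  d <- switch(goal,
    maximize = scale01((y - lower) / (upper - lower))^weight,
    minimize = scale01((upper - y) / (upper - lower))^weight,
    target = {
      if (is.null(target) || target <= lower || target >= upper)
        stop("target goal needs lower < target < upper", call. = FALSE)
      ifelse(y <= target,
             scale01((y - lower) / (target - lower))^weight,
             scale01((upper - y) / (upper - target))^weight)
    })
  as.numeric(d)
}

#' Overall desirability
#'
#' Weighted geometric mean of individual desirabilities,
#' `D = (prod d_i^w_i)^(1/sum w_i)`. Zero whenever any component is zero:
#' one unacceptable response vetoes the compromise.
#'
#' @param d Vector of individual desirabilities in \[0, 1\].
#' @param weights Positive importance weights (recycled; default equal).
#' @return Overall desirability in \[0, 1\].
#' @examples
#' overall_desirability(c(0.25, 1))  # 0.5
#' @export
overall_desirability <- function(d, weights = 1) {
  if (length(d) == 0L) stop("no desirabilities supplied", call. = FALSE)
  if (any(d < 0 | d > 1)) stop("d values must lie in [0, 1]", call. = FALSE)
  weights <- rep_len(weights, length(d))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(d == 0)) return(0)
  exp(sum(weights * log(d)) / sum(weights))
}

#' Specify a multi-response desirability optimization
#'
#' @param goals Named character vector (or list) mapping each response to
#'   `"maximize"` or `"minimize"`.
#' @param anchors `"auto"` (each response anchored to its own fitted
#'   min/max over the search region), or a named list of `c(lower, upper)`.
#' @param weights Named numeric vector of importance weights (default 1 for
#'   every response).
#' @param bounds Coded search region: `c(lo, hi)` for every factor or a
#'   list per factor. The default is the factorial square \[-1, 1\].
#' @return An object of class `desirability_spec`.
#' @export
desirability_spec <- function(goals, anchors = "auto", weights = NULL,
                              bounds = c(-1, 1)) {
  goals <- unlist(goals)
  if (is.null(names(goals)) || any(!nzchar(names(goals))))
    stop("goals must be named by response", call. = FALSE)
  if (!all(goals %in% c("maximize", "minimize")))
    stop("goals must be \"maximize\" or \"minimize\"", call. = FALSE)
  if (is.null(weights)) weights <- setNames(rep(1, length(goals)),
                                            names(goals))
  if (!identical(anchors, "auto")) {
    bad <- vapply(anchors, function(a) a[1L] >= a[2L], logical(1L))
    if (any(bad)) stop("anchors need lower < upper", call. = FALSE)
  }
  structure(list(goals = goals, anchors = anchors,
                 weights = weights, bounds = bounds),
            class = "desirability_spec")
}

resolve_bounds <- function(bounds, k) {
  if (!is.list(bounds)) bounds <- rep(list(bounds), k)
  if (length(bounds) != k)
    stop("need bounds for each of ", k, " factors", call. = FALSE)
  lapply(bounds, function(b) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1L] >= b[2L])
      stop("each bound must be finite c(lo, hi) with lo < hi",
           call. = FALSE)
    b
  })
}

# Resolve "auto" anchors to each response's fitted min/max over the region,
# scanned on the same grid the optimizer uses.
resolve_anchors <- function(fits, spec, resolution) {
  k <- fits[[1L]]$k
  bounds <- resolve_bounds(spec$bounds, k)
  axes <- lapply(bounds, function(b) seq(b[1L], b[2L],
                                         length.out = resolution))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  pred <- lapply(fits, predict, newdata = grid)
  anchors <- lapply(names(fits), function(nm) {
    if (identical(spec$anchors, "auto")) range(pred[[nm]])
    else spec$anchors[[nm]]
  })
  names(anchors) <- names(fits)
  list(grid = grid, pred = pred, anchors = anchors, bounds = bounds)
}

desirability_at <- function(fits, spec, anchors, point) {
  d <- vapply(names(fits), function(nm) {
    y <- predict(fits[[nm]], point)
    individual_desirability(y, spec$goals[[nm]],
                            lower = anchors[[nm]][1L],
                            upper = anchors[[nm]][2L],
                            weight = spec$weights[[nm]])
  }, numeric(1L))
  overall_desirability(d, spec$weights[names(fits)])
}

check_fits <- function(fits, spec) {
  if (!all(vapply(fits, inherits, logical(1L), "quadratic_fit")))
    stop("fits must be quadratic_fit objects", call. = FALSE)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, `[[`, character(1L), "response_name")
  missing_fit <- setdiff(names(spec$goals), names(fits))
  if (length(missing_fit))
    stop("no fit supplied for response(s): ",
         paste(missing_fit, collapse = ", "), call. = FALSE)
  fn <- lapply(fits, `[[`, "factor_names")
  if (length(unique(fn)) != 1L)
    stop("all fits must share the same design factors", call. = FALSE)
  fits[names(spec$goals)]
}

#' Maximize overall desirability over the coded search region
#'
#' A dense deterministic grid scan locates the global basin; a bounded
#' quasi-Newton polish (L-BFGS-B) refines the optimum within the region.
#' Ties on the grid are broken by first-found lexicographic order, so the
#' result is reproducible without a seed.
#'
#' @param fits Named list of `quadratic_fit` objects (names matching the
#'   responses in `spec`).
#' @param spec A `desirability_spec`.
#' @param resolution Grid points per axis for the scan (default 201).
#' @param ccd_spec Optional `ccd_spec`; when given, the optimum is also
#'   reported in actual factor units.
#' @return An object of class `desirability_optimum`: coded (and actual)
#'   optimum, overall `D`, per-response desirabilities and predictions, and
#'   the anchors used.
#' @examples
#' qd <- quebracho_data()
#' fit <- fit_quadratic(qd$design, qd$responses$LC, "LC")
#' opt <- optimize_desirability(list(LC = fit),
#'                              desirability_spec(c(LC = "maximize")))
#' opt$coded  # c(1, -1)
#' @export
optimize_desirability <- function(fits, spec, resolution = 201L,
                                  ccd_spec = NULL) {
  stopifnot(inherits(spec, "desirability_spec"))
  fits <- check_fits(fits, spec)
  k <- fits[[1L]]$k
  res <- resolve_anchors(fits, spec, resolution)

  d_mat <- vapply(names(fits), function(nm)
    individual_desirability(res$pred[[nm]], spec$goals[[nm]],
                            lower = res$anchors[[nm]][1L],
                            upper = res$anchors[[nm]][2L],
                            weight = spec$weights[[nm]]),
    numeric(nrow(res$grid)))
  w <- spec$weights[names(fits)]
  logd <- log(pmax(d_mat, .Machine$double.xmin))
  D_grid <- exp(drop(logd %*% w) / sum(w))
  D_grid[apply(d_mat == 0, 1L, any)] <- 0

  best <- which.max(D_grid)  # first-found on ties (lexicographic grid order)
  start <- res$grid[best, ]

  lo <- vapply(res$bounds, `[[`, numeric(1L), 1L)
  hi <- vapply(res$bounds, `[[`, numeric(1L), 2L)
  polish <- optim(start,
                  fn = function(p) -desirability_at(fits, spec,
                                                    res$anchors, p),
                  method = "L-BFGS-B", lower = lo, upper = hi)
  coded_opt <- polish$par
  D_opt <- -polish$value
  if (D_opt < D_grid[best]) {  # polish must never lose to the scan
    coded_opt <- start
    D_opt <- D_grid[best]
  }
  names(coded_opt) <- fits[[1L]]$factor_names

  pred_opt <- vapply(fits, predict, numeric(1L), newdata = coded_opt)
  d_opt <- vapply(names(fits), function(nm)
    individual_desirability(pred_opt[[nm]], spec$goals[[nm]],
                            lower = res$anchors[[nm]][1L],
                            upper = res$anchors[[nm]][2L],
                            weight = spec$weights[[nm]]), numeric(1L))
  actual <- if (!is.null(ccd_spec)) code_to_actual(ccd_spec, unname(coded_opt))

  structure(list(coded = coded_opt, actual = actual,
                 D = D_opt, d = d_opt, predicted = pred_opt,
                 anchors = res$anchors, weights = w,
                 resolution = resolution),
            class = "desirability_optimum")
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat("Desirability optimum: D =", round(x$D, 3), "\n")
  cat("  coded:", paste(sprintf("%s = %.3f", names(x$coded), x$coded),
                        collapse = ", "), "\n")
  if (!is.null(x$actual))
    cat("  actual:", paste(sprintf("%.3g", x$actual), collapse = ", "), "\n")
  for (nm in names(x$d))
    cat(sprintf("  %s: predicted %.3f, d = %.3f\n",
                nm, x$predicted[[nm]], x$d[[nm]]))
  invisible(x)
}

#' Overall-desirability surface on a grid
#'
#' @inheritParams optimize_desirability
#' @param resolution Grid points per axis.
#' @return Data frame: one coded column per factor, the per-response
#'   desirabilities (`d_<response>`) and the overall `D`.
#' @export
desirability_grid <- function(fits, spec, resolution = 101L) {
  stopifnot(inherits(spec, "desirability_spec"))
  fits <- check_fits(fits, spec)
  res <- resolve_anchors(fits, spec, resolution)
  out <- as.data.frame(res$grid)
  names(out) <- fits[[1L]]$factor_names
  d_mat <- vapply(names(fits), function(nm)
    individual_desirability(res$pred[[nm]], spec$goals[[nm]],
                            lower = res$anchors[[nm]][1L],
                            upper = res$anchors[[nm]][2L],
                            weight = spec$weights[[nm]]),
    numeric(nrow(res$grid)))
  w <- spec$weights[names(fits)]
  logd <- log(pmax(d_mat, .Machine$double.xmin))
  D <- exp(drop(logd %*% w) / sum(w))
  D[apply(d_mat == 0, 1L, any)] <- 0
  for (nm in names(fits)) out[[paste0("d_", nm)]] <- d_mat[, nm]
  out$D <- D
  out
}
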