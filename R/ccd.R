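#' Define a design factor
#'
#' A factor for a central composite design is parameterized by the actual
#' value at the coded center (coded 0) and the actual increment per coded
#' unit, so that `actual = center + step * coded`. Two-component mass ratios
#' with a fixed total (e.g. a core:shell ratio with the shell mass held at 5,
#' or an MD:GA blend with MD + GA = 5) are represented by their first
#' coordinate; the pair is only rendered for display.
#'
#' @param name Factor label (used as a column suffix in design tables).
#' @param center Actual value at coded 0. Must be finite.
#' @param step Actual increment per coded unit. Must be positive.
#' @param unit Free-text unit description.
#' @return An object of class `ccd_factor`.
#' @examples
#' ccd_factor("core_shell", center = 1, step = 0.5,
#'            unit = "core mass, shell fixed at 5")
#' @export
ccd_factor <- function(name, center, step, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(center))
    stop("factor '", name, "': center must be finite", call. = FALSE)
  if (!is.finite(step) || step <= 0)
    stop("factor '", name, "': step must be positive", call. = FALSE)
  structure(list(name = name, center = as.numeric(center),
                 step = as.numeric(step), unit = unit),
            class = "ccd_factor")
}

#' Specify a central composite design
#'
#' A CCD for `k` factors consists of a full two-level factorial (coded
#' settings all combinations of -1/+1), `2k` axial ("star") points at coded
#' distance `alpha` along one axis, and `n_center` replicated center points.
#'
#' @param ... `ccd_factor` objects (at least two), or a single list of them.
#' @param n_center Number of center-point replicates (>= 1).
#' @param alpha Axial distance: a positive number, or `"rotatable"` for
#'   `2^(k/4)`, which equalizes prediction variance on spheres about the
#'   center.
#' @return An object of class `ccd_spec`.
#' @examples
#' spec <- ccd_spec(ccd_factor("core_shell", 1, 0.5),
#'                  ccd_factor("md_ga", 2.5, 0.5),
#'                  n_center = 5, alpha = "rotatable")
#' @export
ccd_spec <- function(..., n_center = 5L, alpha = "rotatable") {
  factors <- list(...)
  if (length(factors) == 1L && !inherits(factors[[1L]], "ccd_factor"))
    factors <- factors[[1L]]
  if (!all(vapply(factors, inherits, logical(1L), "ccd_factor")))
    stop("all factors must be ccd_factor objects", call. = FALSE)
  k <- length(factors)
  if (k < 2L) stop("a CCD needs at least 2 factors", call. = FALSE)
  n_center <- as.integer(n_center)
  if (n_center < 1L) stop("n_center must be >= 1", call. = FALSE)
  if (identical(alpha, "rotatable")) {
    alpha_val <- 2^(k / 4)
  } else {
    alpha_val <- as.numeric(alpha)
    if (!is.finite(alpha_val) || alpha_val <= 0)
      stop("alpha must be positive or \"rotatable\"", call. = FALSE)
  }
  names(factors) <- vapply(factors, `[[`, character(1L), "name")
  structure(list(factors = factors, k = k, n_center = n_center,
                 alpha = alpha_val,
                 rotatable = identical(alpha, "rotatable")),
            class = "ccd_spec")
}

factor_names <- function(spec) names(spec$factors)
factor_centers <- function(spec)
  vapply(spec$factors, `[[`, numeric(1L), "center")
factor_steps <- function(spec)
  vapply(spec$factors, `[[`, numeric(1L), "step")

#' Generate a central composite design
#'
#' Runs are laid out in the canonical order factorial, axial, center. Coded
#' and actual factor settings are both populated; the coded columns of any
#' CCD built this way sum to zero and are mutually orthogonal.
#'
#' @param spec A `ccd_spec`.
#' @return A data frame of class `ccd_design` with columns `run_id`,
#'   `point_class`, `coded_<factor>` and `actual_<factor>`, carrying the
#'   spec in attribute `"spec"`. Run count is `2^k + 2k + n_center`.
#' @examples
#' spec <- ccd_spec(ccd_factor("core_shell", 1, 0.5),
#'                  ccd_factor("md_ga", 2.5, 0.5), n_center = 5)
#' des <- ccd_design(spec)
#' nrow(des)  # 13
#' @export
ccd_design <- function(spec) {
  stopifnot(inherits(spec, "ccd_spec"))
  k <- spec$k
  # first factor varies fastest, the conventional run order of printed CCDs
  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, nrow = 2L * k, ncol = k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -spec$alpha
    axial[2L * j, j] <- spec$alpha
  }
  centr <- matrix(0, nrow = spec$n_center, ncol = k)
  coded <- rbind(fact, axial, centr)
  dimnames(coded) <- NULL
  point_class <- rep(c("factorial", "axial", "center"),
                     c(nrow(fact), nrow(axial), nrow(centr)))
  actual <- sweep(sweep(coded, 2L, factor_steps(spec), `*`),
                  2L, factor_centers(spec), `+`)
  out <- data.frame(run_id = seq_len(nrow(coded)), point_class = point_class)
  nm <- factor_names(spec)
  for (j in seq_len(k)) out[[paste0("coded_", nm[j])]] <- coded[, j]
  for (j in seq_len(k)) out[[paste0("actual_", nm[j])]] <- actual[, j]
  structure(out, spec = spec, class = c("ccd_design", "data.frame"))
}

#' Convert coded factor settings to actual values
#'
#' @param spec A `ccd_spec`.
#' @param coded Numeric vector of length `k` (one coded setting per factor),
#'   or a matrix with `k` columns.
#' @return Actual values, `center + step * coded`, same shape as `coded`.
#' @examples
#' spec <- ccd_spec(ccd_factor("core_shell", 1, 0.5),
#'                  ccd_factor("md_ga", 2.5, 0.5))
#' code_to_actual(spec, c(1, -1))  # 1.5, 2.0
#' @export
code_to_actual <- function(spec, coded) {
  stopifnot(inherits(spec, "ccd_spec"))
  if (is.matrix(coded)) {
    if (ncol(coded) != spec$k)
      stop("coded point has ", ncol(coded), " columns; design has ",
           spec$k, " factors", call. = FALSE)
    return(sweep(sweep(coded, 2L, factor_steps(spec), `*`),
                 2L, factor_centers(spec), `+`))
  }
  if (length(coded) != spec$k)
    stop("coded point has length ", length(coded), "; design has ",
         spec$k, " factors", call. = FALSE)
  unname(factor_centers(spec) + factor_steps(spec) * coded)
}

#' Convert actual factor values to coded settings
#'
#' Exact inverse of [code_to_actual()]: `(actual - center) / step`.
#'
#' @param spec A `ccd_spec`.
#' @param actual Numeric vector of length `k`, or a matrix with `k` columns.
#' @return Coded values, same shape as `actual`.
#' @export
actual_to_code <- function(spec, actual) {
  stopifnot(inherits(spec, "ccd_spec"))
  if (is.matrix(actual)) {
    if (ncol(actual) != spec$k)
      stop("actual point has ", ncol(actual), " columns; design has ",
           spec$k, " factors", call. = FALSE)
    return(sweep(sweep(actual, 2L, factor_centers(spec), `-`),
                 2L, factor_steps(spec), `/`))
  }
  if (length(actual) != spec$k)
    stop("actual point has length ", length(actual), "; design has ",
         spec$k, " factors", call. = FALSE)
  unname((actual - factor_centers(spec)) / factor_steps(spec))
}

coded_matrix <- function(design) {
  cols <- grep("^coded_", names(design), value = TRUE)
  m <- as.matrix(design[cols])
  colnames(m) <- sub("^coded_", "", cols)
  m
}

actual_matrix <- function(design) {
  cols <- grep("^actual_", names(design), value = TRUE)
  m <- as.matrix(design[cols])
  colnames(m) <- sub("^actual_", "", cols)
  m
}

#' Validate the structure of a central composite design
#'
#' Checks the design invariants: run count `2^k + 2k + n_center`, zero
#' column sums, mutual orthogonality of the coded factor columns and of each
#' factor with the pairwise interaction columns, the coded-to-actual affine
#' mapping, and duplicated non-center runs. Violations are reported, not
#' raised: printed tables from the literature sometimes carry internal
#' inconsistencies that should be surfaced without blocking analysis.
#'
#' @param design A `ccd_design` (or a data frame with `coded_*`/`actual_*`
#'   columns and a `"spec"` attribute).
#' @param tol Numerical tolerance for the orthogonality checks.
#' @param actual_tol Tolerance for the coded-to-actual mapping check;
#'   the default 0.01 absorbs the rounding of actual values as printed in
#'   published tables while still catching genuine mismatches.
#' @return An object of class `ccd_validation`: a list with elements
#'   `checks` (data frame of check name, measured value, pass flag) and
#'   `ok` (all passed).
#' @export
validate_design <- function(design, tol = 1e-8, actual_tol = 0.01) {
  spec <- attr(design, "spec")
  coded <- coded_matrix(design)
  k <- ncol(coded)
  checks <- list()
  add <- function(name, value, pass)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, value = value, pass = pass)

  if (!is.null(spec)) {
    expected_n <- 2^spec$k + 2L * spec$k + spec$n_center
    add("run_count", nrow(design), nrow(design) == expected_n)
  }
  for (j in seq_len(k))
    add(paste0("sum_", colnames(coded)[j]), sum(coded[, j]),
        abs(sum(coded[, j])) <= tol)
  if (k >= 2L) {
    pairs <- utils::combn(k, 2L)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      ip <- sum(coded[, i] * coded[, j])
      add(paste0("dot_", colnames(coded)[i], "_", colnames(coded)[j]),
          ip, abs(ip) <= tol)
      ij <- coded[, i] * coded[, j]
      for (l in seq_len(k)) {
        ipl <- sum(coded[, l] * ij)
        add(paste0("dot_", colnames(coded)[l], "_x_",
                   colnames(coded)[i], colnames(coded)[j]),
            ipl, abs(ipl) <= tol)
      }
    }
  }
  if (!is.null(spec)) {
    actual <- actual_matrix(design)
    expect <- code_to_actual(spec, coded)
    dev <- abs(actual - expect)
    for (j in seq_len(k))
      add(paste0("actual_mapping_", colnames(coded)[j]),
          max(dev[, j]), max(dev[, j]) <= actual_tol)
  }
  non_center <- design$point_class != "center"
  dup <- anyDuplicated(coded[non_center, , drop = FALSE])
  add("no_duplicate_noncenter_runs", dup, dup == 0L)

  checks <- do.call(rbind, checks)
  rownames(checks) <- NULL
  structure(list(checks = checks, ok = all(checks$pass)),
            class = "ccd_validation")
}

#' @export
print.ccd_validation <- function(x, ...) {
  cat(if (x$ok) "CCD valid:" else "CCD has violations:", "\n")
  bad <- x$checks[!x$checks$pass, , drop = FALSE]
  if (nrow(bad) == 0L) {
    cat("  all", nrow(x$checks), "checks passed\n")
  } else {
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  FAIL %s (value %.6g)\n", bad$check[i], bad$value[i]))
  }
  invisible(x)
}

#' Write / read a design table as CSV
#'
#' The CSV carries `run_id`, `point_class`, `coded_*` and `actual_*`
#' columns; the spec is not serialized, so a design read back can be
#' revalidated only against an explicitly supplied spec.
#'
#' @param design A `ccd_design`.
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` returns a
#'   `ccd_design` (with `spec` attribute attached when supplied).
#' @param spec Optional `ccd_spec` to attach on read.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, spec = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(d, spec = spec, class = c("ccd_design", "data.frame"))
}
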