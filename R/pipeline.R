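#' Configure the formulation-optimization pipeline
#'
#' @param responses Character vector of response columns to model.
#' @param tc_units Scale for the tannin-content response: `"mg_per_g"`
#'   (default; the g/100 g table values times 10 — the scale on which the
#'   study's published TC coefficients were fitted) or `"g_per_100g"`.
#' @param correct_run7_ey Apply the run-7 EY correction (see
#'   [quebracho_data()]).
#' @param goals Desirability goal per response (default: maximize all).
#' @param out_dir Output directory for the report bundle, or `NULL` to
#'   skip writing files.
#' @param resolution Grid resolution for the desirability scan.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(responses = c("LC", "EE", "EY", "TC"),
                            tc_units = c("mg_per_g", "g_per_100g"),
                            correct_run7_ey = TRUE,
                            goals = NULL, out_dir = NULL,
                            resolution = 201L) {
  tc_units <- match.arg(tc_units)
  if (length(responses) == 0L)
    stop("at least one response must be modeled", call. = FALSE)
  if (is.null(goals))
    goals <- setNames(rep("maximize", length(responses)), responses)
  structure(list(responses = responses, tc_units = tc_units,
                 correct_run7_ey = correct_run7_ey, goals = goals,
                 out_dir = out_dir, resolution = as.integer(resolution)),
            class = "pipeline_config")
}

#' Run the formulation-optimization pipeline on the study tables
#'
#' End-to-end reproduction of the study's analysis: load the packaged
#' design and response tables, validate the design, fit the full
#' second-order model for each configured response (with lack-of-fit
#' ANOVA), and locate the multi-response desirability optimum. When
#' `config$out_dir` is set, the bundle (design CSV, coefficient table,
#' per-fit JSON, desirability grid CSV, optimum JSON, log) is written
#' there; outputs are deterministic for a given config.
#'
#' @param config A `pipeline_config`.
#' @return List with `design`, `responses`, `validation`, `fits` (named
#'   list of `quadratic_fit`), `optimum` (`desirability_optimum`) and
#'   `table` (the rendered coefficient table, character vector).
#' @examples
#' res <- run_pipeline(pipeline_config(responses = "LC"))
#' round(coef(res$fits$LC)["b1"], 3)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  qd <- quebracho_data(correct_run7_ey = config$correct_run7_ey)
  missing_cols <- setdiff(config$responses, names(qd$responses))
  if (length(missing_cols))
    stop("response column(s) not in table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  validation <- validate_design(qd$design)

  fits <- lapply(config$responses, function(nm) {
    y <- qd$responses[[nm]]
    if (nm == "TC" && config$tc_units == "mg_per_g") y <- y * 10
    fit_quadratic(qd$design, y, response_name = nm)
  })
  names(fits) <- config$responses

  dspec <- desirability_spec(config$goals)
  optimum <- optimize_desirability(fits, dspec,
                                   resolution = config$resolution,
                                   ccd_spec = qd$spec)
  tab <- render_coef_table(fits)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_design(qd$design, file.path(config$out_dir, "design.csv"))
    writeLines(tab, file.path(config$out_dir, "coefficients.txt"))
    for (nm in names(fits))
      write_fit_json(fits[[nm]],
                     file.path(config$out_dir, paste0("fit_", nm, ".json")))
    grid <- desirability_grid(fits, dspec, resolution = 101L)
    utils::write.csv(grid, file.path(config$out_dir,
                                     "desirability_grid.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(coded = as.list(optimum$coded),
           actual = as.list(setNames(as.numeric(optimum$actual),
                                     names(optimum$coded))),
           D = optimum$D, d = as.list(optimum$d),
           predicted = as.list(optimum$predicted)),
      file.path(config$out_dir, "optimum.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(c(
      sprintf("responses: %s", paste(config$responses, collapse = ", ")),
      sprintf("tc_units: %s", config$tc_units),
      sprintf("correct_run7_ey: %s", config$correct_run7_ey),
      sprintf("design_valid: %s", validation$ok),
      sprintf("grid_resolution: %d", config$resolution)),
      file.path(config$out_dir, "pipeline_log.txt"))
  }

  list(design = qd$design, responses = qd$responses,
       validation = validation, fits = fits, optimum = optimum,
       table = tab)
}

#' Render a coefficient table across fitted responses
#'
#' Plain-text table in the conventional layout of published RSM coefficient
#' tables: one column per response; rows for the intercept, linear,
#' quadratic and interaction coefficients (each with its significance
#' mark), then R-squared, adjusted R-squared, the lack-of-fit p-value and
#' the model p-value. Coefficients are shown to 3 decimals.
#'
#' @param fits Named list of `quadratic_fit` objects sharing one design.
#' @return Character vector of table lines (also printed nicely via
#'   `writeLines`).
#' @export
render_coef_table <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, `[[`, character(1L), "response_name")
  terms <- names(fits[[1L]]$coefficients)
  cell <- function(fit, term)
    sprintf("%.3f %s", fit$coefficients[[term]], fit$marks[[term]])
  stat_row <- function(label, vals)
    c(label, vals)
  rows <- lapply(terms, function(tm)
    c(tm, vapply(fits, cell, character(1L), term = tm)))
  rows <- c(rows,
    list(stat_row("R2", vapply(fits, function(f)
      sprintf("%.3f", f$r2), character(1L)))),
    list(stat_row("R2_adj", vapply(fits, function(f)
      sprintf("%.3f", f$r2_adj), character(1L)))),
    list(stat_row("lack_of_fit_p", vapply(fits, function(f) {
      if (is.null(f$anova)) return("-")
      p <- f$anova$p[f$anova$source == "lack_of_fit"]
      if (is.finite(p)) sprintf("%.3f", p) else "-"
    }, character(1L)))),
    list(stat_row("model_p", vapply(fits, function(f) {
      if (is.null(f$anova)) return("-")
      p <- f$anova$p[f$anova$source == "model"]
      if (p < 1e-4) "<0.0001" else sprintf("%.4f", p)
    }, character(1L)))))
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("term", names(fits))
  widths <- pmax(nchar(colnames(mat)),
                 apply(nchar(mat), 2L, max))
  fmt_line <- function(vals)
    paste(mapply(formatC, vals, width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  ")
  c(fmt_line(colnames(mat)),
    paste(rep("-", sum(widths) + 2L * (ncol(mat) - 1L)), collapse = ""),
    apply(mat, 1L, fmt_line))
}

#' Write a fit report as JSON
#'
#' Full-precision machine-readable report of a [fit_quadratic()] result:
#' coefficients, standard errors, t and p values, significance marks,
#' R-squared statistics and the ANOVA decomposition.
#'
#' @param fit A `quadratic_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "quadratic_fit"))
  payload <- list(
    response = fit$response_name,
    coefficients = as.list(fit$coefficients),
    standard_errors = as.list(fit$standard_errors),
    t_values = as.list(fit$t_values),
    p_values = as.list(fit$p_values),
    significance = as.list(fit$marks),
    r2 = fit$r2, r2_adj = fit$r2_adj,
    anova = if (!is.null(fit$anova)) as.list(as.data.frame(fit$anova)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
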