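#' Factor specification of the quebracho encapsulation study
#'
#' Two formulation factors: the core:shell ratio (quebracho extract mass,
#' with the shell mass fixed at 5; center 1, step 0.5) and the MD:GA blend
#' (maltodextrin mass as the varying coordinate with MD + GA = 5; center
#' 2.5, step 0.5).
#'
#' @return A `ccd_spec` with 5 center replicates and rotatable axial
#'   distance (2^(1/2) for two factors).
#' @export
quebracho_spec <- function() {
  ccd_spec(
    ccd_factor("core_shell", center = 1, step = 0.5,
               unit = "core (quebracho) mass; shell fixed at 5"),
    ccd_factor("md_ga", center = 2.5, step = 0.5,
               unit = "maltodextrin mass; MD + GA = 5"),
    n_center = 5L, alpha = "rotatable")
}

#' Quebracho microencapsulation study tables
#'
#' The 13-run central composite design and measured responses of the
#' spray-dried quebracho-tannin encapsulation study, as printed: coded and
#' actual factor settings, and per-run means with standard deviations for
#' encapsulation yield (EY, %), total and surface phenolics (g/100 g),
#' tannin content (TC, g/100 g), encapsulation efficiency (EE, %), loading
#' capacity (LC, %), and the passthrough columns (moisture, water activity,
#' CIELAB color).
#'
#' Two recorded printing artifacts are handled explicitly:
#' \itemize{
#'   \item Run 7's EY is printed as 39.75 in the response table but the
#'     accompanying text gives 29.75 for that formulation, and only 29.75
#'     is consistent with the published regression coefficients. With
#'     `correct_run7_ey = TRUE` (default) the corrected value is used; the
#'     printed value is kept under `EY_printed`.
#'   \item Two unparseable SD strings are stored as `NA` with the raw
#'     text preserved in the `sd_raw` column.
#' }
#'
#' The MD:GA axial runs carry the printed actual values (1.5 and 3.5),
#' which correspond to coded ±2 under the factor's center/step, while the
#' printed coded values are ±1.414; [validate_design()] flags this
#' inconsistency. All regression in this package uses the printed coded
#' values, which reproduce the published coefficient tables.
#'
#' @param correct_run7_ey Replace run 7's printed EY with the text value
#'   29.75 (default `TRUE`).
#' @return List with elements `design` (a `ccd_design`), `responses`
#'   (data frame keyed by `run_id`) and `spec` (the `ccd_spec`).
#' @examples
#' qd <- quebracho_data()
#' qd$responses$LC[2]  # 17.67
#' @export
quebracho_data <- function(correct_run7_ey = TRUE) {
  spec <- quebracho_spec()
  design <- read_design(
    system.file("extdata", "quebracho_ccd_design.csv", package = "encapr",
                mustWork = TRUE), spec = spec)
  responses <- utils::read.csv(
    system.file("extdata", "quebracho_responses.csv", package = "encapr",
                mustWork = TRUE), stringsAsFactors = FALSE)
  responses$EY_printed <- responses$EY
  if (correct_run7_ey) responses$EY[responses$run_id == 7L] <- 29.75
  attr(responses, "correct_run7_ey") <- correct_run7_ey
  list(design = design, responses = responses, spec = spec)
}

#' Paths of the packaged study tables
#'
#' @return Named character vector of the CSV fixture paths.
#' @export
quebracho_fixture_paths <- function() {
  c(design = system.file("extdata", "quebracho_ccd_design.csv",
                         package = "encapr", mustWork = TRUE),
    responses = system.file("extdata", "quebracho_responses.csv",
                            package = "encapr", mustWork = TRUE))
}
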