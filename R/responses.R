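#' Encapsulation yield
#'
#' Mass of powder recovered from the spray dryer as a percentage of the
#' solids fed.
#'
#' @param powder_collected Mass of powder collected (g), >= 0.
#' @param solids_fed Mass of solids in the feed suspension (g), > 0.
#' @return Yield in percent.
#' @examples
#' encapsulation_yield(50, 100)  # 50
#' @export
encapsulation_yield <- function(powder_collected, solids_fed) {
  if (any(solids_fed <= 0))
    stop("solids_fed must be positive", call. = FALSE)
  if (any(powder_collected < 0))
    stop("powder_collected must be non-negative", call. = FALSE)
  100 * powder_collected / solids_fed
}

#' Loading capacity
#'
#' Entrapped phenolics per unit mass of microparticles. With both contents
#' already expressed in g per 100 g of powder the formula's normalization by
#' particle mass is the identity, so LC is simply total minus surface.
#'
#' @param total_phenolics Total phenolic content (g/100 g powder).
#' @param surface_phenolics Surface phenolic content (g/100 g powder);
#'   must not exceed the total.
#' @return Loading capacity (g/100 g powder, i.e. percent w/w).
#' @examples
#' loading_capacity(18.24, 0.56)  # 17.68
#' @export
loading_capacity <- function(total_phenolics, surface_phenolics) {
  if (any(surface_phenolics > total_phenolics))
    stop("surface phenolic content exceeds total", call. = FALSE)
  if (any(surface_phenolics < 0))
    stop("phenolic contents must be non-negative", call. = FALSE)
  total_phenolics - surface_phenolics
}

#' Theoretical phenolic content of a formulation
#'
#' The phenolic content (g/100 g powder) the particles would have if every
#' gram of core material were phenolic and fully retained: the core mass
#' fraction of total solids, times 100. Treating the core extract as 100%
#' phenolics is the convention under which recomputed efficiencies match the
#' study's printed values; scaling by the extract's assayed phenolic
#' fraction instead does not (see the package vignette).
#'
#' @param core_mass Core (active) mass in the formulation.
#' @param shell_mass Shell (carrier) mass in the formulation.
#' @return Theoretical phenolic content in g/100 g.
#' @export
theoretical_phenolics <- function(core_mass, shell_mass) {
  if (any(core_mass + shell_mass <= 0))
    stop("core_mass + shell_mass must be positive", call. = FALSE)
  if (any(core_mass < 0) || any(shell_mass < 0))
    stop("masses must be non-negative", call. = FALSE)
  100 * core_mass / (core_mass + shell_mass)
}

#' Encapsulation efficiency
#'
#' Phenolics actually entrapped (total minus surface) as a percentage of the
#' formulation's theoretical phenolic content.
#'
#' @inheritParams loading_capacity
#' @inheritParams theoretical_phenolics
#' @return Efficiency in percent.
#' @examples
#' encapsulation_efficiency(6.93, 0.32, core_mass = 0.5, shell_mass = 5)
#' @export
encapsulation_efficiency <- function(total_phenolics, surface_phenolics,
                                     core_mass, shell_mass) {
  entrapped <- loading_capacity(total_phenolics, surface_phenolics)
  100 * entrapped / theoretical_phenolics(core_mass, shell_mass)
}

#' Compute encapsulation responses for a set of runs
#'
#' Builds a response table (EY, EE, LC) from per-run measurements, carrying
#' any extra columns (moisture, water activity, color) through untouched.
#'
#' @param measurements Data frame with columns `run_id`, `powder_collected`,
#'   `solids_fed`, `total_phenolics`, `surface_phenolics`, `core_mass`,
#'   `shell_mass`; further columns are passed through.
#' @return Data frame with `run_id`, `EY`, `EE`, `LC` and the passthrough
#'   columns.
#' @export
compute_responses <- function(measurements) {
  req <- c("run_id", "powder_collected", "solids_fed", "total_phenolics",
           "surface_phenolics", "core_mass", "shell_mass")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols))
    stop("missing measurement columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(
    run_id = measurements$run_id,
    EY = encapsulation_yield(measurements$powder_collected,
                             measurements$solids_fed),
    EE = encapsulation_efficiency(measurements$total_phenolics,
                                  measurements$surface_phenolics,
                                  measurements$core_mass,
                                  measurements$shell_mass),
    LC = loading_capacity(measurements$total_phenolics,
                          measurements$surface_phenolics))
  passthrough <- setdiff(names(measurements), req)
  for (col in passthrough) out[[col]] <- measurements[[col]]
  out
}
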