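#' Build a four-variant scenario set
#'
#' Control, each single stress, and the combination, sharing the base
#' configuration and seed; the variants differ only in their stress events,
#' so growth differences are attributable to the stress treatments alone.
#'
#' @param config Base `wgdt_config` (its own `stress_events` are ignored).
#' @param events_a,events_b Lists of [stress_event()] objects defining the
#'   two single-stress treatments.
#' @return A `wgdt_scenario_set`: named list of four configs
#'   (`control`, `stress_a`, `stress_b`, `combined`).
#' @export
make_scenario_set <- function(config, events_a, events_b) {
  variant <- function(events) {
    cfg <- config
    cfg$stress_events <- events
    cfg
  }
  structure(list(
    control = variant(list()),
    stress_a = variant(events_a),
    stress_b = variant(events_b),
    combined = variant(c(events_a, events_b))
  ), class = "wgdt_scenario_set")
}

#' Default combined-stress scenario set
#'
#' The package's reference experiment: a mid-season heat wave (abiotic, all
#' organs, days 40-70, peak 0.4) and a foliar pathogen infection (biotic,
#' mature and growing leaves, days 50-80, peak 0.4), overlapping so that the
#' configured combination rule acts where both signals co-occur.
#'
#' @param config Base `wgdt_config`.
#' @return A `wgdt_scenario_set`.
#' @export
default_scenario_set <- function(config = default_config()) {
  heat <- stress_event("heat", "abiotic", start_day = 40, end_day = 70,
                       peak_intensity = 0.4, ramp_days = 5)
  pathogen <- stress_event("pathogen", "biotic", start_day = 50, end_day = 80,
                           peak_intensity = 0.4, ramp_days = 5,
                           target_organs = c("mature_leaf", "growing_leaf"))
  make_scenario_set(config, list(heat), list(pathogen))
}

#' Run every variant of a scenario set
#'
#' @param scenarios A `wgdt_scenario_set`.
#' @return Named list of `wgdt_trajectory` objects.
#' @export
run_scenario_set <- function(scenarios) {
  lapply(scenarios, run_simulation)
}

#' Comparison table for a set of scenario runs
#'
#' @param results Named list of trajectories from [run_scenario_set()].
#' @return Data frame with one row per variant: final biomass, biomass loss
#'   relative to control, cumulative gross assimilation and respiration.
#' @export
compare_scenarios <- function(results) {
  b <- vapply(results, final_biomass, numeric(1))
  ctl <- b[["control"]]
  data.frame(
    variant = names(results),
    final_biomass = unname(b),
    delta_vs_control = unname(ctl - b),
    relative_loss = unname((ctl - b) / ctl),
    gross_assim_c = vapply(results, function(r) sum(r$plant$a_gross), numeric(1)),
    respiration_c = vapply(results, function(r) {
      sum(r$plant$rd_c + r$plant$r_maint_basal + r$plant$r_maint_defense +
            r$plant$r_growth + r$plant$r_def_synth)
    }, numeric(1)),
    row.names = NULL
  )
}

#' Non-additivity index of a combined-stress experiment
#'
#' Quantifies how far the combined-stress growth response departs from the
#' sum of the single-stress responses:
#' \deqn{NAI = \frac{\Delta_{comb} - (\Delta_a + \Delta_b)}{B_{control}},
#'   \quad \Delta_x = B_{control} - B_x}
#' with `B` the final total structural biomass. `NAI > 0` indicates
#' synergistic damage (the combination hurts more than its parts),
#' `NAI < 0` antagonistic damage.
#'
#' @param results Named list of the four trajectories (`control`,
#'   `stress_a`, `stress_b`, `combined`), all run with identical seed and
#'   horizon.
#' @return List with `nai`, per-variant biomasses, the deltas, and `sign`
#'   (`"synergistic"`, `"antagonistic"`, or `"additive"`).
#' @export
non_additivity_index <- function(results) {
  need <- c("control", "stress_a", "stress_b", "combined")
  if (!all(need %in% names(results))) {
    stop_wgdt("results must contain variants: ", paste(need, collapse = ", "))
  }
  seeds <- vapply(results[need], function(r) as.integer(r$config$seed),
                  integer(1))
  horizons <- vapply(results[need], function(r) as.integer(r$config$horizon_days),
                     integer(1))
  if (length(unique(seeds)) != 1 || length(unique(horizons)) != 1) {
    stop_wgdt("scenario variants are not comparable: seeds/horizons differ")
  }
  b <- vapply(results[need], final_biomass, numeric(1))
  delta <- b[["control"]] - b
  nai <- (delta[["combined"]] - (delta[["stress_a"]] + delta[["stress_b"]])) /
    b[["control"]]
  list(nai = nai,
       biomass = as.list(b),
       delta = as.list(delta[c("stress_a", "stress_b", "combined")]),
       sign = if (nai > 0) "synergistic" else if (nai < 0) "antagonistic"
              else "additive")
}

#' Default sustained biotic challenge with full defense activation
#'
#' Configures the reference calibration run behind the defense-cost
#' accounting: a sustained 20-day foliar pathogen challenge (days 60-79,
#' constant intensity) with the defense coefficient clamped at 1 on the
#' mature leaf over the same window.
#'
#' @param config Base `wgdt_config`.
#' @param start_day First challenge day (runs 20 days).
#' @param intensity Challenge intensity in `[0, 1]`.
#' @return The modified config.
#' @export
biotic_challenge_config <- function(config = default_config(),
                                    start_day = 60, intensity = 0.6) {
  end_day <- start_day + 19
  config$stress_events <- list(
    stress_event("pathogen", "biotic", start_day = start_day,
                 end_day = end_day, peak_intensity = intensity,
                 ramp_days = 0, target_organs = "mature_leaf"))
  config$force_d <- list(kinds = "mature_leaf", value = 1,
                         start_day = start_day, end_day = end_day)
  config
}

#' Defense carbon consumption as a share of gross photosynthate
#'
#' Over a day window, sums an organ's defense-associated carbon consumption -
#' the defense-augmented maintenance respiration term plus the full
#' glucose-equivalent substrate of defense compound synthesis - and divides
#' by the organ's gross assimilated carbon over the same window.
#'
#' @param trajectory A `wgdt_trajectory`.
#' @param kind Organ kind (default `mature_leaf`).
#' @param days Day records to include (defaults to all simulated days).
#' @return Percentage (0-100) of gross photosynthate consumed by defense.
#' @export
defense_c_fraction <- function(trajectory, kind = "mature_leaf", days = NULL) {
  org <- trajectory$organs
  rows <- org$organ == kind & org$day > 0
  if (!is.null(days)) rows <- rows & org$day %in% days
  def_c <- sum(org$maint_defense_c[rows]) + sum(org$def_synth_c[rows])
  gross <- sum(org$assim_c[rows])
  if (gross <= 0) stop_wgdt("organ assimilated no carbon over the window")
  100 * def_c / gross
}
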