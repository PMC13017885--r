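#' Q10 temperature factor for maintenance respiration
#'
#' \eqn{f_T = Q_{10}^{(T - T_{ref})/10}} with reference 25 degC.
#'
#' @param t Temperature, degC.
#' @param t_ref Reference temperature, degC.
#' @param q10 Q10 coefficient.
#' @return Dimensionless factor (1 at the reference temperature).
#' @export
temperature_factor <- function(t, t_ref = 25, q10 = 2) {
  q10^((t - t_ref) / 10)
}

#' Maintenance respiration with explicit defense augmentation
#'
#' Maintenance carbon cost of an organ,
#' \deqn{R_{maintenance} = R_{basal} + D \times C_{defense} \times mass}
#' where the basal term is `m_base(kind) x mass x f_T` (Q10-scaled) and the
#' defense term makes the energetic cost of defense activation (defense
#' enzyme turnover, transport) explicit rather than lumping it into a generic
#' maintenance coefficient. `C_defense` is a per-unit-mass cost, matching the
#' mass-proportional defense sink.
#'
#' @param organ An `organ_state`.
#' @param t Temperature, degC (drives the Q10 factor of the basal term).
#' @param params Respiration parameter block
#'   (see `default_config()$respiration`).
#' @return List with `basal`, `defense` and `total`, g C d-1.
#' @export
maintenance_respiration <- function(organ, t, params) {
  f_t <- temperature_factor(t, params$t_ref %||% 25, params$q10)
  basal <- params$m_base[[organ$kind]] * organ$structural_mass * f_t
  defense <- organ$d_coef * params$c_defense * organ$structural_mass
  list(basal = basal, defense = defense, total = basal + defense)
}

#' Growth respiration
#'
#' Carbon respired while synthesizing `delta_mass` g of new structural dry
#' matter with growth yield `Yg`:
#' \eqn{R_g = c_{DM}\,\Delta m\,(1 - Y_g)/Y_g}, where `c_DM` is the
#' structural carbon content per g DM.
#'
#' @param delta_mass New structural dry matter, g (>= 0).
#' @param params Respiration parameter block (uses `growth_yield`).
#' @param c_per_g Structural carbon content, g C g-1 DM.
#' @return Carbon respired, g C.
#' @export
growth_respiration <- function(delta_mass, params, c_per_g) {
  if (delta_mass < 0) stop_wgdt("delta_mass must be >= 0")
  c_per_g * delta_mass * (1 - params$growth_yield) / params$growth_yield
}

#' Process-itemized ("general paradigm") respiration
#'
#' Alternative accounting mode summing the activity rate of each listed
#' process multiplied by its metabolic cost (e.g. phloem loading, nitrate
#' uptake and reduction). Exposed as a diagnostic; the default model uses the
#' basal + defense maintenance form.
#'
#' @param activities Named numeric vector/list of process activities (units
#'   per day).
#' @param params Respiration parameter block with `process_costs`, a named
#'   list of g C per unit activity.
#' @return Total carbon cost, g C d-1.
#' @export
process_sum_respiration <- function(activities, params) {
  if (length(activities) == 0) return(0)
  acts <- unlist(activities)
  costs <- params$process_costs
  missing <- setdiff(names(acts), names(costs))
  if (length(missing)) {
    stop_wgdt("no metabolic cost declared for process(es): ",
              paste(missing, collapse = ", "))
  }
  sum(vapply(names(acts), function(p) acts[[p]] * costs[[p]], numeric(1)))
}
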