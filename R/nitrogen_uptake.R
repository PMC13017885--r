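#' High-affinity (HATS) nitrate uptake rate
#'
#' Michaelis-Menten saturating uptake,
#' \eqn{v = V_{max}\, [NO_3] / (K_m + [NO_3])}.
#'
#' @param no3 Soil nitrate concentration, mol m-3 (>= 0).
#' @param vmax_hats Maximum uptake rate, g N g-1 root d-1.
#' @param km_hats Half-saturation constant, mol m-3 (> 0).
#' @return Uptake rate, g N g-1 root d-1.
#' @export
hats_rate <- function(no3, vmax_hats, km_hats) {
  if (no3 < 0) stop_wgdt("no3 must be >= 0")
  vmax_hats * no3 / (km_hats + no3)
}

#' Low-affinity (LATS) nitrate uptake rate
#'
#' Linear uptake component dominating at high nitrate concentrations,
#' \eqn{v = k \max([NO_3] - c_0, 0)}. The default activation threshold
#' `c0 = 0` leaves the pure linear form, whose contribution is naturally
#' negligible at low concentration.
#'
#' @param no3 Soil nitrate concentration, mol m-3 (>= 0).
#' @param k_lats Linear coefficient, g N g-1 root d-1 per (mol m-3).
#' @param threshold Optional activation threshold, mol m-3.
#' @return Uptake rate, g N g-1 root d-1.
#' @export
lats_rate <- function(no3, k_lats, threshold = 0) {
  if (no3 < 0) stop_wgdt("no3 must be >= 0")
  k_lats * max(no3 - threshold, 0)
}

#' Daily root nitrogen uptake
#'
#' Whole-root nitrate uptake combining the HATS and LATS transport systems,
#' regulated by root carbon status through a bounded saturating factor
#' \deqn{f_C = f_{min} + (1 - f_{min}) \frac{c}{K_c + c},\quad
#'       c = \frac{C_{store}}{mass_{root}}}
#' and scaled by root structural mass and stress-driven source
#' downregulation. Soil nitrate is an exogenous, non-limiting driver: uptake
#' is not debited from the soil.
#'
#' @param root An `organ_state` of kind `roots`.
#' @param env Environment-day list with `soil_no3`.
#' @param params Uptake parameter block (see `default_config()$uptake`).
#' @param downregulation Fraction in `[0, 1]`.
#' @return Nitrogen uptake, g N d-1.
#' @export
organ_nitrogen_uptake <- function(root, env, params, downregulation = 0) {
  if (root$kind != "roots") stop_wgdt("organ_nitrogen_uptake needs the roots organ")
  mass <- root$structural_mass
  if (mass <= 0) return(0)
  c_conc <- root$c_store / mass
  f_c <- params$f_min + (1 - params$f_min) * c_conc / (params$c_reg_k + c_conc)
  rate <- hats_rate(env$soil_no3, params$vmax_hats, params$km_hats) +
    lats_rate(env$soil_no3, params$k_lats, params$lats_threshold %||% 0)
  rate * f_c * mass * (1 - clamp(downregulation, 0, 1))
}
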