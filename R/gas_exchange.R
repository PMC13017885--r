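#' Arrhenius temperature scaling of a photosynthetic parameter
#'
#' Scales a parameter value defined at the 25 degC reference temperature to
#' the current leaf temperature with the standard (non-peaked) Arrhenius
#' function
#' \deqn{p(T) = p_{25} \exp\!\left[\frac{E_a (T - 298.15)}{298.15\,R\,T}\right]}
#' with `T` in kelvin and `R = 8.314` J mol-1 K-1. At 25 degC the value is
#' returned unchanged for any activation energy.
#'
#' @param p25 Parameter value at 25 degC.
#' @param ea Activation energy, J mol-1.
#' @param t_leaf Leaf temperature, degC (> -273.15).
#' @return The scaled parameter value.
#' @export
arrhenius_scale <- function(p25, ea, t_leaf) {
  tk <- t_leaf + 273.15
  p25 * exp(ea * (tk - 298.15) / (298.15 * 8.314 * tk))
}

#' Potential electron transport rate
#'
#' Smaller root of the non-rectangular hyperbola
#' \eqn{\theta J^2 - (\alpha I + J_{max}) J + \alpha I J_{max} = 0}, where
#' `I` is absorbed PAR. At `theta = 0` the rectangular-hyperbola limit
#' \eqn{\alpha I J_{max} / (\alpha I + J_{max})} is used.
#'
#' @param par Absorbed PAR, umol photons m-2 s-1 (>= 0).
#' @param jmax Maximum electron transport rate, umol m-2 s-1.
#' @param alpha Quantum yield of electron transport.
#' @param theta Curvature parameter in `[0, 1]`.
#' @return J in `[0, jmax]`, umol m-2 s-1.
#' @export
electron_transport <- function(par, jmax, alpha, theta) {
  if (par < 0) stop_wgdt("par must be >= 0")
  ai <- alpha * par
  if (ai == 0 || jmax <= 0) return(0)
  if (theta == 0) return(ai * jmax / (ai + jmax))
  b <- ai + jmax
  disc <- b * b - 4 * theta * ai * jmax
  disc <- max(disc, 0)
  (b - sqrt(disc)) / (2 * theta)
}

# Arrhenius-scale the full FvCB parameter set to leaf temperature
scaled_fvcb_params <- function(params, t_leaf) {
  ea <- params$ea
  list(
    vcmax = arrhenius_scale(params$vcmax25, ea$vcmax, t_leaf),
    jmax = arrhenius_scale(params$jmax25, ea$jmax, t_leaf),
    tpu = arrhenius_scale(params$tpu25, ea$tpu, t_leaf),
    rd = arrhenius_scale(params$rd25, ea$rd, t_leaf),
    kc = arrhenius_scale(params$kc25, ea$kc, t_leaf),
    ko = arrhenius_scale(params$ko25, ea$ko, t_leaf),
    gamma_star = arrhenius_scale(params$gamma_star25, ea$gamma_star, t_leaf)
  )
}

#' FvCB net assimilation at a given intercellular CO2
#'
#' Net CO2 assimilation as the minimum of the Rubisco-limited, electron
#' transport-limited, and triose-phosphate-limited rates minus day
#' respiration, with all kinetic parameters Arrhenius-scaled to leaf
#' temperature:
#' \deqn{A_c = V_{cmax}\frac{C_i - \Gamma^*}{C_i + K_c(1 + O/K_o)},\quad
#'       A_j = J\frac{C_i - \Gamma^*}{4C_i + 8\Gamma^*},\quad A_p = 3\,TPU}
#'
#' @param ci Intercellular CO2 mole fraction, umol mol-1 (> 0).
#' @param par Absorbed PAR, umol m-2 s-1.
#' @param t_leaf Leaf temperature, degC.
#' @param params Gas exchange parameter block
#'   (see `default_config()$gas_exchange`).
#' @return List with `a_net`, `a_gross` (the limiting gross rate), `rd`, and
#'   `limitation` in `rubisco`, `electron_transport`, `tpu`, or `dark`.
#' @export
net_assimilation_at_ci <- function(ci, par, t_leaf, params) {
  if (ci <= 0) stop_wgdt("ci must be > 0")
  sp <- scaled_fvcb_params(params, t_leaf)
  ac <- sp$vcmax * (ci - sp$gamma_star) /
    (ci + sp$kc * (1 + params$o2 / sp$ko))
  j <- electron_transport(par, sp$jmax, params$alpha, params$theta)
  aj <- j * (ci - sp$gamma_star) / (4 * ci + 8 * sp$gamma_star)
  ap <- 3 * sp$tpu
  rates <- c(rubisco = ac, electron_transport = aj, tpu = ap)
  lim <- names(rates)[which.min(rates)]
  a_gross <- min(rates)
  if (par <= 0) lim <- "dark"
  list(a_net = a_gross - sp$rd, a_gross = a_gross, rd = sp$rd,
       limitation = lim)
}

#' Ball-Woodrow-Berry stomatal conductance
#'
#' Empirical linear conductance response,
#' \eqn{g_s = g_0 + g_1 \max(A_n, 0)\, h_s / c_s}. The assimilation term is
#' clamped at zero so that nocturnal (negative) assimilation returns the
#' residual conductance `g0` rather than values below it.
#'
#' @param a_net Net assimilation, umol m-2 s-1.
#' @param rel_humidity Relative humidity at the leaf surface, fraction.
#' @param cs CO2 mole fraction at the leaf surface, umol mol-1 (> 0).
#' @param g0 Residual conductance, mol m-2 s-1.
#' @param g1 Slope, dimensionless.
#' @return Stomatal conductance to CO2, mol m-2 s-1 (>= g0).
#' @export
stomatal_conductance <- function(a_net, rel_humidity, cs, g0, g1) {
  if (cs <= 0) stop_wgdt("cs must be > 0")
  g0 + g1 * max(a_net, 0) * rel_humidity / cs
}

# saturation vapor pressure, kPa (Tetens)
svp_kpa <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

#' Coupled FvCB-BWB leaf gas exchange
#'
#' Solves for the intercellular CO2 concentration that simultaneously
#' satisfies the FvCB biochemistry and the diffusion constraint
#' \eqn{C_i = C_a - 1.6 A_n / g_s} with `gs` from the BWB relation, by
#' bisection on \eqn{C_i \in (\Gamma^*, C_a]}. Boundary-layer conductance is
#' omitted (`cs = ca`, `hs` = air relative humidity). Stress-driven source
#' downregulation scales `Vcmax`, `Jmax` and `TPU` by `1 - downregulation`;
#' at full downregulation (or in darkness) the dark solution
#' `a_net = -Rd, gs = g0` is returned. Transpiration is the water-vapor
#' diffusion flux `1.6 gs x VPD / P`.
#'
#' @param env Environment-day list with `par`, `t_leaf`, `t_air`,
#'   `rel_humidity`, `ca`.
#' @param params Gas exchange parameter block.
#' @param downregulation Fraction in `[0, 1]` by which photosynthetic
#'   capacities are scaled down.
#' @param tol Bisection tolerance on ci, umol mol-1.
#' @return List with `a_net`, `a_gross`, `rd`, `gs`, `ci`, `e_transp`
#'   (mmol H2O m-2 s-1) and `limitation`.
#' @export
solve_gas_exchange <- function(env, params, downregulation = 0,
                               tol = 1e-6) {
  downregulation <- clamp(downregulation, 0, 1)
  eff <- params
  eff$vcmax25 <- params$vcmax25 * (1 - downregulation)
  eff$jmax25 <- params$jmax25 * (1 - downregulation)
  eff$tpu25 <- params$tpu25 * (1 - downregulation)

  sp <- scaled_fvcb_params(eff, env$t_leaf)
  vpd <- max(0, svp_kpa(env$t_leaf) - env$rel_humidity * svp_kpa(env$t_air))

  dark_solution <- function(limitation) {
    a_net <- -sp$rd
    gs <- stomatal_conductance(a_net, env$rel_humidity, env$ca,
                               params$g0, params$g1)
    ci <- env$ca - 1.6 * a_net / gs
    list(a_net = a_net, a_gross = 0, rd = sp$rd, gs = gs, ci = ci,
         e_transp = 1.6 * gs * vpd / 101.325 * 1000, limitation = limitation)
  }

  if (env$par <= 0) return(dark_solution("dark"))
  if (downregulation >= 1 || sp$vcmax <= 0) return(dark_solution("dark"))

  resid <- function(ci) {
    a <- net_assimilation_at_ci(ci, env$par, env$t_leaf, eff)
    gs <- stomatal_conductance(a$a_net, env$rel_humidity, env$ca,
                               params$g0, params$g1)
    env$ca - 1.6 * a$a_net / gs - ci
  }

  lo <- sp$gamma_star * (1 + 1e-9)
  hi <- env$ca
  flo <- resid(lo)
  fhi <- resid(hi)
  if (flo < 0 || fhi > 0) {
    if (fhi > 0) {
      # assimilation negative over the whole bracket: settle at the boundary
      ci <- hi
    } else {
      stop_wgdt(sprintf(
        "gas exchange solver: no sign change on [%g, %g] (f = %g, %g)",
        lo, hi, flo, fhi), class = "wgdt_solver_error")
    }
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (resid(mid) >= 0) lo <- mid else hi <- mid
    }
    ci <- (lo + hi) / 2
  }

  a <- net_assimilation_at_ci(ci, env$par, env$t_leaf, eff)
  gs <- stomatal_conductance(a$a_net, env$rel_humidity, env$ca,
                             params$g0, params$g1)
  list(a_net = a$a_net, a_gross = a$a_gross, rd = a$rd, gs = gs, ci = ci,
       e_transp = 1.6 * gs * vpd / 101.325 * 1000, limitation = a$limitation)
}
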