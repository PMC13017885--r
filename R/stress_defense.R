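#' Local stress signal from measurable proxies
#'
#' Aggregates normalized molecular stress indicators (hormone concentrations,
#' transcriptional markers, NIRS-derived metabolite scores, each scaled to
#' `[0, 1]`) into a single dimensionless organ stress signal `s0` as their
#' weight-normalized mean, clamped to `[0, 1]`.
#'
#' @param values Named numeric vector of proxy values in `[0, 1]`.
#' @param weights Named numeric vector of non-negative weights (same names).
#' @return `s0` in `[0, 1]`.
#' @export
stress_signal_from_proxies <- function(values, weights) {
  values <- unlist(values); weights <- unlist(weights)
  if (length(values) == 0) stop_wgdt("no proxies supplied")
  if (any(weights < 0)) stop_wgdt("proxy weights must be >= 0")
  w <- weights[names(values)]
  if (any(is.na(w))) stop_wgdt("every proxy needs a weight")
  if (sum(w) <= 0) stop_wgdt("at least one proxy weight must be positive")
  clamp(sum(w * values) / sum(w), 0, 1)
}

#' Combine two stress signals
#'
#' Composition rules for co-occurring stress signals (e.g. the abiotic and
#' biotic signal on one organ):
#' * `additive`: \eqn{\min(s_a + s_b, 1)}
#' * `surface`: \eqn{\min(s_a + s_b + \gamma s_a s_b, 1)} - an interaction
#'   response surface; `gamma > 0` synergistic, `gamma < 0` antagonistic
#' * `dominance`: \eqn{\max(s_a, s_b)} - the most limiting stress governs
#'
#' @param s_a,s_b Signals in `[0, 1]`.
#' @param mode One of `"additive"`, `"surface"`, `"dominance"`.
#' @param gamma Interaction coefficient (surface mode only).
#' @return Combined signal in `[0, 1]`.
#' @export
combine_stress_signals <- function(s_a, s_b, mode = "additive", gamma = 0) {
  stopifnot(s_a >= 0, s_a <= 1, s_b >= 0, s_b <= 1)
  out <- switch(mode,
    additive = s_a + s_b,
    surface = s_a + s_b + gamma * s_a * s_b,
    dominance = max(s_a, s_b),
    stop_wgdt("unknown stress combination mode: ", mode,
              class = "wgdt_config_error")
  )
  clamp(out, 0, 1)
}

#' Defense dose-response
#'
#' Target defense activation for a given stress signal, a Hill (sigmoidal /
#' hyperbolic) dose-response saturating at `d_max`:
#' \deqn{d_{target} = d_{max}\, s_0^h / (s_{50}^h + s_0^h)}
#' In `categorical3` mode the continuous value is snapped to the three
#' activation states `{0, d_max/2, d_max}` by terciles of `d_max` (a
#' calibration convenience for low/moderate/high defense states).
#'
#' @param s0 Stress signal in `[0, 1]`.
#' @param params Defense parameter block (see `default_config()$defense`).
#' @return Target defense coefficient in `[0, d_max]`.
#' @export
defense_dose_response <- function(s0, params) {
  stopifnot(s0 >= 0, s0 <= 1)
  if (s0 == 0) return(0)
  d <- params$d_max * s0^params$hill_h /
    (params$s50^params$hill_h + s0^params$hill_h)
  if (identical(params$mode, "categorical3")) {
    d <- if (d < params$d_max / 3) 0
         else if (d < 2 * params$d_max / 3) params$d_max / 2
         else params$d_max
  }
  d
}

#' First-order defense coefficient dynamics
#'
#' Relaxation of the defense coefficient toward its dose-response target with
#' asymmetric rates: induction at `k_induction` while the target exceeds the
#' current state, relaxation at `k_relaxation` during decline. Over one step,
#' \deqn{d' = d + (1 - e^{-k\,dt}) (d_{target} - d)}
#' clamped to `[0, 1]`. The asymmetry (`k_relaxation < k_induction` by
#' default) produces hysteresis and priming-like behaviour: residual
#' activation after a first stress pulse lets a second pulse reach a given
#' level sooner.
#'
#' @param d Current defense coefficient in `[0, 1]`.
#' @param d_target Target from [defense_dose_response()].
#' @param params Defense parameter block.
#' @param dt Time step, days.
#' @return Updated defense coefficient.
#' @export
update_defense_coefficient <- function(d, d_target, params, dt = 1) {
  stopifnot(d >= 0, d <= 1, d_target >= 0, d_target <= 1)
  k <- if (d_target > d) params$k_induction else params$k_relaxation
  clamp(d + (1 - exp(-k * dt)) * (d_target - d), 0, 1)
}

# simulate a D trajectory for a given stress series (days of constant s0
# within each step); used by the recovery routine and tests
simulate_defense_series <- function(s_series, params, d0 = 0) {
  d <- numeric(length(s_series))
  cur <- d0
  for (i in seq_along(s_series)) {
    tgt <- defense_dose_response(s_series[i], params)
    cur <- update_defense_coefficient(cur, tgt, params)
    d[i] <- cur
  }
  d
}

#' Recover defense parameters from an observed activation time series
#'
#' Two-stage grid search estimating `(s50, k_induction)` from a noisy defense
#' coefficient time series recorded under a known stress schedule, by
#' minimizing the sum of squared errors between the observed series and
#' simulated first-order Hill dynamics. A coarse grid is refined once around
#' its minimum.
#'
#' @param d_obs Observed defense coefficient series.
#' @param s_series Stress signal series driving it (same length).
#' @param params Defense parameter block supplying the fixed parameters
#'   (`d_max`, `hill_h`, `k_relaxation`).
#' @param s50_range,k_range Search intervals.
#' @param n_grid Grid points per dimension and stage.
#' @return List with `s50`, `k_induction` and the achieved `sse`.
#' @export
recover_defense_params <- function(d_obs, s_series, params,
                                   s50_range = c(0.05, 0.95),
                                   k_range = c(0.05, 2),
                                   n_grid = 25) {
  stopifnot(length(d_obs) == length(s_series))
  sse <- function(s50, k) {
    p <- params
    p$s50 <- s50
    p$k_induction <- k
    sum((simulate_defense_series(s_series, p) - d_obs)^2)
  }
  search <- function(s50s, ks) {
    grid <- expand.grid(s50 = s50s, k = ks)
    err <- mapply(sse, grid$s50, grid$k)
    grid[which.min(err), , drop = FALSE]
  }
  best <- search(seq(s50_range[1], s50_range[2], length.out = n_grid),
                 seq(k_range[1], k_range[2], length.out = n_grid))
  step_s <- diff(s50_range) / (n_grid - 1)
  step_k <- diff(k_range) / (n_grid - 1)
  best <- search(
    seq(max(s50_range[1], best$s50 - step_s),
        min(s50_range[2], best$s50 + step_s), length.out = n_grid),
    seq(max(k_range[1], best$k - step_k),
        min(k_range[2], best$k + step_k), length.out = n_grid))
  list(s50 = best$s50, k_induction = best$k,
       sse = sse(best$s50, best$k))
}

# aggregate an organ's per-stressor intensities into the local signal s0:
# same-class stressors combine by maximum, classes by the configured rule
organ_stress_signal <- function(intensities, classes, mode, gamma) {
  if (length(intensities) == 0) return(0)
  cls <- classes[names(intensities)]
  s_abiotic <- if (any(cls == "abiotic")) max(intensities[cls == "abiotic"]) else 0
  s_biotic <- if (any(cls == "biotic")) max(intensities[cls == "biotic"]) else 0
  combine_stress_signals(s_abiotic, s_biotic, mode, gamma)
}
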