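#' Generate a synthetic daily weather series
#'
#' Produces daily environmental drivers for the simulator: a sinusoidal
#' seasonal course with seeded Gaussian noise for air temperature and PAR
#' (clipped at zero), AR(1) relative humidity clamped to `[0, 1]`, constant
#' atmospheric CO2, and a constant or linearly depleting soil nitrate
#' concentration. With all noise amplitudes set to zero the series equals the
#' closed-form seasonal curves
#' \deqn{T(d) = T_{mean} + T_{amp} \sin(\pi d / n_{season}),\quad
#'       PAR(d) = \max(0, PAR_{mean} + PAR_{amp} \sin(\pi d / n_{season}))}
#' for day index `d = 0, ..., n_days - 1`.
#'
#' @param n_days Number of days to generate (>= 1).
#' @param seed Integer RNG seed; the series is deterministic given the seed.
#' @param params Weather parameter block (see `default_config()$weather`).
#' @return A data.frame with one row per day and columns `day`, `par`,
#'   `t_air`, `t_leaf`, `rel_humidity`, `ca`, `soil_no3`.
#' @export
generate_weather <- function(n_days, seed = 1L,
                             params = default_config()$weather) {
  if (!is.numeric(n_days) || length(n_days) != 1 || n_days < 1) {
    stop_wgdt("n_days must be a positive number")
  }
  n_days <- as.integer(n_days)
  p <- deep_merge(default_config()$weather, params)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  d <- seq_len(n_days) - 1L
  phase <- sin(pi * d / p$season_days)

  t_air <- p$t_mean + p$t_amp * phase +
    if (p$t_noise_sd > 0) stats::rnorm(n_days, 0, p$t_noise_sd) else 0
  par <- pmax(0, p$par_mean + p$par_amp * phase +
                if (p$par_noise_sd > 0) stats::rnorm(n_days, 0, p$par_noise_sd) else 0)

  rh <- numeric(n_days)
  eps <- if (p$rh_noise_sd > 0) stats::rnorm(n_days, 0, p$rh_noise_sd) else numeric(n_days)
  prev <- p$rh_mean
  for (i in seq_len(n_days)) {
    prev <- clamp(p$rh_mean + p$rh_ar1 * (prev - p$rh_mean) + eps[i], 0, 1)
    rh[i] <- prev
  }

  soil_no3 <- pmax(0, p$no3_init + p$no3_slope * d)

  data.frame(
    day = d,
    par = par,
    t_air = t_air,
    t_leaf = t_air + p$t_leaf_offset,
    rel_humidity = rh,
    ca = rep(p$ca, n_days),
    soil_no3 = soil_no3
  )
}

#' Declare a stress event
#'
#' A stress event applies a trapezoidal intensity profile (linear ramp up over
#' `ramp_days`, plateau at `peak_intensity`, linear ramp down) to a set of
#' target organs between `start_day` and `end_day` (inclusive, 0-based day
#' index). Abiotic stressors target all organs by default; biotic events must
#' name their target organs (a local infection).
#'
#' @param stressor Free-form stressor label (e.g. "heat", "rust").
#' @param class Either "abiotic" or "biotic".
#' @param start_day,end_day First and last day of the event (0-based).
#' @param peak_intensity Plateau intensity in `[0, 1]`.
#' @param ramp_days Length of the linear ramps, days (>= 0).
#' @param target_organs Character vector of organ kinds; defaults to all
#'   organs for abiotic stressors and is required for biotic ones.
#' @return A `stress_event` list.
#' @export
stress_event <- function(stressor, class = c("abiotic", "biotic"),
                         start_day, end_day, peak_intensity,
                         ramp_days = 0L, target_organs = NULL) {
  class <- match.arg(class)
  if (is.null(target_organs)) {
    if (class == "biotic") {
      stop_wgdt("biotic stress events must name their target organs")
    }
    target_organs <- organ_kinds()
  }
  if (!all(target_organs %in% organ_kinds())) {
    stop_wgdt("unknown organ kind in target_organs: ",
              paste(setdiff(target_organs, organ_kinds()), collapse = ", "))
  }
  if (start_day > end_day) stop_wgdt("start_day must be <= end_day")
  if (peak_intensity < 0 || peak_intensity > 1) {
    stop_wgdt("peak_intensity must be in [0, 1]")
  }
  if (ramp_days < 0) stop_wgdt("ramp_days must be >= 0")
  structure(list(
    stressor = stressor, class = class,
    target_organs = target_organs,
    start_day = as.integer(start_day), end_day = as.integer(end_day),
    peak_intensity = peak_intensity, ramp_days = as.integer(ramp_days)
  ), class = "stress_event")
}

# trapezoid intensity of one event on one day: linear ramp up over ramp_days
# from start_day, plateau through end_day, linear ramp down after end_day
event_intensity <- function(event, day) {
  r <- event$ramp_days
  if (day < event$start_day || day > event$end_day + r) return(0)
  if (day <= event$end_day) {
    up <- if (r > 0) min(1, (day - event$start_day) / r) else 1
    return(clamp(event$peak_intensity * up, 0, 1))
  }
  clamp(event$peak_intensity * (1 - (day - event$end_day) / r), 0, 1)
}

#' Expand stress events into per-day, per-organ stress inputs
#'
#' Evaluates the trapezoid profile of every event on every day. Overlapping
#' events with the same stressor label combine by maximum; organs not targeted
#' receive zero. The expansion is idempotent: the same events always yield the
#' same inputs.
#'
#' @param events List of [stress_event()] objects.
#' @param n_days Simulation horizon; all events must fall inside `[0, n_days)`.
#' @return A list with `inputs` (length `n_days`; each element a per-organ
#'   named list of stressor -> intensity vectors) and `classes` (named
#'   character vector stressor -> class).
#' @export
apply_stress_schedule <- function(events, n_days) {
  n_days <- as.integer(n_days)
  classes <- character()
  for (ev in events) {
    if (!inherits(ev, "stress_event")) {
      stop_wgdt("all events must be created with stress_event()")
    }
    if (ev$start_day < 0 || ev$end_day >= n_days) {
      stop_wgdt(sprintf("event '%s' (days %d-%d) lies outside the horizon [0, %d)",
                        ev$stressor, ev$start_day, ev$end_day, n_days))
    }
    if (!is.null(classes[ev$stressor]) && !is.na(classes[ev$stressor]) &&
        classes[ev$stressor] != ev$class) {
      stop_wgdt("stressor '", ev$stressor, "' declared with two classes")
    }
    classes[ev$stressor] <- ev$class
  }
  empty <- stats::setNames(
    rep(list(stats::setNames(numeric(0), character(0))), length(organ_kinds())),
    organ_kinds())
  inputs <- rep(list(empty), n_days)
  for (ev in events) {
    last <- min(ev$end_day + ev$ramp_days, n_days - 1L)
    for (day in ev$start_day:last) {
      inten <- event_intensity(ev, day)
      if (inten <= 0) next
      for (k in ev$target_organs) {
        cur <- inputs[[day + 1L]][[k]]
        cur[ev$stressor] <- max(inten, cur[ev$stressor] %|NA|% 0)
        inputs[[day + 1L]][[k]] <- cur
      }
    }
  }
  list(inputs = inputs, classes = classes)
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Build the full environment series for a configuration
#'
#' Combines the seeded weather generator with the expanded stress schedule of
#' the configured events.
#'
#' @param config A `wgdt_config` (see [default_config()]).
#' @return An `environment_series` list with elements `weather` (data.frame),
#'   `stress` (per-day inputs) and `stress_classes`.
#' @export
make_environment <- function(config) {
  n <- as.integer(config$horizon_days)
  weather <- generate_weather(max(n, 1L), seed = config$seed,
                              params = config$weather)
  sched <- apply_stress_schedule(config$stress_events, max(n, 1L))
  structure(list(weather = weather, stress = sched$inputs,
                 stress_classes = sched$classes),
            class = "environment_series")
}

# assemble the EnvironmentDay view used by step()
environment_day <- function(env_series, day) {
  w <- env_series$weather[day + 1L, ]
  list(day = day, par = w$par, t_air = w$t_air, t_leaf = w$t_leaf,
       rel_humidity = w$rel_humidity, ca = w$ca, soil_no3 = w$soil_no3,
       stress_inputs = env_series$stress[[day + 1L]],
       stress_classes = env_series$stress_classes)
}

#' @export
print.environment_series <- function(x, ...) {
  cat(sprintf("<environment_series> %d days, %d stressor(s)\n",
              nrow(x$weather), length(x$stress_classes)))
  invisible(x)
}
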