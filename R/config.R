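#' Default simulation configuration
#'
#' Returns the complete default scenario configuration: a single spring-wheat
#' plant followed for 150 days at a daily time step, with anthesis at day 80.
#' All parameter blocks (gas exchange, nitrate uptake, respiration, defense
#' dynamics, stoichiometry, allocation, weather generator) are filled with the
#' default genotype values; user configs override any subset of keys (see
#' [parse_config()]).
#'
#' Units: whole-plant C and N budgets are in grams per plant per day;
#' leaf-level assimilation in umol CO2 m-2 s-1 is integrated over
#' `daylight_hours` and leaf area (mass x SLA) at 12e-6 g C per umol.
#'
#' @return A nested list with class `wgdt_config`.
#' @export
default_config <- function() {
  cfg <- list(
    horizon_days = 150L,
    seed = 1L,
    anthesis_day = 80L,
    daylight_hours = 12,
    defense_enabled = TRUE,
    # optional clamp of the defense coefficient, e.g. for calibration runs:
    # list(kinds = "mature_leaf", value = 1, start_day = 60, end_day = 79)
    force_d = NULL,
    combination = list(mode = "surface", gamma = 0),
    pool = list(carbon = 0.05, nitrogen = 0.005),
    organs = list(
      roots          = list(mass = 0.30, c_store = 0.030, n_store = 0.0100),
      senescent_leaf = list(mass = 0.05, c_store = 0.005, n_store = 0.0030),
      mature_leaf    = list(mass = 0.40, c_store = 0.040, n_store = 0.0130),
      growing_leaf   = list(mass = 0.15, c_store = 0.015, n_store = 0.0050),
      emerging_leaf  = list(mass = 0.05, c_store = 0.005, n_store = 0.0017),
      grain          = list(mass = 0.00, c_store = 0.000, n_store = 0.0000)
    ),
    # specific leaf area, m2 per g DM
    sla = list(senescent_leaf = 0.020, mature_leaf = 0.025,
               growing_leaf = 0.025, emerging_leaf = 0.030),
    gas_exchange = list(
      vcmax25 = 90, jmax25 = 170, tpu25 = 11, rd25 = 1.0,
      kc25 = 404.9, ko25 = 278.4, gamma_star25 = 42.75, o2 = 210,
      ea = list(vcmax = 65330, jmax = 43540, tpu = 53100, rd = 46390,
                kc = 79430, ko = 36380, gamma_star = 37830),
      alpha = 0.3, theta = 0.9, g0 = 0.01, g1 = 9
    ),
    uptake = list(
      vmax_hats = 0.015,  # g N g-1 root d-1
      km_hats = 0.1,      # mol m-3
      k_lats = 0.002,     # g N g-1 root d-1 per (mol m-3)
      lats_threshold = 0, # mol m-3; linear LATS already vanishes at low NO3
      c_reg_k = 0.05,     # g C g-1 root, half-saturation of C regulation
      f_min = 0.2
    ),
    respiration = list(
      growth_yield = 0.75,
      q10 = 2, t_ref = 25,
      m_base = list(roots = 0.010, senescent_leaf = 0.004, mature_leaf = 0.012,
                    growing_leaf = 0.012, emerging_leaf = 0.012, grain = 0.006),
      c_defense = 0.012,      # g C g-1 DM d-1 at D = 1 (defense respiration)
      process_costs = list()  # optional "general paradigm" itemization
    ),
    defense = list(
      d_max = 1, s50 = 0.4, hill_h = 2,
      k_induction = 0.5, k_relaxation = 0.2,   # d-1; asymmetry => hysteresis
      mode = "continuous", genotype_id = "default",
      s_def_rate = 0.012,       # g defense compound g-1 DM d-1 at D = 1
      compound_c_frac = 0.60,   # g C retained per g defense compound
      protein_c_frac = 0.53     # g C per g protein (so N = 0.53/3.5 ~ 15%)
    ),
    stoichiometry = list(
      c_per_g_dm = list(roots = 0.45, senescent_leaf = 0.45, mature_leaf = 0.45,
                        growing_leaf = 0.45, emerging_leaf = 0.45, grain = 0.44),
      tissue_cn = list(roots = 25, senescent_leaf = 12.5, mature_leaf = 12.5,
                       growing_leaf = 12.5, emerging_leaf = 12.5, grain = 18),
      protein_cn = 3.5,
      phenolic_glucose_cost = 2.5,   # g glucose equivalents per g compound
      defense_protein_fraction = 0.3
    ),
    allocation = list(
      beta_stress = 0.5,  # priority boost per unit s0
      sigma_max = 0.5,    # max stress-driven source downregulation
      priorities = list(
        vegetative = list(roots = 1.0, senescent_leaf = 0.2, mature_leaf = 0.6,
                          growing_leaf = 1.0, emerging_leaf = 1.0, grain = 0),
        reproductive = list(roots = 0.4, senescent_leaf = 0.2, mature_leaf = 0.5,
                            growing_leaf = 0.4, emerging_leaf = 0.3, grain = 2.0)
      ),
      # potential relative growth rate, g DM g-1 d-1 at sink-strength peak
      # potential growth is kept generous relative to carbon supply so that
      # realized growth is source-limited, as in field-grown cereals
      g_pot = list(roots = 0.06, senescent_leaf = 0, mature_leaf = 0,
                   growing_leaf = 0.08, emerging_leaf = 0.09, grain = 0.30),
      # reference mass floor so zero-mass organs (grain at anthesis) can start
      m_ref = list(roots = 0, senescent_leaf = 0, mature_leaf = 0,
                   growing_leaf = 0, emerging_leaf = 0, grain = 0.1),
      # beta-shaped sink strength over organ age (grain age counts from
      # anthesis); f(x) = x^(a-1)(1-x)^(b-1) normalized to peak 1
      sink_beta = list(
        roots         = list(t0 = 0, t1 = 80, a = 1.0, b = 2.0),
        growing_leaf  = list(t0 = 0, t1 = 45, a = 2.0, b = 2.5),
        emerging_leaf = list(t0 = 0, t1 = 55, a = 2.0, b = 2.0),
        grain         = list(t0 = 0, t1 = 55, a = 2.0, b = 2.0)
      )
    ),
    remobilization = list(r_c = 0.01, r_n = 0.02, a_sen = 1),
    weather = list(
      season_days = 150,
      par_mean = 900, par_amp = 300, par_noise_sd = 120,  # umol m-2 s-1
      t_mean = 16, t_amp = 6, t_noise_sd = 1.5,           # deg C
      t_leaf_offset = 0,
      rh_mean = 0.65, rh_ar1 = 0.7, rh_noise_sd = 0.08,
      ca = 400,                                           # umol mol-1
      no3_init = 1.0, no3_slope = 0                       # mol m-3 (per day)
    ),
    stress_events = list(),
    output_dir = NULL
  )
  class(cfg) <- c("wgdt_config", "list")
  cfg
}

#' Read and validate a scenario configuration file
#'
#' Reads a YAML scenario file, fills every omitted key from
#' [default_config()], and validates all parameter ranges. Validation reports
#' every offending key path in a single error.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `wgdt_config` list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop_wgdt("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- deep_merge(default_config(), user)
  class(cfg) <- c("wgdt_config", "list")
  validate_config(cfg)
}

#' Validate a configuration
#'
#' Range-checks every parameter against the invariants of its owning block
#' and errors with the full list of offending key paths. In the default
#' genotype, leaf structural C:N outside the physiological 10-15 bracket or a
#' phenolic synthesis cost outside 2-3 g glucose per g raises a warning.
#'
#' @param config A `wgdt_config` list (see [default_config()]).
#' @return The validated config, invisibly classed.
#' @export
validate_config <- function(config) {
  errs <- character()
  bad <- function(cond, key, msg) {
    if (isTRUE(cond)) errs[[length(errs) + 1L]] <<- paste0(key, ": ", msg)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

  bad(!num1(config$horizon_days) || config$horizon_days < 0,
      "horizon_days", "must be a non-negative number")
  bad(!num1(config$anthesis_day) || config$anthesis_day < 0,
      "anthesis_day", "must be a non-negative day index")
  bad(!num1(config$daylight_hours) || config$daylight_hours <= 0 ||
        config$daylight_hours > 24, "daylight_hours", "must be in (0, 24]")
  bad(!num1(config$pool$carbon) || config$pool$carbon < 0,
      "pool.carbon", "must be >= 0")
  bad(!num1(config$pool$nitrogen) || config$pool$nitrogen < 0,
      "pool.nitrogen", "must be >= 0")

  for (k in organ_kinds()) {
    o <- config$organs[[k]]
    if (is.null(o)) {
      bad(TRUE, paste0("organs.", k), "missing organ entry")
      next
    }
    for (f in c("mass", "c_store", "n_store")) {
      bad(!num1(o[[f]]) || o[[f]] < 0,
          paste0("organs.", k, ".", f), "must be a number >= 0")
    }
  }

  gx <- config$gas_exchange
  for (f in c("vcmax25", "jmax25", "tpu25", "rd25", "kc25", "ko25",
              "gamma_star25", "o2", "alpha", "g1")) {
    bad(!num1(gx[[f]]) || gx[[f]] <= 0, paste0("gas_exchange.", f),
        "must be > 0")
  }
  bad(!num1(gx$g0) || gx$g0 < 0, "gas_exchange.g0", "must be >= 0")
  bad(!num1(gx$theta) || gx$theta < 0 || gx$theta > 1,
      "gas_exchange.theta", "must be in [0, 1]")

  up <- config$uptake
  bad(!num1(up$vmax_hats) || up$vmax_hats < 0, "uptake.vmax_hats", ">= 0")
  bad(!num1(up$km_hats) || up$km_hats <= 0, "uptake.km_hats", "must be > 0")
  bad(!num1(up$k_lats) || up$k_lats < 0, "uptake.k_lats", ">= 0")
  bad(!num1(up$f_min) || up$f_min < 0 || up$f_min > 1,
      "uptake.f_min", "must be in [0, 1]")

  rp <- config$respiration
  bad(!num1(rp$growth_yield) || rp$growth_yield <= 0 || rp$growth_yield > 1,
      "respiration.growth_yield", "must be in (0, 1]")
  bad(!num1(rp$q10) || rp$q10 <= 0, "respiration.q10", "must be > 0")
  bad(!num1(rp$c_defense) || rp$c_defense < 0, "respiration.c_defense", ">= 0")
  for (k in organ_kinds()) {
    bad(!num1(rp$m_base[[k]]) || rp$m_base[[k]] < 0,
        paste0("respiration.m_base.", k), ">= 0")
  }

  dp <- config$defense
  bad(!num1(dp$d_max) || dp$d_max <= 0 || dp$d_max > 1,
      "defense.d_max", "must be in (0, 1]")
  bad(!num1(dp$s50) || dp$s50 <= 0 || dp$s50 >= 1,
      "defense.s50", "must be in (0, 1)")
  bad(!num1(dp$hill_h) || dp$hill_h < 1, "defense.hill_h", "must be >= 1")
  bad(!num1(dp$k_induction) || dp$k_induction <= 0,
      "defense.k_induction", "must be > 0")
  bad(!num1(dp$k_relaxation) || dp$k_relaxation <= 0,
      "defense.k_relaxation", "must be > 0")
  bad(!dp$mode %in% c("continuous", "categorical3"),
      "defense.mode", "must be 'continuous' or 'categorical3'")
  bad(!num1(dp$s_def_rate) || dp$s_def_rate < 0, "defense.s_def_rate", ">= 0")

  st <- config$stoichiometry
  bad(!num1(st$protein_cn) || st$protein_cn <= 0,
      "stoichiometry.protein_cn", "must be > 0")
  bad(!num1(st$phenolic_glucose_cost) || st$phenolic_glucose_cost <= 0,
      "stoichiometry.phenolic_glucose_cost", "must be > 0")
  bad(!num1(st$defense_protein_fraction) || st$defense_protein_fraction < 0 ||
        st$defense_protein_fraction > 1,
      "stoichiometry.defense_protein_fraction", "must be in [0, 1]")
  # substrate C per g compound must cover the C retained in the compound
  if (num1(st$phenolic_glucose_cost) && num1(config$defense$compound_c_frac)) {
    bad(st$phenolic_glucose_cost * GLUCOSE_C_FRAC <
          config$defense$compound_c_frac,
        "stoichiometry.phenolic_glucose_cost",
        "glucose substrate C must be >= compound_c_frac")
  }
  for (k in organ_kinds()) {
    bad(!num1(st$tissue_cn[[k]]) || st$tissue_cn[[k]] <= 0,
        paste0("stoichiometry.tissue_cn.", k), "must be > 0")
    bad(!num1(st$c_per_g_dm[[k]]) || st$c_per_g_dm[[k]] <= 0 ||
          st$c_per_g_dm[[k]] > 1,
        paste0("stoichiometry.c_per_g_dm.", k), "must be in (0, 1]")
  }

  al <- config$allocation
  bad(!num1(al$beta_stress) || al$beta_stress < 0,
      "allocation.beta_stress", ">= 0")
  bad(!num1(al$sigma_max) || al$sigma_max < 0 || al$sigma_max > 1,
      "allocation.sigma_max", "must be in [0, 1]")
  for (stage in c("vegetative", "reproductive")) {
    pr <- al$priorities[[stage]]
    for (k in organ_kinds()) {
      bad(!num1(pr[[k]]) || pr[[k]] < 0,
          paste0("allocation.priorities.", stage, ".", k), ">= 0")
    }
    if (all(vapply(organ_kinds(), function(k) {
      num1(pr[[k]]) && pr[[k]] == 0
    }, logical(1)))) {
      bad(TRUE, paste0("allocation.priorities.", stage),
          "at least one priority must be positive")
    }
  }

  rm <- config$remobilization
  for (f in c("r_c", "r_n")) {
    bad(!num1(rm[[f]]) || rm[[f]] < 0 || rm[[f]] > 1,
        paste0("remobilization.", f), "must be in [0, 1]")
  }
  bad(!num1(rm$a_sen) || rm$a_sen < 0, "remobilization.a_sen", ">= 0")

  cm <- config$combination
  bad(!cm$mode %in% c("additive", "surface", "dominance"),
      "combination.mode", "must be additive, surface or dominance")
  bad(!num1(cm$gamma), "combination.gamma", "must be a number")

  if (length(errs)) {
    stop_wgdt("invalid configuration:\n  ",
              paste(errs, collapse = "\n  "),
              class = "wgdt_config_error")
  }

  if (identical(config$defense$genotype_id, "default")) {
    for (k in setdiff(leaf_kinds(), "senescent_leaf")) {
      cn <- st$tissue_cn[[k]]
      if (cn < 10 || cn > 15) {
        warning(sprintf(
          "stoichiometry.tissue_cn.%s = %g is outside the physiological 10-15 leaf C:N bracket",
          k, cn), call. = FALSE)
      }
    }
    if (st$phenolic_glucose_cost < 2 || st$phenolic_glucose_cost > 3) {
      warning(sprintf(
        "stoichiometry.phenolic_glucose_cost = %g is outside the 2-3 g glucose/g bracket",
        st$phenolic_glucose_cost), call. = FALSE)
    }
  }

  class(config) <- c("wgdt_config", "list")
  invisible(config)
}

#' @export
print.wgdt_config <- function(x, ...) {
  cat(sprintf(
    "<wgdt_config> genotype '%s': horizon %d d, anthesis day %d, seed %d, %d stress event(s)\n",
    x$defense$genotype_id, as.integer(x$horizon_days),
    as.integer(x$anthesis_day), as.integer(x$seed),
    length(x$stress_events)))
  invisible(x)
}
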