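#' Initialize the plant state
#'
#' Builds the six-organ plant state from a validated configuration: organs
#' with their configured structural masses and labile stores, zero stress
#' signals and defense coefficients, the common pool, day 0, and neutral
#' allocation directives.
#'
#' @param config A `wgdt_config` (validated; see [validate_config()]).
#' @return A `plant_state` list.
#' @export
initialize_plant <- function(config) {
  config <- validate_config(config)
  organs <- stats::setNames(lapply(organ_kinds(), function(k) {
    o <- config$organs[[k]]
    new_organ_state(k, o$mass, o$c_store, o$n_store)
  }), organ_kinds())
  zero <- stats::setNames(numeric(length(organ_kinds())), organ_kinds())
  structure(list(
    day = 0L,
    organs = organs,
    pool = list(carbon = config$pool$carbon, nitrogen = config$pool$nitrogen),
    stage = if (0 >= config$anthesis_day) "reproductive" else "vegetative",
    status = NULL,
    directives = structure(list(priority = zero + 1,
                                source_downregulation = zero,
                                stress_boost_beta = 0),
                           class = "allocation_directives")
  ), class = "plant_state")
}

#' Remobilization from the senescent leaf cohort
#'
#' Exports a fraction `r_C` of the labile carbon store and `r_N` of the
#' nitrogen store per day, accelerated by whole-plant stress:
#' `flux = min(1, r x (1 + a_sen x s_plant)) x store`. Structural mass is
#' unchanged (organ mortality is out of scope); stress-induced senescence is
#' represented only as accelerated remobilization.
#'
#' @param organ The senescent-leaf `organ_state`.
#' @param status A `plant_status` (uses `s_plant_mean`); `NULL` means no
#'   stress.
#' @param params Remobilization parameter block
#'   (see `default_config()$remobilization`).
#' @return List with `flux_c`, `flux_n` (g d-1) and the updated `organ`.
#' @export
remobilize_senescent <- function(organ, status, params) {
  if (organ$kind != "senescent_leaf") {
    stop_wgdt("remobilize_senescent needs the senescent_leaf organ")
  }
  s <- if (is.null(status)) 0 else status$s_plant_mean
  accel <- 1 + params$a_sen * s
  frac_c <- clamp(params$r_c * accel, 0, 1)
  frac_n <- clamp(params$r_n * accel, 0, 1)
  flux_c <- frac_c * organ$c_store
  flux_n <- frac_n * organ$n_store
  organ$c_store <- organ$c_store - flux_c
  organ$n_store <- organ$n_store - flux_n
  list(flux_c = flux_c, flux_n = flux_n, organ = organ)
}

# total C and N stocks of a plant state (pool + stores + structure + defense)
plant_totals <- function(plant, config) {
  st <- config$stoichiometry
  cc <- config$defense$compound_c_frac
  tc <- plant$pool$carbon
  tn <- plant$pool$nitrogen
  for (o in plant$organs) {
    cpg <- st$c_per_g_dm[[o$kind]]
    tc <- tc + o$c_store + o$structural_mass * cpg + o$defense_pool * cc
    tn <- tn + o$n_store + o$structural_mass * cpg / st$tissue_cn[[o$kind]] +
      o$defense_n
  }
  list(carbon = tc, nitrogen = tn)
}

check_finite <- function(x, phase, organ) {
  v <- unlist(x)
  v <- v[vapply(v, is.numeric, logical(1))]
  if (!all(is.finite(v))) {
    stop_wgdt(sprintf("non-finite value in phase %s (organ: %s)",
                      phase, organ), class = "wgdt_numerical_error")
  }
}

#' Advance the plant by one day
#'
#' Executes the three sub-daily phases of the discrete-time cycle:
#'
#' * Phase A (time t): leaf-level gas exchange for the photosynthetic leaves
#'   (with the source downregulation held in the current directives), root
#'   nitrate uptake, and the per-organ stress-signal and defense-coefficient
#'   update.
#' * Phase B (t + delta): transfer of newly assimilated C and absorbed N to
#'   the common pool, remobilization from the senescent cohort, and
#'   integration of the organ signals into the plant status and the new
#'   allocation directives.
#' * Phase C (t + 1): pool allocation across organs, within-organ
#'   maintenance-first partition into maintenance, defense and growth,
#'   respiration debits, structural growth, and return of unused resources
#'   to the pool.
#'
#' The phases run sequentially within one daily update; the sub-daily
#' instants order information flow, not real durations.
#'
#' @param plant A `plant_state`.
#' @param env An environment-day list (see [make_environment()]).
#' @param config A `wgdt_config`.
#' @return List with the updated `plant` and a `record` (list `plant_row`,
#'   `organ_rows`) holding every state and flux of the day.
#' @export
step <- function(plant, env, config) {
  kinds <- organ_kinds()
  directives <- plant$directives
  cm <- config$combination
  daylight_s <- config$daylight_hours * 3600
  day <- plant$day

  ## --- Phase A: sources and signals at time t -------------------------
  assim_c <- stats::setNames(numeric(length(kinds)), kinds)
  rd_c <- assim_c
  gx_diag <- list()
  for (k in photosynthetic_kinds()) {
    organ <- plant$organs[[k]]
    area <- organ_area(organ, config$sla)
    if (area <= 0) next
    gx <- solve_gas_exchange(env, config$gas_exchange,
                             directives$source_downregulation[[k]])
    check_finite(gx, "A (gas exchange)", k)
    conv <- area * daylight_s * C_PER_UMOL
    assim_c[k] <- gx$a_gross * conv
    rd_c[k] <- gx$rd * conv
    gx_diag[[k]] <- gx
  }

  n_uptake <- organ_nitrogen_uptake(
    plant$organs$roots, env, config$uptake,
    directives$source_downregulation[["roots"]])
  check_finite(n_uptake, "A (N uptake)", "roots")

  for (k in kinds) {
    organ <- plant$organs[[k]]
    s0 <- organ_stress_signal(env$stress_inputs[[k]], env$stress_classes,
                              cm$mode, cm$gamma)
    organ$s0 <- s0
    if (isTRUE(config$defense_enabled)) {
      d_target <- defense_dose_response(s0, config$defense)
      organ$d_coef <- update_defense_coefficient(organ$d_coef, d_target,
                                                 config$defense)
      fd <- config$force_d
      if (!is.null(fd) && k %in% fd$kinds &&
          day >= fd$start_day && day <= fd$end_day) {
        organ$d_coef <- clamp(fd$value, 0, 1)
      }
    } else {
      organ$d_coef <- 0
    }
    check_finite(organ[c("s0", "d_coef")], "A (stress update)", k)
    plant$organs[[k]] <- organ
  }

  ## --- Phase B: pooling and integration at t + delta ------------------
  plant$pool$carbon <- plant$pool$carbon + sum(assim_c)
  plant$pool$nitrogen <- plant$pool$nitrogen + n_uptake

  # leaf dark respiration is paid from the pool the new assimilate entered,
  # falling back on the leaf's own labile store; unpayable Rd is logged as a
  # deficit (the organ does not die: mortality is out of scope)
  rd_unpaid_total <- 0
  for (k in photosynthetic_kinds()) {
    rd_need <- rd_c[[k]]
    if (rd_need <= 0) next
    pay_pool <- min(plant$pool$carbon, rd_need)
    plant$pool$carbon <- plant$pool$carbon - pay_pool
    rem <- rd_need - pay_pool
    pay_store <- min(plant$organs[[k]]$c_store, rem)
    plant$organs[[k]]$c_store <- plant$organs[[k]]$c_store - pay_store
    unpaid <- rem - pay_store
    rd_c[k] <- pay_pool + pay_store
    if (unpaid > 0) {
      plant$organs[[k]]$deficit_cum <- plant$organs[[k]]$deficit_cum + unpaid
      rd_unpaid_total <- rd_unpaid_total + unpaid
    }
  }

  plant$stage <- if (day >= config$anthesis_day) "reproductive" else "vegetative"
  status <- integrate_plant_status(plant$organs, plant$pool, plant$stage)

  remob <- remobilize_senescent(plant$organs$senescent_leaf, status,
                                config$remobilization)
  plant$organs$senescent_leaf <- remob$organ
  plant$pool$carbon <- plant$pool$carbon + remob$flux_c
  plant$pool$nitrogen <- plant$pool$nitrogen + remob$flux_n

  directives_new <- compute_directives(status, config)
  check_finite(directives_new$priority, "B (integration)", "plant")

  ## --- Phase C: allocation and partition at t + 1 ---------------------
  demands <- stats::setNames(lapply(kinds, function(k) {
    organ_demand(plant$organs[[k]], config, env$t_air, day)
  }), kinds)
  alloc <- allocate_pool(plant$pool, demands, directives_new)
  plant$pool <- alloc$pool

  organ_rows <- vector("list", length(kinds))
  returned_c_total <- 0
  returned_n_total <- 0
  sums <- list(maint_basal = 0, maint_defense = 0, growth_resp = 0,
               def_resp = 0, deficit = 0)
  for (i in seq_along(kinds)) {
    k <- kinds[i]
    organ <- plant$organs[[k]]
    del <- alloc$deliveries[[k]]
    part <- partition_within_organ(del$c, del$n, organ, demands[[k]], config)
    check_finite(part[c("maint_respired", "returned_c", "returned_n")],
                 "C (partition)", k)

    organ$c_store <- organ$c_store - part$store_draw
    organ$structural_mass <- organ$structural_mass + part$growth$delta_mass
    organ$defense_pool <- organ$defense_pool + part$def_mass
    organ$defense_n <- organ$defense_n + part$def_n_used
    organ$maintenance_deficit <- part$deficit > 0
    organ$deficit_cum <- organ$deficit_cum + part$deficit
    plant$organs[[k]] <- organ

    returned_c_total <- returned_c_total + part$returned_c
    returned_n_total <- returned_n_total + part$returned_n
    sums$maint_basal <- sums$maint_basal + part$maint_basal
    sums$maint_defense <- sums$maint_defense + part$maint_defense
    sums$growth_resp <- sums$growth_resp + part$growth$c_respired
    sums$def_resp <- sums$def_resp + part$def_c_respired
    sums$deficit <- sums$deficit + part$deficit

    organ_rows[[i]] <- data.frame(
      day = day + 1L, organ = k,
      mass = organ$structural_mass, c_store = organ$c_store,
      n_store = organ$n_store, defense_pool = organ$defense_pool,
      defense_n = organ$defense_n, s0 = organ$s0, d_coef = organ$d_coef,
      area = organ_area(organ, config$sla),
      assim_c = assim_c[[k]], rd_c = rd_c[[k]],
      downregulation = directives$source_downregulation[[k]],
      delivered_c = del$c, delivered_n = del$n,
      maint_basal_c = part$maint_basal, maint_defense_c = part$maint_defense,
      def_synth_c = part$def_c_used, def_resp_c = part$def_c_respired,
      def_mass_synth = part$def_mass,
      growth_dm = part$growth$delta_mass,
      growth_resp_c = part$growth$c_respired,
      returned_c = part$returned_c, returned_n = part$returned_n,
      deficit_c = part$deficit
    )
  }
  plant$pool$carbon <- plant$pool$carbon + returned_c_total
  plant$pool$nitrogen <- plant$pool$nitrogen + returned_n_total

  plant$day <- day + 1L
  plant$status <- status
  plant$directives <- directives_new

  totals <- plant_totals(plant, config)
  plant_row <- data.frame(
    day = plant$day,
    pool_c = plant$pool$carbon, pool_n = plant$pool$nitrogen,
    stage = plant$stage,
    s_plant_mean = status$s_plant_mean, s_plant_max = status$s_plant_max,
    a_gross = sum(assim_c), rd_c = sum(rd_c), n_uptake = n_uptake,
    r_maint_basal = sums$maint_basal, r_maint_defense = sums$maint_defense,
    r_growth = sums$growth_resp, r_def_synth = sums$def_resp,
    remob_c = remob$flux_c, remob_n = remob$flux_n,
    returned_c = returned_c_total, returned_n = returned_n_total,
    deficit_c = sums$deficit + rd_unpaid_total,
    total_c = totals$carbon, total_n = totals$nitrogen
  )
  list(plant = plant,
       record = list(plant_row = plant_row,
                     organ_rows = do.call(rbind, organ_rows),
                     gas_exchange = gx_diag))
}

initial_record <- function(plant, config) {
  totals <- plant_totals(plant, config)
  plant_row <- data.frame(
    day = 0L, pool_c = plant$pool$carbon, pool_n = plant$pool$nitrogen,
    stage = plant$stage, s_plant_mean = 0, s_plant_max = 0,
    a_gross = 0, rd_c = 0, n_uptake = 0,
    r_maint_basal = 0, r_maint_defense = 0, r_growth = 0, r_def_synth = 0,
    remob_c = 0, remob_n = 0, returned_c = 0, returned_n = 0, deficit_c = 0,
    total_c = totals$carbon, total_n = totals$nitrogen
  )
  organ_rows <- do.call(rbind, lapply(plant$organs, function(o) {
    data.frame(
      day = 0L, organ = o$kind, mass = o$structural_mass,
      c_store = o$c_store, n_store = o$n_store,
      defense_pool = o$defense_pool, defense_n = o$defense_n,
      s0 = o$s0, d_coef = o$d_coef,
      area = organ_area(o, config$sla),
      assim_c = 0, rd_c = 0, downregulation = 0,
      delivered_c = 0, delivered_n = 0,
      maint_basal_c = 0, maint_defense_c = 0,
      def_synth_c = 0, def_resp_c = 0, def_mass_synth = 0,
      growth_dm = 0, growth_resp_c = 0,
      returned_c = 0, returned_n = 0, deficit_c = 0
    )
  }))
  rownames(organ_rows) <- NULL
  list(plant_row = plant_row, organ_rows = organ_rows)
}

#' Run a full simulation
#'
#' Initializes the plant from the configuration and advances it day by day
#' over the horizon, recording every state and flux. Deterministic given the
#' configuration and seed (the only stochastic component is the weather
#' generator).
#'
#' @param config A `wgdt_config`.
#' @param env_series Optional `environment_series`; generated from the
#'   config (seeded weather + stress schedule) when omitted.
#' @return A `wgdt_trajectory` with data frames `plant` (one row per day,
#'   day 0 included) and `organs` (one row per day x organ), the `config`,
#'   and the `final_state`.
#' @export
run_simulation <- function(config, env_series = NULL) {
  config <- validate_config(config)
  n <- as.integer(config$horizon_days)
  if (is.null(env_series)) env_series <- make_environment(config)
  if (nrow(env_series$weather) < n) {
    stop_wgdt(sprintf("environment series (%d days) shorter than horizon (%d)",
                      nrow(env_series$weather), n))
  }
  plant <- initialize_plant(config)
  rec0 <- initial_record(plant, config)
  plant_rows <- vector("list", n + 1L)
  organ_rows <- vector("list", n + 1L)
  plant_rows[[1L]] <- rec0$plant_row
  organ_rows[[1L]] <- rec0$organ_rows
  for (d in seq_len(n)) {
    env <- environment_day(env_series, d - 1L)
    out <- step(plant, env, config)
    plant <- out$plant
    plant_rows[[d + 1L]] <- out$record$plant_row
    organ_rows[[d + 1L]] <- out$record$organ_rows
  }
  organs <- do.call(rbind, organ_rows)
  rownames(organs) <- NULL
  structure(list(
    plant = do.call(rbind, plant_rows),
    organs = organs,
    config = config,
    final_state = plant
  ), class = "wgdt_trajectory")
}

#' Audit whole-plant mass balance of a trajectory
#'
#' Recomputes, for every simulated day, the carbon and nitrogen closure
#' identities from the recorded stocks and fluxes:
#' \deqn{\Delta C_{total} = A_{gross} - R_{total},\qquad
#'       \Delta N_{total} = U_N}
#' where `R_total` sums leaf dark respiration, basal and defense-augmented
#' maintenance, growth respiration and defense synthesis respiration.
#' Residuals are reported relative to the daily throughput and any day whose
#' relative residual exceeds `tol` is flagged.
#'
#' @param trajectory A `wgdt_trajectory`.
#' @param tol Relative tolerance (default 1e-9).
#' @return Data frame with one row per simulated day: `day`,
#'   `c_residual_rel`, `n_residual_rel`, `flagged`.
#' @export
audit_mass_balance <- function(trajectory, tol = 1e-9) {
  p <- trajectory$plant
  required <- c("day", "total_c", "total_n", "a_gross", "rd_c", "n_uptake",
                "r_maint_basal", "r_maint_defense", "r_growth", "r_def_synth")
  missing <- setdiff(required, names(p))
  if (length(missing)) {
    stop_wgdt("trajectory is missing flux fields: ",
              paste(missing, collapse = ", "))
  }
  if (nrow(p) <= 1) {
    return(data.frame(day = integer(0), c_residual_rel = numeric(0),
                      n_residual_rel = numeric(0), flagged = logical(0)))
  }
  i <- 2:nrow(p)
  r_total <- p$rd_c[i] + p$r_maint_basal[i] + p$r_maint_defense[i] +
    p$r_growth[i] + p$r_def_synth[i]
  dc <- p$total_c[i] - p$total_c[i - 1]
  dn <- p$total_n[i] - p$total_n[i - 1]
  thr_c <- pmax(abs(p$a_gross[i]) + abs(r_total), abs(p$total_c[i]) * 1e-3, 1e-6)
  thr_n <- pmax(abs(p$n_uptake[i]), abs(p$total_n[i]) * 1e-3, 1e-9)
  c_res <- abs(dc - (p$a_gross[i] - r_total)) / thr_c
  n_res <- abs(dn - p$n_uptake[i]) / thr_n
  data.frame(day = p$day[i], c_residual_rel = c_res, n_residual_rel = n_res,
             flagged = c_res > tol | n_res > tol)
}

#' Total structural biomass of the final state
#'
#' @param trajectory A `wgdt_trajectory`.
#' @return Final whole-plant structural dry mass, g.
#' @export
final_biomass <- function(trajectory) {
  sum(vapply(trajectory$final_state$organs,
             function(o) o$structural_mass, numeric(1)))
}

#' @export
print.wgdt_trajectory <- function(x, ...) {
  n <- max(x$plant$day)
  cat(sprintf(
    "<wgdt_trajectory> %d days; final biomass %.3f g (initial %.3f g); pool C %.3f g, N %.4f g\n",
    n, final_biomass(x),
    sum(x$organs$mass[x$organs$day == 0]),
    x$final_state$pool$carbon, x$final_state$pool$nitrogen))
  res <- audit_mass_balance(x)
  if (nrow(res)) {
    cat(sprintf("  mass-balance: max residual C %.2e, N %.2e (%d day(s) flagged)\n",
                max(res$c_residual_rel), max(res$n_residual_rel),
                sum(res$flagged)))
  }
  invisible(x)
}

#' @export
print.plant_state <- function(x, ...) {
  cat(sprintf("<plant_state> day %d (%s); pool C %.3f g, N %.4f g\n",
              x$day, x$stage, x$pool$carbon, x$pool$nitrogen))
  for (o in x$organs) print(o)
  invisible(x)
}

#' Export a trajectory to disk
#'
#' Writes the tidy long-format trajectory CSV (one row per day x organ x
#' variable) and a run-level JSON summary (final masses, cumulative fluxes,
#' audit residuals).
#'
#' @param trajectory A `wgdt_trajectory`.
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(trajectory, dir, stem = "trajectory") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  org <- trajectory$organs
  vars <- setdiff(names(org), c("day", "organ"))
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(day = org$day, organ = org$organ, variable = v,
               value = org[[v]])
  }))
  long <- long[order(long$day, long$organ, long$variable), ]
  csv_path <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(long, csv_path, row.names = FALSE)

  plant_path <- file.path(dir, paste0(stem, "_plant.csv"))
  utils::write.csv(trajectory$plant, plant_path, row.names = FALSE)

  audit <- audit_mass_balance(trajectory)
  final_masses <- vapply(trajectory$final_state$organs,
                         function(o) o$structural_mass, numeric(1))
  summary <- list(
    horizon_days = max(trajectory$plant$day),
    seed = trajectory$config$seed,
    final_biomass = final_biomass(trajectory),
    final_masses = as.list(final_masses),
    pool = trajectory$final_state$pool,
    cumulative = list(
      gross_assimilation_c = sum(trajectory$plant$a_gross),
      n_uptake = sum(trajectory$plant$n_uptake),
      respiration_c = sum(trajectory$plant$rd_c +
                            trajectory$plant$r_maint_basal +
                            trajectory$plant$r_maint_defense +
                            trajectory$plant$r_growth +
                            trajectory$plant$r_def_synth),
      maintenance_deficit_c = sum(trajectory$plant$deficit_c)
    ),
    audit = list(
      max_c_residual_rel = if (nrow(audit)) max(audit$c_residual_rel) else 0,
      max_n_residual_rel = if (nrow(audit)) max(audit$n_residual_rel) else 0,
      days_flagged = if (nrow(audit)) sum(audit$flagged) else 0L
    )
  )
  json_path <- file.path(dir, paste0(stem, "_summary.json"))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv_path, plant_path, json_path))
}

#' Read a written trajectory CSV back for auditing
#'
#' Rebuilds the plant-level flux table from the files written by
#' [write_trajectory()] so a stored run can be re-audited.
#'
#' @param dir Directory holding the exported files.
#' @param stem File name stem used at export.
#' @return A list mimicking a `wgdt_trajectory` for [audit_mass_balance()].
#' @export
read_trajectory <- function(dir, stem = "trajectory") {
  plant <- utils::read.csv(file.path(dir, paste0(stem, "_plant.csv")))
  organs_long <- utils::read.csv(file.path(dir, paste0(stem, ".csv")))
  structure(list(plant = plant, organs_long = organs_long),
            class = "wgdt_trajectory")
}
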