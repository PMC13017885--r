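#' Aggregate organ stress signals into the plant status
#'
#' The integration unit's whole-plant summary: the structural-mass-weighted
#' mean and the maximum of the organ stress signals, plus a snapshot of the
#' common pool and the phenological stage.
#'
#' @param organs Named list of `organ_state` objects.
#' @param pool List with `carbon` and `nitrogen`, g.
#' @param stage `"vegetative"` or `"reproductive"`.
#' @return A `plant_status` list with `s_plant_mean`, `s_plant_max`,
#'   `organ_s0` (named vector), `pool`, `stage`.
#' @export
integrate_plant_status <- function(organs, pool, stage) {
  masses <- vapply(organs, function(o) o$structural_mass, numeric(1))
  s0 <- vapply(organs, function(o) o$s0, numeric(1))
  if (sum(masses) <= 0) stop_wgdt("total structural mass is zero")
  structure(list(
    s_plant_mean = sum(masses * s0) / sum(masses),
    s_plant_max = max(s0),
    organ_s0 = s0,
    pool = pool,
    stage = stage
  ), class = "plant_status")
}

#' Allocation directives from the plant status
#'
#' Translates the integrated status into the directives applied at the next
#' allocation: stage-dependent base priorities (growing tissue and roots
#' during the vegetative stage, grain dominant after anthesis), per-organ
#' effective priority boosted toward stressed organs as
#' `base x (1 + beta x s0)`, and stress-driven downregulation of source
#' activities (`sigma_max x s0` on photosynthesis of mature/growing leaves
#' and on root nitrate uptake).
#'
#' @param status A `plant_status` from [integrate_plant_status()].
#' @param config A `wgdt_config`.
#' @return An `allocation_directives` list with `priority`,
#'   `source_downregulation` (both named by organ kind) and
#'   `stress_boost_beta`.
#' @export
compute_directives <- function(status, config) {
  al <- config$allocation
  base <- unlist(al$priorities[[status$stage]])[organ_kinds()]
  s0 <- status$organ_s0[organ_kinds()]
  priority <- base * (1 + al$beta_stress * s0)
  downreg <- stats::setNames(numeric(length(organ_kinds())), organ_kinds())
  for (k in source_kinds()) downreg[k] <- clamp(al$sigma_max * s0[[k]], 0, 1)
  structure(list(
    priority = priority,
    source_downregulation = downreg,
    stress_boost_beta = al$beta_stress
  ), class = "allocation_directives")
}

# normalized beta-shaped sink strength over organ age, peaking mid-expansion
sink_strength_beta <- function(age, pars) {
  if (is.null(pars)) return(0)
  x <- (age - pars$t0) / (pars$t1 - pars$t0)
  if (x <= 0 || x >= 1) return(0)
  a <- pars$a; b <- pars$b
  f <- x^(a - 1) * (1 - x)^(b - 1)
  if (a > 1 && b > 1) {
    xs <- (a - 1) / (a + b - 2)
    f / (xs^(a - 1) * (1 - xs)^(b - 1))
  } else {
    # monotone shapes: normalize by the supremum over (0, 1)
    f / max(1, f)
  }
}

# defense stoichiometry: per g of defense compound synthesized
defense_unit_costs <- function(config) {
  st <- config$stoichiometry
  dp <- config$defense
  c_per_g <- st$phenolic_glucose_cost * GLUCOSE_C_FRAC
  n_per_g <- st$defense_protein_fraction * dp$protein_c_frac / st$protein_cn
  list(c_per_g = c_per_g, n_per_g = n_per_g,
       c_retained = dp$compound_c_frac,
       c_respired = c_per_g - dp$compound_c_frac)
}

#' Daily resource demand of one organ
#'
#' Three demand components per organ and element:
#' * maintenance C from [maintenance_respiration()] (basal + defense term);
#' * the explicit defense sink, proportional to `D x mass`
#'   (`m_def = d_coef x mass x s_def_rate` g compound d-1), costed in C via
#'   the glucose-equivalent synthesis cost (glucose at 0.4 g C g-1) and in N
#'   via the protein C:N ratio on the protein fraction of the compound mix;
#' * potential growth `g_pot x sink_beta(age) x mass`, costed by structural
#'   carbon content, growth-respiration overhead (`1/Yg`) and tissue C:N.
#'
#' @param organ An `organ_state`.
#' @param config A `wgdt_config`.
#' @param t Temperature for the maintenance Q10 factor, degC.
#' @param day Current simulation day (organ age basis; grain age counts from
#'   anthesis).
#' @return An `organ_demand` list.
#' @export
organ_demand <- function(organ, config, t, day) {
  st <- config$stoichiometry
  al <- config$allocation
  kind <- organ$kind
  maint <- maintenance_respiration(organ, t, config$respiration)

  def_enabled <- isTRUE(config$defense_enabled)
  uc <- defense_unit_costs(config)
  m_def <- if (def_enabled) {
    organ$d_coef * organ$structural_mass * config$defense$s_def_rate
  } else 0
  c_defense <- m_def * uc$c_per_g
  n_defense <- m_def * uc$n_per_g

  age <- if (kind == "grain") day - config$anthesis_day else day
  sink_g <- sink_strength_beta(age, al$sink_beta[[kind]])
  mass_basis <- max(organ$structural_mass, al$m_ref[[kind]] %||% 0)
  pot_dm <- al$g_pot[[kind]] * sink_g * mass_basis
  c_per_g <- st$c_per_g_dm[[kind]]
  c_growth <- pot_dm * c_per_g / config$respiration$growth_yield
  n_growth <- pot_dm * c_per_g / st$tissue_cn[[kind]]

  structure(list(
    kind = kind,
    c_maintenance = maint$total,
    maint_basal = maint$basal, maint_defense = maint$defense,
    m_def_demand = m_def,
    c_defense = c_defense, n_defense = n_defense,
    pot_dm = pot_dm, sink_strength_g = sink_g,
    c_growth = c_growth, n_growth = n_growth
  ), class = "organ_demand")
}

#' Allocate the common pool among organs
#'
#' Carbon and nitrogen are allocated independently. Per element: if the pool
#' covers total demand, every organ with a positive effective priority
#' receives its demand; under scarcity, organ `i` receives
#' \eqn{\min(d_i,\; pool \cdot w_i d_i / \sum_j w_j d_j)} with `w` the
#' effective priorities - a single-pass, order-independent capped
#' proportional share. The remainder legitimately stays in the pool.
#'
#' @param pool List with `carbon` and `nitrogen`, g.
#' @param demands Named list of [organ_demand()] results.
#' @param directives An `allocation_directives` object.
#' @return List with `deliveries` (per organ: `c`, `n`) and the reduced
#'   `pool`.
#' @export
allocate_pool <- function(pool, demands, directives) {
  kinds <- names(demands)
  w <- directives$priority[kinds]
  share <- function(avail, dem) {
    if (any(dem < 0)) stop_wgdt("negative demand")
    dem <- ifelse(w > 0, dem, 0)
    total <- sum(dem)
    if (total <= avail || total == 0) return(dem)
    pmin(dem, avail * w * dem / sum(w * dem))
  }
  dem_c <- vapply(demands, function(d) d$c_maintenance + d$c_defense + d$c_growth,
                  numeric(1))
  dem_n <- vapply(demands, function(d) d$n_defense + d$n_growth, numeric(1))
  del_c <- share(pool$carbon, dem_c)
  del_n <- share(pool$nitrogen, dem_n)
  deliveries <- stats::setNames(lapply(seq_along(kinds), function(i) {
    list(c = del_c[[i]], n = del_n[[i]])
  }), kinds)
  pool$carbon <- pool$carbon - sum(del_c)
  pool$nitrogen <- pool$nitrogen - sum(del_n)
  list(deliveries = deliveries, pool = pool)
}

#' Convert allocated C and N into structural growth
#'
#' New structural dry matter requires `c_per_g_dm / Yg` g C per g (substrate
#' plus growth respiration) and `c_per_g_dm / tissue_cn` g N per g; realized
#' growth is the minimum of the C-limited and N-limited masses
#' (stoichiometric limitation) and the surplus of the non-limiting element is
#' returned. The realized structural C:N ratio therefore equals `tissue_cn`
#' exactly whenever growth is positive.
#'
#' @param c_for_growth,n_for_growth Available C and N, g.
#' @param organ_kind Organ kind (selects stoichiometry).
#' @param stoich Stoichiometry parameter block.
#' @param resp_params Respiration parameter block (growth yield).
#' @param cap Optional upper bound on delta_mass (potential growth), g DM.
#' @return List with `delta_mass`, `c_used`, `n_used`, `c_respired`,
#'   `c_structural`, `returned` (list `c`, `n`).
#' @export
structural_growth <- function(c_for_growth, n_for_growth, organ_kind,
                              stoich, resp_params, cap = Inf) {
  stopifnot(c_for_growth >= -1e-9, n_for_growth >= -1e-9)
  # tolerate one-ulp negatives from upstream subtraction
  c_for_growth <- max(c_for_growth, 0)
  n_for_growth <- max(n_for_growth, 0)
  c_per_g <- stoich$c_per_g_dm[[organ_kind]]
  yg <- resp_params$growth_yield
  c_need <- c_per_g / yg
  n_need <- c_per_g / stoich$tissue_cn[[organ_kind]]
  delta <- min(c_for_growth / c_need, n_for_growth / n_need, cap)
  c_used <- delta * c_need
  n_used <- delta * n_need
  list(delta_mass = delta,
       c_used = c_used, n_used = n_used,
       c_structural = delta * c_per_g,
       c_respired = c_used - delta * c_per_g,
       returned = list(c = c_for_growth - c_used,
                       n = n_for_growth - n_used))
}

#' Hierarchical within-organ partition: maintenance, defense, growth
#'
#' Implements the maintenance-first hierarchy. Delivered carbon first covers
#' the maintenance requirement; a shortfall is drawn from the organ's labile
#' carbon store, and only if the store is also exhausted is the maintenance
#' deficit flagged - in which case no allocation to defense or growth occurs
#' and any delivered nitrogen is returned. Otherwise the post-maintenance
#' carbon splits: a fraction `phi = d_coef` is offered to defense (capped by
#' the organ's defense demand and by delivered nitrogen through the protein
#' fraction), the rest is offered to growth via [structural_growth()].
#' Unused resources are returned to the common pool. Per element,
#' `M + D + G + returned = delivered + store_draw` exactly.
#'
#' @param delivery_c,delivery_n Delivered C and N, g.
#' @param organ An `organ_state`.
#' @param demand The organ's [organ_demand()].
#' @param config A `wgdt_config`.
#' @return A `partition_result` list; see Details.
#' @export
partition_within_organ <- function(delivery_c, delivery_n, organ, demand,
                                   config) {
  stopifnot(delivery_c >= 0, delivery_n >= 0)
  uc <- defense_unit_costs(config)

  maint_need <- demand$c_maintenance
  m_from_delivery <- min(delivery_c, maint_need)
  shortfall <- maint_need - m_from_delivery
  store_draw <- min(organ$c_store, shortfall)
  deficit <- shortfall - store_draw
  maint_respired <- m_from_delivery + store_draw

  if (deficit > 0) {
    sat <- if (maint_need > 0) maint_respired / maint_need else 1
    return(structure(list(
      maint_respired = maint_respired,
      maint_basal = demand$maint_basal * sat,
      maint_defense = demand$maint_defense * sat,
      store_draw = store_draw, deficit = deficit,
      def_mass = 0, def_c_used = 0, def_n_used = 0,
      def_c_respired = 0, def_c_retained = 0,
      growth = list(delta_mass = 0, c_used = 0, n_used = 0,
                    c_respired = 0, c_structural = 0),
      returned_c = delivery_c - m_from_delivery,
      returned_n = delivery_n
    ), class = "partition_result"))
  }

  c_after <- delivery_c - m_from_delivery
  phi <- organ$d_coef
  c_def_offer <- min(phi * c_after, demand$c_defense)
  m_by_c <- if (uc$c_per_g > 0) c_def_offer / uc$c_per_g else 0
  m_by_n <- if (uc$n_per_g > 0) delivery_n / uc$n_per_g else Inf
  def_mass <- min(m_by_c, m_by_n, demand$m_def_demand)
  # re-multiplication may overshoot the available amount by one ulp
  def_c_used <- min(def_mass * uc$c_per_g, c_after)
  def_n_used <- min(def_mass * uc$n_per_g, delivery_n)

  growth <- structural_growth(
    c_for_growth = c_after - def_c_used,
    n_for_growth = delivery_n - def_n_used,
    organ_kind = organ$kind,
    stoich = config$stoichiometry,
    resp_params = config$respiration,
    cap = demand$pot_dm)

  structure(list(
    maint_respired = maint_respired,
    maint_basal = demand$maint_basal,
    maint_defense = demand$maint_defense,
    store_draw = store_draw, deficit = 0,
    def_mass = def_mass,
    def_c_used = def_c_used, def_n_used = def_n_used,
    def_c_respired = def_mass * uc$c_respired,
    def_c_retained = def_mass * uc$c_retained,
    growth = growth[c("delta_mass", "c_used", "n_used",
                      "c_respired", "c_structural")],
    returned_c = max(0, delivery_c - m_from_delivery - def_c_used - growth$c_used),
    returned_n = max(0, delivery_n - def_n_used - growth$n_used)
  ), class = "partition_result")
}
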