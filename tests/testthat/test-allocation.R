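cfg <- default_config()

mk_organs <- function(masses, s0s) {
  kinds <- organ_kinds()[seq_along(masses)]
  out <- lapply(seq_along(masses), function(i) {
    organ_fixture(kinds[i], mass = masses[i], s0 = s0s[i])
  })
  stats::setNames(out, kinds)
}

test_that("plant status is the mass-weighted mean and max of organ signals", {
  organs <- mk_organs(c(1, 1, 2), c(0, 0.4, 0.5))
  st <- integrate_plant_status(organs, list(carbon = 1, nitrogen = 0.1),
                               "vegetative")
  expect_equal(st$s_plant_mean, 0.35)
  expect_equal(st$s_plant_max, 0.5)
  expect_lte(st$s_plant_mean, st$s_plant_max)
  empty <- mk_organs(c(0, 0), c(0.2, 0.2))
  expect_error(integrate_plant_status(empty, list(carbon = 0, nitrogen = 0),
                                      "vegetative"), "mass")
})

test_that("directives follow stage priorities and stress modulation", {
  plant <- initialize_plant(cfg)
  st <- integrate_plant_status(plant$organs, plant$pool, "vegetative")
  d <- compute_directives(st, cfg)
  expect_equal(unname(d$priority[["grain"]]), 0)
  expect_equal(unname(d$priority[organ_kinds()]),
               unname(unlist(cfg$allocation$priorities$vegetative)[organ_kinds()]))
  # beta = 0 removes the stress boost entirely
  plant$organs$mature_leaf$s0 <- 0.6
  st2 <- integrate_plant_status(plant$organs, plant$pool, "vegetative")
  cfg0 <- cfg
  cfg0$allocation$beta_stress <- 0
  d0 <- compute_directives(st2, cfg0)
  expect_equal(unname(d0$priority[["mature_leaf"]]),
               cfg$allocation$priorities$vegetative$mature_leaf)
  # base 1, beta 0.5, s0 = 0.6 -> effective 1.3
  cfg1 <- cfg
  cfg1$allocation$priorities$vegetative$mature_leaf <- 1
  d1 <- compute_directives(st2, cfg1)
  expect_equal(unname(d1$priority[["mature_leaf"]]), 1.3)
  # downregulation hits source organs proportionally to their own s0
  expect_equal(unname(d1$source_downregulation[["mature_leaf"]]),
               cfg$allocation$sigma_max * 0.6)
  expect_equal(unname(d1$source_downregulation[["roots"]]), 0)
  expect_equal(unname(d1$source_downregulation[["grain"]]), 0)
})

test_that("defense demand is exactly proportional to D times organ mass", {
  c2 <- cfg
  c2$defense$s_def_rate <- 0.01
  c2$stoichiometry$phenolic_glucose_cost <- 2.5
  organ <- organ_fixture("mature_leaf", mass = 2, d_coef = 0.5)
  dem <- organ_demand(organ, c2, t = 25, day = 10)
  expect_equal(dem$c_defense, 0.5 * 2 * 0.01 * 2.5 * 0.4)
  none <- organ_fixture("mature_leaf", mass = 2, d_coef = 0)
  expect_equal(organ_demand(none, c2, 25, 10)$c_defense, 0)
  # proportionality in D and in mass, over a grid
  base <- organ_demand(organ_fixture("mature_leaf", 1, d_coef = 1), c2, 25, 10)
  for (dd in c(0.2, 0.7)) {
    for (mm in c(0.5, 3)) {
      dem_i <- organ_demand(organ_fixture("mature_leaf", mm, d_coef = dd),
                            c2, 25, 10)
      expect_equal(dem_i$c_defense, base$c_defense * dd * mm)
      expect_equal(dem_i$n_defense, base$n_defense * dd * mm)
    }
  }
})

test_that("sink strength follows the normalized beta shape", {
  pars <- list(t0 = 0, t1 = 40, a = 2, b = 2.5)
  f <- vapply(0:40, wheatgdt:::sink_strength_beta, numeric(1), pars = pars)
  expect_equal(f[1], 0)
  expect_equal(f[41], 0)
  expect_equal(max(f), 1, tolerance = 0.01)  # peaks near 1 by normalization
  # grain demand is zero before anthesis (negative age)
  grain <- organ_fixture("grain", mass = 0.2)
  dem <- organ_demand(grain, cfg, 25, day = 20)
  expect_equal(dem$c_growth, 0)
})

test_that("pool allocation delivers demands when ample and shares when scarce", {
  plant <- initialize_plant(cfg)
  st <- integrate_plant_status(plant$organs, plant$pool, "vegetative")
  dir <- compute_directives(st, cfg)
  demands <- stats::setNames(lapply(organ_kinds(), function(k) {
    organ_demand(plant$organs[[k]], cfg, 25, 10)
  }), organ_kinds())
  dem_c <- vapply(demands, function(d) d$c_maintenance + d$c_defense + d$c_growth,
                  numeric(1))
  ample <- allocate_pool(list(carbon = 10, nitrogen = 1), demands, dir)
  got_c <- vapply(ample$deliveries, function(d) d$c, numeric(1))
  eligible <- dir$priority[organ_kinds()] > 0
  expect_equal(got_c[eligible], dem_c[eligible])
  expect_equal(got_c[["grain"]], 0)  # zero priority excludes the organ
  expect_equal(ample$pool$carbon, 10 - sum(got_c))
  none <- allocate_pool(list(carbon = 0, nitrogen = 0), demands, dir)
  expect_equal(sum(vapply(none$deliveries, function(d) d$c, numeric(1))), 0)
})

test_that("scarce pool follows the capped proportional sharing rule", {
  demands <- list(
    mature_leaf = structure(list(kind = "mature_leaf", c_maintenance = 0.8,
                                 maint_basal = 0.8, maint_defense = 0,
                                 m_def_demand = 0, c_defense = 0, n_defense = 0,
                                 pot_dm = 0, sink_strength_g = 0,
                                 c_growth = 0, n_growth = 0),
                            class = "organ_demand"),
    growing_leaf = structure(list(kind = "growing_leaf", c_maintenance = 0.8,
                                  maint_basal = 0.8, maint_defense = 0,
                                  m_def_demand = 0, c_defense = 0, n_defense = 0,
                                  pot_dm = 0, sink_strength_g = 0,
                                  c_growth = 0, n_growth = 0),
                             class = "organ_demand"))
  dir <- structure(list(
    priority = c(mature_leaf = 1, growing_leaf = 1),
    source_downregulation = c(mature_leaf = 0, growing_leaf = 0),
    stress_boost_beta = 0), class = "allocation_directives")
  out <- allocate_pool(list(carbon = 1, nitrogen = 0), demands, dir)
  expect_equal(out$deliveries$mature_leaf$c, 0.5)
  expect_equal(out$deliveries$growing_leaf$c, 0.5)
  expect_equal(out$pool$carbon, 0)
  # deliveries never exceed demand even when weights are skewed
  dir$priority <- c(mature_leaf = 10, growing_leaf = 1)
  out2 <- allocate_pool(list(carbon = 1, nitrogen = 0), demands, dir)
  expect_lte(out2$deliveries$mature_leaf$c, 0.8)
  expect_equal(out2$deliveries$mature_leaf$c,
               min(0.8, 1 * 10 * 0.8 / (10 * 0.8 + 1 * 0.8)))
  demands$mature_leaf$c_growth <- -1
  expect_error(allocate_pool(list(carbon = 1, nitrogen = 0), demands, dir),
               "negative demand")
})

test_that("structural growth respects the two-element stoichiometric limits", {
  st <- cfg$stoichiometry
  rp <- cfg$respiration
  st$c_per_g_dm$mature_leaf <- 0.45
  st$tissue_cn$mature_leaf <- 15
  rp$growth_yield <- 0.75
  # N-limitation shuts growth down and returns all C
  g0 <- structural_growth(0.5, 0, "mature_leaf", st, rp)
  expect_equal(g0$delta_mass, 0)
  expect_equal(g0$returned$c, 0.5)
  # exactly balanced C and N leave no surplus
  m <- 0.8
  gb <- structural_growth(m * 0.45 / 0.75, m * 0.45 / 15, "mature_leaf", st, rp)
  expect_equal(gb$delta_mass, m)
  expect_equal(gb$returned$c, 0, tolerance = 1e-15)
  expect_equal(gb$returned$n, 0, tolerance = 1e-15)
  # two-limit arithmetic: C would build 1.5 g, N only 1.0 g
  g <- structural_growth(0.9, 0.03, "mature_leaf", st, rp)
  expect_equal(g$delta_mass, 1.0)
  expect_equal(g$c_used, 0.6)
  expect_equal(g$returned$c, 0.3, tolerance = 1e-12)
  expect_equal(g$c_respired, 0.6 - 0.45)
  # realized structural C:N equals tissue_cn whenever growth is positive
  expect_equal(g$c_structural / g$n_used, 15)
})

test_that("within-organ partition enforces maintenance-first hierarchy", {
  organ <- organ_fixture("mature_leaf", mass = 1, c_store = 0.05, d_coef = 0.5)
  dem <- organ_demand(organ, cfg, 25, 10)
  # delivery + store below the maintenance need: deficit, nothing downstream
  short <- partition_within_organ(dem$c_maintenance / 4, 0.01, organ, dem, cfg)
  expect_equal(short$deficit, 0)  # store covers this one
  organ_poor <- organ_fixture("mature_leaf", mass = 1, c_store = 0, d_coef = 0.5)
  dem2 <- organ_demand(organ_poor, cfg, 25, 10)
  starved <- partition_within_organ(dem2$c_maintenance / 4, 0.01, organ_poor,
                                    dem2, cfg)
  expect_gt(starved$deficit, 0)
  expect_equal(starved$def_c_used, 0)
  expect_equal(starved$growth$delta_mass, 0)
  expect_equal(starved$returned_n, 0.01)
})

test_that("worked partition example conserves carbon through all routes", {
  c2 <- cfg
  c2$defense$s_def_rate <- 1  # make the defense demand non-binding
  organ <- organ_fixture("growing_leaf", mass = 1, c_store = 0.2, d_coef = 0.25)
  dem <- organ_demand(organ, c2, 25, 10)
  dem$c_maintenance <- 0.2
  p <- partition_within_organ(1.0, 0.5, organ, dem, c2)
  expect_equal(p$maint_respired, 0.2)
  expect_equal(p$def_c_used, 0.25 * 0.8)  # phi = d_coef of post-maintenance C
  # conservation: M + D + G + returned = delivered (store untouched here)
  expect_equal(p$store_draw, 0)
  expect_equal(p$maint_respired + p$def_c_used + p$growth$c_used + p$returned_c,
               1.0)
  expect_equal(p$def_n_used + p$growth$n_used + p$returned_n, 0.5)
  # d_coef = 0 sends everything past maintenance to growth
  organ0 <- organ_fixture("growing_leaf", mass = 1, c_store = 0.2, d_coef = 0)
  dem0 <- organ_demand(organ0, c2, 25, 10)
  p0 <- partition_within_organ(1.0, 0.5, organ0, dem0, c2)
  expect_equal(p0$def_c_used, 0)
})

test_that("randomized partitions conserve mass and respect the hierarchy", {
  set.seed(314)
  for (i in 1:200) {
    kind <- sample(organ_kinds(), 1)
    organ <- organ_fixture(kind, mass = runif(1, 0.01, 3),
                           c_store = runif(1, 0, 0.2),
                           d_coef = runif(1))
    organ$s0 <- runif(1)
    dem <- organ_demand(organ, cfg, runif(1, 5, 35), sample(0:140, 1))
    del_c <- runif(1, 0, 0.3)
    del_n <- runif(1, 0, 0.03)
    p <- partition_within_organ(del_c, del_n, organ, dem, cfg)
    # element conservation, exact
    expect_equal(p$maint_respired - p$store_draw + p$def_c_used +
                   p$growth$c_used + p$returned_c, del_c, tolerance = 1e-12)
    expect_equal(p$def_n_used + p$growth$n_used + p$returned_n, del_n,
                 tolerance = 1e-12)
    # no defense or growth while maintenance is unmet
    if (p$deficit > 0) {
      expect_equal(p$def_c_used, 0)
      expect_equal(p$growth$delta_mass, 0)
    }
    # nothing is negative
    expect_true(all(unlist(p[c("maint_respired", "store_draw", "deficit",
                               "def_c_used", "def_n_used", "returned_c",
                               "returned_n")]) >= 0))
  }
})

test_that("defense share of post-maintenance carbon is non-decreasing in D", {
  shares <- vapply(seq(0, 1, by = 0.1), function(d) {
    organ <- organ_fixture("mature_leaf", mass = 1, c_store = 0.1, d_coef = d)
    dem <- organ_demand(organ, cfg, 25, 10)
    p <- partition_within_organ(0.2, 0.02, organ, dem, cfg)
    post <- 0.2 - min(0.2, dem$c_maintenance)
    if (post > 0) p$def_c_used / post else 0
  }, numeric(1))
  expect_true(all(diff(shares) >= -1e-12))
})
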