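test_that("plant initialization creates six quiescent organs", {
  plant <- initialize_plant(default_config())
  expect_setequal(names(plant$organs), organ_kinds())
  expect_length(plant$organs, 6)
  for (o in plant$organs) {
    expect_equal(o$s0, 0)
    expect_equal(o$d_coef, 0)
    expect_gte(o$structural_mass, 0)
  }
  expect_equal(plant$day, 0L)
  expect_identical(plant$stage, "vegetative")
  # grain with zero mass before anthesis is a valid state
  expect_equal(plant$organs$grain$structural_mass, 0)
})

test_that("invalid initial states are rejected with the offending key", {
  bad <- default_config()
  bad$organs$roots$mass <- -0.1
  expect_error(initialize_plant(bad), "organs.roots.mass")
  missing <- default_config()
  missing$organs$grain <- NULL
  expect_error(initialize_plant(missing), "organs.grain")
})

test_that("a dark, unstressed day yields zero assimilation and drains the pool", {
  cfg <- small_config(horizon = 1)
  env_series <- make_environment(cfg)
  env_series$weather$par <- 0
  traj <- run_simulation(cfg, env_series)
  day1 <- traj$plant[2, ]
  expect_equal(day1$a_gross, 0)
  expect_gt(day1$rd_c + day1$r_maint_basal, 0)
  expect_lt(day1$pool_c, cfg$pool$carbon + day1$remob_c)
})

test_that("every simulated day closes the carbon and nitrogen ledgers", {
  traj <- run_simulation(small_config(horizon = 60))
  res <- audit_mass_balance(traj)
  expect_equal(nrow(res), 60)
  expect_lte(max(res$c_residual_rel), 1e-9)
  expect_lte(max(res$n_residual_rel), 1e-9)
  expect_false(any(res$flagged))
  # stocks never go negative at any recorded boundary
  expect_true(all(traj$plant$pool_c >= 0))
  expect_true(all(traj$plant$pool_n >= 0))
  expect_true(all(traj$organs$mass >= 0))
  expect_true(all(traj$organs$c_store >= -1e-15))
  expect_true(all(traj$organs$n_store >= -1e-15))
})

test_that("audit flags an injected single-flux fault", {
  traj <- run_simulation(small_config(horizon = 20))
  clean <- audit_mass_balance(traj)
  expect_false(any(clean$flagged))
  traj$plant$a_gross[10] <- traj$plant$a_gross[10] + 0.001
  res <- audit_mass_balance(traj)
  expect_true(res$flagged[9])          # record row 10 is simulated day 9
  expect_equal(sum(res$flagged), 1)
  traj$plant$r_growth <- NULL
  expect_error(audit_mass_balance(traj), "r_growth")
})

test_that("simulations are deterministic and horizon 0 keeps only day 0", {
  t1 <- run_simulation(small_config(horizon = 25, seed = 3))
  t2 <- run_simulation(small_config(horizon = 25, seed = 3))
  expect_identical(t1$plant, t2$plant)
  expect_identical(t1$organs, t2$organs)
  t3 <- run_simulation(small_config(horizon = 25, seed = 4))
  expect_false(identical(t1$plant$a_gross, t3$plant$a_gross))

  t0 <- run_simulation(small_config(horizon = 0))
  expect_equal(nrow(t0$plant), 1)
  expect_equal(t0$plant$day, 0L)
  expect_equal(nrow(audit_mass_balance(t0)), 0)
})

test_that("an environment series shorter than the horizon is rejected", {
  cfg <- small_config(horizon = 50)
  env <- make_environment(small_config(horizon = 20))
  expect_error(run_simulation(cfg, env), "shorter than")
})

test_that("senescent remobilization follows the accelerated fractional rule", {
  params <- list(r_c = 0.01, r_n = 0.05, a_sen = 1)
  organ <- organ_fixture("senescent_leaf", mass = 0.5, c_store = 0.4,
                         n_store = 1.0)
  calm <- list(s_plant_mean = 0, s_plant_max = 0)
  out <- remobilize_senescent(organ, calm, params)
  expect_equal(out$flux_n, 0.05)
  expect_equal(out$organ$n_store, 0.95)
  expect_equal(out$organ$structural_mass, 0.5)  # mass never remobilizes
  # full stress with a_sen = 1 exactly doubles both fluxes
  stressed <- list(s_plant_mean = 1, s_plant_max = 1)
  out2 <- remobilize_senescent(organ, stressed, params)
  expect_equal(out2$flux_c, 2 * out$flux_c)
  expect_equal(out2$flux_n, 2 * out$flux_n)
  # switch-off
  off <- remobilize_senescent(organ, calm, list(r_c = 0, r_n = 0, a_sen = 1))
  expect_equal(off$flux_n, 0)
  expect_equal(off$organ$n_store, organ$n_store)
  expect_error(remobilize_senescent(organ_fixture("roots"), calm, params),
               "senescent")
})

test_that("zero-stress trajectories equal a defense-bypassed run exactly", {
  on <- small_config(horizon = 50)
  off <- on
  off$defense_enabled <- FALSE
  t_on <- run_simulation(on)
  t_off <- run_simulation(off)
  num <- vapply(t_on$organs, is.numeric, logical(1))
  expect_equal(as.matrix(t_on$organs[, num]), as.matrix(t_off$organs[, num]),
               tolerance = 1e-12)
  expect_equal(t_on$plant$total_c, t_off$plant$total_c, tolerance = 1e-12)
})

test_that("a step under stress produces organ signals and defense costs", {
  cfg <- small_config(horizon = 30)
  cfg$stress_events <- list(
    stress_event("rust", "biotic", 2, 25, 0.8, 2,
                 target_organs = "mature_leaf"))
  traj <- run_simulation(cfg)
  ml <- traj$organs[traj$organs$organ == "mature_leaf", ]
  expect_gt(max(ml$s0), 0.7)
  expect_gt(max(ml$d_coef), 0.3)
  expect_gt(sum(ml$maint_defense_c), 0)
  expect_gt(sum(ml$def_synth_c), 0)
  expect_gt(max(ml$defense_pool), 0)
  # untargeted organs stay quiet
  rt <- traj$organs[traj$organs$organ == "roots", ]
  expect_equal(max(rt$s0), 0)
  expect_equal(sum(rt$def_synth_c), 0)
  # the audit still closes under stress
  expect_false(any(audit_mass_balance(traj)$flagged))
})

test_that("forcing the defense coefficient clamps it over the window", {
  cfg <- small_config(horizon = 30)
  cfg$force_d <- list(kinds = "mature_leaf", value = 1,
                      start_day = 10, end_day = 19)
  traj <- run_simulation(cfg)
  ml <- traj$organs[traj$organs$organ == "mature_leaf", ]
  expect_equal(ml$d_coef[ml$day %in% 11:20], rep(1, 10))
  expect_equal(ml$d_coef[ml$day %in% 1:10], rep(0, 10))
})

test_that("a default run accumulates biomass and the grain fills after anthesis", {
  traj <- run_simulation(small_config(horizon = 110, seed = 1))
  expect_gt(final_biomass(traj), sum(traj$organs$mass[traj$organs$day == 0]))
  grain <- traj$organs[traj$organs$organ == "grain", ]
  expect_equal(max(grain$mass[grain$day <= 80]), 0)
  expect_gt(grain$mass[grain$day == 110], 0)
})
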