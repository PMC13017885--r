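# shared fixtures, built in code

# short-horizon config for fast integration tests
small_config <- function(horizon = 40L, seed = 11L) {
  cfg <- default_config()
  cfg$horizon_days <- as.integer(horizon)
  cfg$seed <- as.integer(seed)
  cfg
}

# a single environment day for unit tests of the leaf/root operations
env_day_fixture <- function(par = 1200, t_air = 22, rel_humidity = 0.7,
                            ca = 400, soil_no3 = 1.0, t_leaf = t_air) {
  list(day = 0L, par = par, t_air = t_air, t_leaf = t_leaf,
       rel_humidity = rel_humidity, ca = ca, soil_no3 = soil_no3,
       stress_inputs = stats::setNames(
         rep(list(stats::setNames(numeric(0), character(0))),
             length(organ_kinds())), organ_kinds()),
       stress_classes = character())
}

organ_fixture <- function(kind = "mature_leaf", mass = 1, c_store = 0.1,
                          n_store = 0.03, s0 = 0, d_coef = 0) {
  o <- wheatgdt::initialize_plant(small_config())$organs[[kind]]
  o$structural_mass <- mass
  o$c_store <- c_store
  o$n_store <- n_store
  o$s0 <- s0
  o$d_coef <- d_coef
  o
}

# sustained whole-season abiotic stress at intensity S
sustained_stress_config <- function(S, base = default_config()) {
  if (S > 0) {
    base$stress_events <- list(
      stress_event("osmotic", "abiotic", start_day = 0,
                   end_day = base$horizon_days - 1, peak_intensity = S,
                   ramp_days = 0))
  }
  base
}
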