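# Shared lazily-computed simulations, cached for the whole test run.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# Fast patient for mechanics plumbing tests: fewer layers, same physics.
fast_patient <- function(preset = "default", overrides = list()) {
  ov <- utils::modifyList(list(n_layers = 25L), overrides)
  build_patient(preset, ov)
}

# Recorded on a 10 ms grid: fine enough that trapezoidal re-integration of
# the sampled flows resolves the solver's own volume conservation.
baseline_sim <- function() cached("baseline", {
  simulate_breaths(build_patient(), V_pf = 0, n_breaths = 2, dt_out = 0.01)
})

pe3_sim <- function(preset = "default") cached(paste0("pe3_", preset), {
  simulate_breaths(build_patient(preset), V_pf = 3, n_breaths = 2,
                   dt_out = 0.01)
})

# Last full breath of a simulation plus its mouth-volume signal.
last_breath <- function(sim) {
  b <- sim$recording[sim$recording$breath == max(sim$recording$breath), ]
  dt <- b$t[2] - b$t[1]
  V <- pleurasim:::cumtrapz(b$Q_mouth, dt)
  list(b = b, V = V, dt = dt)
}

sim_pv_loop <- function(sim) {
  lb <- last_breath(sim)
  pv_loop(lb$b$P_pl_ipsi, lb$V)
}
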