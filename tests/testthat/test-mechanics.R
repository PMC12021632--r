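test_that("hydrostatic pressure grows linearly with depth below the fluid", {
  expect_equal(hydrostatic_ppl(-0.5, 0), -0.5)
  expect_equal(hydrostatic_ppl(-0.5, 10), -0.5 + 10 * 0.0981)
  expect_equal(hydrostatic_ppl(0, 20), 2 * hydrostatic_ppl(0, 10))
  expect_error(hydrostatic_ppl(0, -1), ">= 0")
})

test_that("fluid level is linear in volume for the prismatic hemithorax", {
  p <- build_patient()
  expect_equal(fluid_surface_level(0, p), 0)
  expect_equal(fluid_surface_level(p$hemithorax_cap / 2, p),
               p$lung_height / 2)
  expect_gte(fluid_surface_level(2, p), fluid_surface_level(1, p))
  expect_error(fluid_surface_level(p$hemithorax_cap + 0.1, p), "capacity")
  expect_error(fluid_surface_level(-0.1, p), ">= 0")
})

test_that("recruitment flags follow a hand-stepped hysteresis automaton", {
  p <- build_patient()   # P_close = 0, P_open = 0.3
  # oracle: scalar automaton stepped by hand over a pressure cycle
  ptp_seq <- c(0.5, 0.2, 0.1, -0.05, 0.1, 0.25, 0.31, 0.5, -0.1, 0.4)
  oracle <- logical(length(ptp_seq))
  state <- TRUE
  for (i in seq_along(ptp_seq)) {
    if (state && ptp_seq[i] < 0) state <- FALSE
    else if (!state && ptp_seq[i] > 0.3) state <- TRUE
    oracle[i] <- state
  }
  got <- logical(length(ptp_seq))
  st <- TRUE
  for (i in seq_along(ptp_seq)) {
    st <- layer_recruitment_update(st, ptp_seq[i], p)
    got[i] <- st
  }
  expect_identical(got, oracle)
  # vectorised fixed point: well-inflated layers never change
  open <- c(TRUE, TRUE, FALSE)
  expect_identical(layer_recruitment_update(open, c(1, 1, 0.1), p),
                   c(TRUE, TRUE, FALSE))
  expect_identical(layer_recruitment_update(open, c(1, -0.1, 0.1), p),
                   c(TRUE, FALSE, FALSE))
})

test_that("muscle driver transmits drive by force-length state and phase", {
  p <- build_patient()
  d <- make_drive(2)
  T_b <- 60 / p$RR
  Ti <- p$Ti_frac * T_b
  # at rest length the full drive is transmitted at mid-inspiration
  md <- muscle_driver(Ti / 2, p, d, x_di = c(-0.2, -0.2))
  expect_equal(md$P_di_ipsi, 2)
  expect_equal(md$P_rc_mus, 2 * p$rc_mus_frac)
  expect_equal(md$phase, "inspiration")
  # maximal inversion: paradoxical floor
  md_inv <- muscle_driver(Ti / 2, p, d, x_di = c(5, -0.2))
  expect_equal(md_inv$P_di_ipsi, 2 * p$di_eps_floor)
  expect_equal(di_force_length(5, p), abs(p$di_eps_floor))
  expect_equal(di_force_length(-0.2, p), 1)
  # end-expiration: waveform zero
  md_exp <- muscle_driver(T_b - 0.01, p, d)
  expect_equal(md_exp$P_di_ipsi, 0)
  expect_equal(md_exp$phase, "expiration")
})

test_that("single-compartment reduction matches the closed-form RC step", {
  # 1 layer, rigid rib cage, rigid mediastinum, no effusion, small step
  p <- build_patient(overrides = list(
    n_layers = 1L, C_rc = 1e-5, C_med = 1e-9, dt = 0.002))
  st <- pleurasim:::static_equilibrium(p, 0)
  A <- 0.02
  out <- pleurasim:::integrate_cycles(st, p, make_drive(A, "const"), 2L,
                                      dt_out = 0.01)
  r <- out$rec
  Vtot <- r$V_lung_ipsi + r$V_lung_contra
  dV <- Vtot - Vtot[1]
  # independent closed form: chest-wall elastance per side in series with
  # the linearised lung recoil, two sides in parallel behind the trachea
  E_w <- 1 / p$C_di_ipsi + 2 / p$C_ab
  V_frc <- p$FRC_side
  E_L <- 1 / (p$lung_k * (p$lung_Vmax - V_frc))
  R_eff <- 2 * p$R_tr + p$R_mb_ipsi + p$R_small   # per-side path
  tau <- R_eff / (E_w + E_L)
  dV_inf <- 2 * A / (E_w + E_L)
  expected <- dV_inf * (1 - exp(-r$t / tau))
  idx <- r$t > 0.05 & r$t < 5 * tau
  expect_lt(max(abs(dV[idx] - expected[idx])) / dV_inf, 0.005)
})

test_that("flow continuity holds at the carina and per-cycle volume closes", {
  sim <- baseline_sim()
  r <- sim$recording
  expect_lt(max(abs(r$Q_mouth - (r$Q_mb_ipsi + r$Q_mb_contra))), 1e-12)
  lb <- last_breath(sim)
  net <- sum((lb$b$Q_mouth[-1] + lb$b$Q_mouth[-nrow(lb$b)]) / 2) * lb$dt
  VT <- sim$per_breath$VT[nrow(sim$per_breath)]
  expect_lt(abs(net), 0.001 * VT)
  # the controller holds the tidal volume at target
  expect_lt(abs(VT - sim$params$VT_target) / sim$params$VT_target, 0.02)
})

test_that("mediastinal coupling obeys its force balance and limits", {
  # recorded mediastinal displacement satisfies V_med = C_med (Ppl_i - Ppl_c)
  sim <- pe3_sim()
  r <- sim$recording
  expect_lt(max(abs(r$V_med - sim$params$C_med *
                      (r$P_pl_ipsi - r$P_pl_contra))), 1e-9)
  # transmission limit: interpleural pressure difference shrinks as C_med
  # grows, displacement shrinks as C_med falls; monotone across a sweep
  drive <- make_drive(1)
  base <- fast_patient()
  maxdiff <- c(); maxvmed <- c()
  for (f in c(0.1, 0.5, 1, 5, 50)) {
    p <- scale_param(base, "C_med", f)
    st <- pleurasim:::static_equilibrium(p, 0.5)   # mild effusion: asymmetric
    out <- pleurasim:::integrate_cycles(st, p, drive, 2L, dt_out = 0.04)
    r2 <- out$rec
    maxdiff <- c(maxdiff, max(abs(r2$P_pl_ipsi - r2$P_pl_contra)))
    maxvmed <- c(maxvmed, max(abs(r2$V_med - r2$V_med[1])))
  }
  expect_true(all(diff(maxdiff) < 1e-10))      # pressure equalisation
  expect_true(all(diff(maxvmed) > -1e-10))     # decoupling as C_med -> 0
  expect_lt(maxdiff[5], maxdiff[1] / 5)
  expect_lt(maxvmed[1], 0.05 * maxvmed[5])
})

test_that("a large effusion routes inspiratory flow to the contralateral lung
           and spares an apical cap of the ipsilateral one", {
  sim <- pe3_sim()
  lb <- last_breath(sim)
  dt <- lb$dt
  Vi <- pleurasim:::cumtrapz(lb$b$Q_mb_ipsi, dt)
  Vc <- pleurasim:::cumtrapz(lb$b$Q_mb_contra, dt)
  expect_gt(max(Vc) - min(Vc), 3 * (max(Vi) - min(Vi)))
  n <- sim$params$n_layers
  open_i <- sim$state$open[seq_len(n)]
  expect_gt(sum(open_i), 0)                    # apical layers open
  expect_lt(sum(open_i), n)                    # dependent layers closed
  # the open layers sit at the top of the lung
  expect_true(all(which(open_i) > n / 2))
  # hydrostatic consistency at the deepest layer
  level <- fluid_surface_level(3, sim$params)
  z1 <- pleurasim:::layer_heights(sim$params)[1]
  d <- derivatives(sim$state, 0, sim$params, sim$drive)
  expect_equal(unname(d$Ppl_layer[1] - d$P_pl[1]),
               0.0981 * sim$params$rho_f * (level - z1))
})

test_that("drive adaptation is deterministic and reports unreachable targets", {
  p <- fast_patient()
  a1 <- adapt_drive_to_vt(p, V_pf = 0)
  a2 <- adapt_drive_to_vt(p, V_pf = 0)
  expect_identical(a1$drive$A, a2$drive$A)
  expect_lt(abs(a1$VT - p$VT_target) / p$VT_target, 0.02)
  # a large effusion demands a stronger drive for the same tidal volume
  a3 <- adapt_drive_to_vt(build_patient(), V_pf = 3)
  a4 <- adapt_drive_to_vt(build_patient(), V_pf = 0)
  expect_gt(a3$drive$A, a4$drive$A)
  expect_error(
    adapt_drive_to_vt(fast_patient(overrides = list(VT_target = 10))),
    "bound|converge")
})

test_that("simulation is reproducible step for step", {
  p <- fast_patient()
  st <- pleurasim:::static_equilibrium(p, 0.5)
  o1 <- pleurasim:::integrate_cycles(st, p, make_drive(1), 1L)
  o2 <- pleurasim:::integrate_cycles(st, p, make_drive(1), 1L)
  expect_identical(o1$rec, o2$rec)
  expect_identical(o1$state$V_alv, o2$state$V_alv)
})
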