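test_that("breath segmentation counts sinusoidal breaths and shrugs off
           sub-band noise", {
  fs <- 25; RR <- 12
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  flow <- sin(2 * pi * RR / 60 * t)
  br <- segment_breaths(flow, fs)
  expect_length(br, 11)     # 12 cycles; trailing partial dropped
  # onsets fall on the upward zero crossings (one sample of latitude)
  starts <- vapply(br, `[[`, numeric(1), "start")
  expect_true(all(abs((t[starts] %% 5)) <= 2 / fs |
                    abs((t[starts] %% 5) - 5) <= 2 / fs))
  # noise below the hysteresis band does not move the boundaries
  set.seed(42)
  noisy <- flow + runif(length(flow), -0.015, 0.015)
  br2 <- segment_breaths(noisy, fs)
  expect_equal(vapply(br2, `[[`, numeric(1), "start"), starts)
  expect_error(segment_breaths(rep(0, 500), fs), "zero")
})

test_that("flow integration matches closed forms and closes each breath", {
  fs <- 25
  flow <- rep(0.5, fs + 1)
  V <- integrate_flow(flow, fs)
  expect_equal(V[length(V)], 0.5, tolerance = 1e-12)
  # sinusoid: numerical integral within 0.1% of the analytic integral
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  om <- 2 * pi / 5
  V2 <- integrate_flow(sin(om * t), fs)
  expect_lt(max(abs(V2 - (1 - cos(om * t)) / om)), 0.001 * 2 / om)
  # re-zeroing: V returns to 0 at each onset
  flow3 <- sin(om * seq(0, 20 - 1 / fs, by = 1 / fs))
  br <- segment_breaths(flow3, fs)
  V3 <- integrate_flow(flow3, fs, br)
  for (b in br) expect_equal(V3[b$start], 0)
})

test_that("lean classification follows the end-inspiratory pressure
           difference", {
  # parametric ellipse with a phase offset between P and V
  mk <- function(phi) {
    t <- seq(0, 5 - 0.04, by = 0.04)
    om <- 2 * pi / 5
    V <- (1 - cos(om * t)) / om * 0.5
    P <- -0.5 + 0.3 * sin(om * t + phi)
    pv_loop(P, V)
  }
  # endpoint oracle: P(end insp) - P(end exp) = -2 a sin(phi)
  expect_equal(classify_lean(mk(0.6)), "right")
  expect_equal(classify_lean(mk(-0.6)), "left")
  expect_equal(classify_lean(mk(0)), "vertical")
  expect_equal(classify_lean(pv_loop(c(-0.2, -0.6, -0.2, -0.5, -0.45, -0.5,
                                       -0.52, -0.5),
                                     c(0, 0.2, 0.5, 0.4, 0.3, 0.2, 0.1, 0))),
               "left")   # P_end_insp -0.2 > P_end_exp -0.5
  expect_error(classify_lean(mk(0), epsilon = -1), ">= 0")
})

test_that("figure-eight detection agrees with geometry", {
  t <- seq(0, 2 * pi, length.out = 65)[-65]
  ellipse <- pv_loop(cos(t), 0.5 * sin(t))
  expect_false(detect_eight(ellipse)$eight)
  # offset the phase so the self-crossing falls inside segments rather
  # than exactly on two coincident vertices
  t <- t + 0.05
  lemni <- pv_loop(sin(t), sin(2 * t))
  d <- detect_eight(lemni)
  expect_true(d$eight)
  expect_true(any(sqrt(rowSums(d$crossings^2)) < 0.1))  # crossing near origin
  # invariance under cyclic rotation of the sample order
  for (k in c(7, 23, 41)) {
    rot <- pv_loop(sin(t)[c(k:64, 1:(k - 1))], sin(2 * t)[c(k:64, 1:(k - 1))])
    expect_true(detect_eight(rot)$eight)
  }
  expect_error(detect_eight(pv_loop(rep(c(0, 1), 8), rep(c(0, 1), 8))),
               "degenerate")
})

test_that("amplitude statistics take the per-breath median", {
  fs <- 25
  t <- seq(0, 15 - 1 / fs, by = 1 / fs)
  om <- 2 * pi / 5
  flow <- sin(om * t)
  amps <- c(1, 2, 9)
  P <- rep(amps / 2, each = 125) * sin(om * t)
  breaths <- list(list(start = 1, end = 125), list(start = 126, end = 250),
                  list(start = 251, end = 375))
  expect_equal(amplitude_stats(P, fs, breaths), 2, tolerance = 1e-3)
  a <- 0.4
  expect_equal(amplitude_stats(a * sin(om * t), fs, breaths), 2 * a,
               tolerance = 1e-3)
  expect_error(amplitude_stats(P, fs, list()), "no complete breath")
})

test_that("pendelluft fraction equals the sign-opposition measure of
           phase-shifted sinusoids", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  om <- 2 * pi / 5
  for (phi in c(0, 0.4, pi / 2, 2.2, pi)) {
    f <- pendelluft_fraction(sin(om * t), sin(om * t + phi), dead_frac = 0)
    # grid boundaries shift the opposition intervals by at most a sample
    expect_lt(abs(f$fraction - phi / pi), 0.02)
  }
  expect_equal(pendelluft_fraction(sin(t), sin(t))$fraction, 0)
  expect_equal(pendelluft_fraction(sin(om * t), -sin(om * t),
                                   dead_frac = 0)$fraction, 1,
               tolerance = 2e-3)
  expect_error(pendelluft_fraction(1:5, 1:4), "equal length")
})

test_that("vitals indices compute their defining products", {
  expect_equal(co_index(120, 80, 60), 2400)
  expect_equal(minute_ventilation(0.5, 12), 6)
  expect_error(co_index(110, 110, 70), "SBP must exceed DBP")
  expect_error(minute_ventilation(0, 12), "positive")
})

test_that("two-stage slopes reproduce closed-form least squares", {
  # perfect line: both stages recover the slope exactly
  x <- seq(0, 3.8, by = 0.2)
  s <- stage_slopes(x, 3 * x + 1, V_withdrawn = x)
  expect_equal(s$slope_stage1, 3)
  expect_equal(s$slope_stage2, 3)
  # piecewise design with slopes (-2, +1), noise-free OLS via normal
  # equations as an independent oracle
  y <- ifelse(x < 1.9, -2 * x, 1 * x)
  s2 <- stage_slopes(x, y, x, split = 1.9)
  ols <- function(xx, yy) {
    n <- length(xx)
    (n * sum(xx * yy) - sum(xx) * sum(yy)) / (n * sum(xx^2) - sum(xx)^2)
  }
  expect_equal(s2$slope_stage1, ols(x[x < 1.9], y[x < 1.9]))
  expect_equal(s2$slope_stage1, -2)
  expect_equal(s2$slope_stage2, 1)
  # a single point in a stage leaves that slope undefined, not an error
  s3 <- stage_slopes(c(0.5, 1, 2.0), c(1, 2, 3), c(0.5, 1, 2.0))
  expect_true(is.na(s3$slope_stage2))
  expect_false(is.na(s3$slope_stage1))
})

test_that("analysis metrics agree between the 25 Hz grid and a finer
           solver grid", {
  p <- fast_patient()
  st <- pleurasim:::static_equilibrium(p, 0)
  d <- make_drive(1)
  coarse <- pleurasim:::integrate_cycles(st, p, d, 2L, dt_out = 0.04)$rec
  fine <- pleurasim:::integrate_cycles(st, p, d, 2L, dt_out = 0.01)$rec
  amp_c <- max(coarse$P_pl_ipsi) - min(coarse$P_pl_ipsi)
  amp_f <- max(fine$P_pl_ipsi) - min(fine$P_pl_ipsi)
  expect_lt(abs(amp_c - amp_f) / amp_f, 0.02)
  pf_c <- pendelluft_fraction(coarse$Q_mb_ipsi, coarse$Q_mb_contra)$fraction
  pf_f <- pendelluft_fraction(fine$Q_mb_ipsi, fine$Q_mb_contra)$fraction
  expect_lt(abs(pf_c - pf_f), 0.05)
})
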