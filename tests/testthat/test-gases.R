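test_that("fresh gas ratio follows its definition and doubles for one lung", {
  expect_equal(fresh_gas_ratio(0.5, 2.4, 0.15), 0.5 / 2.55)
  expect_equal(round(fresh_gas_ratio(0.5, 2.4, 0.15), 3), 0.196)
  # collapsed ipsilateral lung: FRC and VD halve, ratio doubles exactly
  expect_equal(fresh_gas_ratio(0.5, 1.2, 0.075),
               2 * fresh_gas_ratio(0.5, 2.4, 0.15))
  expect_equal(fresh_gas_ratio(1.0, 2.4, 0.15),
               2 * fresh_gas_ratio(0.5, 2.4, 0.15))   # linear in VT
  expect_error(fresh_gas_ratio(0, 2.4, 0.15), "> 0")
})

test_that("oxyhemoglobin saturation and contents behave", {
  p <- build_patient()
  expect_equal(so2_hill(p$P50, p$P50, p$hill_n), 0.5)
  expect_equal(so2_hill(13.3, 3.55, 2.7), 13.3^2.7 / (13.3^2.7 + 3.55^2.7))
  expect_equal(round(so2_hill(13.3, 3.55, 2.7), 4), 0.9725)
  po2 <- seq(1, 30, by = 0.5)
  expect_true(all(diff(o2_content(po2, p)) > 0))
  expect_true(all(diff(co2_content(seq(2, 10, 0.5), p)) > 0))
  expect_error(o2_content(-1, p), "range")
  expect_error(co2_content(200, p), "range")
})

test_that("perfusion split conserves cardiac output and suppresses the
           high-pressure side", {
  p <- build_patient()
  eq <- perfusion_split(c(-0.5, -0.5), c(1, 1), p)
  expect_equal(eq$q_ipsi, p$CO_total / 2)
  expect_equal(eq$q_contra, p$CO_total / 2)
  expect_equal(eq$q_shunt, 0)
  hi <- perfusion_split(c(0.5, -0.5), c(1, 1), p)
  expect_lt(hi$q_ipsi, hi$q_contra)
  expect_equal(hi$q_ipsi + hi$q_contra + hi$q_shunt, p$CO_total)
  # closed tissue of a perfused side becomes shunt
  sh <- perfusion_split(c(-0.5, -0.5), c(0, 1), p)
  expect_equal(sh$q_shunt, sh$q_side[1])
  expect_equal(sh$q_ipsi, 0)
  expect_error(perfusion_split(c(0, 0), c(-0.1, 1), p), "open_frac")
})

test_that("steady-state alveolar CO2 matches the alveolar ventilation
           equation and the O2 balance closes", {
  p <- build_patient()
  VA <- c(2.1, 2.1)
  gs <- gas_exchange_steady(VA, c(2.5, 2.5), 0, p)
  P_ACO2_pred <- p$VCO2 * (p$P_atm - 6.27) / sum(VA)
  expect_lt(abs(gs$P_ACO2[1] - P_ACO2_pred) / P_ACO2_pred, 0.05)
  # per-lung O2 mass balance residual at the reported steady state
  Pb_eff <- p$P_atm - 6.27
  resid <- VA[1] * 1000 * (gs$P_IO2 - gs$P_AO2[1]) / Pb_eff -
    2.5 * 10 * (o2_content(gs$P_AO2[1], p) - gs$CvO2)
  delivery <- VA[1] * 1000 * (gs$P_IO2 - gs$P_AO2[1]) / Pb_eff
  expect_lt(abs(resid) / delivery, 0.01)
  # symmetric inputs give symmetric lungs
  expect_equal(gs$P_AO2[1], gs$P_AO2[2])
  # an alveolar_step at the fixed point does not move
  gas <- list(P_AO2 = gs$P_AO2, P_ACO2 = gs$P_ACO2,
              CvO2 = gs$CvO2, CvCO2 = gs$CvCO2)
  stepped <- alveolar_step(gas, VA, c(2.5, 2.5), p)
  expect_lt(max(abs(stepped$dPO2)), 0.05)       # kPa/min, ~0 at steady state
})

test_that("unperfused or unventilated lungs go to their limiting gases", {
  p <- build_patient()
  gs <- gas_exchange_steady(c(2.1, 2.1), c(2.5, 0), 2.5, p)
  # zero perfusion: alveolar O2 relaxes to inspired (no uptake possible)
  gas <- list(P_AO2 = c(10, 10), P_ACO2 = c(5, 5), CvO2 = gs$CvO2,
              CvCO2 = gs$CvCO2)
  for (i in 1:4000) gas <- alveolar_step(gas, c(2.1, 2.1), c(2.5, 0), p,
                                         dt_min = 0.01)
  expect_lt(abs(gas$P_AO2[2] - gs$P_IO2), 0.05)
  # an unventilated side is reclassified as shunt
  gs2 <- gas_exchange_steady(c(0, 4.2), c(2, 2.5), 0.5, p)
  expect_true(is.na(gs2$P_AO2[1]))
  expect_equal(gs2$q_shunt, 2.5)
})

test_that("arterial mixing happens in content space and is monotone in
           shunt", {
  p <- build_patient()
  # all streams identical: mixing returns the stream
  one <- mix_arterial(list(PO2 = c(13, 13), PCO2 = c(5, 5)),
                      flows = c(2, 3), q_shunt = 0,
                      venous = list(CvO2 = 15, CvCO2 = 52), p)
  expect_equal(one$PaO2, 13, tolerance = 1e-6)
  expect_equal(one$PaCO2, 5, tolerance = 1e-9)
  # brute-force oracle: bisection on the mixed content
  ven <- list(CvO2 = 14.5, CvCO2 = 52)
  mx <- mix_arterial(list(PO2 = 13.5, PCO2 = 5), flows = 2.5,
                     q_shunt = 2.5, venous = ven, p)
  target <- (2.5 * o2_content(13.5, p) + 2.5 * ven$CvO2) / 5
  lo <- 0.5; hi <- 20
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (o2_content(mid, p) < target) lo <- mid else hi <- mid
  }
  expect_equal(mx$PaO2, (lo + hi) / 2, tolerance = 1e-6)
  expect_lt(mx$PaO2, 13.5)
  # increasing shunt strictly decreases PaO2
  pa <- vapply(c(0, 0.5, 1, 2), function(qs)
    mix_arterial(list(PO2 = 13.5, PCO2 = 5), flows = 5 - qs, q_shunt = qs,
                 venous = ven, p)$PaO2, numeric(1))
  expect_true(all(diff(pa) < 0))
})

test_that("a large effusion drives contralateral hyperoxygenation and a
           shunt that depresses arterial oxygen", {
  base <- cached("gases_baseline", gases_from_sim(baseline_sim()))
  pe <- cached("gases_pe3", gases_from_sim(pe3_sim()))
  # the ventilated contralateral lung receives (almost) the whole tidal
  # volume: its fresh-gas ratio and alveolar O2 exceed baseline
  expect_gt(pe$fresh_gas_ratio[2], 1.5 * base$fresh_gas_ratio[2])
  expect_gt(pe$P_AO2[2], base$P_AO2[2])
  expect_gt(pe$q_shunt, 0)
  expect_lt(pe$PaO2, base$PaO2)
  # reducing shunt at fixed ventilation raises PaO2
  less <- gas_exchange_steady(pe$VA, pe$q_vent + c(0, pe$q_shunt / 2),
                              pe$q_shunt / 2, pe3_sim()$params)
  expect_gt(less$PaO2, pe$PaO2)
})
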