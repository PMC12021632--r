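# ---------------------------------------------------------------------------
# Blood gas transport
# ---------------------------------------------------------------------------

# Saturated water vapour pressure at body temperature, kPa.
P_H2O <- 6.27
KPA_TO_MMHG <- 7.50062

#' Oxyhemoglobin saturation (Hill equation)
#'
#' @param PO2 oxygen partial pressure, kPa.
#' @param P50 half-saturation pressure, kPa.
#' @param n Hill coefficient.
#' @return Saturation in \[0, 1\].
#' @export
so2_hill <- function(PO2, P50 = 3.55, n = 2.7) {
  PO2^n / (PO2^n + P50^n)
}

#' Blood oxygen and carbon dioxide content
#'
#' `o2_content()` combines hemoglobin-bound oxygen (1.34 mL O2 per g Hb at
#' full saturation, Hill saturation curve) with physically dissolved oxygen
#' (0.003 mL/dL/mmHg).  `co2_content()` uses a dissociation curve
#' linearised around 5.33 kPa (40 mmHg), adequate over the physiological
#' range when acid-base chemistry is out of scope.  Both are strictly
#' increasing, which the content-space mixing in [mix_arterial()] relies on
#' for invertibility.
#'
#' @param PO2,PCO2 partial pressures, kPa; must lie in (0, `P_atm`).
#' @param params a `patient_params` (uses `Hb`, `P50`, `hill_n`, `P_atm`).
#' @return Content in mL gas (STPD) per dL blood.
#' @export
o2_content <- function(PO2, params) {
  if (any(PO2 <= 0) || any(PO2 >= params$P_atm))
    stop("PO2 out of range (0, P_atm)")
  1.34 * params$Hb * so2_hill(PO2, params$P50, params$hill_n) +
    0.003 * PO2 * KPA_TO_MMHG
}

#' @rdname o2_content
#' @export
co2_content <- function(PCO2, params) {
  if (any(PCO2 <= 0) || any(PCO2 >= params$P_atm))
    stop("PCO2 out of range (0, P_atm)")
  48 + 3.5 * (PCO2 - 5.33)
}

# Inverse of co2_content (linear).
co2_pressure <- function(content) 5.33 + (content - 48) / 3.5

# Numeric inverse of o2_content.
o2_pressure <- function(content, params) {
  lo <- 1e-3; hi <- params$P_atm - 1e-3
  clo <- o2_content(lo, params); chi <- o2_content(hi, params)
  if (content <= clo) return(lo)
  if (content >= chi) return(hi)
  uniroot(function(p) o2_content(p, params) - content,
          lower = lo, upper = hi, tol = 1e-9)$root
}

#' Fresh-gas dilution ratio
#'
#' The ratio of tidal volume to the processed gas it mixes with on
#' inspiration (end-expiratory volume plus anatomical dead space).  It sets
#' how far the alveolar mixture is pulled toward inspired air; when one
#' lung is collapsed and tidal volume is maintained, FRC + VD belong to the
#' ventilated lung alone, and the ratio can double.
#'
#' @param VT tidal volume, L.
#' @param FRC end-expiratory open gas volume, L.
#' @param VD anatomical dead space, L.
#' @return Dimensionless ratio.
#' @examples
#' fresh_gas_ratio(0.5, 2.4, 0.15)
#' fresh_gas_ratio(0.5, 1.2, 0.075)  # single ventilated lung: doubled
#' @export
fresh_gas_ratio <- function(VT, FRC, VD) {
  if (any(c(VT, FRC, VD) <= 0)) stop("VT, FRC, VD must all be > 0")
  VT / (FRC + VD)
}

# ---------------------------------------------------------------------------
# Perfusion
# ---------------------------------------------------------------------------

#' Split cardiac output by local pleural pressure and recruitment
#'
#' Per-side vascular conductance falls smoothly with the local (mid-lung)
#' pleural pressure, `g = 1 / (1 + exp((P_pl - perf_P_half)/perf_w))`:
#' raised ipsilateral pressure under an effusion squeezes the vessels so
#' that almost all blood flows through the contralateral lung.  Flow
#' reaching the non-ventilated (closed) fraction of a side is shunt.  The
#' three components sum to `CO_total` exactly.
#'
#' @param P_pl_mean length-2 mean pleural pressure (ipsi, contra), kPa.
#' @param open_frac length-2 ventilated (open-layer) fraction per side.
#' @param params a `patient_params`.
#' @return A list with `q_ipsi`, `q_contra` (perfusion of ventilated
#'   tissue, L/min), `q_shunt` (L/min) and the per-side total flows
#'   `q_side`.
#' @export
perfusion_split <- function(P_pl_mean, open_frac, params) {
  stopifnot(length(P_pl_mean) == 2, length(open_frac) == 2)
  if (any(open_frac < 0 | open_frac > 1))
    stop("open_frac must lie in [0, 1]")
  g <- 1 / (1 + exp((P_pl_mean - params$perf_P_half) / params$perf_w))
  q_side <- params$CO_total * g / sum(g)
  q_vent <- q_side * open_frac
  q_shunt <- params$CO_total - sum(q_vent)
  list(q_ipsi = q_vent[1], q_contra = q_vent[2], q_shunt = q_shunt,
       q_side = q_side)
}

# ---------------------------------------------------------------------------
# Alveolar gas balance
# ---------------------------------------------------------------------------

#' Advance one well-mixed alveolar compartment pair
#'
#' Explicit relaxation step of the per-lung O2/CO2 mass balances: fresh-gas
#' inflow at (humidified) inspired partial pressures, uptake/output by
#' perfusion-weighted equilibration with end-capillary blood.  Iterating to
#' a fixed point gives the steady state that [gas_exchange_steady()] solves
#' directly.
#'
#' @param gas a list with `P_AO2`, `P_ACO2` (length-2, kPa) and venous
#'   contents `CvO2`, `CvCO2` (mL/dL).
#' @param VA length-2 alveolar ventilation, L/min.
#' @param q length-2 perfusion of ventilated tissue, L/min.
#' @param params a `patient_params`.
#' @param dt_min step, min.
#' @param FRC_eff effective per-lung mixing volume, L.
#' @return Updated `gas` list, plus `dPO2`/`dPCO2` rates (kPa/min).
#' @export
alveolar_step <- function(gas, VA, q, params, dt_min = 0.02,
                          FRC_eff = c(1.2, 1.2)) {
  Pb_eff <- params$P_atm - P_H2O
  P_IO2 <- params$FiO2 * Pb_eff
  # net flux in mL STPD/min: ventilation delivery minus blood uptake
  fO2 <- VA * 1000 * (P_IO2 - gas$P_AO2) / Pb_eff -
    q * 10 * (o2_content(gas$P_AO2, params) - gas$CvO2)
  fCO2 <- -VA * 1000 * gas$P_ACO2 / Pb_eff +
    q * 10 * (gas$CvCO2 - co2_content(gas$P_ACO2, params))
  dPO2 <- fO2 / 1000 / FRC_eff * Pb_eff
  dPCO2 <- fCO2 / 1000 / FRC_eff * Pb_eff
  gas$P_AO2 <- pmin(pmax(gas$P_AO2 + dt_min * dPO2, 0.1), P_IO2)
  gas$P_ACO2 <- pmin(pmax(gas$P_ACO2 + dt_min * dPCO2, 0.05), 20)
  gas$dPO2 <- dPO2; gas$dPCO2 <- dPCO2
  gas
}

#' Mix pulmonary venous streams into arterial blood
#'
#' Flow-weighted mixing is performed in content space (contents are
#' conserved quantities; partial pressures are not), then converted back to
#' partial pressures by inverting the content curves.
#'
#' @param P_cap length-2 list/vectors of end-capillary `PO2` and `PCO2`
#'   per ventilated side, kPa.
#' @param flows length-2 ventilated flows, L/min.
#' @param q_shunt shunt flow carrying mixed-venous blood, L/min.
#' @param venous list with `CvO2`, `CvCO2` (mL/dL).
#' @param params a `patient_params`.
#' @return List with `PaO2`, `PaCO2` (kPa), `CaO2`, `CaCO2` (mL/dL).
#' @export
mix_arterial <- function(P_cap, flows, q_shunt, venous, params) {
  CO <- sum(flows) + q_shunt
  if (CO <= 0) stop("total flow must be positive")
  cc_o2 <- vapply(P_cap$PO2, o2_content, numeric(1), params = params)
  cc_co2 <- co2_content(P_cap$PCO2, params)
  CaO2 <- (sum(flows * cc_o2) + q_shunt * venous$CvO2) / CO
  CaCO2 <- (sum(flows * cc_co2) + q_shunt * venous$CvCO2) / CO
  list(PaO2 = o2_pressure(CaO2, params), PaCO2 = co2_pressure(CaCO2),
       CaO2 = CaO2, CaCO2 = CaCO2)
}

#' Steady-state gas exchange for a two-lung / shunt circulation
#'
#' Solves the coupled per-lung alveolar balances, arterial mixing and the
#' Fick closure of the venous return (fixed tissue VO2/VCO2) by damped
#' fixed-point iteration; each lung's O2 balance is solved by root
#' bracketing at the current venous state.
#'
#' @param VA length-2 alveolar ventilation (ipsi, contra), L/min.
#' @param q_vent length-2 perfusion of ventilated tissue, L/min.
#' @param q_shunt shunt perfusion, L/min.
#' @param params a `patient_params`.
#' @return A `gas_state` list: `P_AO2`, `P_ACO2` (per side, kPa; `NA` for
#'   an unventilated side), `PaO2`, `PaCO2`, `CvO2`, `CvCO2`, flows, and
#'   `P_IO2`.
#' @export
gas_exchange_steady <- function(VA, q_vent, q_shunt, params) {
  Pb_eff <- params$P_atm - P_H2O
  P_IO2 <- params$FiO2 * Pb_eff
  CO <- sum(q_vent) + q_shunt
  stopifnot(CO > 0)
  # a side with (almost) no ventilation cannot exchange: its flow is shunt
  dead <- VA < 1e-6
  q_shunt <- q_shunt + sum(q_vent[dead])
  q_vent[dead] <- 0

  CvO2 <- 15; CvCO2 <- 52        # mixed-venous starting guess
  P_AO2 <- c(NA_real_, NA_real_); P_ACO2 <- c(NA_real_, NA_real_)
  art <- NULL
  for (it in 1:80) {
    for (s in 1:2) {
      if (dead[s] || q_vent[s] < 1e-9) next
      # O2: VA (P_IO2 - P)/Pb * 1000 = q * 10 * (Cc(P) - CvO2)
      f <- function(P) VA[s] * 1000 * (P_IO2 - P) / Pb_eff -
        q_vent[s] * 10 * (o2_content(P, params) - CvO2)
      P_AO2[s] <- uniroot(f, lower = 0.2, upper = P_IO2 - 1e-6,
                          tol = 1e-9)$root
      # CO2 (linear content curve): closed form
      a <- VA[s] * 1000 / Pb_eff
      P_ACO2[s] <- (q_vent[s] * 10 * (CvCO2 - 48 + 3.5 * 5.33)) /
        (a + q_vent[s] * 10 * 3.5)
    }
    vent <- which(!dead & q_vent > 1e-9)
    if (!length(vent)) {
      art <- list(PaO2 = o2_pressure(CvO2, params),
                  PaCO2 = co2_pressure(CvCO2),
                  CaO2 = CvO2, CaCO2 = CvCO2)
    } else {
      art <- mix_arterial(list(PO2 = P_AO2[vent], PCO2 = P_ACO2[vent]),
                          flows = q_vent[vent], q_shunt = q_shunt,
                          venous = list(CvO2 = CvO2, CvCO2 = CvCO2),
                          params = params)
    }
    CvO2_new <- art$CaO2 - 100 * params$VO2 / params$CO_total
    CvCO2_new <- art$CaCO2 + 100 * params$VCO2 / params$CO_total
    CvO2_new <- max(CvO2_new, 0.5)
    if (abs(CvO2_new - CvO2) < 1e-8 && abs(CvCO2_new - CvCO2) < 1e-8) {
      CvO2 <- CvO2_new; CvCO2 <- CvCO2_new
      break
    }
    CvO2 <- CvO2 + 0.6 * (CvO2_new - CvO2)
    CvCO2 <- CvCO2 + 0.6 * (CvCO2_new - CvCO2)
  }
  structure(list(P_AO2 = P_AO2, P_ACO2 = P_ACO2,
                 PaO2 = art$PaO2, PaCO2 = art$PaCO2,
                 CvO2 = CvO2, CvCO2 = CvCO2,
                 q_vent = q_vent, q_shunt = q_shunt,
                 VA = VA, P_IO2 = P_IO2,
                 P_O2_atm_dry = params$FiO2 * params$P_atm),
            class = "gas_state")
}

#' @export
print.gas_state <- function(x, ...) {
  cat("<gas_state>\n")
  cat(sprintf("  P_AO2 %s kPa, P_ACO2 %s kPa\n",
              paste(signif(x$P_AO2, 4), collapse = "/"),
              paste(signif(x$P_ACO2, 4), collapse = "/")))
  cat(sprintf("  PaO2 %.2f kPa, PaCO2 %.2f kPa; shunt %.2f L/min\n",
              x$PaO2, x$PaCO2, x$q_shunt))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Coupling from a mechanics simulation
# ---------------------------------------------------------------------------

#' Derive steady-state gases from a breathing simulation
#'
#' Extracts per-lung tidal ventilation, end-expiratory volumes, open-layer
#' fractions and mean mid-lung pleural pressures from a [simulate_breaths()]
#' result, splits perfusion with [perfusion_split()] and solves
#' [gas_exchange_steady()].
#'
#' @param sim a `breath_sim`.
#' @return A `gas_state` with extra elements `FRC` (per side), `VT_side`,
#'   `fresh_gas_ratio` (per side, `NA` for an unventilated side) and
#'   `open_frac`.
#' @export
gases_from_sim <- function(sim) {
  params <- sim$params
  rec <- sim$recording
  b <- rec[rec$breath == max(rec$breath), ]
  dt <- b$t[2] - b$t[1]
  n <- params$n_layers
  # per-lung tidal volumes from bronchial flow integrals
  VT_side <- c(max(cumtrapz(b$Q_mb_ipsi, dt)) - min(cumtrapz(b$Q_mb_ipsi, dt)),
               max(cumtrapz(b$Q_mb_contra, dt)) - min(cumtrapz(b$Q_mb_contra, dt)))
  # end-expiratory OPEN gas volume per lung
  st <- sim$state
  FRC <- c(sum(st$V_alv[seq_len(n)][st$open[seq_len(n)]]),
           sum(st$V_alv[n + seq_len(n)][st$open[n + seq_len(n)]]))
  open_frac <- c(mean(st$open[seq_len(n)]), mean(st$open[n + seq_len(n)]))
  VD_side <- rep(params$VD_anat / 2, 2)
  VA <- pmax(VT_side - VD_side, 0) * params$RR
  # mid-lung mean pleural pressure (hydrostatic offset at mid height)
  level <- fluid_surface_level(sim$V_pf, params)
  hyd_mid <- 0.0981 * params$rho_f * max(0, level - params$lung_height / 2)
  P_mid <- c(mean(b$P_pl_ipsi) + hyd_mid, mean(b$P_pl_contra))
  perf <- perfusion_split(P_mid, open_frac, params)
  gs <- gas_exchange_steady(VA, c(perf$q_ipsi, perf$q_contra),
                            perf$q_shunt, params)
  gs$FRC <- FRC
  gs$VT_side <- VT_side
  gs$open_frac <- open_frac
  gs$fresh_gas_ratio <- ifelse(VA > 1e-6,
                               VT_side / (FRC + VD_side), NA_real_)
  gs$P_pl_mid <- P_mid
  gs
}
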