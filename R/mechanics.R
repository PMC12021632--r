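# ---------------------------------------------------------------------------
# Geometry and hydrostatics
# ---------------------------------------------------------------------------

#' Local pleural pressure under a pleural fluid column
#'
#' Pleural pressure is referenced at the lung apex of each hemithorax
#' (`P_pl_top`).  Below the surface of the pleural fluid it rises
#' hydrostatically with depth; 1 cm of fluid of density 1 kg/L adds
#' 0.0981 kPa.
#'
#' @param P_pl_top apical pleural pressure, kPa.
#' @param depth depth below the fluid surface, cm (0 for structures in the
#'   gas-filled part of the pleural space).
#' @param rho_f fluid density, kg/L.
#' @return Local pleural pressure, kPa.
#' @examples
#' hydrostatic_ppl(-0.5, 10)  # 10 cm below the surface
#' @export
hydrostatic_ppl <- function(P_pl_top, depth, rho_f = 1.0) {
  if (any(depth < 0)) stop("depth below the fluid surface must be >= 0")
  P_pl_top + 0.0981 * rho_f * depth
}

#' Pleural fluid surface level
#'
#' Each hemithorax is modelled as a vertical prism of uniform cross-section
#' `hemithorax_cap / lung_height`, so the fluid surface rises linearly with
#' fluid volume.
#'
#' @param V_pf pleural fluid volume, L.
#' @param params a `patient_params` object.
#' @return Fluid surface level in cm above the lung base.
#' @export
fluid_surface_level <- function(V_pf, params) {
  if (any(V_pf < 0)) stop("pleural fluid volume must be >= 0")
  if (any(V_pf > params$hemithorax_cap))
    stop("pleural fluid volume exceeds hemithorax capacity (",
         params$hemithorax_cap, " L)")
  V_pf * params$lung_height / params$hemithorax_cap
}

# Layer centre heights above the lung base, cm (layer 1 = most dependent).
layer_heights <- function(params) {
  n <- params$n_layers
  params$lung_height * (seq_len(n) - 0.5) / n
}

# ---------------------------------------------------------------------------
# Constitutive laws
# ---------------------------------------------------------------------------

# Exponential lung recoil P_el(V) = -(1/k) log(1 - V/Vmax) per layer, so the
# tissue stiffens towards its capacity (the nonlinearity responsible for
# contralateral overdistension under a collapsed ipsilateral lung).
lung_recoil <- function(V, Vmax, k) {
  v <- pmin(pmax(V / Vmax, 0), 0.995)
  -log1p(-v) / k
}

# Signed effectiveness of diaphragm contraction as a function of caudal
# displacement x (L).  At or beyond resting length the full drive is
# transmitted (1).  As the dome is pushed caudally by fluid the muscle
# shortens and flattens; effectiveness falls linearly, crosses zero at
# di_eps_zero and saturates at the paradoxical floor di_eps_floor: an
# inverted hemidiaphragm pulls itself upward when it contracts, raising
# rather than lowering ipsilateral pleural pressure.
di_effectiveness <- function(x, params) {
  pmin(1, pmax(params$di_eps_floor, 1 - x / params$di_eps_zero))
}

#' Force-length factor of a hemidiaphragm
#'
#' Magnitude of the transmitted active pressure, between 0 and 1, as a
#' function of caudal displacement volume.  The sign of the action (normal
#' vs. paradoxical when the dome is inverted) is handled inside the solver;
#' this accessor reports the magnitude.
#'
#' @param x_di caudal displacement volume of the hemidiaphragm, L.
#' @param params a `patient_params` object.
#' @return A value in \[0, 1\].
#' @export
di_force_length <- function(x_di, params) abs(di_effectiveness(x_di, params))

# ---------------------------------------------------------------------------
# Muscle driver
# ---------------------------------------------------------------------------

#' Respiratory muscle driver
#'
#' A half-sinusoid active pressure over the inspiratory fraction `Ti_frac`
#' of the cycle, zero during passive expiration.  The neural amplitude is
#' shared by the two hemidiaphragms and scaled per side by the signed
#' force-length effectiveness of each; rib-cage muscles receive the
#' fraction `rc_mus_frac` of the diaphragm drive.
#'
#' @param t time, s (vectorised).
#' @param params a `patient_params` object.
#' @param drive a drive state from [make_drive()].
#' @param x_di optional length-2 vector of current hemidiaphragm
#'   displacements (ipsi, contra), L, for the force-length scaling;
#'   defaults to the resting displacements.
#' @return A list with elements `P_di_ipsi`, `P_di_contra`, `P_rc_mus`
#'   (kPa) and `phase` (`"inspiration"`/`"expiration"`).
#' @export
muscle_driver <- function(t, params, drive, x_di = params$x_di_rest) {
  w <- drive_waveform(t, params, drive)
  eps <- di_effectiveness(x_di, params)
  list(P_di_ipsi   = drive$A * w * eps[1],
       P_di_contra = drive$A * w * eps[2],
       P_rc_mus    = drive$A * w * params$rc_mus_frac,
       phase = ifelse((t %% (60 / params$RR)) <
                        params$Ti_frac * 60 / params$RR,
                      "inspiration", "expiration"))
}

# Raw normalized waveform in [0, 1].
drive_waveform <- function(t, params, drive) {
  if (!is.null(drive$waveform) && drive$waveform == "const")
    return(rep(1, length(t)))
  T_b <- 60 / params$RR
  Ti <- params$Ti_frac * T_b
  tc <- t %% T_b
  ifelse(tc < Ti, sin(pi * tc / Ti), 0)
}

#' Construct a drive state
#'
#' @param A neural drive amplitude, kPa (peak diaphragm pressure at full
#'   effectiveness).
#' @param waveform `"halfsin"` (default breathing waveform) or `"const"`
#'   (a sustained step, used for system-identification checks).
#' @return A list of class `drive_state`.
#' @export
make_drive <- function(A, waveform = "halfsin") {
  if (!is.numeric(A) || length(A) != 1L || A < 0)
    stop("drive amplitude must be a non-negative number")
  structure(list(A = A, waveform = waveform), class = "drive_state")
}

# ---------------------------------------------------------------------------
# Recruitment hysteresis
# ---------------------------------------------------------------------------

#' Layer recruitment / derecruitment with hysteresis
#'
#' Open layers whose transpulmonary pressure falls below `P_close` collapse;
#' closed layers whose available inflation pressure exceeds `P_open` reopen;
#' all other flags are unchanged.  The gap `P_open > P_close` prevents
#' chatter at the threshold.
#'
#' @param open logical vector of current recruitment flags.
#' @param P_tp transpulmonary (or airway-minus-local-pleural, for closed
#'   layers) pressure per layer, kPa.
#' @param params a `patient_params` object (uses `P_close`, `P_open`).
#' @return Updated logical vector.
#' @export
layer_recruitment_update <- function(open, P_tp, params) {
  stopifnot(length(open) == length(P_tp))
  (open & P_tp >= params$P_close) | (!open & P_tp > params$P_open)
}

# ---------------------------------------------------------------------------
# Mechanical state
# ---------------------------------------------------------------------------

# A mech_state is a list:
#   V_alv  : length-2n vector of layer gas volumes (ipsi then contra), L
#   open   : length-2n logical recruitment flags
#   V_rc   : rib-cage volume above relaxation, L
#   V_pf   : ipsilateral pleural fluid volume, L
#   P_pl_top : length-2 apical pleural pressures (ipsi, contra), kPa
#   x_di   : length-2 hemidiaphragm displacements, L
#   V_med  : mediastinal displacement (positive toward contralateral), L
#   Pb_lag : length-2 lagged bronchial node pressures, kPa

new_mech_state <- function(V_alv, open, V_rc, V_pf, P_pl_top, x_di, V_med) {
  structure(list(V_alv = V_alv, open = open, V_rc = V_rc, V_pf = V_pf,
                 P_pl_top = P_pl_top, x_di = x_di, V_med = V_med,
                 Pb_lag = c(0, 0)),
            class = "mech_state")
}

state_side <- function(state, side = c("ipsi", "contra")) {
  n <- length(state$V_alv) / 2L
  if (match.arg(side) == "ipsi") seq_len(n) else n + seq_len(n)
}

#' @export
print.mech_state <- function(x, ...) {
  n <- length(x$V_alv) / 2L
  i <- seq_len(n); j <- n + i
  cat("<mech_state>\n")
  cat(sprintf("  open layers ipsi %d/%d, contra %d/%d; V_pf %.2f L\n",
              sum(x$open[i]), n, sum(x$open[j]), n, x$V_pf))
  cat(sprintf("  gas ipsi %.3f L, contra %.3f L; P_pl_top %.2f / %.2f kPa\n",
              sum(x$V_alv[i]), sum(x$V_alv[j]),
              x$P_pl_top[1], x$P_pl_top[2]))
  invisible(x)
}

# Per-run precomputed constants: hydrostatic offsets, chest-wall matrix
# inverse, airway constants.
sim_precompute <- function(params, V_pf) {
  n <- params$n_layers
  level <- fluid_surface_level(V_pf, params)
  z <- layer_heights(params)
  hyd <- c(0.0981 * params$rho_f * pmax(0, level - z), numeric(n))
  Cdi <- params$C_di_ipsi; Cdc <- params$C_di_contra
  Cm <- params$C_med; Cab <- params$C_ab
  M <- matrix(c(Cdi + Cm, -Cm,       -Cdi,
                -Cm,      Cdc + Cm,  -Cdc,
                Cdi,      Cdc,       -(Cab + Cdi + Cdc)),
              3, 3, byrow = TRUE)
  list(n = n, level = level,
       hyd = hyd,
       h_di = 0.0981 * params$rho_f * level,
       hyd_mid = 0.0981 * params$rho_f * max(0, level - params$lung_height / 2),
       Vmax_l = params$lung_Vmax / n,
       Minv = solve(M),
       Rmb = c(params$R_mb_ipsi, params$R_mb_contra),
       R_layer0 = params$R_small * n,
       rigid_rc = params$C_rc <= 1e-4,
       idx_i = seq_len(n), idx_c = n + seq_len(n))
}

# Chest-wall force balance for the apical pleural pressures, abdominal
# pressure, diaphragm displacements and mediastinal shift, given the
# hemithorax content sums.  Linear for fixed diaphragm effectiveness; two
# Picard passes update the effectiveness at the solved displacement.
chest_solve <- function(S_i, S_c, V_rc, P_act, params, pre, x_guess) {
  Cdi <- params$C_di_ipsi; Cdc <- params$C_di_contra
  b1c <- S_i - unname(params$V0[1]) - V_rc / 2
  b2c <- S_c - unname(params$V0[2]) - V_rc / 2
  Mi <- pre$Minv
  x1 <- x_guess[1]; x2 <- x_guess[2]
  for (it in 1:2) {
    e1 <- min(1, max(params$di_eps_floor, 1 - x1 / params$di_eps_zero))
    e2 <- min(1, max(params$di_eps_floor, 1 - x2 / params$di_eps_zero))
    a_i <- e1 * P_act + pre$h_di
    a_c <- e2 * P_act
    b1 <- b1c - Cdi * a_i
    b2 <- b2c - Cdc * a_c
    b3 <- -Cdi * a_i - Cdc * a_c
    u1 <- Mi[1, 1] * b1 + Mi[1, 2] * b2 + Mi[1, 3] * b3
    u2 <- Mi[2, 1] * b1 + Mi[2, 2] * b2 + Mi[2, 3] * b3
    u3 <- Mi[3, 1] * b1 + Mi[3, 2] * b2 + Mi[3, 3] * b3
    x1 <- Cdi * (a_i + u1 - u3)
    x2 <- Cdc * (a_c + u2 - u3)
  }
  list(P_pl = c(u1, u2), P_ab = u3, x_di = c(x1, x2),
       V_med = params$C_med * (u1 - u2))
}

# Time derivative of the integrated state (layer volumes, rib-cage volume)
# plus the algebraic diagnostics.  `openv` is a numeric 0/1 vector.
mech_derivs <- function(t, y, openv, Pb_lag, x_di, V_pf, params, drive, pre) {
  n <- pre$n
  V <- y[seq_len(2L * n)]
  V_rc <- if (pre$rigid_rc) 0 else y[2L * n + 1L]

  P_act <- drive$A * (if (!is.null(drive$waveform) && drive$waveform == "const") 1
                      else {
                        T_b <- 60 / params$RR
                        tc <- t %% T_b
                        Ti <- params$Ti_frac * T_b
                        if (tc < Ti) sin(pi * tc / Ti) else 0
                      })

  S_i <- sum(V[pre$idx_i]) + V_pf
  S_c <- sum(V[pre$idx_c])
  cw <- chest_solve(S_i, S_c, V_rc, P_act, params, pre, x_di)

  Ppl_layer <- c(rep.int(cw$P_pl[1], n), rep.int(cw$P_pl[2], n)) + pre$hyd
  P_el <- lung_recoil(V, pre$Vmax_l, params$lung_k)
  P_alv <- Ppl_layer + P_el

  Pb_rep <- c(rep.int(Pb_lag[1], n), rep.int(Pb_lag[2], n))
  cf <- pmin(1 + params$beta_aw * pmax(0, Ppl_layer - Pb_rep), params$beta_cap)
  g <- openv / (pre$R_layer0 * cf)

  gi <- g[pre$idx_i]; gc <- g[pre$idx_c]
  G1 <- sum(gi); G2 <- sum(gc)
  gp1 <- sum(gi * P_alv[pre$idx_i]); gp2 <- sum(gc * P_alv[pre$idx_c])
  Rmb <- pre$Rmb
  bden1 <- 1 / Rmb[1] + G1; bden2 <- 1 / Rmb[2] + G2
  bb1 <- 1 / (Rmb[1] * bden1); bb2 <- 1 / (Rmb[2] * bden2)
  aa1 <- gp1 / bden1; aa2 <- gp2 / bden2
  Pc <- (aa1 / Rmb[1] + aa2 / Rmb[2]) /
    (1 / params$R_tr + (1 - bb1) / Rmb[1] + (1 - bb2) / Rmb[2])
  Pb <- c(aa1 + bb1 * Pc, aa2 + bb2 * Pc)
  dV <- g * (c(rep.int(Pb[1], n), rep.int(Pb[2], n)) - P_alv)
  Q_mb <- (Pc - Pb) / Rmb

  P_cage <- ((cw$P_pl[1] + pre$hyd_mid) + cw$P_pl[2]) / 2
  dV_rc <- if (pre$rigid_rc) 0 else
    (params$C_rc * (P_cage + params$rc_mus_frac * P_act) - V_rc) /
      (params$R_rc * params$C_rc)

  list(dy = c(dV, dV_rc),
       P_pl = cw$P_pl, P_ab = cw$P_ab, x_di = cw$x_di, V_med = cw$V_med,
       Ppl_layer = Ppl_layer, P_alv = P_alv, Pb = Pb,
       Q_mb = Q_mb, Q_mouth = -Pc / params$R_tr, P_act = P_act)
}

#' Time derivatives of the mechanical state
#'
#' Evaluates the pressure-balance network (mouth, trachea, main bronchi,
#' per-layer collapsible airways, alveoli; mediastinum, rib cage,
#' hemidiaphragms, abdomen) at one instant.  Flow continuity at the carina
#' and bronchial nodes holds exactly because the node pressures are
#' eliminated in closed form.
#'
#' @param state a `mech_state`.
#' @param t time, s.
#' @param params a `patient_params`.
#' @param drive a `drive_state`.
#' @return A list with `dy` (stacked derivatives of layer volumes and the
#'   rib-cage volume) and the instantaneous algebraic variables (`P_pl`,
#'   `Q_mb`, `Q_mouth`, `V_med`, `x_di`, ...).
#' @export
derivatives <- function(state, t, params, drive) {
  y <- c(state$V_alv, state$V_rc)
  if (any(!is.finite(y))) stop("non-finite mechanical state")
  pre <- sim_precompute(params, state$V_pf)
  mech_derivs(t, y, as.numeric(state$open), state$Pb_lag, state$x_di,
              state$V_pf, params, drive, pre)
}

# ---------------------------------------------------------------------------
# Static equilibrium
# ---------------------------------------------------------------------------

# Relaxed (zero-drive) equilibrium at a given pleural fluid volume, used as
# the initial condition.  Damped fixed-point iteration between layer volumes
# (alveolar pressure 0 through an open airway) and the chest-wall balance;
# layer volumes are relaxed continuously so that discrete recruitment flips
# cannot cycle.
static_equilibrium <- function(params, V_pf) {
  pre <- sim_precompute(params, V_pf)
  n <- pre$n
  Ppl <- c(params$P_pl_frc, params$P_pl_frc) + c(0.3 * V_pf, 0)
  x_di <- params$x_di_rest
  V <- rep(params$FRC_side / n, 2L * n)
  cw <- NULL
  for (it in 1:600) {
    Ppl_layer <- c(rep.int(Ppl[1], n), rep.int(Ppl[2], n)) + pre$hyd
    open <- Ppl_layer < -params$P_close
    V_target <- ifelse(open,
                       pre$Vmax_l * (1 - exp(params$lung_k * pmin(Ppl_layer, 0))),
                       params$trapped_frac * pre$Vmax_l)
    V <- V + 0.4 * (V_target - V)
    P_cage <- ((Ppl[1] + pre$hyd_mid) + Ppl[2]) / 2
    V_rc <- if (pre$rigid_rc) 0 else params$C_rc * P_cage
    S_i <- sum(V[pre$idx_i]) + V_pf
    S_c <- sum(V[pre$idx_c])
    cw <- chest_solve(S_i, S_c, V_rc, 0, params, pre, x_di)
    delta <- cw$P_pl - Ppl
    Ppl <- Ppl + 0.25 * delta
    x_di <- cw$x_di
    if (max(abs(delta)) < 1e-10 && max(abs(V_target - V)) < 1e-10) break
  }
  Ppl_layer <- c(rep.int(Ppl[1], n), rep.int(Ppl[2], n)) + pre$hyd
  open <- Ppl_layer < -params$P_close
  V <- ifelse(open,
              pre$Vmax_l * (1 - exp(params$lung_k * pmin(Ppl_layer, 0))),
              params$trapped_frac * pre$Vmax_l)
  new_mech_state(V, open, V_rc, V_pf, Ppl, x_di, cw$V_med)
}

# ---------------------------------------------------------------------------
# Breath simulation (fixed-step RK4)
# ---------------------------------------------------------------------------

# Integrate `n_breaths` full cycles from `state`.  Recruitment flags and
# lagged quantities are updated once per accepted step.
integrate_cycles <- function(state, params, drive, n_breaths,
                             dt_out = 0.04, record = TRUE) {
  pre <- sim_precompute(params, state$V_pf)
  n <- pre$n
  dt <- params$dt
  T_breath <- 60 / params$RR
  steps_per_breath <- max(1L, round(T_breath / dt))
  dt <- T_breath / steps_per_breath
  rec_every <- max(1L, round(dt_out / dt))
  total_steps <- steps_per_breath * n_breaths

  y <- c(state$V_alv, state$V_rc)
  openv <- as.numeric(state$open)
  Pb_lag <- state$Pb_lag
  x_di <- state$x_di
  V_pf <- state$V_pf
  t <- 0
  if (record) {
    nrec <- floor(total_steps / rec_every) + 1L
    rec <- matrix(NA_real_, nrec, 14)
    colnames(rec) <- c("t", "P_pl_ipsi", "P_pl_contra", "Q_mouth",
                       "Q_mb_ipsi", "Q_mb_contra", "V_lung_ipsi",
                       "V_lung_contra", "V_med", "x_di_ipsi", "x_di_contra",
                       "P_act", "open_ipsi", "open_contra")
    irec <- 0L
  }

  d1 <- NULL
  for (k in seq_len(total_steps + 1L)) {
    d1 <- mech_derivs(t, y, openv, Pb_lag, x_di, V_pf, params, drive, pre)
    if (record && ((k - 1L) %% rec_every == 0L)) {
      irec <- irec + 1L
      rec[irec, ] <- c(t, d1$P_pl[1], d1$P_pl[2], d1$Q_mouth,
                       d1$Q_mb[1], d1$Q_mb[2], sum(y[pre$idx_i]),
                       sum(y[pre$idx_c]), d1$V_med, d1$x_di[1], d1$x_di[2],
                       d1$P_act, sum(openv[pre$idx_i]), sum(openv[pre$idx_c]))
    }
    if (k > total_steps) break
    h2 <- dt / 2
    d2 <- mech_derivs(t + h2, y + h2 * d1$dy, openv, Pb_lag, x_di, V_pf,
                      params, drive, pre)
    d3 <- mech_derivs(t + h2, y + h2 * d2$dy, openv, Pb_lag, x_di, V_pf,
                      params, drive, pre)
    d4 <- mech_derivs(t + dt, y + dt * d3$dy, openv, Pb_lag, x_di, V_pf,
                      params, drive, pre)
    y <- y + dt / 6 * (d1$dy + 2 * d2$dy + 2 * d3$dy + d4$dy)
    t <- t + dt
    if (any(!is.finite(y)))
      stop("solver failure: non-finite state at t = ", signif(t, 4))

    # post-step updates: lags and recruitment hysteresis
    x_di <- d1$x_di
    Pb_lag <- d1$Pb
    # available inflation pressure: bronchial node vs. local pleural.  An
    # open layer whose feeding pressure falls below local pleural pressure
    # (beyond P_close) collapses once its gas has actually been squeezed
    # down to the trapped volume; a closed layer reopens past P_open.
    Ppl_layer <- c(rep.int(d1$P_pl[1], n), rep.int(d1$P_pl[2], n)) + pre$hyd
    V <- y[seq_len(2L * n)]
    P_tp <- c(rep.int(Pb_lag[1], n), rep.int(Pb_lag[2], n)) - Ppl_layer
    open_new <- layer_recruitment_update(openv > 0, P_tp, params) |
      ((openv > 0) & V > 1.05 * params$trapped_frac * pre$Vmax_l)
    closed_now <- (openv > 0) & !open_new
    if (any(closed_now)) {
      V[closed_now] <- pmin(V[closed_now], params$trapped_frac * pre$Vmax_l)
      y[seq_len(2L * n)] <- V
    }
    openv <- as.numeric(open_new)
  }

  st <- new_mech_state(y[seq_len(2L * n)], openv > 0,
                       if (pre$rigid_rc) 0 else y[2L * n + 1L],
                       V_pf, d1$P_pl, x_di, d1$V_med)
  st$Pb_lag <- Pb_lag
  out <- list(state = st)
  if (record) out$rec <- as.data.frame(rec[seq_len(irec), , drop = FALSE])
  out
}

#' Simulate steady-state breathing
#'
#' Integrates the respiratory-mechanics network with the fixed-step RK4
#' solver, applying recruitment/derecruitment after every step.  A number of
#' wash-in breaths is discarded before recording; the drive controller
#' [adapt_drive_to_vt()] is run first unless an explicit `drive` is given.
#'
#' @param params a `patient_params`.
#' @param V_pf ipsilateral pleural fluid volume, L.
#' @param n_breaths number of recorded steady-state breaths.
#' @param dt_out output sampling interval, s (default 0.04 s = 25 Hz).
#' @param drive optional `drive_state`; when `NULL` the controller adapts
#'   the amplitude to the target tidal volume first.
#' @param state0 optional warm-start `mech_state` (e.g. from a previous
#'   aliquot); defaults to the relaxed equilibrium at `V_pf`.
#' @param check_periodic if `TRUE`, error when the last two recorded
#'   breaths differ by more than 0.5\% in tidal volume or end-expiratory
#'   volume.
#' @return A list of class `breath_sim` with elements `recording` (a
#'   `breath_recording` data frame), `state` (final `mech_state`), `drive`
#'   and `per_breath` summaries (`VT`, `EEV`, `amp`).
#' @export
simulate_breaths <- function(params, V_pf = 0, n_breaths = 3, dt_out = 0.04,
                             drive = NULL, state0 = NULL,
                             check_periodic = TRUE) {
  stopifnot(inherits(params, "patient_params"), n_breaths >= 1)
  if (is.null(state0)) state0 <- static_equilibrium(params, V_pf)
  state0$V_pf <- V_pf
  if (is.null(drive)) {
    ad <- adapt_drive_to_vt(params, V_pf, state0 = state0)
    drive <- ad$drive
    state0 <- ad$state
    washin <- 2L
  } else washin <- params$washin_breaths
  if (washin > 0L) {
    wi <- integrate_cycles(state0, params, drive, washin, record = FALSE)
    state0 <- wi$state
  }
  T_breath <- 60 / params$RR
  rel <- function(a, b) abs(a - b) / max(abs(b), 1e-9)
  for (attempt in 1:4) {
    out <- integrate_cycles(state0, params, drive, n_breaths,
                            dt_out = dt_out)
    rec <- out$rec
    rec$breath <- pmin(n_breaths, floor(rec$t / T_breath + 1e-9) + 1L)
    Ti <- params$Ti_frac * T_breath
    rec$phase <- ifelse(rec$t %% T_breath < Ti - 1e-9, "inspiration",
                        "expiration")
    class(rec) <- c("breath_recording", "data.frame")
    per_breath <- breath_summaries(rec)
    if (!check_periodic || n_breaths < 2) break
    m <- nrow(per_breath)
    periodic <- rel(per_breath$VT[m], per_breath$VT[m - 1]) <= 0.005 &&
      rel(per_breath$EEV[m], per_breath$EEV[m - 1]) <= 0.005
    if (periodic) break
    if (attempt == 4)
      stop("periodic steady state not reached: tidal volume or ",
           "end-expiratory volume still drifting > 0.5% between breaths")
    state0 <- out$state      # keep washing in until periodic
  }
  structure(list(recording = rec, state = out$state, drive = drive,
                 per_breath = per_breath, params = params, V_pf = V_pf),
            class = "breath_sim")
}

# Per-breath tidal volume (mouth-flow integral), end-expiratory open-gas
# volume and ipsilateral pleural pressure amplitude.
breath_summaries <- function(rec) {
  out <- do.call(rbind, lapply(split(rec, rec$breath), function(b) {
    V <- cumtrapz(b$Q_mouth, dt = b$t[2] - b$t[1])
    data.frame(VT = max(V) - min(V),
               EEV = min(b$V_lung_ipsi + b$V_lung_contra),
               amp = max(b$P_pl_ipsi) - min(b$P_pl_ipsi),
               P_pl_end_exp = b$P_pl_ipsi[length(b$P_pl_ipsi)])
  }))
  rownames(out) <- NULL
  out
}

cumtrapz <- function(x, dt) {
  if (length(x) < 2) return(0 * x)
  c(0, cumsum((x[-1] + x[-length(x)]) / 2 * dt))
}

#' @export
print.breath_sim <- function(x, ...) {
  pb <- x$per_breath[nrow(x$per_breath), ]
  cat("<breath_sim>\n")
  cat(sprintf(
    "  V_pf %.2f L, drive %.3g kPa; VT %.3f L, EEV %.3f L, P_pl amp %.3f kPa\n",
    x$V_pf, x$drive$A, pb$VT, pb$EEV, pb$amp))
  invisible(x)
}

#' Adapt the neural drive to the target tidal volume
#'
#' Deterministic fixed-point iteration on the drive amplitude: each
#' iteration simulates a few breaths from the running state and rescales
#' the amplitude by the (damped) ratio of target to achieved tidal volume,
#' stopping when the tidal volume is within `tol` of `VT_target`.
#'
#' @param params a `patient_params`.
#' @param V_pf pleural fluid volume, L.
#' @param state0 optional warm-start state.
#' @param tol relative tidal-volume tolerance (default 0.02).
#' @param max_iter iteration cap.
#' @return A list with `drive` (converged `drive_state`), `state` (the
#'   mechanical state at the end of the last probe simulation, suitable for
#'   continuing), achieved `VT` and the iteration count.
#' @export
adapt_drive_to_vt <- function(params, V_pf = 0, state0 = NULL, tol = 0.02,
                              max_iter = 15L) {
  if (is.null(state0)) state0 <- static_equilibrium(params, V_pf)
  state0$V_pf <- V_pf
  A <- params$VT_target / 0.6        # first guess from a nominal compliance
  st <- state0
  VT <- NA_real_
  for (it in seq_len(max_iter)) {
    drive <- make_drive(A)
    sim <- integrate_cycles(st, params, drive, 3L, dt_out = 0.02)
    st <- sim$state
    rec <- sim$rec
    T_breath <- 60 / params$RR
    last <- rec[rec$t >= 2 * T_breath, ]
    V <- cumtrapz(last$Q_mouth, dt = last$t[2] - last$t[1])
    VT <- max(V) - min(V)
    if (abs(VT - params$VT_target) <= tol * params$VT_target)
      return(list(drive = drive, state = st, VT = VT, iterations = it))
    A_new <- A * (params$VT_target / max(VT, 1e-6))^0.8
    if (A_new > params$drive_max)
      stop(sprintf(paste0("drive bound %.3g kPa reached before convergence: ",
                          "best achieved VT = %.3f L (target %.3f L)"),
                   params$drive_max, VT, params$VT_target))
    A <- A_new
  }
  stop(sprintf(
    "drive controller did not converge in %d iterations: best VT = %.3f L",
    max_iter, VT))
}
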