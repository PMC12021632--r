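# ---------------------------------------------------------------------------
# Therapeutic thoracentesis protocol
# ---------------------------------------------------------------------------

#' Aliquot schedule for stepwise pleural fluid withdrawal
#'
#' The clinical protocol aspirates 200 mL aliquots until 1 L has been
#' withdrawn, then 100 mL aliquots; the final aliquot is truncated so the
#' cumulative volume hits `total` exactly.
#'
#' @param total total volume to withdraw, L.
#' @return Numeric vector of aliquot volumes, L.
#' @examples
#' make_schedule(0.5)
#' length(make_schedule(3.8))   # 5 x 0.2 + 28 x 0.1
#' @export
make_schedule <- function(total) {
  if (!is.numeric(total) || length(total) != 1L || total < 0)
    stop("total withdrawal volume must be a non-negative number")
  out <- numeric(0)
  cum <- 0
  repeat {
    if (total - cum < 1e-12) break
    step <- if (cum < 1 - 1e-12) 0.2 else 0.1
    step <- min(step, total - cum)
    out <- c(out, step)
    cum <- cum + step
  }
  out
}

#' Run a simulated therapeutic thoracentesis session
#'
#' Starting from the relaxed state at `V_pf0`, records a baseline breathing
#' interval, then withdraws fluid aliquot by aliquot following
#' [make_schedule()].  After each aliquot the drive controller re-adapts to
#' the target tidal volume and the model is run to a periodic steady state
#' before the interval observables are recorded: pleural pressure at FRC,
#' median pressure amplitude, the pressure-volume loop and its morphology,
#' pendelluft fraction, open-layer counts and steady-state gases.
#'
#' @param params a `patient_params`.
#' @param V_pf0 initial pleural fluid volume, L.
#' @param stop total volume to withdraw, L (default: all of it).
#' @param n_breaths recorded breaths per interval.
#' @param keep_recordings keep each interval's full `breath_recording`
#'   (memory-heavier); loops are always kept.
#' @return An object of class `tt_session`: a list with `aliquots` (data
#'   frame, one row per interval including baseline), `loops`, `schedule`,
#'   `params`, and optionally `recordings`.
#' @export
run_tt <- function(params, V_pf0 = 3.0, stop = V_pf0, n_breaths = 2,
                   keep_recordings = FALSE) {
  stopifnot(inherits(params, "patient_params"))
  if (stop > V_pf0 + 1e-12) stop("cannot withdraw more than the initial volume")
  schedule <- make_schedule(stop)
  V_pf <- V_pf0
  state <- static_equilibrium(params, V_pf)
  rows <- list(); loops <- list(); recs <- list()
  for (k in seq_len(length(schedule) + 1L)) {
    aliq <- if (k == 1L) 0 else schedule[k - 1L]
    if (k > 1L) {
      V_pf <- max(0, V_pf - aliq)
      state$V_pf <- V_pf
    }
    sim <- tryCatch(
      simulate_breaths(params, V_pf = V_pf, n_breaths = n_breaths,
                       state0 = state),
      error = function(e)
        stop("aliquot ", k - 1L, " (V_withdrawn = ",
             signif(V_pf0 - V_pf, 4), " L): ", conditionMessage(e)))
    state <- sim$state
    b <- sim$recording[sim$recording$breath == max(sim$recording$breath), ]
    dt <- b$t[2] - b$t[1]
    V <- cumtrapz(b$Q_mouth, dt)
    loop <- pv_loop(b$P_pl_ipsi, V)
    met <- loop_metrics(loop)
    pf <- pendelluft_fraction(b$Q_mb_ipsi, b$Q_mb_contra)
    gs <- gases_from_sim(sim)
    amps <- sim$per_breath$amp
    n <- params$n_layers
    rows[[k]] <- data.frame(
      interval = k - 1L,
      V_withdrawn_cum = V_pf0 - V_pf,
      V_pf = V_pf,
      P_pl_at_FRC = b$P_pl_ipsi[nrow(b)],
      amp_median = stats::median(amps),
      lean = met$lean,
      eight_shaped = met$eight_shaped,
      PaO2 = gs$PaO2, PaCO2 = gs$PaCO2,
      P_AO2_contra = gs$P_AO2[2],
      q_shunt = gs$q_shunt,
      pendelluft_fraction = pf$fraction,
      open_ipsi = sum(state$open[seq_len(n)]),
      open_contra = sum(state$open[n + seq_len(n)]),
      FRC_total = gs$FRC[1] + gs$FRC[2],
      fresh_gas_ratio_contra = gs$fresh_gas_ratio[2],
      VT = sim$per_breath$VT[nrow(sim$per_breath)],
      drive_A = sim$drive$A)
    loops[[k]] <- loop
    if (keep_recordings) recs[[k]] <- sim$recording
  }
  ses <- structure(list(aliquots = do.call(rbind, rows), loops = loops,
                        schedule = schedule, V_pf0 = V_pf0, params = params),
                   class = "tt_session")
  if (keep_recordings) ses$recordings <- recs
  ses
}

#' @export
print.tt_session <- function(x, ...) {
  a <- x$aliquots
  cat(sprintf("<tt_session> %d intervals, %.2f -> %.2f L pleural fluid\n",
              nrow(a), x$V_pf0, a$V_pf[nrow(a)]))
  cat(sprintf("  P_pl@FRC %.2f -> %.2f kPa; amp %.2f -> %.2f kPa; PaO2 %.1f -> %.1f kPa\n",
              a$P_pl_at_FRC[1], a$P_pl_at_FRC[nrow(a)],
              a$amp_median[1], a$amp_median[nrow(a)],
              a$PaO2[1], a$PaO2[nrow(a)]))
  invisible(x)
}

#' Two-stage trend slopes of a session observable
#'
#' Convenience wrapper around [stage_slopes()] for a `tt_session` column,
#' trended against withdrawn volume.
#'
#' @param session a `tt_session`.
#' @param what column of `session$aliquots` to trend.
#' @param split stage boundary, L.
#' @return A `trend_slopes` object.
#' @export
session_slopes <- function(session, what = "amp_median", split = 1.9) {
  a <- session$aliquots
  stage_slopes(a$V_withdrawn_cum, a[[what]], a$V_withdrawn_cum, split = split)
}

#' Serialize a session to JSON
#'
#' @param session a `tt_session`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tt_session <- function(session, path) {
  out <- list(
    V_pf0 = session$V_pf0,
    schedule = session$schedule,
    aliquots = session$aliquots,
    loops = lapply(session$loops, function(l)
      list(P = l$P, V = l$V, phase = l$phase)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
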