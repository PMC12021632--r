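# ---------------------------------------------------------------------------
# Synthetic manometry + spirometry sessions
# ---------------------------------------------------------------------------

#' Specification of a synthetic recording session
#'
#' Defines a parametric stand-in for a clinical drainage recording:
#' 25 Hz pleural pressure and mouth flow in one-minute intervals between
#' aliquots, with per-interval mean pressure and amplitude following linear
#' trajectories in withdrawn volume.  The pressure waveform is a
#' two-harmonic series: with no second harmonic the loop is an ellipse
#' whose lean is set by the phase offset `lean_phase`; a sufficiently
#' strong second harmonic (`eight_w`) makes the loop self-intersect.  This
#' is a signal-level emulation for exercising the analysis pipeline, not a
#' physiological model.
#'
#' @param RR respiratory rate, 1/min.
#' @param VT tidal volume, L.
#' @param fs sampling frequency, Hz.
#' @param total total withdrawn volume, L (drives [make_schedule()]).
#' @param P_mean0,P_mean_slope mean pleural pressure at baseline (kPa) and
#'   its slope per L withdrawn.
#' @param amp0,amp_slope first-harmonic peak-to-peak amplitude (kPa) and
#'   slope per L withdrawn.
#' @param lean_phase phase offset of pressure relative to flow, rad;
#'   negative values lean the loop left.
#' @param eight_w second-harmonic weight relative to the first (0 = simple
#'   ellipse).
#' @param noise_sd additive Gaussian noise on pressure, kPa.
#' @param seed RNG seed (mandatory; the generator uses a private stream).
#' @param interval_s recorded seconds per interval.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(RR = 12, VT = 0.5, fs = 25, total = 3.8,
                       P_mean0 = 1.0, P_mean_slope = -0.4,
                       amp0 = 0.6, amp_slope = 0.15,
                       lean_phase = 0, eight_w = 0, noise_sd = 0,
                       seed, interval_s = 60) {
  if (missing(seed)) stop("seed is mandatory for a synth_spec")
  if (fs <= 8 * RR / 60) stop("fs too low to resolve breaths")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(RR = RR, VT = VT, fs = fs, total = total,
                 P_mean0 = P_mean0, P_mean_slope = P_mean_slope,
                 amp0 = amp0, amp_slope = amp_slope,
                 lean_phase = lean_phase, eight_w = eight_w,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 interval_s = interval_s),
            class = "synth_spec")
}

# Evaluate one noiseless breath of the spec at given interval trajectory
# values; t is time within the breath.
synth_waveforms <- function(spec, t, P_mean, amp) {
  T_b <- 60 / spec$RR
  om <- 2 * pi / T_b
  Qamp <- pi * spec$VT / T_b         # inspired volume = Qamp * T/pi = VT
  flow <- Qamp * sin(om * t)
  a <- amp / 2
  P <- P_mean + a * sin(om * t + spec$lean_phase) +
    spec$eight_w * a * sin(2 * om * t + pi / 3)
  list(flow = flow, P = P)
}

#' Generate one synthetic breath
#'
#' @param spec a `synth_spec`.
#' @param breath_index 1-based breath counter (controls the noise stream
#'   position only).
#' @param P_mean,amp trajectory values for the containing interval;
#'   default baseline values.
#' @return A data frame with `t`, `Ppl`, `flow` covering one breath.
#' @export
gen_breath <- function(spec, breath_index = 1L, P_mean = spec$P_mean0,
                       amp = spec$amp0) {
  T_b <- 60 / spec$RR
  t <- seq(0, T_b - 1 / spec$fs, by = 1 / spec$fs)
  wf <- synth_waveforms(spec, t, P_mean, amp)
  if (spec$noise_sd > 0) {
    noise <- with_private_rng(spec$seed + breath_index,
                              stats::rnorm(length(t), 0, spec$noise_sd))
    wf$P <- wf$P + noise
  }
  data.frame(t = t, Ppl = wf$P, flow = wf$flow)
}

# Run `expr` under a private RNG stream, restoring global state.
with_private_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a full synthetic drainage session
#'
#' Produces a 25 Hz recording with one `interval_s`-second interval at
#' baseline and after each aliquot of the withdrawal schedule, plus
#' per-interval vitals and the ground truth of every quantity the analysis
#' pipeline should recover.  Byte-identical for identical specs.
#'
#' @param spec a `synth_spec`.
#' @return A list of class `synth_session`: `recording` (data frame `t`,
#'   `Ppl`, `flow`, `interval`, `V_withdrawn`), `vitals` (per interval),
#'   `truth` (list: per-interval `amp`, `P_mean`, `lean`, `eight`, and the
#'   trajectory slopes).
#' @export
gen_session <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  sched <- make_schedule(spec$total)
  Vw <- c(0, cumsum(sched))
  n_int <- length(Vw)
  T_b <- 60 / spec$RR
  n_breaths <- max(1L, floor(spec$interval_s / T_b))
  parts <- vector("list", n_int)
  vit <- vector("list", n_int)
  truth_amp <- numeric(n_int); truth_lean <- character(n_int)
  truth_eight <- logical(n_int); truth_pmean <- numeric(n_int)
  t_off <- 0
  for (i in seq_len(n_int)) {
    P_mean <- spec$P_mean0 + spec$P_mean_slope * Vw[i]
    amp <- spec$amp0 + spec$amp_slope * Vw[i]
    t <- seq(0, n_breaths * T_b - 1 / spec$fs, by = 1 / spec$fs)
    wf <- synth_waveforms(spec, t, P_mean, amp)
    P <- wf$P
    if (spec$noise_sd > 0)
      P <- P + with_private_rng(spec$seed * 1000L + i,
                                stats::rnorm(length(t), 0, spec$noise_sd))
    parts[[i]] <- data.frame(t = t_off + t, Ppl = P, flow = wf$flow,
                             interval = i - 1L, V_withdrawn = Vw[i])
    t_off <- t_off + n_breaths * T_b
    # noiseless single-breath ground truth
    tb <- seq(0, T_b - 1 / spec$fs, by = 1 / spec$fs)
    wb <- synth_waveforms(spec, tb, P_mean, amp)
    truth_amp[i] <- max(wb$P) - min(wb$P)
    truth_pmean[i] <- P_mean
    Vb <- cumtrapz(wb$flow, 1 / spec$fs)
    lp <- pv_loop(wb$P, Vb)
    truth_lean[i] <- classify_lean(lp)
    truth_eight[i] <- detect_eight(lp)$eight
    vit[[i]] <- data.frame(
      interval = i - 1L, V_withdrawn = Vw[i], t_min = (i - 1L),
      SBP = 125 - 2 * Vw[i], DBP = 80, HR = 80 - 1.5 * Vw[i],
      VT = spec$VT, RR = spec$RR)
  }
  structure(list(
    recording = do.call(rbind, parts),
    vitals = do.call(rbind, vit),
    truth = list(amp = truth_amp, P_mean = truth_pmean,
                 lean = truth_lean, eight = truth_eight,
                 V_withdrawn = Vw,
                 amp_slope = spec$amp_slope,
                 P_mean_slope = spec$P_mean_slope),
    spec = spec), class = "synth_session")
}

#' Analyze a synthetic session with the measurement pipeline
#'
#' Applies [analyze_recording()] interval by interval and assembles the
#' per-interval amplitude trend for [stage_slopes()].
#'
#' @param session a `synth_session`.
#' @param epsilon lean dead band, kPa.
#' @return A data frame with one row per interval (`V_withdrawn`,
#'   `amp_median`, `lean`, `eight_shaped`).
#' @export
analyze_session <- function(session, epsilon = 0.05) {
  rec <- session$recording
  fs <- session$spec$fs
  out <- lapply(split(rec, rec$interval), function(ri) {
    an <- analyze_recording(ri, fs, epsilon = epsilon)
    data.frame(interval = ri$interval[1], V_withdrawn = ri$V_withdrawn[1],
               amp_median = an$amp_median, lean = an$lean,
               eight_shaped = an$eight_shaped, n_breaths = an$n_breaths)
  })
  res <- do.call(rbind, out)
  res[order(res$interval), ]
}

#' Write a synthetic session to CSV (+ ground-truth JSON)
#'
#' @param session a `synth_session`.
#' @param path CSV path for the recording.
#' @param truth_path optional JSON path for the ground truth.
#' @return `path`, invisibly.
#' @export
write_synth_session <- function(session, path, truth_path = NULL) {
  utils::write.csv(session$recording, path, row.names = FALSE)
  if (!is.null(truth_path))
    jsonlite::write_json(session$truth, truth_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
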