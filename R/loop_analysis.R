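# ---------------------------------------------------------------------------
# Breath segmentation and volume reconstruction
# ---------------------------------------------------------------------------

#' Segment a flow signal into breaths
#'
#' Breaths are delimited at inspiratory onsets: upward crossings of zero
#' mouth flow, detected with a hysteresis band of +/- `hyst_frac` of the
#' peak absolute flow so that noise below the band cannot split a breath.
#' The leading and trailing partial breaths are dropped.
#'
#' @param flow mouth airflow samples, L/s (positive = inspiratory).
#' @param fs sampling frequency, Hz.
#' @param hyst_frac hysteresis half-band as a fraction of peak flow.
#' @return A list of integer index ranges (`start`, `end`), one per
#'   complete breath; `end` is the sample before the next onset.
#' @export
segment_breaths <- function(flow, fs, hyst_frac = 0.02) {
  if (fs <= 0) stop("fs must be positive")
  if (length(flow) < 4) stop("flow series too short")
  peak <- max(abs(flow))
  if (peak == 0) stop("no complete breath found: flow is identically zero")
  band <- hyst_frac * peak
  onsets <- integer(0)
  armed <- TRUE                    # treat the start as if expiring
  for (i in seq_along(flow)) {
    if (armed && flow[i] > band) {
      onsets <- c(onsets, i)
      armed <- FALSE
    } else if (!armed && flow[i] < -band) {
      armed <- TRUE
    }
  }
  if (length(onsets) < 2)
    stop("no complete breath found: fewer than two inspiratory onsets")
  lapply(seq_len(length(onsets) - 1L), function(k)
    list(start = onsets[k], end = onsets[k + 1L] - 1L))
}

#' Integrate airflow into volume
#'
#' Cumulative trapezoidal integral of the flow signal.  When breath ranges
#' are supplied the volume is re-zeroed at each inspiratory onset, removing
#' integration drift per breath as is standard for spirometry-derived
#' pressure-volume loops.
#'
#' @param flow airflow, L/s.
#' @param fs sampling frequency, Hz.
#' @param breaths optional result of [segment_breaths()].
#' @return Volume signal, L, same length as `flow`.
#' @export
integrate_flow <- function(flow, fs, breaths = NULL) {
  if (any(!is.finite(flow))) stop("flow contains non-finite samples")
  V <- cumtrapz(flow, dt = 1 / fs)
  if (!is.null(breaths)) {
    for (b in breaths) {
      idx <- b$start:b$end
      V[idx] <- V[idx] - V[b$start]
    }
  }
  V
}

# ---------------------------------------------------------------------------
# Pressure-volume loops
# ---------------------------------------------------------------------------

#' Construct a pleural pressure-volume loop
#'
#' One breath's closed (P, V) curve, where P is the ipsilateral pleural
#' pressure and V the volume inhaled/exhaled by the whole respiratory
#' system (zeroed at the breath onset).  Phase labels mark samples up to
#' the volume peak as inspiration.
#'
#' @param P pleural pressure samples, kPa.
#' @param V volume samples, L.
#' @return An object of class `pv_loop`.
#' @export
pv_loop <- function(P, V) {
  stopifnot(length(P) == length(V))
  if (length(P) < 8) stop("a loop needs at least 8 samples")
  imax <- which.max(V)
  phase <- rep("expiration", length(V))
  phase[seq_len(imax)] <- "inspiration"
  structure(list(P = P, V = V, phase = phase), class = "pv_loop")
}

#' @export
print.pv_loop <- function(x, ...) {
  m <- loop_metrics(x)
  cat(sprintf("<pv_loop> %d samples, amplitude %.3f kPa, lean %s%s\n",
              length(x$P), m$amplitude, m$lean,
              if (m$eight_shaped) ", 8-shaped" else ""))
  invisible(x)
}

#' Plot a pressure-volume loop
#'
#' @param x a `pv_loop`.
#' @param ... passed to [plot()].
#' @export
plot.pv_loop <- function(x, ...) {
  insp <- x$phase == "inspiration"
  plot(x$P, x$V, type = "n", xlab = "P_pl ipsilateral (kPa)",
       ylab = "Inhaled volume (L)", ...)
  lines(x$P[insp], x$V[insp], col = "darkgreen")
  lines(x$P[!insp], x$V[!insp], col = "firebrick")
  invisible(x)
}

#' Classify the lean of a pressure-volume loop
#'
#' If the ipsilateral pleural pressure at the end of inspiration (volume
#' peak) exceeds the end-expiratory pressure by more than `epsilon`, the
#' loop leans to the left and the hemidiaphragm is functionally inverted
#' (pleural pressure paradoxically rises on inspiration); the mirror case
#' leans right; differences within `epsilon` are vertical.
#'
#' @param loop a `pv_loop`.
#' @param epsilon dead band for the vertical class, kPa.
#' @return `"left"`, `"vertical"` or `"right"`.
#' @export
classify_lean <- function(loop, epsilon = 0.05) {
  stopifnot(inherits(loop, "pv_loop"))
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (is.null(loop$phase)) stop("loop lacks phase labels")
  d <- lean_delta(loop)
  if (d > epsilon) "left" else if (d < -epsilon) "right" else "vertical"
}

# End-inspiratory minus end-expiratory pressure.
lean_delta <- function(loop) {
  P_ei <- loop$P[which.max(loop$V)]
  P_ee <- loop$P[length(loop$P)]
  P_ei - P_ee
}

#' Detect a figure-eight (self-intersecting) loop
#'
#' Tests whether the closed polyline of the loop properly self-intersects:
#' some pair of non-adjacent segments crosses transversally.  Figure-eight
#' loops arise when the direction of the ipsilateral pressure excursion
#' reverses mid-phase (paradoxical hemidiaphragm action with interlung gas
#' redistribution).
#'
#' @param loop a `pv_loop`.
#' @return A list with `eight` (logical) and `crossings` (matrix of
#'   crossing coordinates, 0 rows if none).
#' @export
detect_eight <- function(loop) {
  stopifnot(inherits(loop, "pv_loop"))
  x <- loop$P; y <- loop$V
  # collapse consecutive duplicate vertices
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]; y <- y[keep]
  m <- length(x)
  if (m < 4) stop("degenerate loop: fewer than 4 distinct vertices")
  # degeneracy = all vertices (numerically) collinear; the signed shoelace
  # area is useless here because the two lobes of a figure-eight cancel it
  sx <- diff(range(x)); sy <- diff(range(y))
  cross <- (x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1])
  if (!is.finite(sx + sy) || max(abs(cross)) <= 1e-12 * max(sx, sy, 1)^2)
    stop("degenerate loop: zero enclosed area")
  # closed polyline: segment i runs from vertex i to i+1 (mod m)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  crossings <- NULL
  for (i in seq_len(m - 2L)) {
    jmax <- if (i == 1L) m - 1L else m
    js <- (i + 2L):jmax
    if (!length(js)) next
    d1x <- x2[i] - x[i]; d1y <- y2[i] - y[i]
    d2x <- x2[js] - x[js]; d2y <- y2[js] - y[js]
    denom <- d1x * d2y - d1y * d2x
    ex <- x[js] - x[i]; ey <- y[js] - y[i]
    tnum <- ex * d2y - ey * d2x
    unum <- ex * d1y - ey * d1x
    ok <- abs(denom) > 1e-14
    tt <- tnum / denom; uu <- unum / denom
    hit <- ok & tt > 1e-9 & tt < 1 - 1e-9 & uu > 1e-9 & uu < 1 - 1e-9
    if (any(hit)) {
      px <- x[i] + tt[hit] * d1x
      py <- y[i] + tt[hit] * d1y
      crossings <- rbind(crossings, cbind(P = px, V = py))
    }
  }
  if (is.null(crossings)) crossings <- matrix(numeric(0), 0, 2,
                                              dimnames = list(NULL, c("P", "V")))
  list(eight = nrow(crossings) > 0, crossings = crossings)
}

#' Summary metrics of one loop
#'
#' @param loop a `pv_loop`.
#' @param epsilon lean dead band, kPa.
#' @return A list: `lean`, `eight_shaped`, `amplitude` (max P - min P),
#'   `P_end_insp`, `P_end_exp`.
#' @export
loop_metrics <- function(loop, epsilon = 0.05) {
  e8 <- tryCatch(detect_eight(loop)$eight, error = function(e) FALSE)
  list(lean = classify_lean(loop, epsilon),
       eight_shaped = e8,
       amplitude = max(loop$P) - min(loop$P),
       P_end_insp = loop$P[which.max(loop$V)],
       P_end_exp = loop$P[length(loop$P)])
}

# ---------------------------------------------------------------------------
# Interval statistics
# ---------------------------------------------------------------------------

#' Median per-breath pleural pressure amplitude
#'
#' The manometry summary recorded between aliquots: each breath's
#' amplitude is max - min of the pleural pressure over the breath, and the
#' interval statistic is the median across complete breaths (robust to a
#' cough or swallow corrupting one breath).
#'
#' @param P pleural pressure samples, kPa.
#' @param fs sampling frequency, Hz.
#' @param breaths breath ranges from [segment_breaths()]; if `NULL`,
#'   `flow` must be given and is segmented first.
#' @param flow optional mouth flow for segmentation.
#' @return Median amplitude, kPa.
#' @export
amplitude_stats <- function(P, fs, breaths = NULL, flow = NULL) {
  if (is.null(breaths)) {
    if (is.null(flow)) stop("either breaths or flow must be supplied")
    breaths <- segment_breaths(flow, fs)
  }
  if (!length(breaths)) stop("no complete breath in interval")
  amps <- vapply(breaths, function(b) {
    seg <- P[b$start:b$end]
    max(seg) - min(seg)
  }, numeric(1))
  stats::median(amps)
}

#' Pendelluft fraction of a breath
#'
#' Fraction of samples in which the two main-bronchial flows have opposite
#' signs (gas leaving one lung while entering the other), both beyond a
#' dead band of `dead_frac` of each series' peak flow.  The returned mask
#' marks the opposing samples, so their phase distribution (late
#' inspiration / early expiration) can be inspected.
#'
#' @param Q_ipsi,Q_contra main-bronchial flows, L/s, equal length.
#' @param dead_frac dead band fraction (default 1\% of peak flow).
#' @param phase optional per-sample phase labels carried into the output.
#' @return List with `fraction`, logical `mask`, and `phase` (mask-aligned
#'   labels, if given).
#' @export
pendelluft_fraction <- function(Q_ipsi, Q_contra, dead_frac = 0.01,
                                phase = NULL) {
  if (length(Q_ipsi) != length(Q_contra))
    stop("flow series must have equal length")
  band_i <- dead_frac * max(abs(Q_ipsi))
  band_c <- dead_frac * max(abs(Q_contra))
  mask <- (Q_ipsi > band_i & Q_contra < -band_c) |
          (Q_ipsi < -band_i & Q_contra > band_c)
  out <- list(fraction = mean(mask), mask = mask)
  if (!is.null(phase)) out$phase <- phase[mask]
  out
}

#' Pulse-pressure cardiac output index and minute ventilation
#'
#' `co_index()` is the pulse pressure times heart rate, a trend proxy for
#' cardiac output when stroke volume is not measurable; `minute_ventilation()`
#' is tidal volume times respiratory rate.
#'
#' @param SBP,DBP systolic and diastolic pressures (any consistent unit).
#' @param HR heart rate, 1/min.
#' @param VT tidal volume, L.
#' @param RR respiratory rate, 1/min.
#' @return Numeric index (pressure unit / min), or L/min.
#' @examples
#' co_index(120, 80, 60)
#' minute_ventilation(0.5, 12)
#' @export
co_index <- function(SBP, DBP, HR) {
  if (any(SBP <= DBP)) stop("SBP must exceed DBP")
  if (any(DBP <= 0) || any(HR <= 0)) stop("DBP and HR must be positive")
  (SBP - DBP) * HR
}

#' @rdname co_index
#' @export
minute_ventilation <- function(VT, RR) {
  if (any(VT <= 0) || any(RR <= 0)) stop("VT and RR must be positive")
  VT * RR
}

#' Two-stage trend slopes
#'
#' Ordinary least-squares slope of `y` on `x`, computed separately for
#' points with withdrawn volume below `split` (first drainage stage) and at
#' or above it (second stage).  A stage with fewer than two points, or with
#' no spread in `x`, has slope `NA`.
#'
#' @param x abscissa (time in min, or withdrawn volume in L).
#' @param y trended quantity.
#' @param V_withdrawn cumulative withdrawn volume per point, L.
#' @param split stage boundary, L (default 1.9).
#' @return A list of class `trend_slopes`: `slope_stage1`, `slope_stage2`,
#'   `split_at`, `n_stage1`, `n_stage2`.
#' @export
stage_slopes <- function(x, y, V_withdrawn, split = 1.9) {
  stopifnot(length(x) == length(y), length(x) == length(V_withdrawn))
  if (split <= 0) stop("split must be positive")
  ols <- function(sel) {
    if (sum(sel) < 2 || stats::var(x[sel]) == 0) return(NA_real_)
    stats::cov(x[sel], y[sel]) / stats::var(x[sel])
  }
  s1 <- V_withdrawn < split
  structure(list(slope_stage1 = ols(s1), slope_stage2 = ols(!s1),
                 split_at = split, n_stage1 = sum(s1), n_stage2 = sum(!s1)),
            class = "trend_slopes")
}

#' @export
print.trend_slopes <- function(x, ...) {
  cat(sprintf("<trend_slopes> stage1 (<%g L): %s (n=%d); stage2: %s (n=%d)\n",
              x$split_at, format(x$slope_stage1, digits = 4), x$n_stage1,
              format(x$slope_stage2, digits = 4), x$n_stage2))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Whole-recording analysis
# ---------------------------------------------------------------------------

#' Analyze a manometry + spirometry recording
#'
#' Runs the full measurement pipeline on a recording data frame (columns
#' `t`, `Ppl`, `flow`, optionally `Q_ipsi`/`Q_contra`): segments breaths,
#' integrates flow, builds per-breath loops and aggregates their metrics.
#'
#' @param rec data frame with at least `t`, `Ppl`, `flow`.
#' @param fs sampling frequency, Hz.
#' @param epsilon lean dead band, kPa.
#' @return A list: `n_breaths`, `amp_median`, `lean` (modal class),
#'   `eight_shaped` (majority), `loops` (list of `pv_loop`),
#'   `pendelluft` (if bronchial flows present).
#' @export
analyze_recording <- function(rec, fs, epsilon = 0.05) {
  stopifnot(all(c("Ppl", "flow") %in% names(rec)))
  breaths <- segment_breaths(rec$flow, fs)
  V <- integrate_flow(rec$flow, fs, breaths)
  loops <- lapply(breaths, function(b)
    pv_loop(rec$Ppl[b$start:b$end], V[b$start:b$end]))
  mets <- lapply(loops, loop_metrics, epsilon = epsilon)
  leans <- vapply(mets, `[[`, character(1), "lean")
  out <- list(
    n_breaths = length(breaths),
    amp_median = stats::median(vapply(mets, `[[`, numeric(1), "amplitude")),
    lean = names(sort(table(leans), decreasing = TRUE))[1],
    eight_shaped = mean(vapply(mets, `[[`, logical(1), "eight_shaped")) > 0.5,
    loops = loops)
  if (all(c("Q_ipsi", "Q_contra") %in% names(rec))) {
    ph <- rep(NA_character_, nrow(rec))
    for (b in breaths) {
      idx <- b$start:b$end
      imax <- idx[which.max(V[idx])]
      ph[idx] <- ifelse(idx <= imax, "inspiration", "expiration")
    }
    out$pendelluft <- pendelluft_fraction(rec$Q_ipsi, rec$Q_contra,
                                          phase = ph)
  }
  out
}
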