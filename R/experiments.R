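# ---------------------------------------------------------------------------
# The four-question experiment grid
# ---------------------------------------------------------------------------

#' Run one of the four standard in-silico experiments
#'
#' The simulator's study design revolves around four questions about large
#' unilateral effusion:
#' \describe{
#'   \item{q1}{Why may the hemidiaphragm escape functional inversion despite
#'     a very large effusion?  Sweep mediastinal compliance over
#'     `sweep` x default at 3 L effusion and classify the loop lean of each
#'     run.}
#'   \item{q2}{Why are some pressure-volume loops 8-shaped?  Run the stiff
#'     mediastinum preset at 3 L and return the loop, the phase-resolved
#'     main-bronchial flows and the pendelluft mask.}
#'   \item{q3}{Why is the blood-gas response to drainage blunted?  Full
#'     drainage session on the default patient, tracking shunt, per-lung
#'     alveolar gases and the fresh-gas dilution ratio.}
#'   \item{q4}{Why may the pleural pressure amplitude fall during early
#'     drainage?  Drainage sessions under the compliant and stiff
#'     mediastinum presets, comparing amplitude trajectories.}
#' }
#'
#' @param q question number, 1..4.
#' @param overrides named list of parameter overrides applied on top of
#'   each preset involved.
#' @param V_pf effusion volume, L (default 3).
#' @param sweep multipliers for the q1 compliance sweep.
#' @return A list report; every report carries `provenance` (parameter
#'   hash, solver settings) and is deterministic under the fixed-step
#'   solver.
#' @export
run_question <- function(q, overrides = list(), V_pf = 3.0,
                         sweep = c(0.2, 0.5, 1, 2, 5)) {
  if (!(q %in% 1:4)) stop("q must be 1, 2, 3 or 4")
  rep <- switch(as.character(q),
    "1" = q1_lean_sweep(overrides, V_pf, sweep),
    "2" = q2_eight_shape(overrides, V_pf),
    "3" = q3_gases(overrides, V_pf),
    "4" = q4_amplitude(overrides, V_pf))
  rep$question <- q
  rep
}

provenance <- function(params) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(params)[order(names(unclass(params)))], tf,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(config_md5 = unname(tools::md5sum(tf)),
       dt = params$dt, n_layers = params$n_layers,
       solver = "fixed-step RK4")
}

sim_loop_metrics <- function(params, V_pf, n_breaths = 2) {
  # 10 ms sampling: loop-geometry classification (self-intersection) needs
  # a finer grid than the 25 Hz manometry dialect
  sim <- simulate_breaths(params, V_pf = V_pf, n_breaths = n_breaths,
                          dt_out = 0.01)
  b <- sim$recording[sim$recording$breath == max(sim$recording$breath), ]
  V <- cumtrapz(b$Q_mouth, b$t[2] - b$t[1])
  loop <- pv_loop(b$P_pl_ipsi, V)
  imax <- which.max(V)
  phase <- rep("expiration", nrow(b)); phase[seq_len(imax)] <- "inspiration"
  list(sim = sim, breath = b, loop = loop,
       metrics = loop_metrics(loop),
       pendelluft = pendelluft_fraction(b$Q_mb_ipsi, b$Q_mb_contra,
                                        phase = phase),
       phase = phase)
}

q1_lean_sweep <- function(overrides, V_pf, sweep) {
  base <- build_patient("default", overrides)
  runs <- lapply(sweep, function(f) {
    p <- scale_param(base, "C_med", f)
    r <- sim_loop_metrics(p, V_pf)
    list(C_med_factor = f, C_med = p$C_med,
         lean = r$metrics$lean, lean_delta = lean_delta(r$loop),
         eight_shaped = r$metrics$eight_shaped,
         amplitude = r$metrics$amplitude,
         open_ipsi = sum(r$sim$state$open[seq_len(p$n_layers)]))
  })
  list(kind = "C_med lean sweep", V_pf = V_pf,
       sweep = do.call(rbind, lapply(runs, as.data.frame)),
       provenance = provenance(base))
}

q2_eight_shape <- function(overrides, V_pf) {
  p <- build_patient("stiff_mediastinum", overrides)
  r <- sim_loop_metrics(p, V_pf)
  b <- r$breath
  list(kind = "figure-eight morphology (stiff mediastinum)",
       V_pf = V_pf,
       metrics = r$metrics,
       loop = r$loop,
       flows = data.frame(t = b$t, Q_mb_ipsi = b$Q_mb_ipsi,
                          Q_mb_contra = b$Q_mb_contra, phase = r$phase),
       pendelluft = r$pendelluft,
       provenance = provenance(p))
}

q3_gases <- function(overrides, V_pf) {
  p <- build_patient("default", overrides)
  ses <- run_tt(p, V_pf0 = V_pf)
  a <- ses$aliquots
  list(kind = "gases along full drainage",
       session = a,
       slopes_PaO2 = session_slopes(ses, "PaO2"),
       slopes_shunt = session_slopes(ses, "q_shunt"),
       provenance = provenance(p))
}

q4_amplitude <- function(overrides, V_pf) {
  pc <- build_patient("compliant_mediastinum", overrides)
  ps <- build_patient("stiff_mediastinum", overrides)
  sc <- run_tt(pc, V_pf0 = V_pf)
  ss <- run_tt(ps, V_pf0 = V_pf)
  list(kind = "amplitude trajectory, compliant vs stiff mediastinum",
       compliant = sc$aliquots[, c("V_withdrawn_cum", "amp_median", "lean",
                                   "open_ipsi")],
       stiff = ss$aliquots[, c("V_withdrawn_cum", "amp_median", "lean",
                               "open_ipsi")],
       slopes_compliant = session_slopes(sc, "amp_median"),
       slopes_stiff = session_slopes(ss, "amp_median"),
       provenance = list(compliant = provenance(pc),
                         stiff = provenance(ps)))
}
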