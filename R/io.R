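# ---------------------------------------------------------------------------
# Recording CSV dialects
# ---------------------------------------------------------------------------

#' Write / read recording CSV files
#'
#' Two tidy CSV dialects are supported: the simulator dialect (all columns
#' of a `breath_recording`, one row per sample) and the manometry dialect
#' used by the analysis pipeline (`t`, `Ppl`, `flow`, optionally `Q_ipsi`,
#' `Q_contra`, `V_withdrawn`, vitals).  `read_recording_csv()` accepts
#' either and maps simulator column names onto the analysis names.
#'
#' @param rec a `breath_recording` or any data frame of samples.
#' @param path file path.
#' @return `read_recording_csv()` returns a data frame with at least `t`,
#'   `Ppl`, `flow`.
#' @export
write_recording_csv <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!"Ppl" %in% names(d) && "P_pl_ipsi" %in% names(d)) d$Ppl <- d$P_pl_ipsi
  if (!"flow" %in% names(d) && "Q_mouth" %in% names(d)) d$flow <- d$Q_mouth
  if (!"Q_ipsi" %in% names(d) && "Q_mb_ipsi" %in% names(d)) {
    d$Q_ipsi <- d$Q_mb_ipsi
    d$Q_contra <- d$Q_mb_contra
  }
  if (!all(c("t", "Ppl", "flow") %in% names(d)))
    stop("recording must provide columns t, Ppl (or P_pl_ipsi), flow (or Q_mouth)")
  d
}

# Unit conversion helpers used at I/O boundaries (internally everything is
# kPa / L / s).

#' Pressure unit conversions
#'
#' @param x pressure values.
#' @return Converted values.
#' @export
kpa_to_mmhg <- function(x) x * 7.50062

#' @rdname kpa_to_mmhg
#' @export
mmhg_to_kpa <- function(x) x / 7.50062

#' @rdname kpa_to_mmhg
#' @export
kpa_to_cmh2o <- function(x) x / 0.0981
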