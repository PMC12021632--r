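#' Patient parameter set for the virtual-patient simulator
#'
#' `build_patient()` assembles and validates the full set of mechanical,
#' gas-exchange and circulatory constants that every other function in the
#' package consumes read-only.  Internal units are fixed package-wide:
#' pressures in kPa, volumes in L, flows in L/s, time in s (rates such as
#' cardiac output and metabolic gas exchange are quoted per minute, as is
#' conventional).
#'
#' Three presets are available.  They differ only in mediastinal compliance
#' `C_med`: `"stiff_mediastinum"` divides the default by 5 and
#' `"compliant_mediastinum"` multiplies it by 5.  The mediastinum is the
#' structure through which breathing-related pleural-pressure swings in one
#' hemithorax are transmitted to the other, and its compliance is the single
#' most influential parameter for pressure-volume loop morphology under a
#' large effusion.
#'
#' The numeric defaults describe a generic healthy adult (textbook resting
#' physiology: FRC about 2.4 L, tidal volume 0.5 L at 12 breaths/min,
#' cardiac output 5 L/min, room air).  All of them can be overridden, so any
#' calibration to an individual is data, not code.
#'
#' @param preset one of `"default"`, `"stiff_mediastinum"`,
#'   `"compliant_mediastinum"`.
#' @param overrides named list of field values replacing the preset defaults.
#'   Unknown names are an error.
#' @return An object of class `patient_params`: a validated named list.
#' @examples
#' p <- build_patient()
#' p$n_layers
#' stiff <- build_patient("stiff_mediastinum")
#' stiff$C_med / p$C_med
#' @export
build_patient <- function(preset = "default", overrides = list()) {
  presets <- c("default", "stiff_mediastinum", "compliant_mediastinum")
  if (!is.character(preset) || length(preset) != 1L || !(preset %in% presets))
    stop("unknown preset: ", paste(preset, collapse = ", "),
         " (must be one of ", paste(presets, collapse = ", "), ")")
  p <- patient_defaults()
  if (preset == "stiff_mediastinum")     p$C_med <- p$C_med / 5
  if (preset == "compliant_mediastinum") p$C_med <- p$C_med * 5
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("overrides must be a fully named list")
    bad <- setdiff(nm, names(p))
    if (length(bad))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    p[nm] <- overrides[nm]
  }
  p <- validate_patient(p)
  p <- calibrate_rest_geometry(p)
  class(p) <- "patient_params"
  p
}

# Raw defaults, before validation and derived-geometry calibration.
patient_defaults <- function() {
  list(
    n_layers      = 100L,   # horizontal layers per lung
    C_med         = 0.5,    # mediastinal compliance, L/kPa
    C_rc          = 2.0,    # rib-cage compliance, L/kPa
    R_rc          = 0.1,    # rib-cage viscous resistance, kPa s/L
    C_ab          = 3.0,    # abdominal compliance, L/kPa
    R_ab          = 0.05,   # abdominal viscous resistance, kPa s/L
    C_di_ipsi     = 1.2,    # hemidiaphragm passive compliance, L/kPa
    C_di_contra   = 1.2,
    R_tr          = 0.05,   # tracheal resistance, kPa s/L
    R_mb_ipsi     = 0.05,   # main-bronchus resistance, each side
    R_mb_contra   = 0.05,
    R_small       = 0.10,   # peripheral resistance per lung (all layers in parallel)
    lung_Vmax     = 3.0,    # per-lung exponential P-V asymptote, L
    lung_k        = 1.0,    # per-lung P-V shape constant, 1/kPa
    P_close       = 0.0,    # derecruitment transpulmonary threshold, kPa
    P_open        = 0.3,    # recruitment threshold, kPa (hysteresis interval)
    rho_f         = 1.0,    # pleural fluid density, kg/L
    lung_height   = 24,     # apex-to-base height, cm
    hemithorax_cap = 4.0,   # hemithorax capacity bounding the fluid column, L
    VD_anat       = 0.15,   # total anatomical dead space (both lungs + trachea), L
    VO2           = 0.25,   # metabolic O2 uptake, L/min
    VCO2          = 0.20,   # metabolic CO2 output, L/min
    Hb            = 14,     # hemoglobin, g/dL
    P50           = 3.55,   # oxyhemoglobin half-saturation pressure, kPa
    hill_n        = 2.7,    # Hill coefficient
    CO_total      = 5.0,    # cardiac output, L/min
    perf_P_half   = 0.5,    # local P_pl at which vascular conductance halves, kPa
    perf_w        = 0.3,    # width of the conductance roll-off, kPa
    VT_target     = 0.5,    # target tidal volume, L
    RR            = 12,     # respiratory rate, 1/min
    FiO2          = 0.21,
    P_atm         = 101.3,  # barometric pressure, kPa
    # --- muscle driver ---
    Ti_frac       = 0.4,    # inspiratory fraction of the cycle
    rc_mus_frac   = 0.25,   # rib-cage muscle pressure as a fraction of diaphragm drive
    di_eps_zero   = 0.6,    # caudal displacement at which diaphragm action nulls, L
    di_eps_floor  = -0.3,   # paradoxical (inverted) effectiveness floor
    drive_max     = 15,     # amplitude bound for the VT controller, kPa
    # --- solver ---
    dt            = 0.005,  # fixed RK4 step, s
    washin_breaths = 3L,    # discarded before recording
    trapped_frac  = 0.05,   # residual gas fraction of layer capacity when collapsed
    beta_aw       = 5,      # collapsible-bronchus resistance gain, 1/kPa
    beta_cap      = 20,     # cap on the resistance multiplication factor
    P_pl_frc      = -0.5    # resting pleural pressure used to place chest-wall neutral volumes, kPa
  )
}

positive_fields <- c(
  "C_med", "C_rc", "R_rc", "C_ab", "R_ab", "C_di_ipsi", "C_di_contra",
  "R_tr", "R_mb_ipsi", "R_mb_contra", "R_small", "lung_Vmax", "lung_k",
  "rho_f", "lung_height", "hemithorax_cap", "VD_anat", "VO2", "VCO2",
  "Hb", "P50", "hill_n", "CO_total", "perf_P_half", "perf_w", "VT_target",
  "RR", "P_atm", "Ti_frac", "rc_mus_frac", "di_eps_zero", "drive_max",
  "dt", "trapped_frac", "beta_aw", "beta_cap")

validate_patient <- function(p) {
  for (f in positive_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("validation error: field '", f, "' must be a strictly positive number")
  }
  p$n_layers <- as.integer(p$n_layers)
  if (is.na(p$n_layers) || p$n_layers < 1L)
    stop("validation error: field 'n_layers' must be an integer >= 1")
  p$washin_breaths <- as.integer(p$washin_breaths)
  if (is.na(p$washin_breaths) || p$washin_breaths < 0L)
    stop("validation error: field 'washin_breaths' must be a non-negative integer")
  if (!is.numeric(p$P_open) || !is.numeric(p$P_close) || p$P_open <= p$P_close)
    stop("validation error: recruitment hysteresis requires P_open > P_close")
  if (p$FiO2 <= 0 || p$FiO2 > 1)
    stop("validation error: field 'FiO2' must lie in (0, 1]")
  if (p$Ti_frac >= 1)
    stop("validation error: field 'Ti_frac' must lie in (0, 1)")
  if (p$trapped_frac >= 1)
    stop("validation error: field 'trapped_frac' must lie in (0, 1)")
  if (!is.numeric(p$P_pl_frc) || p$P_pl_frc >= 0)
    stop("validation error: field 'P_pl_frc' must be negative")
  if (!is.numeric(p$di_eps_floor) || p$di_eps_floor >= 1)
    stop("validation error: field 'di_eps_floor' must be < 1")
  p
}

# Chest-wall neutral volumes V0 per hemithorax are derived so that with no
# effusion and no muscle activity the model rests exactly at the target
# pleural pressure P_pl_frc, with per-lung FRC given by the lung recoil law.
calibrate_rest_geometry <- function(p) {
  p0  <- p$P_pl_frc
  frc <- p$lung_Vmax * (1 - exp(p$lung_k * p0))        # p0 < 0
  # diaphragm rest displacements: x_s = C_di_s (p0 - P_ab), P_ab = (x_i + x_c)/C_ab
  ci <- p$C_di_ipsi; cc <- p$C_di_contra
  A <- matrix(c(1 + ci / p$C_ab, ci / p$C_ab,
                cc / p$C_ab,     1 + cc / p$C_ab), 2, 2, byrow = TRUE)
  x <- solve(A, c(ci * p0, cc * p0))
  vrc0 <- p$C_rc * p0
  p$FRC_side <- frc
  p$x_di_rest <- x                     # c(ipsi, contra)
  p$V0 <- c(ipsi   = frc - vrc0 / 2 - x[1],
            contra = frc - vrc0 / 2 - x[2])
  p
}

#' Scale one scalar parameter of a patient
#'
#' Returns a copy of `params` with a single field multiplied by `factor`;
#' the original object is untouched.  This is the primitive used by the
#' compliance-sweep experiments, where one chest-wall coefficient is first
#' reduced below and then raised above its default.
#'
#' @param params a `patient_params` object.
#' @param field name of a positive scalar field, e.g. `"C_med"`.
#' @param factor strictly positive multiplier.
#' @return A new validated `patient_params`.
#' @examples
#' p <- build_patient()
#' stiff <- scale_param(p, "C_med", 0.2)
#' stiff$C_med / p$C_med
#' @export
scale_param <- function(params, field, factor) {
  stopifnot(inherits(params, "patient_params"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0)
    stop("factor must be a strictly positive number")
  if (!(field %in% positive_fields))
    stop("field '", field, "' is not a scalable scalar parameter")
  q <- unclass(params)
  q[[field]] <- q[[field]] * factor
  q <- validate_patient(q)
  q <- calibrate_rest_geometry(q)
  class(q) <- "patient_params"
  q
}

#' @export
print.patient_params <- function(x, ...) {
  cat("<patient_params>\n")
  cat(sprintf("  layers/lung: %d, C_med %.3g L/kPa, C_rc %.3g, C_ab %.3g\n",
              x$n_layers, x$C_med, x$C_rc, x$C_ab))
  cat(sprintf("  lung Vmax %.3g L, k %.3g /kPa; per-lung FRC at rest %.3g L\n",
              x$lung_Vmax, x$lung_k, x$FRC_side))
  cat(sprintf("  VT target %.3g L @ RR %g/min; FiO2 %.2f; CO %.3g L/min\n",
              x$VT_target, x$RR, x$FiO2, x$CO_total))
  invisible(x)
}

#' Read and write patient configuration files
#'
#' Patient parameters are stored as flat YAML with exactly the field names
#' of [build_patient()].  Unknown keys are rejected so that typos do not
#' silently fall back to defaults.  Derived fields (`V0`, `FRC_side`,
#' `x_di_rest`) are recomputed on read, never stored.
#'
#' @param params a `patient_params` object.
#' @param path file path.
#' @return `read_patient_config()` returns a validated `patient_params`;
#'   `write_patient_config()` returns `path` invisibly.
#' @export
write_patient_config <- function(params, path) {
  stopifnot(inherits(params, "patient_params"))
  keep <- names(patient_defaults())
  yaml::write_yaml(unclass(params)[keep], path, precision = 15L)
  invisible(path)
}

#' @rdname write_patient_config
#' @export
read_patient_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration error: config must be a YAML mapping")
  build_patient("default", overrides = raw)
}
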