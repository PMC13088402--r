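#' Construct a Doppler measurement
#'
#' One brachial-artery Doppler assessment. Velocities are in cm/s by default;
#' pass `velocity_unit = "m/s"` for machines reporting SI velocities (converted
#' internally, x100).
#'
#' @param vessel_area Lumen cross-section, cm^2 (> 0).
#' @param mean_time_integral Velocity-time integral per beat, cm.
#' @param heart_rate Beats per minute (> 0).
#' @param peak_systolic_velocity PSV (> 0).
#' @param lowest_diastolic_velocity Lowest diastolic velocity,
#'   `0 <= LDV <= PSV`.
#' @param velocity_unit `"cm/s"` (default) or `"m/s"`.
#' @return A `doppler_measurement` list (velocities stored in cm/s).
#' @export
doppler_measurement <- function(vessel_area, mean_time_integral, heart_rate,
                                peak_systolic_velocity = NA_real_,
                                lowest_diastolic_velocity = NA_real_,
                                velocity_unit = c("cm/s", "m/s")) {
  velocity_unit <- match.arg(velocity_unit)
  k <- if (velocity_unit == "m/s") 100 else 1
  mean_time_integral <- mean_time_integral * k
  peak_systolic_velocity <- peak_systolic_velocity * k
  lowest_diastolic_velocity <- lowest_diastolic_velocity * k
  if (!(vessel_area > 0)) stop("vessel_area must be > 0 cm^2", call. = FALSE)
  if (!(heart_rate > 0)) stop("heart_rate must be > 0 bpm", call. = FALSE)
  if (mean_time_integral < 0)
    stop("mean_time_integral must be >= 0", call. = FALSE)
  if (!is.na(peak_systolic_velocity)) {
    if (!(peak_systolic_velocity > 0))
      stop("peak_systolic_velocity must be > 0", call. = FALSE)
    if (!is.na(lowest_diastolic_velocity) &&
        (lowest_diastolic_velocity < 0 ||
         lowest_diastolic_velocity > peak_systolic_velocity))
      stop("lowest_diastolic_velocity must lie in [0, PSV]", call. = FALSE)
  }
  structure(list(vessel_area = vessel_area,
                 mean_time_integral = mean_time_integral,
                 heart_rate = heart_rate,
                 peak_systolic_velocity = peak_systolic_velocity,
                 lowest_diastolic_velocity = lowest_diastolic_velocity),
            class = "doppler_measurement")
}

#' Time-averaged velocity
#'
#' `TAV (cm/s) = MTI (cm/beat) x HR (beats/min) / 60 (s/min)` — the standard
#' Doppler time-averaged mean velocity, expressed in consistent cm units.
#'
#' @param m A [doppler_measurement()].
#' @return TAV in cm/s.
#' @export
time_averaged_velocity <- function(m) {
  stopifnot(inherits(m, "doppler_measurement"))
  m$mean_time_integral * m$heart_rate / 60
}

#' Brachial artery flow volume
#'
#' `FV (mL/min) = vessel area (cm^2) x TAV (cm/s) x 60 (s/min)`; cm^3/min is
#' identically mL/min.
#'
#' @param m A [doppler_measurement()].
#' @return FV in mL/min.
#' @export
flow_volume <- function(m) {
  stopifnot(inherits(m, "doppler_measurement"))
  m$vessel_area * time_averaged_velocity(m) * 60
}

#' Resistance index
#'
#' `RI = (PSV - LDV) / PSV`, in \[0, 1\] by the measurement invariants; higher
#' values indicate higher downstream resistance.
#'
#' @param m A [doppler_measurement()].
#' @return RI, unitless.
#' @export
resistance_index <- function(m) {
  stopifnot(inherits(m, "doppler_measurement"))
  if (is.na(m$peak_systolic_velocity) || !(m$peak_systolic_velocity > 0))
    stop("peak_systolic_velocity must be > 0 to compute RI", call. = FALSE)
  (m$peak_systolic_velocity - m$lowest_diastolic_velocity) /
    m$peak_systolic_velocity
}

#' Append hemodynamic results to a Doppler table
#'
#' Takes a data frame with columns `vessel_area_cm2`, `mti_cm`, `hr_bpm`,
#' `psv_cm_s`, `edv_cm_s` and appends `fv_ml_min` and `ri`.
#'
#' @param df Doppler measurement table.
#' @return `df` with `fv_ml_min` and `ri` columns appended.
#' @export
add_hemodynamics <- function(df) {
  need <- c("vessel_area_cm2", "mti_cm", "hr_bpm", "psv_cm_s", "edv_cm_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  res <- lapply(seq_len(nrow(df)), function(i) {
    m <- doppler_measurement(df$vessel_area_cm2[i], df$mti_cm[i],
                             df$hr_bpm[i], df$psv_cm_s[i], df$edv_cm_s[i])
    c(fv = flow_volume(m), ri = resistance_index(m))
  })
  df$fv_ml_min <- vapply(res, `[[`, numeric(1), "fv")
  df$ri <- vapply(res, `[[`, numeric(1), "ri")
  df
}
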