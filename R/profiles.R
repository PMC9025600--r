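#' Sensor response profiles
#'
#' A sensor profile parameterizes one metal-oxide sensor's response to an
#' apple sample: an exponential rise from a baseline voltage towards a
#' grade-dependent plateau, an optional decaying overshoot pulse, and
#' additive Gaussian measurement noise. Profiles for the whole panel are
#' stored as a tibble with one row per sensor.
#'
#' @details Columns of a profile table:
#' \describe{
#'   \item{sensor}{sensor id, one of MQ-9, MQ-3, MQ-6, MQ-8, MQ-2, MQ-135}
#'   \item{baseline_v}{resting output voltage (V)}
#'   \item{plateau_L1, plateau_L2, plateau_L3}{mean plateau voltage per grade (V)}
#'   \item{plateau_sd}{between-recording plateau standard deviation (V)}
#'   \item{rise_tau}{exponential rise time constant (s)}
#'   \item{overshoot_frac}{peak excess over the plateau as a fraction of the
#'     rise amplitude (dimensionless, >= 0)}
#'   \item{overshoot_decay_tau}{overshoot decay time constant (s)}
#'   \item{noise_sd}{additive Gaussian noise standard deviation (V)}
#' }
#'
#' @param path Path to a YAML profile file; `default_sensor_profiles()` reads
#'   the panel shipped with the package.
#' @return A tibble with one row per sensor (see Details).
#' @export
#' @examples
#' default_sensor_profiles()
default_sensor_profiles <- function() {
  read_sensor_profiles(system.file("extdata", "default_profiles.yaml",
                                   package = "enosegrade"))
}

#' @rdname default_sensor_profiles
#' @export
read_sensor_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$sensors)) stop("profile file has no 'sensors' entry", call. = FALSE)
  profiles <- purrr::map_dfr(raw$sensors, function(s) {
    tibble::tibble(
      sensor = s$sensor,
      baseline_v = s$baseline_v,
      plateau_L1 = s$plateau_mean$L1,
      plateau_L2 = s$plateau_mean$L2,
      plateau_L3 = s$plateau_mean$L3,
      plateau_sd = s$plateau_sd,
      rise_tau = s$rise_tau,
      overshoot_frac = s$overshoot_frac,
      overshoot_decay_tau = s$overshoot_decay_tau,
      noise_sd = s$noise_sd
    )
  })
  validate_profiles(profiles)
  profiles
}

#' Validate a sensor profile table
#'
#' Checks the physical invariants of a profile table: baselines below all
#' grade plateaus, plateaus within the 0-3.3 V ADC range, positive rise time
#' constants and non-negative noise and overshoot parameters.
#'
#' @param profiles A profile tibble as returned by [default_sensor_profiles()].
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_profiles <- function(profiles) {
  required <- c("sensor", "baseline_v", "plateau_L1", "plateau_L2",
                "plateau_L3", "plateau_sd", "rise_tau", "overshoot_frac",
                "overshoot_decay_tau", "noise_sd")
  missing <- setdiff(required, names(profiles))
  if (length(missing) > 0) {
    stop("profile table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(profiles$sensor, SENSOR_IDS) || nrow(profiles) != 6L) {
    stop("profile table must contain exactly the six panel sensors: ",
         paste(SENSOR_IDS, collapse = ", "), call. = FALSE)
  }
  plateaus <- as.matrix(profiles[, c("plateau_L1", "plateau_L2", "plateau_L3")])
  if (any(profiles$baseline_v < 0) ||
      any(plateaus <= profiles$baseline_v) ||
      any(plateaus > 3.3)) {
    stop("profiles must satisfy 0 <= baseline_v < plateau[g] <= 3.3 for every grade",
         call. = FALSE)
  }
  if (any(profiles$rise_tau <= 0)) stop("rise_tau must be > 0", call. = FALSE)
  if (any(profiles$noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(profiles$overshoot_frac < 0)) stop("overshoot_frac must be >= 0", call. = FALSE)
  if (any(profiles$overshoot_decay_tau <= 0)) stop("overshoot_decay_tau must be > 0", call. = FALSE)
  invisible(profiles)
}

#' Recording configuration
#'
#' Bundles the acquisition settings of a simulated recording: duration,
#' sampling rate, ADC clip range and the transient cutoff used downstream.
#' The duration must be at least twice the transient cutoff so that a steady
#' segment survives trimming.
#'
#' @param duration_s Recording length in seconds (default 60).
#' @param sample_rate_hz Sampling rate in Hz (default 10; the acquisition
#'   rate is configurable because it is instrument-specific).
#' @param transient_cutoff_s Pre-steady-state transient length in seconds
#'   trimmed before feature extraction (default 20).
#' @param clip_range ADC output range in volts (default `c(0, 3.3)`).
#' @return A list of class `recording_config`.
#' @export
#' @examples
#' recording_config()
recording_config <- function(duration_s = 60, sample_rate_hz = 10,
                             transient_cutoff_s = 20,
                             clip_range = c(0, 3.3)) {
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive", call. = FALSE)
  if (duration_s < 2 * transient_cutoff_s) {
    stop("duration_s must be at least twice transient_cutoff_s so a steady segment remains",
         call. = FALSE)
  }
  structure(
    list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
         transient_cutoff_s = transient_cutoff_s,
         clip_range = clip_range),
    class = "recording_config"
  )
}
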