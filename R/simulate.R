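#' Simulate one sensor trace
#'
#' Generates a single sensor's voltage time series for one sniff of an apple
#' of a given grade: an exponential rise from the baseline towards a plateau
#' drawn once per recording, an optional decaying overshoot pulse, and
#' additive Gaussian noise, clipped to the ADC range.
#'
#' The deterministic part of the response is
#' \deqn{v(t) = b + (p - b)(1 - e^{-t/\tau})(1 + f\, e^{-t/\tau_d})}
#' with baseline \eqn{b}, drawn plateau \eqn{p}, rise constant \eqn{\tau},
#' overshoot fraction \eqn{f} and overshoot decay constant \eqn{\tau_d}, so
#' that \eqn{v(0) = b} and \eqn{v(t) \to p}. The trace uses the current
#' R random-number stream; seed it (e.g. with [set.seed()]) for
#' reproducibility.
#'
#' @param profile One row of a sensor profile table (a data frame or list
#'   with the columns of [default_sensor_profiles()]).
#' @param grade Grade label, one of `"L1"`, `"L2"`, `"L3"`.
#' @param config A [recording_config()].
#' @param plateau Optional plateau voltage; when `NULL` (default) it is drawn
#'   from `Normal(plateau_mean[grade], plateau_sd)`.
#' @return A tibble with columns `time_s` and `voltage`.
#' @export
#' @examples
#' set.seed(1)
#' prof <- default_sensor_profiles()[2, ]
#' tr <- simulate_trace(prof, "L2", recording_config())
#' head(tr)
simulate_trace <- function(profile, grade, config = recording_config(),
                           plateau = NULL) {
  profile <- as.list(profile)
  if (!grade %in% GRADE_LEVELS) {
    stop("unknown grade label: ", grade, call. = FALSE)
  }
  if (!inherits(config, "recording_config")) {
    stop("config must be a recording_config()", call. = FALSE)
  }
  dt <- 1 / config$sample_rate_hz
  time_s <- seq(0, config$duration_s - dt, by = dt)
  if (is.null(plateau)) {
    plateau <- rnorm(1, profile[[paste0("plateau_", grade)]], profile$plateau_sd)
  }
  v <- trace_signal(time_s, profile$baseline_v, plateau, profile$rise_tau,
                    profile$overshoot_frac, profile$overshoot_decay_tau)
  if (profile$noise_sd > 0) {
    v <- v + rnorm(length(v), 0, profile$noise_sd)
  }
  v <- pmin(pmax(v, config$clip_range[1]), config$clip_range[2])
  tibble::tibble(time_s = time_s, voltage = v)
}

# Noiseless response shape shared by simulate_trace() and simulate_dataset().
trace_signal <- function(time_s, baseline, plateau, rise_tau,
                         overshoot_frac, overshoot_decay_tau) {
  rise <- (plateau - baseline) * (1 - exp(-time_s / rise_tau))
  baseline + rise * (1 + overshoot_frac * exp(-time_s / overshoot_decay_tau))
}

#' Simulate a full e-nose dataset
#'
#' Generates recordings for `n_apples_per_grade` apples in each of the three
#' grades, with `recordings_per_apple` repeated sniffs per apple. Apples are
#' the unit of biological variation: each apple carries a shared random
#' plateau offset (standard deviation `plateau_sd / 2`, common factor across
#' its sensors) that all of its recordings inherit, so recordings of one
#' apple are correlated. The default `10 x 10` design yields 300 recordings,
#' 100 per grade.
#'
#' @param n_apples_per_grade Number of apples per grade (default 10).
#' @param recordings_per_apple Repeated recordings per apple (default 10).
#' @param profiles Sensor profile table (default [default_sensor_profiles()]).
#' @param config A [recording_config()].
#' @param seed Integer seed; the dataset is a pure function of the arguments
#'   and this seed.
#' @return A tibble in long-by-time form with columns `recording_id`,
#'   `apple_id`, `grade`, `time_s` and one voltage column per sensor
#'   (`MQ-9`, `MQ-3`, `MQ-6`, `MQ-8`, `MQ-2`, `MQ-135`).
#' @export
#' @examples
#' recs <- simulate_dataset(1, 1, seed = 1)
#' dplyr::count(recs, recording_id, grade)
simulate_dataset <- function(n_apples_per_grade = 10, recordings_per_apple = 10,
                             profiles = default_sensor_profiles(),
                             config = recording_config(), seed = 1) {
  if (n_apples_per_grade < 1 || recordings_per_apple < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  validate_profiles(profiles)
  withr::with_seed(seed, {
    out <- vector("list", 3L * n_apples_per_grade * recordings_per_apple)
    idx <- 0L
    for (grade in GRADE_LEVELS) {
      for (a in seq_len(n_apples_per_grade)) {
        apple_id <- sprintf("%s_a%02d", grade, a)
        # Apple-level random effect: one standard-normal factor per apple,
        # loading plateau_sd / 2 on every sensor.
        z_apple <- rnorm(1)
        for (r in seq_len(recordings_per_apple)) {
          rec_id <- sprintf("%s_a%02d_r%02d", grade, a, r)
          rec <- tibble::tibble(
            recording_id = rec_id, apple_id = apple_id, grade = grade,
            time_s = seq(0, config$duration_s - 1 / config$sample_rate_hz,
                         by = 1 / config$sample_rate_hz)
          )
          for (s in seq_len(nrow(profiles))) {
            prof <- profiles[s, ]
            plateau <- prof[[paste0("plateau_", grade)]] +
              z_apple * prof$plateau_sd / 2 +
              rnorm(1, 0, prof$plateau_sd)
            tr <- simulate_trace(prof, grade, config, plateau = plateau)
            rec[[prof$sensor]] <- tr$voltage
          }
          idx <- idx + 1L
          out[[idx]] <- rec
        }
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Plot simulated sensor response curves
#'
#' Response curves of all six sensors, one facet per sensor, colored by
#' grade. Useful for eyeballing the grade separation and noise level of a
#' simulated dataset.
#'
#' @param recordings A recordings tibble from [simulate_dataset()] (raw or
#'   preprocessed).
#' @param max_recordings Cap on the number of recordings drawn (default 12).
#' @return A ggplot object.
#' @export
plot_recordings <- function(recordings, max_recordings = 12) {
  ids <- unique(recordings$recording_id)
  keep <- ids[seq_len(min(length(ids), max_recordings))]
  long <- recordings |>
    dplyr::filter(.data$recording_id %in% keep) |>
    tidyr::pivot_longer(dplyr::all_of(SENSOR_IDS),
                        names_to = "sensor", values_to = "voltage") |>
    dplyr::mutate(sensor = factor(.data$sensor, levels = SENSOR_IDS))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$voltage,
                                     group = .data$recording_id,
                                     colour = .data$grade)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~sensor) +
    ggplot2::labs(x = "time (s)", y = "sensor output (V)", colour = "grade") +
    ggplot2::theme_minimal()
}
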