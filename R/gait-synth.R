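#' Landmark angles that calibrate the synthetic gait generator
#'
#' The generator reproduces a normal-looking knee-angle cycle constrained to
#' pass through a small set of landmark values: the stance- and swing-phase
#' flexion maxima, the late-cycle adduction peak, and the swing-phase internal
#' and external rotation extrema. Defaults are the mean values reported for an
#' ACL-reconstructed cohort six months post-surgery (stance flexion 14 deg,
#' swing flexion 64 deg, adduction peak 10 deg near 85% cycle, swing internal
#' rotation 7 deg, swing external rotation 12 deg).
#'
#' @param stance_flexion_max Maximum knee flexion during stance, degrees.
#' @param swing_flexion_max Maximum knee flexion during swing, degrees. Must
#'   exceed `stance_flexion_max`.
#' @param adduction_peak Peak knee adduction over the cycle, degrees.
#' @param adduction_peak_time Cycle fraction in `[0, 1]` at which the adduction
#'   peak occurs (default 0.85).
#' @param swing_internal_rot_max Maximum internal tibial rotation during
#'   swing, degrees.
#' @param swing_external_rot_max Magnitude of the most external (most
#'   negative) tibial rotation during swing, degrees.
#' @param stance_fraction Fraction of the cycle spent in stance (default 0.60,
#'   the conventional value for level walking).
#' @return An object of class `gait_landmarks`.
#' @export
#' @examples
#' gait_landmarks()
gait_landmarks <- function(stance_flexion_max = 14,
                           swing_flexion_max = 64,
                           adduction_peak = 10,
                           adduction_peak_time = 0.85,
                           swing_internal_rot_max = 7,
                           swing_external_rot_max = 12,
                           stance_fraction = 0.60) {
  lm <- list(
    stance_flexion_max = as.numeric(stance_flexion_max),
    swing_flexion_max = as.numeric(swing_flexion_max),
    adduction_peak = as.numeric(adduction_peak),
    adduction_peak_time = as.numeric(adduction_peak_time),
    swing_internal_rot_max = as.numeric(swing_internal_rot_max),
    swing_external_rot_max = as.numeric(swing_external_rot_max),
    stance_fraction = as.numeric(stance_fraction)
  )
  class(lm) <- "gait_landmarks"
  validate_gait_landmarks(lm)
  lm
}

validate_gait_landmarks <- function(lm) {
  stopifnot(inherits(lm, "gait_landmarks"))
  vals <- unlist(lm)
  if (any(!is.finite(vals))) {
    stop("gait landmarks must be finite numbers", call. = FALSE)
  }
  angles <- c(
    lm$stance_flexion_max, lm$swing_flexion_max, lm$adduction_peak,
    lm$swing_internal_rot_max, lm$swing_external_rot_max
  )
  if (any(angles < 0)) {
    stop("landmark angle magnitudes must be >= 0", call. = FALSE)
  }
  if (lm$stance_fraction <= 0 || lm$stance_fraction >= 1) {
    stop("stance_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (lm$adduction_peak_time < 0 || lm$adduction_peak_time > 1) {
    stop("adduction_peak_time must lie in [0, 1]", call. = FALSE)
  }
  if (lm$swing_flexion_max <= lm$stance_flexion_max) {
    stop("infeasible landmarks: swing_flexion_max must exceed stance_flexion_max",
      call. = FALSE
    )
  }
  invisible(lm)
}

#' @export
print.gait_landmarks <- function(x, ...) {
  cat("Gait landmarks (degrees):\n")
  cat(sprintf("  flexion max: %.1f (stance) / %.1f (swing)\n",
    x$stance_flexion_max, x$swing_flexion_max))
  cat(sprintf("  adduction peak: %.1f at %.0f%% cycle\n",
    x$adduction_peak, 100 * x$adduction_peak_time))
  cat(sprintf("  swing rotation: +%.1f internal / -%.1f external\n",
    x$swing_internal_rot_max, x$swing_external_rot_max))
  cat(sprintf("  stance fraction: %.2f\n", x$stance_fraction))
  invisible(x)
}

#' Subject anthropometrics and seed
#'
#' @param subject_id Character label.
#' @param height Standing height, meters.
#' @param mass Body mass, kilograms.
#' @param rng_seed Integer seed controlling this subject's kinematic jitter.
#' @param generic_height Height of the generic (unscaled) model, meters;
#'   `uniform_scale = height / generic_height`.
#' @param uniform_scale Override for the geometric scale factor; computed from
#'   height by default.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, height, mass, rng_seed,
                            generic_height = 1.70,
                            uniform_scale = height / generic_height) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.finite(height) || height <= 0) stop("height must be > 0", call. = FALSE)
  if (!is.finite(mass) || mass <= 0) stop("mass must be > 0", call. = FALSE)
  if (!is.finite(uniform_scale) || uniform_scale <= 0) {
    stop("uniform_scale must be > 0", call. = FALSE)
  }
  structure(
    list(
      subject_id = subject_id,
      height = as.numeric(height),
      mass = as.numeric(mass),
      uniform_scale = as.numeric(uniform_scale),
      rng_seed = as.integer(rng_seed)
    ),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "Subject %s: height %.2f m, mass %.1f kg, scale %.3f, seed %d\n",
    x$subject_id, x$height, x$mass, x$uniform_scale, x$rng_seed
  ))
  invisible(x)
}

# Knot templates (cycle fraction, degrees). Landmark knots carry the landmark
# values exactly; the remaining knots are shape defaults giving normal-gait
# curve forms. All knot times sit on the 1% grid so that, at variability 0,
# every landmark is attained exactly at a sampled cycle point.
gait_knot_template <- function(lm) {
  toe_off <- min(12, lm$stance_flexion_max - 0.5)
  hs <- min(5, 0.4 * lm$stance_flexion_max)
  midst <- min(3, 0.25 * lm$stance_flexion_max)
  adt <- round(lm$adduction_peak_time, 2)
  add_base1 <- min(4, 0.4 * lm$adduction_peak)
  add_base2 <- min(2, 0.2 * lm$adduction_peak)
  swing_peak_t <- min(round(lm$stance_fraction + 0.12, 2), 0.95)
  out <- list(
    flexion = data.frame(
      time = c(0, 0.15, 0.40, round(lm$stance_fraction, 2), swing_peak_t, 1),
      value = c(hs, lm$stance_flexion_max, midst, toe_off,
                lm$swing_flexion_max, hs)
    ),
    adduction = data.frame(
      time = c(0, 0.10, 0.45, adt, 1),
      value = c(1, add_base1, add_base2, lm$adduction_peak, 1)
    ),
    internal_rotation = data.frame(
      time = c(0, 0.20, 0.50, 0.68, 0.88, 1),
      value = c(2, -2, 1, -lm$swing_external_rot_max,
                lm$swing_internal_rot_max, 2)
    )
  )
  for (nm in names(out)) {
    if (is.unsorted(out[[nm]]$time, strictly = TRUE)) {
      stop(sprintf(
        "infeasible landmarks: %s knot times are not strictly increasing", nm
      ), call. = FALSE)
    }
  }
  out
}

# Jitter one knot table: multiplicative amplitude noise and additive phase
# noise on interior knots; endpoints share one amplitude draw so the cycle
# still closes. Knot times are kept strictly increasing.
jitter_knots <- function(knots, variability,
                         amp_sd = 0.08, phase_sd = 0.02) {
  n <- nrow(knots)
  end_amp <- 1 + stats::rnorm(1L, sd = amp_sd * variability)
  amp <- 1 + stats::rnorm(n - 2L, sd = amp_sd * variability)
  phase <- stats::rnorm(n - 2L, sd = phase_sd * variability)
  out <- knots
  out$value[c(1L, n)] <- knots$value[c(1L, n)] * end_amp
  out$value[2:(n - 1L)] <- knots$value[2:(n - 1L)] * amp
  tt <- knots$time[2:(n - 1L)] + phase
  # preserve ordering with a minimum gap of 1% cycle
  lo <- knots$time[1L]
  for (i in seq_along(tt)) {
    tt[i] <- max(tt[i], lo + 0.01)
    lo <- tt[i]
  }
  tt <- pmin(tt, knots$time[n] - 0.01 * rev(seq_along(tt)))
  out$time[2:(n - 1L)] <- sort(tt)
  out
}

# Shape-preserving piecewise cubic Hermite interpolation (PCHIP): slopes are
# zero at local extrema, so knot values are never overshot and landmark knots
# are attained exactly at sampled cycle points.
eval_knot_spline <- function(knots, time) {
  pracma::pchip(knots$time, knots$value, time)
}

#' Generate one subject's knee kinematics over a normalized gait cycle
#'
#' Produces 101-point traces (cycle fractions 0, 0.01, ..., 1) of knee
#' flexion, adduction and internal rotation, in degrees. Each trace is a
#' shape-preserving piecewise cubic Hermite spline through a knot table whose
#' landmark knots carry the values in `landmarks`. With `variability = 0` the
#' traces attain every landmark exactly; with `variability > 0` the knots
#' receive seeded multiplicative amplitude and additive phase jitter, so the
#' same `rng_seed` reproduces bit-identical traces.
#'
#' @param landmarks A [gait_landmarks()] object.
#' @param profile A [subject_profile()] object (supplies the RNG seed).
#' @param variability Non-negative noise scale; 0 disables jitter, 1 is the
#'   default inter-subject variability.
#' @param n_points Samples per cycle (default 101).
#' @return An object of class `gait_kinematics` with elements `subject_id`,
#'   `time` (cycle fraction), `flexion`, `adduction`, `internal_rotation`
#'   (degrees) and `stance_fraction`.
#' @export
#' @examples
#' p <- subject_profile("S1", 1.63, 72, rng_seed = 1L)
#' k <- generate_subject_kinematics(gait_landmarks(), p, variability = 0)
#' max(k$flexion[k$time <= 0.60]) # stance flexion maximum, 14 degrees
generate_subject_kinematics <- function(landmarks, profile, variability = 1,
                                        n_points = 101L) {
  validate_gait_landmarks(landmarks)
  stopifnot(inherits(profile, "subject_profile"))
  if (!is.finite(variability) || variability < 0) {
    stop("variability must be >= 0", call. = FALSE)
  }
  knots <- gait_knot_template(landmarks)
  if (variability > 0) {
    knots <- withr::with_seed(profile$rng_seed, {
      lapply(knots, jitter_knots, variability = variability)
    })
  }
  time <- seq(0, 1, length.out = n_points)
  kin <- structure(
    list(
      subject_id = profile$subject_id,
      n_points = as.integer(n_points),
      time = time,
      flexion = eval_knot_spline(knots$flexion, time),
      adduction = eval_knot_spline(knots$adduction, time),
      internal_rotation = eval_knot_spline(knots$internal_rotation, time),
      stance_fraction = landmarks$stance_fraction
    ),
    class = "gait_kinematics"
  )
  validate_gait_kinematics(kin)
  kin
}

validate_gait_kinematics <- function(kin) {
  stopifnot(inherits(kin, "gait_kinematics"))
  n <- kin$n_points
  for (nm in c("flexion", "adduction", "internal_rotation")) {
    tr <- kin[[nm]]
    if (length(tr) != n) {
      stop(sprintf("%s trace must have %d samples", nm, n), call. = FALSE)
    }
    if (any(!is.finite(tr))) stop(sprintf("%s trace must be finite", nm), call. = FALSE)
    if (abs(tr[1L] - tr[n]) >= 1) {
      stop(sprintf("%s trace does not close over the cycle (>= 1 deg gap)", nm),
        call. = FALSE
      )
    }
  }
  invisible(kin)
}

#' @export
print.gait_kinematics <- function(x, ...) {
  cat(sprintf("Gait kinematics for subject %s (%d points, stance %.0f%%)\n",
    x$subject_id, x$n_points, 100 * x$stance_fraction))
  cat(sprintf("  flexion   [%6.1f, %6.1f] deg\n", min(x$flexion), max(x$flexion)))
  cat(sprintf("  adduction [%6.1f, %6.1f] deg\n", min(x$adduction), max(x$adduction)))
  cat(sprintf("  int. rot. [%6.1f, %6.1f] deg\n",
    min(x$internal_rotation), max(x$internal_rotation)))
  invisible(x)
}

#' @export
as.data.frame.gait_kinematics <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id,
    time = x$time,
    knee_flexion = x$flexion,
    knee_adduction = x$adduction,
    knee_rotation = x$internal_rotation,
    stringsAsFactors = FALSE
  )
}

#' Generate a seeded cohort of subjects and their gait kinematics
#'
#' Samples anthropometrics (height, mass) from normal distributions, derives
#' each subject's geometric scale factor as `height / generic_height`, and
#' generates per-subject kinematics with seeds derived deterministically from
#' `master_seed`, so any subset of the cohort is reproducible.
#'
#' @param n_subjects Cohort size (default 7).
#' @param landmarks A [gait_landmarks()] object.
#' @param height_mean,height_sd Height distribution, meters. The default SD
#'   is 0.098 m.
#' @param mass_mean,mass_sd Mass distribution, kilograms.
#' @param variability Kinematic jitter scale passed to
#'   [generate_subject_kinematics()].
#' @param master_seed Integer master seed; all randomness derives from it.
#' @param generic_height Generic model height, meters (default 1.70).
#' @return A list of class `gait_cohort`; each element has `profile` and
#'   `kinematics`.
#' @export
#' @examples
#' cohort <- generate_cohort(n_subjects = 2, master_seed = 42)
#' length(cohort)
generate_cohort <- function(n_subjects = 7L,
                            landmarks = gait_landmarks(),
                            height_mean = 1.63, height_sd = 0.098,
                            mass_mean = 72.04, mass_sd = 15.22,
                            variability = 1,
                            master_seed = 42L,
                            generic_height = 1.70) {
  if (!is.finite(n_subjects) || n_subjects < 1) {
    stop("n_subjects must be >= 1", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  draws <- withr::with_seed(as.integer(master_seed), {
    list(
      heights = stats::rnorm(n_subjects, height_mean, height_sd),
      masses = stats::rnorm(n_subjects, mass_mean, mass_sd),
      seeds = sample.int(.Machine$integer.max - 1L, n_subjects)
    )
  })
  heights <- pmax(draws$heights, 0.5 * height_mean)
  masses <- pmax(draws$masses, 0.5 * mass_mean)
  cohort <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    prof <- subject_profile(
      subject_id = sprintf("S%02d", i),
      height = heights[i],
      mass = masses[i],
      rng_seed = draws$seeds[i],
      generic_height = generic_height
    )
    cohort[[i]] <- list(
      profile = prof,
      kinematics = generate_subject_kinematics(landmarks, prof, variability)
    )
  }
  class(cohort) <- "gait_cohort"
  cohort
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("Gait cohort: %d subjects\n", length(x)))
  for (s in x) print(s$profile)
  invisible(x)
}
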