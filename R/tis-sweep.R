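#' Build the 13-position tibial insertion-site grid
#'
#' The grid is the center position plus offsets of each magnitude in the
#' anterior, posterior, medial and lateral directions (13 positions for the
#' default magnitudes 2.5, 5.0, 7.5 mm). Anterior/posterior offsets move the
#' tibial insertion's x coordinate; medial/lateral offsets move z, with the
#' medial/lateral sign resolved from the side in `convention`. The femoral
#' insertion is never modified. Offsets are given in mm and converted to cm
#' internally.
#'
#' @param center Length-3 numeric, cm: the center tibial insertion in the
#'   tibia frame.
#' @param convention A [frame_convention()].
#' @param magnitudes_mm Offset magnitudes in mm (default `c(2.5, 5, 7.5)`).
#' @return A data frame of class `tis_grid` with columns `direction`,
#'   `magnitude_mm`, `x`, `y`, `z` (cm).
#' @export
#' @examples
#' make_tis_grid(c(1.2, -3.2, -0.1), frame_convention("right"))
make_tis_grid <- function(center, convention = frame_convention(),
                          magnitudes_mm = c(2.5, 5, 7.5)) {
  stopifnot(length(center) == 3L, inherits(convention, "frame_convention"))
  if (any(magnitudes_mm <= 0)) {
    stop("offset magnitudes must be positive (center is added automatically)",
      call. = FALSE
    )
  }
  magnitudes_mm <- sort(unique(magnitudes_mm))
  dirs <- c("anterior", "posterior", "medial", "lateral")
  grid <- data.frame(
    direction = c("center", rep(dirs, each = length(magnitudes_mm))),
    magnitude_mm = c(0, rep(magnitudes_mm, times = length(dirs))),
    stringsAsFactors = FALSE
  )
  lat <- convention$lateral_sign
  cm <- grid$magnitude_mm / 10
  dx <- ifelse(grid$direction == "anterior", cm,
    ifelse(grid$direction == "posterior", -cm, 0))
  dz <- ifelse(grid$direction == "medial", -lat * cm,
    ifelse(grid$direction == "lateral", lat * cm, 0))
  grid$x <- center[1] + dx
  grid$y <- center[2]
  grid$z <- center[3] + dz
  class(grid) <- c("tis_grid", "data.frame")
  grid
}

#' Simulate the ligament force curve for one subject at one insertion site
#'
#' For each sample of the gait cycle the knee pose is converted to a
#' femur-to-tibia transform, the straight-line ligament length and strain are
#' evaluated, and the piecewise force law applied. The computation is fully
#' deterministic given its inputs.
#'
#' @param kin A [generate_subject_kinematics()] result.
#' @param spec A [ligament_spec()] with the tibial insertion already placed at
#'   the insertion site of interest (and scaled to the subject).
#' @param coupling A [knee_coupling()] object, or `NULL` for zero coupling.
#' @param convention A [frame_convention()].
#' @param origin_offset Default-pose tibia-origin offset, cm (already scaled
#'   to the subject).
#' @param direction,magnitude_mm Provenance labels for the insertion site.
#' @return An object of class `force_curve`: `time` (cycle fraction),
#'   `length` (cm), `strain`, `force` (N), and `all_slack` (`TRUE` when the
#'   ligament never carries force over the cycle).
#' @export
simulate_force_curve <- function(kin, spec, coupling = knee_coupling(),
                                 convention = frame_convention(),
                                 origin_offset = c(0, -40, 0),
                                 direction = "center", magnitude_mm = 0) {
  stopifnot(inherits(kin, "gait_kinematics"), inherits(spec, "ligament_spec"))
  n <- kin$n_points
  if (is.null(coupling)) {
    tr <- list(tx = numeric(n), ty = numeric(n))
  } else {
    tr <- evaluate_coupling(coupling, kin$flexion) # vectorized: warns once
  }
  len <- numeric(n)
  for (i in seq_len(n)) {
    pose <- knee_pose(kin$flexion[i], kin$adduction[i], kin$internal_rotation[i])
    tf <- femur_to_tibia_transform(
      pose,
      coupling = NULL, convention = convention,
      origin_offset = origin_offset + c(tr$tx[i], tr$ty[i], 0)
    )
    len[i] <- ligament_length(spec, tf)
  }
  strain <- ligament_strain(len, spec$resting_length)
  force <- ligament_force(strain, spec$stiffness, spec$linear_strain_limit)
  structure(
    list(
      subject_id = kin$subject_id,
      direction = direction,
      magnitude_mm = magnitude_mm,
      time = kin$time,
      length = len,
      strain = strain,
      force = force,
      all_slack = all(force == 0),
      stance_fraction = kin$stance_fraction
    ),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "Force curve: subject %s, TIS %s %.1f mm — peak %.1f N%s\n",
    x$subject_id, x$direction, x$magnitude_mm, max(x$force),
    if (x$all_slack) " (slack over whole cycle)" else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.force_curve <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id,
    direction = x$direction,
    magnitude_mm = x$magnitude_mm,
    cycle_pct = round(100 * x$time, 6),
    force_N = x$force,
    stringsAsFactors = FALSE
  )
}

#' Run the full cohort-by-insertion-site sweep
#'
#' Crosses every subject with every grid position (subject-major order) and
#' simulates the 101-point force curve for each. Insertion-site offsets are
#' applied on the unscaled generic geometry; the whole knee geometry
#' (insertions, default-pose origin offset, coupling translations) is then
#' scaled uniformly to the subject, and the resting length is scaled by the
#' same factor, so the default-pose strain is identical across subjects.
#'
#' @param cohort A [generate_cohort()] result.
#' @param grid A [make_tis_grid()] result, or `NULL` to build the default
#'   grid from the config.
#' @param config A configuration list, see [default_config()].
#' @return An object of class `acl_sweep` holding the list of
#'   [simulate_force_curve()] results plus provenance; `as.data.frame()`
#'   yields the tidy `(subject_id, direction, magnitude_mm, cycle_pct,
#'   force_N)` table.
#' @export
run_sweep <- function(cohort, grid = NULL, config = default_config()) {
  stopifnot(inherits(cohort, "gait_cohort"), length(cohort) >= 1L)
  convention <- frame_convention(config$side)
  spec0 <- config_ligament_spec(config)
  coupling0 <- config_coupling(config)
  offset0 <- as.numeric(config$knee$origin_offset)
  if (is.null(grid)) {
    grid <- make_tis_grid(spec0$tibial_insertion, convention,
      magnitudes_mm = config$grid_magnitudes_mm
    )
  }
  stopifnot(inherits(grid, "tis_grid"), nrow(grid) >= 1L)
  curves <- vector("list", length(cohort) * nrow(grid))
  idx <- 0L
  for (subj in cohort) {
    s <- subj$profile$uniform_scale
    coupling_s <- coupling0
    coupling_s$knots$tx <- coupling0$knots$tx * s
    coupling_s$knots$ty <- coupling0$knots$ty * s
    offset_s <- offset0 * s
    for (g in seq_len(nrow(grid))) {
      spec_g <- spec0
      spec_g$tibial_insertion <- c(grid$x[g], grid$y[g], grid$z[g])
      spec_s <- spec_g
      spec_s$femoral_insertion <- spec_g$femoral_insertion * s
      spec_s$tibial_insertion <- spec_g$tibial_insertion * s
      spec_s$resting_length <- spec_g$resting_length * s
      idx <- idx + 1L
      curve <- tryCatch(
        simulate_force_curve(
          subj$kinematics, spec_s, coupling_s, convention, offset_s,
          direction = grid$direction[g], magnitude_mm = grid$magnitude_mm[g]
        ),
        error = function(e) {
          stop(sprintf(
            "sweep cell failed (subject %s, TIS %s %.1f mm): %s",
            subj$profile$subject_id, grid$direction[g], grid$magnitude_mm[g],
            conditionMessage(e)
          ), call. = FALSE)
        }
      )
      curve$uniform_scale <- s
      curve$rng_seed <- subj$profile$rng_seed
      curves[[idx]] <- curve
    }
  }
  structure(
    list(
      curves = curves,
      grid = grid,
      subject_ids = vapply(cohort, function(s) s$profile$subject_id, character(1)),
      stance_fraction = cohort[[1]]$kinematics$stance_fraction,
      config = config
    ),
    class = "acl_sweep"
  )
}

#' @export
print.acl_sweep <- function(x, ...) {
  cat(sprintf(
    "ACL TIS sweep: %d subjects x %d insertion sites = %d force curves\n",
    length(x$subject_ids), nrow(x$grid), length(x$curves)
  ))
  invisible(x)
}

#' @export
as.data.frame.acl_sweep <- function(x, ...) {
  do.call(rbind, lapply(x$curves, as.data.frame))
}

#' Extract one curve from a sweep
#'
#' @param sweep An [run_sweep()] result.
#' @param subject_id Subject label.
#' @param direction,magnitude_mm Insertion-site condition.
#' @return A `force_curve`, or an error when the cell is absent.
#' @export
sweep_curve <- function(sweep, subject_id, direction, magnitude_mm = 0) {
  stopifnot(inherits(sweep, "acl_sweep"))
  for (cv in sweep$curves) {
    if (cv$subject_id == subject_id && cv$direction == direction &&
        isTRUE(all.equal(cv$magnitude_mm, magnitude_mm))) {
      return(cv)
    }
  }
  stop(sprintf(
    "no curve for subject %s, TIS %s %.1f mm", subject_id, direction,
    magnitude_mm
  ), call. = FALSE)
}
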