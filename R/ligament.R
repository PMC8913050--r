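#' Ligament geometric and mechanical parameters
#'
#' Defaults are the generic-model ACL values: femoral insertion
#' (-1.1, -40.5, 0.7) cm in the femur frame, tibial insertion
#' (1.2, -3.2, -0.1) cm in the tibia frame, resting length 2.8 cm, stiffness
#' 3100 N, linear strain limit 0.03.
#'
#' @param femoral_insertion Length-3 numeric, cm, femur frame.
#' @param tibial_insertion Length-3 numeric, cm, tibia frame.
#' @param resting_length Slack length L0, cm (> 0).
#' @param stiffness Linear-region stiffness k, Newtons (> 0).
#' @param linear_strain_limit Toe-region parameter e_l, dimensionless in
#'   (0, 1); the force law becomes linear at strain 2 * e_l.
#' @return An object of class `ligament_spec`.
#' @export
ligament_spec <- function(femoral_insertion = c(-1.1, -40.5, 0.7),
                          tibial_insertion = c(1.2, -3.2, -0.1),
                          resting_length = 2.8,
                          stiffness = 3100,
                          linear_strain_limit = 0.03) {
  stopifnot(length(femoral_insertion) == 3L, length(tibial_insertion) == 3L)
  if (!is.finite(resting_length) || resting_length <= 0) {
    stop("resting_length must be > 0", call. = FALSE)
  }
  if (!is.finite(stiffness) || stiffness <= 0) {
    stop("stiffness must be > 0", call. = FALSE)
  }
  if (!is.finite(linear_strain_limit) ||
      linear_strain_limit <= 0 || linear_strain_limit >= 1) {
    stop("linear_strain_limit must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      femoral_insertion = as.numeric(femoral_insertion),
      tibial_insertion = as.numeric(tibial_insertion),
      resting_length = as.numeric(resting_length),
      stiffness = as.numeric(stiffness),
      linear_strain_limit = as.numeric(linear_strain_limit)
    ),
    class = "ligament_spec"
  )
}

#' @export
print.ligament_spec <- function(x, ...) {
  cat("Ligament spec:\n")
  cat("  femoral insertion (cm):", paste(x$femoral_insertion, collapse = ", "), "\n")
  cat("  tibial insertion  (cm):", paste(x$tibial_insertion, collapse = ", "), "\n")
  cat(sprintf("  L0 = %.3f cm, k = %.0f N, e_l = %.3f\n",
    x$resting_length, x$stiffness, x$linear_strain_limit))
  invisible(x)
}

#' Straight-line ligament length across the knee
#'
#' The ligament path is a straight line from the femoral insertion (mapped
#' into the tibia frame by the femur-to-tibia transform) to the tibial
#' insertion.
#'
#' @param spec A [ligament_spec()].
#' @param transform A [rigid_transform()] mapping femur-frame coordinates
#'   into the tibia frame.
#' @return Length in cm.
#' @export
ligament_length <- function(spec, transform) {
  stopifnot(inherits(spec, "ligament_spec"))
  p <- transform_point(transform, spec$femoral_insertion)
  sqrt(sum((p - spec$tibial_insertion)^2))
}

#' Ligament strain
#'
#' `e = (L - L0) / L0`; negative values indicate slack.
#'
#' @param length Current length L, cm.
#' @param resting_length Resting length L0, cm (> 0).
#' @return Dimensionless strain (vectorized over `length`).
#' @export
ligament_strain <- function(length, resting_length) {
  if (any(!is.finite(resting_length)) || any(resting_length <= 0)) {
    stop("resting_length must be > 0", call. = FALSE)
  }
  (length - resting_length) / resting_length
}

#' Piecewise nonlinear ligament force law
#'
#' Zero force when slack, a quadratic toe region for small strains, linear
#' above twice the linear strain limit:
#' \deqn{f(e) = 0 \ (e \le 0);\quad 0.25\,k\,e^2/e_l \ (0 \le e \le 2e_l);
#'   \quad k\,(e - e_l) \ (e \ge 2e_l)}
#' The two non-zero branches agree at `e = 2 * e_l` (both give `k * e_l`), so
#' the law is continuous.
#'
#' @param strain Dimensionless strain (vectorized).
#' @param stiffness k, Newtons.
#' @param linear_strain_limit e_l, dimensionless.
#' @return Force in Newtons, same length as `strain`.
#' @export
#' @examples
#' ligament_force(0.03, 3100, 0.03) # toe region: 23.25 N
#' ligament_force(0.06, 3100, 0.03) # transition: 93 N
ligament_force <- function(strain, stiffness, linear_strain_limit) {
  stopifnot(stiffness > 0, linear_strain_limit > 0)
  k <- stiffness
  el <- linear_strain_limit
  ifelse(strain <= 0, 0,
    ifelse(strain <= 2 * el,
      0.25 * k * strain^2 / el,
      k * (strain - el)
    )
  )
}

#' Scale a ligament to a subject's size
#'
#' Insertion coordinates are multiplied by `uniform_scale`; the resting
#' length is multiplied by the ratio of the default-pose path length after
#' scaling to the path length before scaling (for a uniform scale of the
#' whole geometry this ratio equals `uniform_scale`, so the default-pose
#' strain is preserved exactly). Stiffness is never scaled.
#'
#' @param spec A [ligament_spec()].
#' @param uniform_scale Positive scale factor.
#' @param default_pose_transform The default-pose [rigid_transform()] of the
#'   unscaled model, or `NULL` to assume the simple ratio `uniform_scale`.
#' @return A new `ligament_spec`.
#' @export
scale_ligament <- function(spec, uniform_scale, default_pose_transform = NULL) {
  stopifnot(inherits(spec, "ligament_spec"))
  if (!is.finite(uniform_scale) || uniform_scale <= 0) {
    stop("uniform_scale must be > 0", call. = FALSE)
  }
  scaled <- spec
  scaled$femoral_insertion <- spec$femoral_insertion * uniform_scale
  scaled$tibial_insertion <- spec$tibial_insertion * uniform_scale
  if (is.null(default_pose_transform)) {
    ratio <- uniform_scale
  } else {
    l_before <- ligament_length(spec, default_pose_transform)
    if (l_before <= 0) {
      stop("zero default-pose path length; cannot scale resting length",
        call. = FALSE
      )
    }
    tf_after <- rigid_transform(
      rotation = default_pose_transform$rotation,
      translation = default_pose_transform$translation * uniform_scale
    )
    ratio <- ligament_length(scaled, tf_after) / l_before
  }
  scaled$resting_length <- spec$resting_length * ratio
  scaled
}
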