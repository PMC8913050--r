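#' Anatomical frame convention
#'
#' Both the femur and tibia frames use x pointing anteriorly, y proximally and
#' z laterally. The side determines how "medial"/"lateral" map onto the z
#' axis: for a right knee lateral is +z and medial is -z; for a left knee the
#' signs flip.
#'
#' @param side `"right"` (default) or `"left"`.
#' @return An object of class `frame_convention`.
#' @export
frame_convention <- function(side = c("right", "left")) {
  side <- match.arg(side)
  structure(
    list(side = side, lateral_sign = if (side == "right") 1 else -1),
    class = "frame_convention"
  )
}

#' @export
print.frame_convention <- function(x, ...) {
  cat(sprintf(
    "Frame convention: x anterior, y proximal, z lateral; %s knee (lateral = %+dz)\n",
    x$side, x$lateral_sign
  ))
  invisible(x)
}

#' Flexion-coupled tibiofemoral translation
#'
#' The anteroposterior (tx) and superoinferior (ty) translations of the tibia
#' frame origin relative to the femur frame are functions of knee flexion,
#' represented as a knot table and interpolated piecewise-linearly (the
#' default) or with a natural cubic spline. The shipped default table is a
#' generic-model stand-in: posterior femoral roll-back of about 0.5 cm over
#' 0-120 degrees of flexion with a small, nearly constant vertical offset. It
#' is configurable because published whole-body models inherit this coupling
#' from their source knee rigs rather than printing it.
#'
#' @param knots Data frame with columns `flexion` (degrees), `tx` and `ty`
#'   (cm); flexion must be strictly increasing and cover at least 0-90
#'   degrees.
#' @param method `"linear"` (default) or `"spline"`.
#' @return An object of class `knee_coupling`.
#' @export
knee_coupling <- function(knots = default_coupling_knots(),
                          method = c("linear", "spline")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(knots), all(c("flexion", "tx", "ty") %in% names(knots)))
  if (nrow(knots) == 0L) stop("empty coupling knot table", call. = FALSE)
  if (is.unsorted(knots$flexion, strictly = TRUE)) {
    stop("coupling knots must have strictly increasing flexion", call. = FALSE)
  }
  if (min(knots$flexion) > 0 || max(knots$flexion) < 90) {
    stop("coupling knots must cover at least [0, 90] degrees", call. = FALSE)
  }
  structure(
    list(knots = knots, method = method),
    class = "knee_coupling"
  )
}

#' Default tibiofemoral coupling knots
#'
#' Generic stand-in table (flexion degrees; tx, ty cm). See [knee_coupling()].
#' @return Data frame of coupling knots.
#' @export
default_coupling_knots <- function() {
  data.frame(
    flexion = c(0, 15, 30, 60, 90, 120),
    tx = c(0, -0.08, -0.16, -0.32, -0.44, -0.52),
    ty = rep(0.80, 6)
  )
}

#' @export
print.knee_coupling <- function(x, ...) {
  cat(sprintf(
    "Knee coupling (%s interpolation), %d knots over [%g, %g] deg flexion\n",
    x$method, nrow(x$knots), min(x$knots$flexion), max(x$knots$flexion)
  ))
  print(x$knots, row.names = FALSE)
  invisible(x)
}

#' Evaluate the coupling at given flexion angles
#'
#' Flexion outside the knot domain is clamped to the nearest boundary, with a
#' warning, because the table describes a bounded anatomical function.
#'
#' @param coupling A [knee_coupling()] object.
#' @param flexion Numeric vector of flexion angles, degrees.
#' @return List with numeric vectors `tx` and `ty` (cm).
#' @export
evaluate_coupling <- function(coupling, flexion) {
  stopifnot(inherits(coupling, "knee_coupling"))
  kn <- coupling$knots
  lo <- min(kn$flexion)
  hi <- max(kn$flexion)
  out_of_domain <- flexion < lo | flexion > hi
  if (any(out_of_domain)) {
    warning(sprintf(
      "%d flexion value(s) outside coupling domain [%g, %g] deg; clamped",
      sum(out_of_domain), lo, hi
    ), call. = FALSE)
    flexion <- pmin(pmax(flexion, lo), hi)
  }
  if (coupling$method == "linear") {
    tx <- stats::approx(kn$flexion, kn$tx, xout = flexion, rule = 2)$y
    ty <- stats::approx(kn$flexion, kn$ty, xout = flexion, rule = 2)$y
  } else {
    tx <- stats::spline(kn$flexion, kn$tx, xout = flexion, method = "natural")$y
    ty <- stats::spline(kn$flexion, kn$ty, xout = flexion, method = "natural")$y
  }
  list(tx = tx, ty = ty)
}

#' Knee pose (three independent rotations)
#'
#' @param flexion,adduction,internal_rotation Angles in degrees.
#' @return An object of class `knee_pose`.
#' @export
knee_pose <- function(flexion = 0, adduction = 0, internal_rotation = 0) {
  v <- c(flexion, adduction, internal_rotation)
  if (any(!is.finite(v))) stop("pose angles must be finite", call. = FALSE)
  structure(
    list(
      flexion = as.numeric(flexion),
      adduction = as.numeric(adduction),
      internal_rotation = as.numeric(internal_rotation)
    ),
    class = "knee_pose"
  )
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Construct a rigid transform mapping femur-frame points into the tibia frame
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric, cm.
#' @return An object of class `rigid_transform`; `transform_point()` applies
#'   it as `rotation %*% p + translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(
    list(rotation = rotation, translation = as.numeric(translation)),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to points
#'
#' @param tf A [rigid_transform()].
#' @param p Length-3 vector or 3-row matrix of femur-frame coordinates (cm).
#' @return Tibia-frame coordinates, same shape as `p`.
#' @export
transform_point <- function(tf, p) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.matrix(p)) {
    tf$rotation %*% p + tf$translation
  } else {
    as.numeric(tf$rotation %*% p + tf$translation)
  }
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (femur -> tibia frame)\n")
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation (cm):", paste(round(x$translation, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Femur-to-tibia transform at a knee pose
#'
#' The tibia frame's orientation relative to the femur is built from three
#' successive body-fixed rotations in the fixed order flexion (about z),
#' adduction (about x), internal rotation (about y). Its origin sits at the
#' default-pose offset (femoral-head center to epicondyle midpoint) plus the
#' flexion-coupled translation from [evaluate_coupling()]. The returned
#' transform maps femur-frame point coordinates into the tibia frame.
#'
#' @param pose A [knee_pose()].
#' @param coupling A [knee_coupling()] object, or `NULL` for zero coupling.
#' @param convention A [frame_convention()].
#' @param origin_offset Default-pose position of the tibia frame origin in the
#'   femur frame, cm. Default `c(0, -40, 0)`: the epicondyle midpoint about
#'   40 cm distal to the femoral head along the femoral axis.
#' @return A [rigid_transform()].
#' @export
femur_to_tibia_transform <- function(pose, coupling = NULL,
                                     convention = frame_convention(),
                                     origin_offset = c(0, -40, 0)) {
  stopifnot(inherits(pose, "knee_pose"), inherits(convention, "frame_convention"))
  deg <- pi / 180
  # orientation of the tibia frame expressed in the femur frame
  R <- rot_z(-pose$flexion * deg) %*%
    rot_x(pose$adduction * deg) %*%
    rot_y(pose$internal_rotation * deg)
  if (is.null(coupling)) {
    tr <- list(tx = 0, ty = 0)
  } else {
    tr <- evaluate_coupling(coupling, pose$flexion)
  }
  origin <- as.numeric(origin_offset) + c(tr$tx, tr$ty, 0)
  # femur->tibia mapping: p_tibia = R' (p_femur - origin)
  rigid_transform(rotation = t(R), translation = -as.numeric(t(R) %*% origin))
}
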