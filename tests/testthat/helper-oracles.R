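# Independent oracles used by the test suite. These deliberately avoid the
# package's own transform/statistics code paths: the transform oracle builds
# explicit 4x4 homogeneous matrices and inverts with solve(); the statistics
# oracles use textbook sum formulas.

oracle_rot4 <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  c4 <- diag(4)
  c_ <- cos(a)
  s_ <- sin(a)
  if (axis == "x") {
    c4[2:3, 2:3] <- matrix(c(c_, s_, -s_, c_), 2, 2)
  } else if (axis == "y") {
    c4[c(1, 3), c(1, 3)] <- matrix(c(c_, -s_, s_, c_), 2, 2)
  } else {
    c4[1:2, 1:2] <- matrix(c(c_, s_, -s_, c_), 2, 2)
  }
  c4
}

oracle_trans4 <- function(v) {
  m <- diag(4)
  m[1:3, 4] <- v
  m
}

# Femur -> tibia homogeneous transform: tibia frame placed in the femur frame
# by translation (offset + coupling) then body-fixed rotations z(-flex),
# x(add), y(introt); the femur->tibia map is the inverse of that placement.
oracle_femur_to_tibia_h <- function(flexion, adduction, internal_rotation,
                                    tx = 0, ty = 0, offset = c(0, -40, 0)) {
  placement <- oracle_trans4(offset + c(tx, ty, 0)) %*%
    oracle_rot4("z", -flexion) %*%
    oracle_rot4("x", adduction) %*%
    oracle_rot4("y", internal_rotation)
  solve(placement)
}

oracle_map_point <- function(h4, p) {
  as.numeric(h4 %*% c(p, 1))[1:3]
}

oracle_ligament_length <- function(fem, tib, flexion, adduction,
                                   internal_rotation, tx = 0, ty = 0,
                                   offset = c(0, -40, 0)) {
  h <- oracle_femur_to_tibia_h(flexion, adduction, internal_rotation,
    tx = tx, ty = ty, offset = offset
  )
  sqrt(sum((oracle_map_point(h, fem) - tib)^2))
}

# Textbook Pearson correlation with exact-t two-sided p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x)
  sy <- sum(y)
  sxy <- sum(x * y)
  sxx <- sum(x^2)
  syy <- sum(y^2)
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Textbook paired t-test on differences.
oracle_paired_t <- function(x, y) {
  d <- y - x
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# Hand-built toy kinematics for pipeline oracles (closure within 1 deg).
make_toy_kinematics <- function(flexion, adduction, internal_rotation,
                                subject_id = "toy", stance_fraction = 0.6) {
  n <- length(flexion)
  structure(
    list(
      subject_id = subject_id,
      n_points = n,
      time = seq(0, 1, length.out = n),
      flexion = flexion,
      adduction = adduction,
      internal_rotation = internal_rotation,
      stance_fraction = stance_fraction
    ),
    class = "gait_kinematics"
  )
}

# Hand-built force curve for the statistics layer.
make_toy_curve <- function(force, subject_id = "toy", direction = "center",
                           magnitude_mm = 0, stance_fraction = 0.6) {
  n <- length(force)
  structure(
    list(
      subject_id = subject_id,
      direction = direction,
      magnitude_mm = magnitude_mm,
      time = seq(0, 1, length.out = n),
      length = NULL,
      strain = NULL,
      force = force,
      all_slack = all(force == 0),
      stance_fraction = stance_fraction
    ),
    class = "force_curve"
  )
}

random_pose_case <- function() {
  list(
    flexion = stats::runif(1, -10, 110),
    adduction = stats::runif(1, -15, 15),
    internal_rotation = stats::runif(1, -20, 20),
    tx = stats::runif(1, -1, 1),
    ty = stats::runif(1, -1, 1),
    offset = c(stats::runif(1, -2, 2), stats::runif(1, -45, -35),
               stats::runif(1, -2, 2))
  )
}
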