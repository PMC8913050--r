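test_that("the default insertion-site grid has 13 unique resolved positions", {
  grid <- make_tis_grid(c(1.2, -3.2, -0.1), frame_convention("right"))
  expect_equal(nrow(grid), 13)
  expect_equal(sum(grid$direction == "center"), 1)
  expect_false(any(duplicated(grid[, c("direction", "magnitude_mm")])))
  expect_false(any(duplicated(grid[, c("x", "y", "z")])))
  # anterior 2.5 mm moves x by +0.25 cm; y never changes
  ant <- grid[grid$direction == "anterior" & grid$magnitude_mm == 2.5, ]
  expect_equal(ant$x, 1.45)
  expect_equal(ant$z, -0.1)
  expect_true(all(grid$y == -3.2))
  ctr <- grid[grid$direction == "center", ]
  expect_equal(c(ctr$x, ctr$y, ctr$z), c(1.2, -3.2, -0.1))
})

test_that("medial/lateral offsets flip sign between right and left knees", {
  gr <- make_tis_grid(c(0, 0, 0), frame_convention("right"), 2.5)
  gl <- make_tis_grid(c(0, 0, 0), frame_convention("left"), 2.5)
  med_r <- gr$z[gr$direction == "medial"]
  med_l <- gl$z[gl$direction == "medial"]
  expect_equal(med_r, -0.25) # right knee: medial is -z
  expect_equal(med_l, 0.25)
  expect_equal(gr$x[gr$direction == "anterior"], gl$x[gl$direction == "anterior"])
})

test_that("an over-long resting length yields an all-slack, all-zero curve", {
  prof <- subject_profile("S1", 1.7, 70, 1L)
  kin <- generate_subject_kinematics(gait_landmarks(), prof, variability = 0)
  spec <- ligament_spec(resting_length = 50)
  cv <- simulate_force_curve(kin, spec)
  expect_true(cv$all_slack)
  expect_true(all(cv$force == 0))
  expect_true(all(cv$strain < 0))
  expect_length(cv$force, 101)
})

test_that("force curves are deterministic and non-negative", {
  prof <- subject_profile("S1", 1.7, 70, 5L)
  kin <- generate_subject_kinematics(gait_landmarks(), prof, variability = 1)
  c1 <- simulate_force_curve(kin, ligament_spec())
  c2 <- simulate_force_curve(kin, ligament_spec())
  expect_identical(c1$force, c2$force)
  expect_true(all(c1$force >= 0))
})

test_that("a toy cycle reproduces hand-applied length, strain and force values", {
  # 5-point toy cycle; lengths from the independent homogeneous oracle and
  # forces by direct substitution into the piecewise law.
  flex <- c(0, 20, 60, 20, 0)
  add <- c(0, 5, -5, 5, 0)
  rot <- c(0, -5, 10, -5, 0)
  kin <- make_toy_kinematics(flex, add, rot)
  spec <- ligament_spec()
  cp <- knee_coupling()
  off <- c(0, -40, 0)
  cv <- simulate_force_curve(kin, spec, cp, frame_convention(), off)
  tr <- evaluate_coupling(cp, flex)
  for (i in 1:5) {
    len_i <- oracle_ligament_length(
      spec$femoral_insertion, spec$tibial_insertion,
      flex[i], add[i], rot[i],
      tx = tr$tx[i], ty = tr$ty[i], offset = off
    )
    e_i <- (len_i - spec$resting_length) / spec$resting_length
    f_i <- if (e_i <= 0) {
      0
    } else if (e_i <= 2 * spec$linear_strain_limit) {
      0.25 * spec$stiffness * e_i^2 / spec$linear_strain_limit
    } else {
      spec$stiffness * (e_i - spec$linear_strain_limit)
    }
    expect_lt(abs(cv$length[i] - len_i), 1e-9)
    expect_lt(abs(cv$force[i] - f_i), 1e-9)
  }
})

test_that("the default sweep covers the full subject-by-site cross product", {
  cfg <- default_config()
  cohort <- cohort_from_config(cfg)
  sweep <- run_sweep(cohort, config = cfg)
  expect_length(sweep$curves, 91) # 7 subjects x 13 sites
  df <- as.data.frame(sweep)
  expect_equal(nrow(df), 91 * 101)
  counts <- table(df$subject_id)
  expect_true(all(counts == 13 * 101))
  # stable subject-major ordering
  expect_equal(
    unique(df$subject_id),
    vapply(cohort, function(s) s$profile$subject_id, character(1))
  )
  # provenance recorded per curve
  expect_true(all(vapply(sweep$curves, function(cv) {
    is.numeric(cv$uniform_scale) && is.integer(cv$rng_seed)
  }, logical(1))))
})

test_that("a degenerate center-only sweep equals the direct simulation", {
  cfg <- default_config()
  cfg$cohort$n_subjects <- 1L
  cohort <- cohort_from_config(cfg)
  conv <- frame_convention(cfg$side)
  grid <- make_tis_grid(c(1.2, -3.2, -0.1), conv, 2.5)
  grid <- grid[grid$direction == "center", , drop = FALSE]
  class(grid) <- c("tis_grid", "data.frame")
  sweep <- run_sweep(cohort, grid = grid, config = cfg)
  expect_length(sweep$curves, 1)

  s <- cohort[[1]]$profile$uniform_scale
  spec <- ligament_spec()
  spec$femoral_insertion <- spec$femoral_insertion * s
  spec$tibial_insertion <- spec$tibial_insertion * s
  spec$resting_length <- spec$resting_length * s
  cp <- knee_coupling()
  cp$knots$tx <- cp$knots$tx * s
  cp$knots$ty <- cp$knots$ty * s
  direct <- simulate_force_curve(
    cohort[[1]]$kinematics, spec, cp, conv, c(0, -40, 0) * s
  )
  expect_equal(sweep$curves[[1]]$force, direct$force)
})

test_that("sweeps rerun from the same master seed are bit-identical", {
  cfg <- default_config()
  cfg$cohort$n_subjects <- 2L
  s1 <- run_sweep(cohort_from_config(cfg), config = cfg)
  s2 <- run_sweep(cohort_from_config(cfg), config = cfg)
  expect_identical(
    lapply(s1$curves, `[[`, "force"),
    lapply(s2$curves, `[[`, "force")
  )
})

test_that("length grows monotonically with offset magnitude along a lengthening direction", {
  # closed-form check at fixed poses: if the first anterior step lengthens the
  # path, larger anterior offsets lengthen it strictly further (and likewise
  # for each direction), because distance is convex in the moved coordinate.
  spec <- ligament_spec()
  conv <- frame_convention()
  grid <- make_tis_grid(spec$tibial_insertion, conv)
  withr::with_seed(13, {
    for (i in 1:20) {
      cs <- random_pose_case()
      tf <- femur_to_tibia_transform(
        knee_pose(cs$flexion, cs$adduction, cs$internal_rotation),
        coupling = NULL, origin_offset = cs$offset
      )
      p <- transform_point(tf, spec$femoral_insertion)
      len_at <- function(row) sqrt(sum((p - c(row$x, row$y, row$z))^2))
      center_len <- len_at(grid[grid$direction == "center", ])
      for (dir in c("anterior", "posterior", "medial", "lateral")) {
        rows <- grid[grid$direction == dir, ]
        rows <- rows[order(rows$magnitude_mm), ]
        lens <- vapply(seq_len(nrow(rows)), function(j) len_at(rows[j, ]),
          numeric(1)
        )
        if (lens[1] > center_len) {
          expect_true(all(diff(c(center_len, lens)) > 0))
        }
      }
    }
  })
})

test_that("a failing sweep cell is reported with its subject and site", {
  cfg <- default_config()
  cfg$cohort$n_subjects <- 1L
  cohort <- cohort_from_config(cfg)
  cohort[[1]]$kinematics$flexion[5] <- NaN
  expect_error(
    run_sweep(cohort, config = cfg),
    "sweep cell failed.*S01"
  )
})
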