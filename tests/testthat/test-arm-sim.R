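test_that("forward kinematics reproduces the calibrated home position", {
  arm <- desk_arm()
  q0 <- initial_pose(arm)
  expect_equal(forward_kinematics(arm, q0), c(0.24, 0, 0.21),
               tolerance = 1e-5)
})

test_that("fingertip never leaves the sphere of total arm length", {
  arm <- desk_arm()
  set.seed(11)
  for (i in 1:50) {
    q <- runif(7, arm$lower, arm$upper)
    expect_lte(sqrt(sum(forward_kinematics(arm, q)^2)),
               sum(arm$lengths) + 1e-12)
  }
})

test_that("forward kinematics matches the transform-chain oracle", {
  arm <- desk_arm()
  set.seed(7)
  for (i in 1:20) {
    q <- runif(7, arm$lower, arm$upper)
    expect_equal(forward_kinematics(arm, q), oracle_fk(arm, q),
                 tolerance = 1e-10)
  }
  expect_error(forward_kinematics(arm, c(NA, rep(0, 6))),
               class = "motorsynergy_invalid_argument")
})

test_that("fingertip velocity is the Jacobian image of joint velocity", {
  arm <- desk_arm()
  q0 <- initial_pose(arm)
  expect_equal(fingertip_velocity(arm, arm_state(q0)), c(0, 0, 0))
  set.seed(21)
  for (i in 1:10) {
    q <- runif(7, arm$lower * 0.9, arm$upper * 0.9)
    qd <- rnorm(7)
    v1 <- fingertip_velocity(arm, arm_state(q, qd))
    expect_equal(fingertip_velocity(arm, arm_state(q, 2 * qd)), 2 * v1,
                 tolerance = 1e-12)
    # central finite difference of the fingertip position
    h <- 1e-6
    v_fd <- (forward_kinematics(arm, q + h * qd) -
             forward_kinematics(arm, q - h * qd)) / (2 * h)
    expect_equal(v1, v_fd, tolerance = 1e-6)
  }
})

test_that("stepping is deterministic, limit-respecting, and stable at rest", {
  arm <- desk_arm(gravity = c(0, 0, 0))
  st <- arm_state(initial_pose(desk_arm()))
  expect_equal(arm_step(arm, st, rep(0, 7))$q, st$q)

  arm <- desk_arm()
  st <- arm_state(initial_pose(arm), rnorm(7, 0, 2))
  s1 <- arm_step(arm, st, rep(5, 7))
  s2 <- arm_step(arm, st, rep(5, 7))
  expect_identical(s1$q, s2$q)
  # hammer a joint into its limit: angles stay inside
  st <- arm_state(initial_pose(arm))
  for (i in 1:100) {
    st <- arm_step(arm, st, rep(arm$torque_limit * 2, 7))
    expect_true(all(st$q >= arm$lower - 1e-12 & st$q <= arm$upper + 1e-12))
  }
  expect_error(arm_step(arm, st, rep(Inf, 7)),
               class = "motorsynergy_invalid_argument")
})

test_that("inverse dynamics is consistent with forward dynamics", {
  arm <- desk_arm()
  q0 <- initial_pose(arm)
  # statics: gravity compensation holds the arm still
  tau_g <- inverse_dynamics(arm, q0, rep(0, 7), rep(0, 7))
  st <- arm_state(q0)
  for (i in 1:50) st <- arm_step(arm, st, tau_g)
  expect_equal(st$q, q0, tolerance = 1e-9)
  # round trip at random states
  set.seed(3)
  for (i in 1:10) {
    q <- runif(7, arm$lower, arm$upper); qd <- rnorm(7); qdd <- rnorm(7)
    tau <- inverse_dynamics(arm, q, qd, qdd)
    expect_equal(forward_dynamics(arm, q, qd, tau), qdd, tolerance = 1e-8)
  }
  # no gravity, no motion -> no torque
  arm0 <- desk_arm(gravity = c(0, 0, 0), joint_damping = 0)
  expect_equal(inverse_dynamics(arm0, runif(7, -1, 1), rep(0, 7), rep(0, 7)),
               rep(0, 7), tolerance = 1e-12)
})

test_that("free motion conserves energy without gravity or damping", {
  arm <- desk_arm(gravity = c(0, 0, 0), joint_damping = 0)
  st <- arm_state(initial_pose(desk_arm()), c(0.5, -0.3, 0.2, 0.4, -0.2, 0.1, 0.3))
  e0 <- arm_energy(arm, st$q, st$qd)$total
  for (i in 1:100) st <- arm_step(arm, st, rep(0, 7))
  e1 <- arm_energy(arm, st$q, st$qd)$total
  expect_lt(abs(e1 - e0) / e0, 0.005)
})

test_that("elbow pendulum energy drift stays below 0.1% per second", {
  # free elbow, all other joints locked; limits widened so the swing never
  # hits a stop; oracle is the closed-form compound-pendulum energy
  arm <- desk_arm(joint_damping = 0,
                  lower = c(-1.57, -0.85, -0.85, -6, -1.50, -0.50, -1.05),
                  upper = c(0.70, 1.57, 0.85, 6, 1.57, 0.50, 1.05))
  locked <- rep(TRUE, 7); locked[4] <- FALSE
  st <- arm_state(rep(0, 7))
  emin <- oracle_pendulum_energy(arm, pi / 2 - arm$shoulder_tilt, 0)
  e0 <- oracle_pendulum_energy(arm, 0, 0) - emin
  energies <- numeric(100)
  for (i in 1:100) {
    st <- arm_step(arm, st, rep(0, 7), locked = locked)
    energies[i] <- oracle_pendulum_energy(arm, st$q[4], st$qd[4]) - emin
  }
  expect_equal(st$q[c(1:3, 5:7)], rep(0, 6))  # locked joints never move
  drift <- abs(mean(energies[85:100]) - mean(energies[1:16])) / e0
  expect_lt(drift, 0.001)
})

test_that("initial_pose is deterministic and adapts to arm geometry", {
  arm <- desk_arm()
  expect_identical(initial_pose(arm), initial_pose(arm))
  for (preset in c("shorter", "longer")) {
    m <- arm_model(preset)
    qi <- default_q_initial(m)
    q <- initial_pose(m, qi)
    expect_lt(sqrt(sum((forward_kinematics(m, q) - qi)^2)), 1e-6)
    expect_true(all(q >= m$lower & q <= m$upper))
  }
  expect_error(initial_pose(arm, c(2, 0, 0)),
               class = "motorsynergy_no_solution")
})

test_that("arm configuration files round-trip through YAML", {
  arm <- arm_model("shorter", torque_limit = 15)
  path <- tempfile(fileext = ".yaml")
  write_arm_config(arm, path)
  back <- read_arm_config(path)
  expect_equal(back$lengths, arm$lengths)
  expect_equal(back$inertias, arm$inertias, ignore_attr = TRUE)
  expect_equal(back$torque_limit, 15)
  expect_equal(forward_kinematics(back, initial_pose(back, default_q_initial(back))),
               default_q_initial(arm), tolerance = 1e-5)
})

test_that("shipped arm presets load from extdata and match the constructors", {
  for (preset in c("original", "shorter", "longer")) {
    path <- system.file("extdata", "arm", paste0(preset, ".yaml"),
                        package = "motorsynergy")
    expect_true(nzchar(path))
    cfg <- read_arm_config(path)
    ref <- arm_model(preset)
    expect_equal(cfg$lengths, ref$lengths)
    expect_equal(cfg$masses, ref$masses)
    expect_equal(cfg$lower, ref$lower)
  }
})
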