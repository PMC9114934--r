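test_that("target sets follow the plane formulas", {
  task <- desk_task()
  th <- make_targets("horizontal", 8, task)
  expect_equal(th$positions[1, ], c(0.24, -0.15, 0.21))
  tu <- make_targets("upper", 8, task)
  expect_equal(tu$positions[1, ], c(0.24, -0.15, 0.26))
  for (pl in c("horizontal", "sagittal", "frontal")) {
    tg <- make_targets(pl, 8, task)
    d <- sqrt(rowSums(sweep(tg$positions, 2, task$q_initial)^2))
    expect_equal(d, rep(0.15, 8))
  }
  expect_error(make_targets("diagonal", 8, task),
               class = "motorsynergy_invalid_argument")
})

test_that("a 32-direction set contains the 8-direction set as every 4th", {
  task <- desk_task()
  for (pl in c("horizontal", "sagittal", "frontal", "upper")) {
    t8 <- make_targets(pl, 8, task)
    t32 <- make_targets(pl, 32, task)
    expect_equal(t32$positions[seq(1, 32, 4), ], t8$positions)
  }
})

test_that("reward matches hand-evaluated penalty terms", {
  task <- desk_task()
  tgt <- c(0.24, -0.15, 0.21)
  # intermediate sample, zero action: no penalty at all
  expect_equal(task_reward(task, c(1, 1, 1), c(1, 1, 1), rep(0, 7), tgt, 10), 0)
  # on target with zero velocity and zero action at t_target: zero
  expect_equal(task_reward(task, tgt, c(0, 0, 0), rep(0, 7), tgt, 50), 0)
  # hand-computed: 0.1 m error, 0.5 m/s speed, |a| = 2 at t_target
  a <- rep(2 / sqrt(7), 7)
  r <- task_reward(task, tgt + c(0.1, 0, 0), c(0.5, 0, 0), a, tgt, 50)
  expect_equal(r, -(0.01 + 0.002 * 0.25 + 0.2 * 4 * 0.01), tolerance = 1e-12)
  expect_lte(r, 0)
  expect_error(task_reward(task, tgt, c(0, 0, 0), rep(0, 7), tgt, 101),
               class = "motorsynergy_invalid_argument")
})

test_that("the observation layout is frozen", {
  task <- desk_task()
  st <- arm_state(1:7 / 10, (1:7) / 100)
  obs <- task_observation(st, c(0.1, 0.2, 0.3), 25L, task)
  expect_identical(obs, c(1:7 / 10, (1:7) / 100, c(0.1, 0.2, 0.3), 0.25))
  expect_length(obs, 18)
})

test_that("episodes have the declared structure and are reproducible", {
  arm <- desk_arm(); task <- desk_task()
  tgt <- make_targets("horizontal", 8, task)$positions[1, ]
  zero <- function(obs) rep(0, 7)
  tr <- run_episode(arm, task, tgt, zero)
  expect_s3_class(tr, "trajectory")
  expect_equal(dim(tr$observations), c(100, 18))
  expect_equal(dim(tr$actions), c(100, 7))
  expect_equal(nrow(tr$fingertip_positions), 100)
  expect_length(tr$rewards, 100)
  expect_equal(tr$G, sum(tr$rewards))
  expect_lte(tr$G, 0)
  # zero controller: only checkpoint penalties accrue
  expect_equal(sum(tr$rewards[-c(50, 100)]), 0)
  noisy <- function(obs) rnorm(7)
  tr1 <- run_episode(arm, task, tgt, noisy, seed = 5)
  tr2 <- run_episode(arm, task, tgt, noisy, seed = 5)
  expect_identical(tr1$actions, tr2$actions)
  expect_identical(tr1$fingertip_positions, tr2$fingertip_positions)
})

test_that("open-loop episodes agree with the closed-loop reward path", {
  arm <- desk_arm(); task <- desk_task()
  tgt <- make_targets("sagittal", 8, task)$positions[3, ]
  tr <- generate_expert_trajectory(arm, task, tgt)
  replay <- run_open_loop(arm, task, tgt, tr$actions)
  expect_equal(replay$rewards, tr$rewards, tolerance = 1e-10)
  expect_equal(replay$G, tr$G, tolerance = 1e-10)
})

test_that("reaching errors convert to centimetres at the right samples", {
  arm <- desk_arm(); task <- desk_task()
  tgt <- c(0.24, -0.15, 0.21)
  tr <- run_open_loop(arm, task, tgt, matrix(0, 100, 7))
  tr$fingertip_positions[50, ] <- tgt
  tr$fingertip_positions[100, ] <- task$q_initial
  expect_equal(unname(reaching_errors(tr, task, tgt)), c(0, 0))
  tr$fingertip_positions[50, ] <- tgt + c(0.01, 0, 0)
  expect_equal(unname(reaching_errors(tr, task, tgt)[1]), 1)
})

test_that("trajectories round-trip through the tidy CSV container", {
  arm <- desk_arm(); task <- desk_task()
  tgt <- make_targets("horizontal", 8, task)$positions[2, ]
  tr <- generate_expert_trajectory(arm, task, tgt)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$actions, tr$actions, ignore_attr = TRUE)
  expect_equal(back$fingertip_positions, tr$fingertip_positions,
               ignore_attr = TRUE)
  expect_equal(back$G, tr$G)
  expect_equal(back$target, tgt)
  expect_equal(back$metadata$source, "surrogate")
})
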