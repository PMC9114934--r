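test_that("GAE matches limits and the brute-force telescoped sum", {
  z <- compute_gae(rep(0, 5), rep(0, 6))
  expect_equal(z$advantages, rep(0, 5))
  # lambda = 0 reduces to one-step TD errors
  set.seed(14)
  r <- rnorm(10); v <- rnorm(11)
  td <- compute_gae(r, v, gamma = 0.99, lambda = 0)
  expect_equal(td$advantages, r + 0.99 * v[-1] - v[-11], tolerance = 1e-12)
  # spec'd toy instance and random instances against the oracle
  g <- compute_gae(c(1, 1), c(0, 0, 0), 0.99, 0.97)
  o <- oracle_gae(c(1, 1), c(0, 0, 0), 0.99, 0.97)
  expect_equal(g$advantages, o$advantages, tolerance = 1e-12)
  for (i in 1:10) {
    r <- rnorm(20); v <- rnorm(21)
    g <- compute_gae(r, v, 0.95, 0.9)
    o <- oracle_gae(r, v, 0.95, 0.9)
    expect_equal(g$advantages, o$advantages, tolerance = 1e-12)
    expect_equal(g$returns, o$returns, tolerance = 1e-12)
  }
  expect_error(compute_gae(rnorm(5), rnorm(5)),
               class = "motorsynergy_invalid_argument")
})

test_that("the clipped surrogate behaves per the clipping definition", {
  cs <- motorsynergy:::clipped_surrogate
  adv <- rnorm(50)
  # ratio identically 1: clip inactive
  expect_equal(cs(rep(1, 50), adv, 0.2), adv)
  # positive advantage with ratio above the band: gradient plateau value
  expect_equal(cs(1.5, 2, 0.2), 1.2 * 2)
  # negative advantage with ratio below the band
  expect_equal(cs(0.5, -1, 0.2), 0.8 * -1)
})

test_that("default PPO configuration carries the reference hyperparameters", {
  cfg <- ppo_config()
  expect_equal(cfg$n_epochs, 3000)
  expect_equal(cfg$steps_per_epoch, 10000)
  expect_equal(cfg$gamma, 0.99)
  expect_equal(cfg$clip_ratio, 0.2)
  expect_equal(cfg$gae_lambda, 0.97)
  expect_equal(cfg$policy_lr, 3e-4)
  expect_equal(cfg$critic_lr, 1e-3)
  expect_equal(cfg$grad_steps_per_epoch, 80)
  spec <- policy_network_spec()
  expect_equal(spec$input_size, 18)
  expect_equal(spec$hidden, c(256, 256))
  expect_equal(spec$output_size, 7)
})

test_that("one PPO update fits the critic to a synthetic batch", {
  set.seed(31)
  n <- 256; d <- 4; k <- 2
  policy <- motorsynergy:::new_gaussian_policy(
    policy_network_spec(d, c(16, 16), k))
  critic <- list(net = motorsynergy:::mlp_new(c(d, 16, 16, 1)))
  obs <- matrix(rnorm(n * d), n, d)
  mu0 <- motorsynergy:::mlp_forward(policy$net, obs)$out
  actions <- mu0 + matrix(rnorm(n * k), n, k)
  batch <- list(obs = obs, actions = actions,
                advantages = rnorm(n),
                old_logp = motorsynergy:::gaussian_logp(actions, mu0,
                                                        policy$log_std),
                returns = rowSums(obs) * 0.5)
  v0 <- motorsynergy:::mlp_forward(critic$net, obs)$out[, 1]
  mse0 <- mean((v0 - batch$returns)^2)
  cfg <- ppo_config(n_epochs = 1, steps_per_epoch = n,
                    grad_steps_per_epoch = 40, minibatch_size = 64)
  up <- ppo_update(policy, critic, batch, cfg)
  v1 <- motorsynergy:::mlp_forward(up$critic$net, obs)$out[, 1]
  expect_lt(mean((v1 - batch$returns)^2), mse0)
  expect_true(is.finite(up$diagnostics$policy_loss))
})

test_that("PPO learns the point-mass reciprocating task", {
  # scaled-down training budget on the 1-d.f. variant; success means the
  # mean return closes at least half the gap from its first-epoch value to 0
  cfg <- ppo_config(n_epochs = 150, steps_per_epoch = 2000,
                    grad_steps_per_epoch = 20, seed = 77)
  env <- point_mass_env()
  out <- motorsynergy:::ppo_train(env, cfg,
                                  policy_network_spec(4, c(32, 32), 1))
  g_first <- out$log$mean_G[1]
  g_last <- mean(tail(out$log$mean_G, 10))
  expect_gt(g_last, g_first * 0.5)
})

test_that("policy rollouts have the declared shape and determinism", {
  arm <- desk_arm(); task <- desk_task()
  targets <- make_targets("horizontal", 8, task)
  policy <- motorsynergy:::new_gaussian_policy(policy_network_spec(), seed = 3)
  trajs <- rollout_policy(policy, arm, task, targets, deterministic = TRUE)
  expect_length(trajs, 8)
  expect_true(all(vapply(trajs, function(tr)
    nrow(tr$actions) == 100, logical(1))))
  expect_true(all(abs(trajs[[1]]$actions) <= arm$torque_limit + 1e-12))
  trajs2 <- rollout_policy(policy, arm, task, targets, deterministic = TRUE)
  expect_identical(trajs[[1]]$actions, trajs2[[1]]$actions)
})

test_that("policy checkpoints round-trip through JSON", {
  policy <- motorsynergy:::new_gaussian_policy(
    policy_network_spec(4, c(8, 8), 2), seed = 9)
  policy$obs_mean <- rnorm(4); policy$obs_var <- runif(4, 0.5, 2)
  path <- tempfile(fileext = ".json")
  save_policy(list(policy = policy), path)
  back <- load_policy(path)
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(motorsynergy:::mlp_forward(back$net, x)$out,
               motorsynergy:::mlp_forward(policy$net, x)$out,
               tolerance = 1e-12)
  expect_equal(back$obs_mean, policy$obs_mean)
  expect_equal(back$log_std, policy$log_std)
})
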