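make_toy_repertoire <- function(L, M = 2, Tn = 10, seed = 1, source = "toy") {
  set.seed(seed)
  W <- matrix(runif(2 * M * Tn * L), 2 * M * Tn, L)
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  structure(list(W = W, H = matrix(runif(L * 4), L, 4), M = M, T = Tn,
                 L = L, r_squared = NA,
                 provenance = list(source = source)),
            class = "synergy_repertoire")
}

test_that("combining repertoires concatenates columns and metadata", {
  r5 <- make_toy_repertoire(5, seed = 1, source = "horizontal")
  r4 <- make_toy_repertoire(4, seed = 2, source = "sagittal")
  comb <- combine_repertoires(list(r5, r4))
  expect_equal(comb$L, 9)
  expect_equal(ncol(comb$W), 9)
  expect_equal(nrow(comb$W), 2 * 2 * 10)
  expect_equal(comb$W[, 1:5], r5$W)
  expect_equal(comb$W[, 6:9], r4$W)
  expect_equal(comb$spans$horizontal, 1:5)
  expect_equal(comb$spans$sagittal, 6:9)
  # an empty member changes nothing
  r0 <- r4; r0$W <- r4$W[, integer(0), drop = FALSE]
  r0$H <- r4$H[integer(0), , drop = FALSE]; r0$L <- 0L
  comb2 <- combine_repertoires(list(r5, r0))
  expect_equal(comb2$W, r5$W, ignore_attr = TRUE)
  # the full-size case keeps 2MT = 1400 rows
  trials <- lapply(1:8, function(i) matrix(rnorm(700), 100, 7))
  rep7 <- extract_synergies(trials, 2, n_restarts = 2, max_iter = 200, seed = 5)
  expect_equal(nrow(combine_repertoires(list(rep7, rep7))$W), 1400)
  rbad <- make_toy_repertoire(2, M = 3)
  expect_error(combine_repertoires(list(r5, rbad)),
               class = "motorsynergy_invalid_argument")
})

test_that("candidates fold to nonnegative activities", {
  expect_equal(candidate_to_activity(c(-0.3, 0.2)), c(0.3, 0.2))
  x <- abs(rnorm(5))
  expect_identical(candidate_to_activity(x), x)
  expect_true(all(candidate_to_activity(rnorm(100)) >= 0))
})

test_that("decoding is linear and inverts the NMF reconstruction", {
  comb <- combine_repertoires(list(make_toy_repertoire(3),
                                   make_toy_repertoire(2, seed = 5)))
  expect_equal(decode_torques(comb, rep(0, 5)), matrix(0, 10, 2))
  # one-hot activity reproduces a scaled signed synergy waveform
  h <- rep(0, 5); h[2] <- 1.7
  w2 <- unstack_column(comb$W[, 2], 2, 10)
  expect_equal(decode_torques(comb, h), 1.7 * w2, tolerance = 1e-12)
  # linearity under nonnegative combination
  h1 <- runif(5); h2 <- runif(5)
  expect_equal(decode_torques(comb, 2 * h1 + 3 * h2),
               2 * decode_torques(comb, h1) + 3 * decode_torques(comb, h2),
               tolerance = 1e-12)
  expect_error(decode_torques(comb, rep(0.1, 4)),
               class = "motorsynergy_invalid_argument")
  # H-column round trip on a real extraction
  set.seed(2)
  trials <- lapply(1:6, function(i) matrix(rnorm(80), 20, 4))
  rep <- extract_synergies(trials, 3, n_restarts = 3, seed = 2)
  for (n in c(2, 6))
    expect_equal(decode_torques(rep, rep$H[, n]),
                 unstack_column((rep$W %*% rep$H)[, n], 4, 20),
                 tolerance = 1e-10)
})

test_that("CMA-ES recovers a planted optimum through the absolute-value fold", {
  # population for the L' = 9 combined case under natural log
  expect_equal(4 + floor(3 * log(9)), 10)
  set.seed(42)
  hstar <- runif(9, 0, 1)
  res <- cma_es(function(x) -sum((abs(x) - hstar)^2), n = 9,
                sigma = 1e-3, generations = 500, seed = 7)
  expect_lt(max(abs(abs(res$best_x) - hstar)), 1e-3)
  expect_true(all(diff(res$best_curve) >= 0))
})

test_that("activity optimization returns a well-formed result", {
  arm <- desk_arm(); task <- desk_task()
  trials <- surrogate_trials("horizontal")
  rep <- extract_synergies(trials, 4, n_restarts = 3, seed = 1,
                           source = "horizontal")
  tgt <- make_targets("horizontal", 8, task)$positions[1, ]
  res <- optimize_activities(rep, arm, task, tgt,
                             cma_config(generations = 40, seed = 9))
  expect_s3_class(res, "synergy_optimization")
  expect_equal(res$popsize, 4 + floor(3 * log(4)))
  expect_true(all(res$best_h >= 0))
  expect_true(all(diff(res$best_curve) >= 0))
  expect_equal(res$best_G, res$trajectory$G, tolerance = 1e-10)
  # reproducibility under the same seed
  res2 <- optimize_activities(rep, arm, task, tgt,
                              cma_config(generations = 40, seed = 9))
  expect_identical(res$best_h, res2$best_h)
})

test_that("the matching repertoire reaches its own learned targets", {
  arm <- desk_arm(); task <- desk_task()
  rep <- extract_synergies(surrogate_trials("horizontal"), 4,
                           n_restarts = 3, seed = 1, source = "horizontal")
  tgt <- make_targets("horizontal", 8, task)$positions[1, ]
  res <- optimize_activities(rep, arm, task, tgt,
                             cma_config(generations = 200, seed = 9))
  expect_lt(res$errors[1], 3)
})

test_that("target-set optimization summarizes errors per checkpoint", {
  arm <- desk_arm(); task <- desk_task()
  rep <- extract_synergies(surrogate_trials("horizontal"), 4,
                           n_restarts = 3, seed = 1, source = "horizontal")
  tg <- make_targets("horizontal", 2, task)
  res <- optimize_target_set(rep, arm, task, tg,
                             cma_config(generations = 30, seed = 50))
  expect_length(res$results, 2)
  expect_equal(res$summary$checkpoint, c("target", "finish"))
  expect_equal(res$summary$n, c(2, 2))
  expect_true(all(is.finite(res$summary$mean_error_cm)))
})

test_that("optimization results serialize to JSON plus trajectory CSV", {
  arm <- desk_arm(); task <- desk_task()
  rep <- extract_synergies(surrogate_trials("horizontal"), 3,
                           n_restarts = 2, seed = 4, source = "horizontal")
  tgt <- make_targets("horizontal", 8, task)$positions[3, ]
  res <- optimize_activities(rep, arm, task, tgt,
                             cma_config(generations = 10, seed = 2))
  base <- file.path(tempdir(), "opt-test")
  write_optimization(res, base)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(as.numeric(meta$best_h), res$best_h, tolerance = 1e-12)
  expect_equal(meta$generations, 10)
  back <- read_trajectory_csv(paste0(base, "_trajectory.csv"))
  expect_equal(back$G, res$trajectory$G, tolerance = 1e-10)
})
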