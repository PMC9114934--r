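test_that("positive/negative split is lossless with disjoint support", {
  a <- matrix(c(1.5, -2.0, 0, 0.3, -0.1, 2.2), 2, 3)
  sp <- split_pos_neg(a)
  expect_equal(sp$pos[1, 1], 1.5)
  expect_equal(sp$neg[2, 1], 2.0)
  expect_equal(sp$pos - sp$neg, a)
  expect_true(all(sp$pos * sp$neg == 0))
  set.seed(1)
  b <- matrix(rnorm(700), 100, 7)
  sp <- split_pos_neg(b)
  expect_identical(sp$pos - sp$neg, b)
})

test_that("the action matrix has the printed block layout", {
  # toy single-channel case: column order is a+(0), a+(1), a-(0), a-(1)
  X <- build_action_matrix(list(matrix(c(2, -3), 2, 1)))
  expect_equal(as.numeric(X$values), c(2, 0, 0, 3))
  # full-size stack: 2 * 7 * 100 rows by 8 trials
  trials <- lapply(1:8, function(i) matrix(rnorm(700), 100, 7))
  X <- build_action_matrix(trials)
  expect_equal(dim(X$values), c(1400, 8))
  expect_true(all(X$values >= 0))
  # round trip per column
  for (n in c(1, 5, 8))
    expect_equal(unstack_column(X$values[, n], 7, 100), trials[[n]])
  expect_error(build_action_matrix(list(matrix(0, 3, 2), matrix(0, 4, 2))),
               class = "motorsynergy_invalid_argument")
})

test_that("NMF multiplicative updates never increase the objective", {
  set.seed(9)
  X <- matrix(runif(300), 30, 10)
  fit <- nmf(X, 3, n_restarts = 2, max_iter = 400, seed = 2,
             track_objective = TRUE)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
})

test_that("extraction recovers planted nonnegative factors", {
  # 20 generator seeds; ground truth held by the generator only.  Planted
  # synergies are sparse (disjoint dominant supports), the identifiable
  # regime nonnegative factorizations are meant for.
  M <- 3; Tn <- 20; N <- 8; L <- 3
  for (s in 1:20) {
    set.seed(1000 + s)
    Wstar <- planted_factors(2 * M * Tn, L)
    Hstar <- matrix(runif(L * N, 0.2, 1), L, N)
    Hstar[, seq_len(L)] <- 0.05 + diag(L)  # anchor trials fix the factors
    trials <- lapply(seq_len(N), function(n)
      unstack_column(Wstar %*% Hstar[, n], M, Tn))
    rep <- extract_synergies(trials, L, n_restarts = 3, max_iter = 6000,
                             seed = s)
    expect_gte(rep$r_squared, 0.999)
    # match columns greedily by cosine similarity
    cs <- abs(crossprod(
      sweep(rep$W, 2, sqrt(colSums(rep$W^2)), "/"),
      sweep(Wstar, 2, sqrt(colSums(Wstar^2)), "/")))
    matched <- numeric(L)
    used <- integer(0)
    for (l in seq_len(L)) {
      j <- which.max(ifelse(seq_len(L) %in% used, -1, cs[, l]))
      matched[l] <- cs[j, l]
      used <- c(used, j)
    }
    expect_true(all(matched > 0.99))
  }
})

test_that("extraction validates inputs and orders synergies by activation", {
  trials <- lapply(1:5, function(i) matrix(rnorm(60), 20, 3))
  expect_error(extract_synergies(trials, 6),
               class = "motorsynergy_invalid_argument")
  rep <- extract_synergies(trials, 3, n_restarts = 3, seed = 1)
  expect_true(all(rep$W >= 0))
  expect_true(all(rep$H >= 0))
  expect_equal(dim(rep$W), c(2 * 3 * 20, 3))
  expect_equal(dim(rep$H), c(3, 5))
  expect_true(all(diff(rowSums(rep$H)) <= 1e-9))
})

test_that("R^2 matches hand-evaluated cases", {
  a <- list(matrix(c(1, 3), 2, 1))
  expect_equal(r_squared(a, a), 1)
  expect_equal(r_squared(a, list(matrix(c(2, 2), 2, 1))), 0)
  expect_equal(r_squared(a, list(matrix(c(1.5, 2.5), 2, 1))), 0.75)
  expect_error(r_squared(list(matrix(2, 2, 1) * 0 + 2), a[1]),
               class = "motorsynergy_invalid_argument")
  # per-trial values bracket the pooled value's information
  set.seed(4)
  orig <- lapply(1:4, function(i) matrix(rnorm(40), 10, 4))
  reco <- lapply(orig, function(m) m + 0.1 * matrix(rnorm(40), 10, 4))
  pt <- r_squared(orig, reco, per_trial = TRUE)
  expect_length(pt, 4)
})

test_that("activity fitting recovers representable coefficients", {
  set.seed(12)
  M <- 2; Tn <- 10; L <- 3
  W <- matrix(runif(2 * M * Tn * L), 2 * M * Tn, L)
  # give the synergies disjoint positive/negative support per channel-time
  # cell, as canonically encoded trials have, so stacking is invertible
  mask <- runif(M * Tn) < 0.5
  W[seq_len(M * Tn), ][mask, ] <- 0
  W[M * Tn + seq_len(M * Tn), ][!mask, ] <- 0
  h <- c(0.7, 0.2, 1.3)
  trial <- unstack_column(W %*% h, M, Tn)
  expect_equal(fit_activities(W, trial, M = M, T = Tn), h, tolerance = 1e-8)
  expect_equal(fit_activities(W, matrix(0, Tn, M), M = M, T = Tn), rep(0, L))
})

test_that("activity fitting agrees with an exhaustive grid oracle", {
  set.seed(5)
  M <- 1; Tn <- 6; L <- 2
  W <- matrix(runif(2 * M * Tn * L), 2 * M * Tn, L)
  trial <- matrix(rnorm(Tn * M), Tn, M)
  sp <- split_pos_neg(trial)
  x <- c(as.vector(t(sp$pos)), as.vector(t(sp$neg)))
  # quadratic objective evaluated over a nonnegative grid, step 1e-3
  G <- crossprod(W); b <- crossprod(W, x)
  grid <- seq(0, 2, by = 1e-3)
  obj <- function(h1, h2) G[1,1]*h1^2 + G[2,2]*h2^2 + 2*G[1,2]*h1*h2 -
    2*(b[1]*h1 + b[2]*h2)
  vals <- outer(grid, grid, obj)
  idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  h_grid <- c(grid[idx[1]], grid[idx[2]])
  h_nnls <- fit_activities(W, trial, M = M, T = Tn)
  expect_equal(h_nnls, h_grid, tolerance = 2e-3)
})

test_that("fitted activities reproduce the extraction activities on training trials", {
  set.seed(8)
  trials <- lapply(1:6, function(i) matrix(rnorm(80), 20, 4))
  rep <- extract_synergies(trials, 3, n_restarts = 3, seed = 3)
  # the extraction activities come from multiplicative updates, the fit
  # from exact NNLS; they agree up to the update convergence tolerance
  for (n in c(1, 4))
    expect_lt(max(abs(fit_activities(rep, trials[[n]]) - rep$H[, n])), 0.02)
})

test_that("the reconstruction curve is non-decreasing and saturates", {
  set.seed(10)
  trials <- lapply(1:6, function(i) matrix(rnorm(80), 20, 4))
  curve <- reconstruction_curve(trials, 1:6, n_restarts = 4, seed = 6)
  expect_equal(curve$L, 1:6)
  expect_true(all(diff(curve$r_squared) >= -1e-3))
  expect_gte(curve$r_squared[6], curve$r_squared[1])
})

test_that("repertoires round-trip through the CSV+JSON container", {
  set.seed(2)
  trials <- lapply(1:5, function(i) matrix(rnorm(30), 15, 2))
  rep <- extract_synergies(trials, 2, n_restarts = 2, seed = 2,
                           source = "unit-test", arm = "original")
  base <- file.path(tempdir(), "rep-test")
  write_repertoire(rep, base)
  back <- read_repertoire(base)
  expect_equal(back$W, rep$W, tolerance = 1e-12)
  expect_equal(back$H, rep$H, tolerance = 1e-12)
  expect_equal(back$L, rep$L)
  expect_equal(back$provenance$source, "unit-test")
})
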