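#' Covariance matrix adaptation evolution strategy
#'
#' Standard (mu/mu_w, lambda) CMA-ES with rank-one and rank-mu covariance
#' updates and cumulative step-size adaptation.  Maximizes `objective` over
#' an n-dimensional real vector.  The default population size is
#' `4 + floor(3 * log(n))` (natural logarithm).
#'
#' @param objective function of an n-vector returning a finite scalar or
#'   `NA` (treated as a failed, worst-ranked candidate).
#' @param n problem dimension.
#' @param sigma initial step size.
#' @param mean initial mean vector (default zero).
#' @param popsize candidates per generation.
#' @param generations generation budget (the only stopping rule).
#' @param seed integer seed for the Gaussian sampling.
#' @return list with `best_x`, `best_value`, `best_curve` (best-so-far
#'   objective per generation, non-decreasing), `n_failed` and the final
#'   distribution parameters.
#' @export
cma_es <- function(objective, n, sigma = 1e-3, mean = rep(0, n),
                   popsize = 4 + floor(3 * log(n)), generations = 500,
                   seed = NULL) {
  if (n < 1 || popsize < 4 || sigma <= 0)
    abort_invalid("need n >= 1, popsize >= 4 and sigma > 0")
  if (!is.null(seed)) set.seed(seed)
  lambda <- as.integer(popsize)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- as.numeric(mean)
  C <- diag(n)
  pc <- ps <- rep(0, n)
  eig <- list(vectors = diag(n), values = rep(1, n))
  best_x <- m
  best_value <- -Inf
  best_curve <- numeric(generations)
  n_failed <- 0L

  for (g in seq_len(generations)) {
    B <- eig$vectors
    D <- sqrt(pmax(eig$values, 1e-30))
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                      # columns ~ N(0, C)
    X <- m + sigma * Y
    vals <- apply(X, 2, function(x) {
      v <- objective(x)
      if (is.null(v) || is.na(v) || !is.finite(v)) NA_real_ else v
    })
    n_failed <- n_failed + sum(is.na(vals))
    ord <- order(vals, decreasing = TRUE, na.last = TRUE)
    if (!is.na(vals[ord[1]]) && vals[ord[1]] > best_value) {
      best_value <- vals[ord[1]]
      best_x <- X[, ord[1]]
    }
    best_curve[g] <- best_value

    sel <- ord[seq_len(mu)]
    yw <- as.numeric(Y[, sel, drop = FALSE] %*% w)
    m <- m + sigma * yw
    # step-size path uses C^{-1/2} y_w
    Cinv_half_yw <- B %*% ((1 / D) * crossprod(B, yw))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * Cinv_half_yw
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    rank_mu <- matrix(0, n, n)
    for (k in seq_len(mu))
      rank_mu <- rank_mu + w[k] * tcrossprod(Y[, sel[k]])
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * rank_mu
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    eig <- list(vectors = eig$vectors, values = eig$values)
  }
  list(best_x = best_x, best_value = best_value, best_curve = best_curve,
       n_failed = n_failed, mean = m, sigma = sigma, C = C)
}
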