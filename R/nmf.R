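#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative matrix `X` (rows x columns) into `W %*% H` with
#' `W >= 0` (rows x L) and `H >= 0` (L x columns), minimizing the squared
#' Frobenius reconstruction error with the classical multiplicative update
#' rules.  Several random nonnegative initializations are run and the best
#' final objective kept; given a seed the result is deterministic.
#'
#' @param X nonnegative numeric matrix.
#' @param L factorization rank.
#' @param n_restarts random initializations to try.
#' @param max_iter maximum update iterations per restart.
#' @param tol stop when the relative objective improvement over one
#'   iteration falls below this value.
#' @param seed integer seed for the initializations.
#' @param track_objective keep the per-iteration objective trace of the
#'   winning restart (used to verify update monotonicity).
#' @details The first restart is initialized deterministically by
#'   nonnegative double singular value decomposition (NNDSVD), which lands
#'   the updates in a good basin; the remaining restarts use random
#'   nonnegative initializations.
#' @return list with `W`, `H`, `objective` (final squared Frobenius error),
#'   `converged`, `iterations`, and `objective_trace` (if tracked).
#' @export
nmf <- function(X, L, n_restarts = 10, max_iter = 5000, tol = 1e-6,
                seed = NULL, track_objective = FALSE) {
  X <- as.matrix(X)
  if (any(X < 0) || anyNA(X)) abort_invalid("X must be nonnegative")
  if (L < 1 || L > min(dim(X)))
    abort_invalid("L must lie between 1 and min(dim(X))")
  if (!is.null(seed)) set.seed(seed)
  init0 <- nndsvd_init(X, L)
  best <- nmf_mu_run(X, init0$W, init0$H, max_iter, tol, track_objective)
  scale0 <- sqrt(mean(X) / L + 1e-12)
  for (r in seq_len(max(0, n_restarts - 1))) {
    W <- matrix(runif(nrow(X) * L, 0.1, 1), nrow(X), L) * scale0
    H <- matrix(runif(L * ncol(X), 0.1, 1), L, ncol(X)) * scale0
    fit <- nmf_mu_run(X, W, H, max_iter, tol, track_objective)
    if (fit$objective < best$objective) best <- fit
  }
  best
}

# nonnegative double SVD initialization (deterministic)
nndsvd_init <- function(X, L) {
  sv <- svd(X, nu = L, nv = L)
  W <- matrix(0, nrow(X), L)
  H <- matrix(0, L, ncol(X))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (L > 1) for (k in 2:L) {
    u <- sv$u[, k]; v <- sv$v[, k]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npp <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nnn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npp >= nnn) {
      W[, k] <- sqrt(sv$d[k] * npp) * up / max(sqrt(sum(up^2)), 1e-12)
      H[k, ] <- sqrt(sv$d[k] * npp) * vp / max(sqrt(sum(vp^2)), 1e-12)
    } else {
      W[, k] <- sqrt(sv$d[k] * nnn) * un / max(sqrt(sum(un^2)), 1e-12)
      H[k, ] <- sqrt(sv$d[k] * nnn) * vn / max(sqrt(sum(vn^2)), 1e-12)
    }
  }
  # strictly positive entries so multiplicative updates can move everywhere
  eps <- 1e-9 * max(X)
  W[W < eps] <- eps
  H[H < eps] <- eps
  list(W = W, H = H)
}

nmf_mu_run <- function(X, W, H, max_iter, tol, track_objective) {
  eps <- 1e-12
  normX2 <- sum(X^2)
  # ||X - WH||^2 = ||X||^2 - 2<WtX, H> + <WtW H, H>, avoiding the full
  # reconstruction each iteration
  objective <- function(WtX, WtW, H)
    normX2 - 2 * sum(WtX * H) + sum((WtW %*% H) * H)
  WtX <- crossprod(W, X)
  WtW <- crossprod(W)
  obj <- objective(WtX, WtW, H)
  trace <- if (track_objective) numeric(max_iter) else NULL
  converged <- FALSE
  it <- 0L
  # stop when the relative improvement over a 50-iteration window falls
  # below tol; multiplicative updates creep across long plateaus, so a
  # per-iteration check would quit far from the optimum
  window <- 50L
  obj_window <- obj
  while (it < max_iter) {
    it <- it + 1L
    H <- H * WtX / (WtW %*% H + eps)
    HHt <- tcrossprod(H)
    W <- W * (X %*% t(H)) / (W %*% HHt + eps)
    WtX <- crossprod(W, X)
    WtW <- crossprod(W)
    new_obj <- objective(WtX, WtW, H)
    if (track_objective) trace[it] <- new_obj
    obj <- new_obj
    if (it %% window == 0L) {
      if (obj_window - obj <= tol * max(obj_window, eps)) {
        converged <- TRUE
        break
      }
      obj_window <- obj
    }
  }
  list(W = W, H = H, objective = obj, converged = converged,
       iterations = it,
       objective_trace = if (track_objective) trace[seq_len(it)] else NULL)
}
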