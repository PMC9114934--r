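#' Split a signed action sequence into positive and negative parts
#'
#' `a = pos - neg` with `pos = max(a, 0)`, `neg = -min(a, 0)`; the two
#' parts have disjoint support, which makes signed torque sequences
#' representable by nonnegative factor models.
#'
#' @param actions T x M signed matrix (samples by channels).
#' @return list with nonnegative matrices `pos` and `neg` of the same shape.
#' @export
split_pos_neg <- function(actions) {
  actions <- as.matrix(actions)
  check_finite(actions, "actions")
  list(pos = pmax(actions, 0), neg = -pmin(actions, 0))
}

#' Assemble the action matrix for synergy extraction
#'
#' Each trial's T x M torque sequence is split into positive/negative parts
#' and stacked into one column: first the positive parts time-major (the
#' M-vector at sample 0, then sample 1, ...), then the negative parts in
#' the same order.  Columns are trials, giving a 2MT x N nonnegative
#' matrix.
#'
#' @param trials list of T x M signed action matrices (or `trajectory`
#'   objects, whose `actions` field is used).
#' @return object of class `action_matrix` with fields `values`
#'   (2MT x N), `M`, `T`.
#' @export
build_action_matrix <- function(trials) {
  trials <- lapply(trials, function(tr)
    if (inherits(tr, "trajectory")) tr$actions else as.matrix(tr))
  dims <- unique(lapply(trials, dim))
  if (length(dims) != 1)
    abort_invalid("all trials must share the same (T, M) shape")
  Tn <- dims[[1]][1]; M <- dims[[1]][2]
  X <- vapply(trials, function(a) {
    sp <- split_pos_neg(a)
    c(as.vector(t(sp$pos)), as.vector(t(sp$neg)))
  }, numeric(2 * M * Tn))
  structure(list(values = matrix(X, nrow = 2 * M * Tn), M = M, T = Tn),
            class = "action_matrix")
}

#' Recover the signed action sequence from a stacked column
#'
#' Inverse of the stacking in [build_action_matrix()]: the first MT entries
#' are the positive parts, the last MT the negative parts; the signed
#' sequence is their difference.
#'
#' @param x stacked column of length 2MT.
#' @param M number of channels.
#' @param T number of samples.
#' @return T x M signed matrix.
#' @export
unstack_column <- function(x, M, T) {
  if (length(x) != 2 * M * T) abort_invalid("column length must equal 2MT")
  pos <- matrix(x[seq_len(M * T)], ncol = M, byrow = TRUE)
  neg <- matrix(x[M * T + seq_len(M * T)], ncol = M, byrow = TRUE)
  pos - neg
}

#' Extract spatio-temporal synergies from an action matrix
#'
#' Factorizes the 2MT x N action matrix as `X ~ W H` by [nmf()].  Each
#' column of `W` is one spatio-temporal synergy spanning all channels and
#' the full time course; `H` holds the nonnegative activities of each
#' synergy in each trial.  Columns of `W` are normalized to unit Euclidean
#' norm (scale moved into `H`) and ordered by descending total activation.
#'
#' @param X an `action_matrix` (or a list of trials, which is assembled
#'   first).
#' @param L number of synergies, `1 <= L <= N`.
#' @param n_restarts,max_iter,tol,seed passed to [nmf()].
#' @param source provenance label (e.g. `"surrogate horizontal"`).
#' @param arm arm preset name for provenance.
#' @return object of class `synergy_repertoire` with fields `W`
#'   (2MT x L), `H` (L x N), `M`, `T`, `L`, `r_squared` (pooled, at
#'   extraction), `provenance`.
#' @export
extract_synergies <- function(X, L, n_restarts = 10, max_iter = 5000,
                              tol = 1e-6, seed = NULL, source = "unknown",
                              arm = NA_character_) {
  if (!inherits(X, "action_matrix")) X <- build_action_matrix(X)
  N <- ncol(X$values)
  if (L < 1 || L > N)
    abort_invalid("L must lie between 1 and the number of trials")
  fit <- nmf(X$values, L, n_restarts = n_restarts, max_iter = max_iter,
             tol = tol, seed = seed)
  W <- fit$W; H <- fit$H
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(W, 2, nrm, "/")
  H <- sweep(H, 1, nrm, "*")
  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  orig <- lapply(seq_len(N), function(n) unstack_column(X$values[, n], X$M, X$T))
  reco <- lapply(seq_len(N), function(n) unstack_column((W %*% H)[, n], X$M, X$T))
  structure(list(W = W, H = H, M = X$M, T = X$T, L = L,
                 r_squared = r_squared(orig, reco),
                 provenance = list(source = source, arm = arm, seed = seed,
                                   n_restarts = n_restarts,
                                   converged = fit$converged)),
            class = "synergy_repertoire")
}

#' @export
print.synergy_repertoire <- function(x, ...) {
  cat("<synergy_repertoire> L =", x$L, "synergies,", x$M, "channels x",
      x$T, "samples\n")
  cat("  source:", x$provenance$source, " R^2 =",
      format(x$r_squared, digits = 4), "\n")
  invisible(x)
}

#' Reconstruction quality of synergy-decoded actions
#'
#' Coefficient of determination pooled over trials:
#' \deqn{R^2 = 1 - \frac{\sum_n \sum_t \|a_n(t) - \hat a_n(t)\|^2}
#'   {\sum_n \sum_t \|a_n(t) - \bar a\|^2}}
#' where \eqn{\bar a} is the grand mean action over all samples and trials.
#'
#' @param original list of T x M signed action matrices (or trajectories).
#' @param reconstructed matching list of reconstructions.
#' @param per_trial if `TRUE`, return the vector of per-trial values
#'   (each trial scored against its own mean) instead of the pooled value.
#' @return scalar pooled R^2, or a vector if `per_trial`.
#' @export
r_squared <- function(original, reconstructed, per_trial = FALSE) {
  grab <- function(x) if (inherits(x, "trajectory")) x$actions else as.matrix(x)
  original <- lapply(original, grab)
  reconstructed <- lapply(reconstructed, grab)
  if (length(original) != length(reconstructed))
    abort_invalid("trial lists must have equal length")
  if (per_trial) {
    return(vapply(seq_along(original), function(n) {
      a <- original[[n]]; ah <- reconstructed[[n]]
      abar <- colMeans(a)
      den <- sum(sweep(a, 2, abar)^2)
      if (den == 0) abort_invalid("zero total sum of squares")
      1 - sum((a - ah)^2) / den
    }, numeric(1)))
  }
  allA <- do.call(rbind, original)
  allR <- do.call(rbind, reconstructed)
  if (!all(dim(allA) == dim(allR)))
    abort_invalid("original and reconstruction shapes must match")
  abar <- colMeans(allA)
  den <- sum(sweep(allA, 2, abar)^2)
  if (den == 0) abort_invalid("zero total sum of squares")
  1 - sum((allA - allR)^2) / den
}

#' Fit synergy activities for a trial with fixed synergies
#'
#' Nonnegative least-squares fit of a trial's stacked positive/negative
#' column against the synergy matrix `W` (Lawson-Hanson NNLS).
#'
#' @param repertoire a `synergy_repertoire` (or a nonnegative matrix `W`
#'   with attributes taken from `M`, `T`).
#' @param trial T x M signed action matrix (or a `trajectory`).
#' @param M,T channel/sample counts, required when a bare matrix is given.
#' @return nonnegative activity vector of length L.
#' @export
fit_activities <- function(repertoire, trial, M = NULL, T = NULL) {
  if (inherits(repertoire, "synergy_repertoire")) {
    W <- repertoire$W; M <- repertoire$M; T <- repertoire$T
  } else W <- as.matrix(repertoire)
  a <- if (inherits(trial, "trajectory")) trial$actions else as.matrix(trial)
  if (nrow(a) != T || ncol(a) != M)
    abort_invalid("trial shape must match the repertoire (T, M)")
  sp <- split_pos_neg(a)
  x <- c(as.vector(t(sp$pos)), as.vector(t(sp$neg)))
  if (all(x == 0)) return(numeric(ncol(W)))
  pracma::lsqnonneg(W, x)$x
}

#' Reconstruction-quality curve over the number of synergies
#'
#' Extracts synergies at each candidate `L` and scores the pooled
#' reconstruction R^2, the standard model-order diagnostic for choosing a
#' repertoire size.
#'
#' @param trials list of T x M action matrices or trajectories.
#' @param L_range integer vector of synergy counts.
#' @param ... passed to [extract_synergies()].
#' @return tibble with columns `L` and `r_squared`, classed
#'   `synergy_curve`.
#' @export
reconstruction_curve <- function(trials, L_range = NULL, ...) {
  X <- build_action_matrix(trials)
  if (is.null(L_range)) L_range <- seq_len(ncol(X$values))
  r2 <- vapply(L_range, function(L)
    extract_synergies(X, L, ...)$r_squared, numeric(1))
  out <- tibble::tibble(L = as.integer(L_range), r_squared = r2)
  class(out) <- c("synergy_curve", class(out))
  out
}

#' Write / read a synergy repertoire
#'
#' `W` and `H` go to CSV files (`<basename>_W.csv`, `<basename>_H.csv`)
#' with a JSON sidecar (`<basename>.json`) holding dimensions and
#' provenance; the reader validates nonnegativity and shape consistency.
#'
#' @param repertoire a `synergy_repertoire`.
#' @param basename file path prefix.
#' @return `write_repertoire()` returns `basename` invisibly;
#'   `read_repertoire()` returns a `synergy_repertoire`.
#' @export
write_repertoire <- function(repertoire, basename) {
  write.csv(repertoire$W, paste0(basename, "_W.csv"), row.names = FALSE)
  write.csv(repertoire$H, paste0(basename, "_H.csv"), row.names = FALSE)
  meta <- c(repertoire[c("M", "T", "L", "r_squared")],
            list(provenance = repertoire$provenance))
  jsonlite::write_json(meta, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(basename)
}

#' @rdname write_repertoire
#' @export
read_repertoire <- function(basename) {
  W <- as.matrix(read.csv(paste0(basename, "_W.csv")))
  H <- as.matrix(read.csv(paste0(basename, "_H.csv")))
  meta <- jsonlite::read_json(paste0(basename, ".json"),
                              simplifyVector = TRUE)
  dimnames(W) <- NULL; dimnames(H) <- NULL
  if (any(W < 0) || any(H < 0))
    abort_invalid("repertoire factors must be nonnegative")
  if (nrow(W) != 2 * meta$M * meta$T || ncol(W) != meta$L ||
      nrow(H) != meta$L)
    abort_invalid("repertoire shapes inconsistent with metadata")
  structure(list(W = W, H = H, M = meta$M, T = meta$T, L = meta$L,
                 r_squared = meta$r_squared, provenance = meta$provenance),
            class = "synergy_repertoire")
}
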