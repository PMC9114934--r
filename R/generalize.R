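#' Combine synergy repertoires by column concatenation
#'
#' Stacks the synergy matrices of several repertoires side by side,
#' `W' = [W_1 W_2 ...]`, giving `L' = sum(L_i)` synergies over the same
#' channel/sample grid.  Member order and column spans are recorded.
#'
#' @param repertoires list of `synergy_repertoire` objects (members with
#'   `L = 0` columns are allowed and contribute nothing).
#' @return object of class `combined_repertoire` with fields `W`
#'   (2MT x L'), `L`, `M`, `T`, `spans` (named list of column index
#'   ranges) and `members` (provenance).
#' @export
combine_repertoires <- function(repertoires) {
  if (inherits(repertoires, "synergy_repertoire"))
    repertoires <- list(repertoires)
  dims <- unique(lapply(repertoires, function(r) c(r$M, r$T)))
  if (length(dims) != 1)
    abort_invalid("all repertoires must share (M, T)")
  M <- dims[[1]][1]; Tn <- dims[[1]][2]
  W <- do.call(cbind, c(lapply(repertoires, function(r) r$W),
                        list(matrix(0, 2 * M * Tn, 0))))
  Ls <- vapply(repertoires, function(r) ncol(r$W), integer(1))
  ends <- cumsum(Ls)
  spans <- lapply(seq_along(Ls), function(i)
    if (Ls[i] == 0) integer(0) else (ends[i] - Ls[i] + 1):ends[i])
  names(spans) <- vapply(seq_along(repertoires), function(i)
    repertoires[[i]]$provenance$source %||% paste0("member", i), character(1))
  structure(list(W = W, L = sum(Ls), M = M, T = Tn, spans = spans,
                 members = lapply(repertoires, function(r) r$provenance)),
            class = "combined_repertoire")
}

#' Map an unconstrained candidate to nonnegative activities
#'
#' The evolution strategy searches all of R^L'; activity magnitudes must
#' be nonnegative, so candidates are folded by the elementwise absolute
#' value, `h' = |x|`.
#'
#' @param x numeric candidate vector.
#' @return nonnegative activity vector of the same length.
#' @export
candidate_to_activity <- function(x) {
  check_finite(x, "candidate")
  abs(x)
}

#' Decode synergy activities into a torque sequence
#'
#' Computes the stacked nonnegative reconstruction `W' h'`, splits it into
#' its positive and negative blocks and returns the signed T x M torque
#' sequence (their difference).
#'
#' @param repertoire a `combined_repertoire` or `synergy_repertoire`.
#' @param h nonnegative activity vector of length L'.
#' @return T x M matrix of joint torques.
#' @export
decode_torques <- function(repertoire, h) {
  if (length(h) != ncol(repertoire$W))
    abort_invalid("activity length must equal the number of synergies")
  unstack_column(as.numeric(repertoire$W %*% h), repertoire$M, repertoire$T)
}

#' CMA-ES configuration for activity optimization
#'
#' @param sigma initial step size of the search distribution.
#' @param generations generation budget.
#' @param popsize candidates per generation; `NULL` means
#'   `4 + floor(3 * log(L'))` at run time.
#' @param seed integer seed.
#' @return object of class `cma_config`.
#' @export
cma_config <- function(sigma = 1e-3, generations = 500, popsize = NULL,
                       seed = NULL) {
  if (sigma <= 0 || generations < 1) abort_invalid("invalid CMA configuration")
  structure(list(sigma = sigma, generations = generations,
                 popsize = popsize, seed = seed), class = "cma_config")
}

#' Optimize synergy activation magnitudes for one target
#'
#' Runs CMA-ES over activation candidates: each candidate is folded to
#' nonnegative activities, decoded into an open-loop torque sequence,
#' executed for one full episode, and scored by the accumulated task
#' reward G.  Diverging candidates are ranked worst and counted, not
#' fatal.
#'
#' @param repertoire a `combined_repertoire` (or single repertoire).
#' @param model an [arm_model()].
#' @param task a [task_spec()].
#' @param target target position (3-vector, m).
#' @param config a [cma_config()].
#' @return object of class `synergy_optimization`: `best_h`, `best_G`,
#'   `best_curve` (best-so-far G per generation), the decoded best
#'   `trajectory`, `errors` (cm) and the config echo.
#' @export
optimize_activities <- function(repertoire, model, task, target,
                                config = cma_config()) {
  if (inherits(repertoire, "synergy_repertoire"))
    repertoire <- combine_repertoires(list(repertoire))
  if (repertoire$L < 1) abort_invalid("repertoire has no synergies")
  if (repertoire$T != task$T)
    abort_invalid("repertoire sample count must match the task horizon")
  mc <- model_cpp(model)
  q0 <- initial_pose(model, task$q_initial)
  objective <- function(x) {
    h <- candidate_to_activity(x)
    open_loop_return(mc, task, q0, target, decode_torques(repertoire, h))
  }
  popsize <- config$popsize %||% (4 + floor(3 * log(repertoire$L)))
  fit <- cma_es(objective, n = repertoire$L, sigma = config$sigma,
                popsize = popsize, generations = config$generations,
                seed = config$seed)
  best_h <- candidate_to_activity(fit$best_x)
  traj <- run_open_loop(model, task, target,
                        decode_torques(repertoire, best_h))
  structure(list(best_h = best_h, best_G = fit$best_value,
                 best_curve = fit$best_curve, trajectory = traj,
                 errors = reaching_errors(traj, task, target),
                 n_failed = fit$n_failed, config = config,
                 popsize = popsize),
            class = "synergy_optimization")
}

#' @export
print.synergy_optimization <- function(x, ...) {
  cat("<synergy_optimization> L' =", length(x$best_h),
      " G =", format(x$best_G, digits = 5), "\n")
  cat("  errors (cm): target", format(x$errors[1], digits = 3),
      "/ finish", format(x$errors[2], digits = 3), "\n")
  invisible(x)
}

#' Optimize activities independently for every target of a set
#'
#' @inheritParams optimize_activities
#' @param targets a `target_set` from [make_targets()].
#' @param seeds optional integer vector of per-target CMA-ES seeds
#'   (recycled from `config$seed` + target index when omitted).
#' @return object of class `synergy_optimization_set`: list of per-target
#'   results plus a `summary` tibble of mean and SD reaching errors (cm)
#'   at both checkpoints.
#' @export
optimize_target_set <- function(repertoire, model, task, targets,
                                config = cma_config(), seeds = NULL) {
  n <- nrow(targets$positions)
  if (is.null(seeds))
    seeds <- if (is.null(config$seed)) rep(list(NULL), n)
             else as.list(config$seed + seq_len(n) - 1)
  results <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- seeds[[i]]
    tryCatch(
      optimize_activities(repertoire, model, task, targets$positions[i, ], cfg),
      motorsynergy_diverged = function(e) structure(
        list(failed = TRUE, message = conditionMessage(e)),
        class = "synergy_optimization_failure"))
  })
  ok <- !vapply(results, inherits, logical(1), "synergy_optimization_failure")
  errs <- t(vapply(results[ok], function(r) r$errors, numeric(2)))
  summary <- tibble::tibble(
    checkpoint = c("target", "finish"),
    mean_error_cm = c(mean(errs[, 1]), mean(errs[, 2])),
    sd_error_cm = c(sd(errs[, 1]), sd(errs[, 2])),
    n = sum(ok), n_failed = sum(!ok))
  structure(list(results = results, summary = summary,
                 plane_type = targets$plane_type),
            class = "synergy_optimization_set")
}

#' @export
print.synergy_optimization_set <- function(x, ...) {
  cat("<synergy_optimization_set>", x$plane_type, "targets\n")
  print(x$summary)
  invisible(x)
}

#' Write an optimization result to disk
#'
#' JSON summary (best activities, best G, curve, errors) plus the best
#' trajectory as tidy CSV next to it.
#'
#' @param result a `synergy_optimization`.
#' @param basename file path prefix.
#' @return `basename`, invisibly.
#' @export
write_optimization <- function(result, basename) {
  jsonlite::write_json(
    list(best_h = result$best_h, best_G = result$best_G,
         best_curve = result$best_curve, errors = as.list(result$errors),
         popsize = result$popsize, n_failed = result$n_failed,
         generations = result$config$generations,
         sigma = result$config$sigma, seed = result$config$seed),
    paste0(basename, ".json"), auto_unbox = TRUE, digits = NA)
  write_trajectory_csv(result$trajectory, paste0(basename, "_trajectory.csv"))
  invisible(basename)
}
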