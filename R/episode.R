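new_trajectory <- function(observations, actions, tip, tipvel, rewards,
                           target, metadata) {
  structure(list(observations = observations, actions = actions,
                 fingertip_positions = tip, fingertip_velocities = tipvel,
                 rewards = rewards, G = sum(rewards), target = target,
                 metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> T =", nrow(x$actions), "samples,",
      ncol(x$actions), "torque channels\n")
  cat("  source:", x$metadata$source %||% "?",
      " G =", format(x$G, digits = 5), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one closed-loop reaching episode
#'
#' Starts at the calibrated initial pose with zero velocity and iterates
#' observe-act-step-reward for `task$T` samples.
#'
#' @param model an [arm_model()].
#' @param task a [task_spec()].
#' @param target target position (3-vector, m).
#' @param controller function mapping an 18-vector observation to a
#'   7-vector of joint torques.
#' @param seed optional integer; set before the first controller call so
#'   stochastic controllers are reproducible.
#' @param source label stored in the trajectory metadata.
#' @return a `trajectory` object: per-sample observations (T x 18), actions
#'   (T x 7), fingertip positions/velocities (T x 3), rewards (length T)
#'   and their sum `G`.
#' @export
run_episode <- function(model, task, target, controller, seed = NULL,
                        source = "controller") {
  if (!is.null(seed)) set.seed(seed)
  Tn <- task$T
  q0 <- initial_pose(model, task$q_initial)
  state <- arm_state(q0)
  mc <- model_cpp(model)
  obs <- matrix(NA_real_, Tn, 18)
  act <- matrix(NA_real_, Tn, 7)
  tip <- matrix(NA_real_, Tn, 3)
  tipvel <- matrix(NA_real_, Tn, 3)
  rew <- numeric(Tn)
  for (t in seq_len(Tn)) {
    o <- task_observation(state, target, t - 1L, task)
    a <- as.numeric(controller(o))
    if (length(a) != 7 || anyNA(a) || any(!is.finite(a)))
      abort_invalid("controller must return a finite 7-vector torque")
    res <- arm_step_cpp(mc, state$q, state$qd, a, task$dt, logical(0))
    if (!res$ok)
      abort_diverged("simulation diverged during episode",
                     data = list(t = t, obs = obs[seq_len(t - 1), , drop = FALSE]))
    state <- arm_state(res$q, res$qd)
    p <- arm_fk_cpp(mc, state$q)
    v <- as.numeric(arm_jacobian_cpp(mc, state$q) %*% state$qd)
    obs[t, ] <- o; act[t, ] <- a; tip[t, ] <- p; tipvel[t, ] <- v
    rew[t] <- task_reward(task, p, v, a, target, t)
  }
  new_trajectory(obs, act, tip, tipvel, rew, target,
                 list(seed = seed, arm = model$name, source = source))
}

#' Run one open-loop episode from a torque sequence
#'
#' Applies a precomputed T x 7 torque sequence sample by sample (the
#' feed-forward execution mode used when replaying decoded synergy
#' combinations).
#'
#' @inheritParams run_episode
#' @param torques T x 7 matrix of joint torques (N m).
#' @return a `trajectory` object.
#' @export
run_open_loop <- function(model, task, target, torques, source = "synergy") {
  if (!is.matrix(torques) || nrow(torques) != task$T || ncol(torques) != 7)
    abort_invalid("torques must be a T x 7 matrix")
  check_finite(torques, "torques")
  q0 <- initial_pose(model, task$q_initial)
  res <- arm_rollout_cpp(model_cpp(model), q0, rep(0, 7), torques, task$dt)
  if (!res$ok)
    abort_diverged("simulation diverged during open-loop rollout",
                   data = res)
  rew <- episode_rewards(task, res$tip, res$tip_vel, torques, target)
  obs <- cbind(res$q_pre, res$qd_pre,
               matrix(target, task$T, 3, byrow = TRUE),
               (seq_len(task$T) - 1) * task$dt / task$t_finish)
  new_trajectory(obs, torques, res$tip, res$tip_vel, rew, target,
                 list(seed = NULL, arm = model$name, source = source))
}

# fast path for optimizers: accumulated reward only, NA if diverged
open_loop_return <- function(mc, task, q0, target, torques) {
  res <- arm_rollout_cpp(mc, q0, rep(0, 7), torques, task$dt)
  if (!res$ok) return(NA_real_)
  sum(episode_rewards(task, res$tip, res$tip_vel, torques, target))
}

#' Reaching errors of a trajectory
#'
#' Euclidean fingertip distance to the target at the `t_target` sample and
#' to the home position at the `t_finish` sample.
#'
#' @param traj a `trajectory`.
#' @param task a [task_spec()].
#' @param target target position (3-vector, m); defaults to the
#'   trajectory's own target.
#' @return named numeric vector `c(error_at_target, error_at_finish)` in
#'   centimetres.
#' @export
reaching_errors <- function(traj, task, target = traj$target) {
  it <- checkpoint_sample(task, task$t_target)
  ifin <- checkpoint_sample(task, task$t_finish)
  c(error_at_target =
      100 * sqrt(sum((target - traj$fingertip_positions[it, ])^2)),
    error_at_finish =
      100 * sqrt(sum((task$q_initial - traj$fingertip_positions[ifin, ])^2)))
}

#' Export / import a trajectory as tidy CSV
#'
#' One row per sample with joint angles, velocities, torques, fingertip
#' position/velocity and reward; episode-level metadata goes to a JSON
#' sidecar (`<path>.json`).
#'
#' @param traj a `trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a `trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  Tn <- nrow(traj$actions)
  df <- data.frame(sample = seq_len(Tn))
  add <- function(df, m, prefix) {
    m <- as.matrix(m)
    colnames(m) <- paste0(prefix, seq_len(ncol(m)))
    cbind(df, m)
  }
  df <- add(df, traj$observations[, 1:7, drop = FALSE], "angle")
  df <- add(df, traj$observations[, 8:14, drop = FALSE], "velocity")
  df <- add(df, traj$actions, "torque")
  df <- add(df, traj$fingertip_positions, "tip")
  df <- add(df, traj$fingertip_velocities, "tipvel")
  df$reward <- traj$rewards
  write.csv(df, path, row.names = FALSE)
  meta <- traj$metadata
  meta$target <- as.numeric(traj$target)
  meta$G <- traj$G
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  target <- as.numeric(meta$target)
  Tn <- nrow(df)
  grab <- function(prefix, k)
    as.matrix(df[paste0(prefix, seq_len(k))])
  q <- grab("angle", 7); qd <- grab("velocity", 7)
  obs <- cbind(q, qd, matrix(target, Tn, 3, byrow = TRUE),
               (seq_len(Tn) - 1) / Tn)
  traj <- new_trajectory(obs, grab("torque", 7), grab("tip", 3),
                         grab("tipvel", 3), df$reward, target,
                         meta[setdiff(names(meta), c("target", "G"))])
  traj
}
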