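#' Minimum-jerk profile
#'
#' The fifth-order minimum-jerk interpolation fraction
#' \eqn{s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5} with its first and second
#' derivatives with respect to normalized time \eqn{\tau \in [0, 1]}.
#' Boundary conditions: zero velocity and acceleration at both ends.
#'
#' @param tau normalized time, scalar or vector in `[0, 1]`.
#' @return list with `s`, `ds`, `dds` (each the same length as `tau`).
#' @export
min_jerk_profile <- function(tau) {
  check_finite(tau, "tau")
  if (any(tau < 0 | tau > 1)) abort_invalid("tau must lie in [0, 1]")
  list(s = 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
       ds = 30 * tau^2 - 60 * tau^3 + 30 * tau^4,
       dds = 60 * tau - 180 * tau^2 + 120 * tau^3)
}

#' Surrogate-expert configuration
#'
#' The surrogate expert is a training-free stand-in for a learned reaching
#' policy: it tracks an out-and-back minimum-jerk joint-space reference
#' (reversal with zero velocity at `t_target`) with inverse-dynamics
#' feed-forward torque plus PD correction.
#'
#' The PD correction acts in acceleration space (computed-torque control):
#' the commanded torque is the inverse dynamics of the measured state with
#' desired acceleration
#' `qdd_ref + 2 zeta wn (qd_ref - qd) + wn^2 (q_ref - q)`, so every joint
#' error behaves like a critically damped second-order system with natural
#' frequency `wn` regardless of its inertia and of inertial coupling
#' between joints.
#'
#' @param wn closed-loop natural frequency of the error dynamics (rad/s).
#' @param zeta damping ratio.
#' @return object of class `surrogate_config`.
#' @export
surrogate_config <- function(wn = 25, zeta = 1) {
  if (wn <= 0 || zeta <= 0) abort_invalid("wn and zeta must be positive")
  structure(list(wn = wn, zeta = zeta), class = "surrogate_config")
}

# joint-space reference at time t (seconds): out to pose_target over
# [0, t_target], back to pose0 over [t_target, t_finish]
surrogate_reference <- function(t, task, pose0, pose_target) {
  dq <- pose_target - pose0
  if (t <= task$t_target) {
    dur <- task$t_target
    p <- min_jerk_profile(min(t / dur, 1))
    list(q = pose0 + p$s * dq, qd = p$ds * dq / dur,
         qdd = p$dds * dq / dur^2)
  } else {
    dur <- task$t_finish - task$t_target
    p <- min_jerk_profile(min((t - task$t_target) / dur, 1))
    list(q = pose_target - p$s * dq, qd = -p$ds * dq / dur,
         qdd = -p$dds * dq / dur^2)
  }
}

#' Generate a surrogate-expert reaching trajectory
#'
#' Plans a minimum-jerk joint-space reference from the calibrated home pose
#' to the inverse-kinematics pose of the target and back, and tracks it
#' with computed-torque control (inverse dynamics with a PD-corrected
#' reference acceleration).  The resulting fingertip paths are
#' close to straight lines toward the targets, emulating the task-level
#' competence of trained policies without any learning.
#'
#' @param model an [arm_model()].
#' @param task a [task_spec()].
#' @param target target position (3-vector, m).
#' @param config a [surrogate_config()].
#' @return a `trajectory` with metadata source `"surrogate"`.
#' @export
generate_expert_trajectory <- function(model, task, target,
                                       config = surrogate_config()) {
  pose0 <- initial_pose(model, task$q_initial)
  pose_target <- initial_pose(model, target, seed_pose = pose0)
  mc <- model_cpp(model)
  kp <- config$wn^2
  kd <- 2 * config$zeta * config$wn
  controller <- function(obs) {
    t_now <- obs[18] * task$t_finish
    ref <- surrogate_reference(t_now, task, pose0, pose_target)
    qdd_des <- ref$qdd + kd * (ref$qd - obs[8:14]) + kp * (ref$q - obs[1:7])
    arm_rnea_cpp(mc, obs[1:7], obs[8:14], qdd_des, TRUE)
  }
  run_episode(model, task, target, controller, source = "surrogate")
}

#' Surrogate-expert trajectories for a whole target set
#'
#' @inheritParams generate_expert_trajectory
#' @param targets a `target_set` from [make_targets()].
#' @return list of `trajectory` objects, one per target.
#' @export
expert_trajectory_set <- function(model, task, targets,
                                  config = surrogate_config()) {
  lapply(seq_len(nrow(targets$positions)), function(i)
    generate_expert_trajectory(model, task, targets$positions[i, ], config))
}
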