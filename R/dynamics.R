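#' Advance the arm dynamics by one control interval
#'
#' Integrates the rigid-body dynamics over one control interval (default
#' 10 ms) of applied joint torque using semi-implicit Euler substeps.
#' Torques are clamped to the model's `torque_limit` before integration and
#' joint limits are enforced by clamping the angle and zeroing the
#' limit-directed velocity component.
#'
#' @param model an [arm_model()].
#' @param state an [arm_state()].
#' @param torque 7-vector of joint torques (N m).
#' @param dt control interval in seconds.
#' @param locked optional logical 7-vector; locked joints are held still
#'   (their constraint torques are resolved exactly).
#' @return the next [arm_state()].
#' @export
arm_step <- function(model, state, torque, dt = 0.01, locked = NULL) {
  check_finite(torque, "torque")
  if (length(torque) != 7) abort_invalid("torque must have length 7")
  lk <- if (is.null(locked)) logical(0) else as.logical(locked)
  res <- arm_step_cpp(model_cpp(model), state$q, state$qd,
                      as.numeric(torque), dt, lk)
  if (!res$ok) abort_diverged("simulation diverged during integration")
  arm_state(res$q, res$qd)
}

#' Inverse dynamics
#'
#' Joint torques that realize the accelerations `qdd` at configuration
#' (`q`, `qd`) under the model's full dynamics including gravity
#' (recursive Newton-Euler).
#'
#' @param model an [arm_model()].
#' @param q,qd,qdd 7-vectors: joint angles (rad), velocities (rad/s) and
#'   accelerations (rad/s^2).
#' @return 7-vector of joint torques (N m).
#' @export
inverse_dynamics <- function(model, q, qd, qdd) {
  check_finite(q, "q"); check_finite(qd, "qd"); check_finite(qdd, "qdd")
  arm_rnea_cpp(model_cpp(model), as.numeric(q), as.numeric(qd),
               as.numeric(qdd), TRUE)
}

#' Forward dynamics
#'
#' Joint accelerations produced by a torque at a given state (mass matrix
#' by composite rigid bodies, bias by recursive Newton-Euler).
#'
#' @inheritParams inverse_dynamics
#' @param torque 7-vector of joint torques (N m).
#' @return 7-vector of joint accelerations (rad/s^2).
#' @export
forward_dynamics <- function(model, q, qd, torque) {
  check_finite(q, "q"); check_finite(qd, "qd"); check_finite(torque, "torque")
  arm_fd_cpp(model_cpp(model), as.numeric(q), as.numeric(qd),
             as.numeric(torque))
}

#' Mechanical energy of the arm
#'
#' @inheritParams inverse_dynamics
#' @return list with `kinetic`, `potential` and `total` energy (J).
#' @export
arm_energy <- function(model, q, qd) {
  arm_energy_cpp(model_cpp(model), as.numeric(q), as.numeric(qd))
}
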