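#' Reciprocating reaching task specification
#'
#' The task: starting from the calibrated home pose, move the fingertip to a
#' target position by `t_target`, then return to the home position by
#' `t_finish`.  The per-sample reward is the negative of a position/velocity
#' penalty at the two checkpoints plus a torque penalty at every sample:
#' \deqn{r(t) = -(\|q_{chk} - q(t)\|^2 + k_1\|\dot q(t)\|^2 +
#'   k_2\|a(t)\|^2 \Delta t)}
#' at the checkpoints (with \eqn{q_{chk}} the target at `t_target` and the
#' home position at `t_finish`) and \eqn{r(t) = -k_2\|a(t)\|^2\Delta t}
#' otherwise.  Only the torque term carries \eqn{\Delta t}.
#'
#' @param q_initial home fingertip position (3-vector, m).
#' @param t_target checkpoint time for reaching the target (s).
#' @param t_finish episode end / return checkpoint (s).
#' @param dt control interval (s).
#' @param k1 velocity penalty coefficient.
#' @param k2 torque penalty coefficient.
#' @param target_radius radius l of the target circle (m).
#' @param upper_offset vertical offset z of the upper target plane (m).
#' @return object of class `task_spec`; `T` (samples per episode) is derived
#'   as `t_finish / dt`.
#' @export
task_spec <- function(q_initial = c(0.24, 0, 0.21), t_target = 0.5,
                      t_finish = 1.0, dt = 0.01, k1 = 0.002, k2 = 0.2,
                      target_radius = 0.15, upper_offset = 0.05) {
  check_finite(q_initial, "q_initial")
  if (length(q_initial) != 3) abort_invalid("q_initial must be a 3-vector")
  if (t_target >= t_finish) abort_invalid("t_target must be below t_finish")
  if (k1 <= 0 || k2 <= 0 || target_radius <= 0)
    abort_invalid("k1, k2 and target_radius must be positive")
  Tn <- t_finish / dt
  if (abs(Tn - round(Tn)) > 1e-9) abort_invalid("dt must divide t_finish")
  structure(list(q_initial = as.numeric(q_initial), t_target = t_target,
                 t_finish = t_finish, dt = dt, T = as.integer(round(Tn)),
                 k1 = k1, k2 = k2, target_radius = target_radius,
                 upper_offset = upper_offset),
            class = "task_spec")
}

# sample index of a checkpoint time (rewards are indexed 1..T, evaluated
# after each step)
checkpoint_sample <- function(task, time) as.integer(round(time / task$dt))

#' Generate reaching targets on a plane
#'
#' Target positions are placed on a circle of radius `l = target_radius`
#' around the home position, parameterized by direction angles
#' \eqn{\theta = 2\pi n / n_{dir}}:
#' * horizontal: `q_initial + (-l sin th, -l cos th, 0)`
#' * sagittal:   `q_initial + (-l sin th, 0, -l cos th)`
#' * frontal:    `q_initial + (0, -l sin th, -l cos th)`
#' * upper:      `q_initial + (-l sin th, -l cos th, z)`
#'
#' @param plane_type one of `"horizontal"`, `"sagittal"`, `"frontal"`,
#'   `"upper"`.
#' @param n_directions number of equally spaced directions (8 for training,
#'   32 for dense evaluation).
#' @param task a [task_spec()].
#' @return object of class `target_set` with fields `plane_type`,
#'   `direction_angles` (rad) and `positions` (n x 3 matrix, m).
#' @examples
#' make_targets("horizontal", 8, task_spec())
#' @export
make_targets <- function(plane_type, n_directions = 8, task = task_spec()) {
  if (!is.character(plane_type) ||
      !plane_type %in% c("horizontal", "sagittal", "frontal", "upper"))
    abort_invalid("unknown plane_type")
  if (n_directions < 1) abort_invalid("n_directions must be positive")
  th <- 2 * pi * (seq_len(n_directions) - 1) / n_directions
  l <- task$target_radius
  z <- task$upper_offset
  offs <- switch(plane_type,
    horizontal = cbind(-l * sin(th), -l * cos(th), 0),
    sagittal   = cbind(-l * sin(th), 0, -l * cos(th)),
    frontal    = cbind(0, -l * sin(th), -l * cos(th)),
    upper      = cbind(-l * sin(th), -l * cos(th), z))
  pos <- sweep(offs, 2, task$q_initial, "+")
  dimnames(pos) <- NULL
  structure(list(plane_type = plane_type, direction_angles = th,
                 positions = pos), class = "target_set")
}

#' Per-sample task reward
#'
#' @param task a [task_spec()].
#' @param fingertip_pos fingertip position after the step (3-vector, m).
#' @param fingertip_vel fingertip velocity after the step (3-vector, m/s).
#' @param action applied joint torque (7-vector, N m).
#' @param target target position for the episode (3-vector, m).
#' @param t sample index in `1..T` (the reward is evaluated after each
#'   step; `t_target` and `t_finish` correspond to samples 50 and 100 at
#'   the defaults).
#' @return scalar reward, always <= 0.
#' @export
task_reward <- function(task, fingertip_pos, fingertip_vel, action, target, t) {
  if (t < 1 || t > task$T) abort_invalid("sample index t out of range")
  r <- -task$k2 * sum(action^2) * task$dt
  if (t == checkpoint_sample(task, task$t_target))
    r <- r - sum((target - fingertip_pos)^2) - task$k1 * sum(fingertip_vel^2)
  if (t == checkpoint_sample(task, task$t_finish))
    r <- r - sum((task$q_initial - fingertip_pos)^2) -
         task$k1 * sum(fingertip_vel^2)
  r
}

# vectorized rewards for a whole episode; tip/tipvel are T x 3, actions T x 7
episode_rewards <- function(task, tip, tipvel, actions, target) {
  r <- -task$k2 * rowSums(actions^2) * task$dt
  it <- checkpoint_sample(task, task$t_target)
  ifin <- checkpoint_sample(task, task$t_finish)
  r[it] <- r[it] - sum((target - tip[it, ])^2) -
    task$k1 * sum(tipvel[it, ]^2)
  r[ifin] <- r[ifin] - sum((task$q_initial - tip[ifin, ])^2) -
    task$k1 * sum(tipvel[ifin, ]^2)
  r
}

#' Task observation vector
#'
#' The observation at sample index `t` (0-based, before the action is
#' applied) concatenates joint angles (7), joint velocities (7), the target
#' position (3) and normalized time `phi = t * dt / t_finish` (1), in that
#' frozen order.
#'
#' @param state an [arm_state()].
#' @param target target position (3-vector, m).
#' @param t 0-based sample index.
#' @param task a [task_spec()].
#' @return numeric vector of length 18.
#' @export
task_observation <- function(state, target, t, task) {
  c(state$q, state$qd, target, t * task$dt / task$t_finish)
}
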