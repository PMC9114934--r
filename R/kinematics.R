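#' Fingertip forward kinematics
#'
#' Maps joint angles to the fingertip reference point (the centre of the
#' hand segment's distal end) in the shoulder-centred base frame.
#'
#' @param model an [arm_model()].
#' @param joint_angles 7-vector, radians.
#' @return 3-vector, metres.
#' @examples
#' arm <- arm_model()
#' forward_kinematics(arm, rep(0, 7))
#' @export
forward_kinematics <- function(model, joint_angles) {
  check_finite(joint_angles, "joint_angles")
  if (length(joint_angles) != 7) abort_invalid("joint_angles must have length 7")
  arm_fk_cpp(model_cpp(model), as.numeric(joint_angles))
}

#' Fingertip velocity
#'
#' Jacobian-times-velocity of the fingertip reference point.
#'
#' @param model an [arm_model()].
#' @param state an [arm_state()].
#' @return 3-vector, m/s.
#' @export
fingertip_velocity <- function(model, state) {
  check_finite(state$q, "joint_angles"); check_finite(state$qd, "joint_velocities")
  J <- arm_jacobian_cpp(model_cpp(model), state$q)
  as.numeric(J %*% state$qd)
}

#' Fingertip Jacobian
#'
#' @inheritParams fingertip_velocity
#' @param joint_angles 7-vector, radians.
#' @return 3 x 7 matrix mapping joint velocities to fingertip velocity.
#' @export
arm_jacobian <- function(model, joint_angles) {
  check_finite(joint_angles, "joint_angles")
  arm_jacobian_cpp(model_cpp(model), as.numeric(joint_angles))
}

# one IK pose per (model geometry, target) pair, reused across episodes
.ik_cache <- new.env(parent = emptyenv())

#' Calibrated joint configuration for a fingertip position
#'
#' Deterministic damped-least-squares inverse kinematics from a fixed,
#' documented seed pose (shoulder flexed forward, elbow bent), clamped to
#' the joint limits at every iteration.  The solution is cached per
#' (model, target) pair so every episode of a study starts from the same
#' calibrated pose.
#'
#' @param model an [arm_model()].
#' @param q_target fingertip position to realize (3-vector, m); defaults to
#'   the model's home position [default_q_initial()].
#' @param seed_pose starting joint configuration for the solver.
#' @param tol fingertip residual tolerance (m).
#' @return 7-vector of joint angles whose fingertip matches `q_target`
#'   within `tol`.
#' @export
initial_pose <- function(model, q_target = default_q_initial(model),
                         seed_pose = c(-0.9, 0, 0, 0.6, 0, 0, 0),
                         tol = 1e-6) {
  check_finite(q_target, "q_target")
  key <- paste(c(model$lengths, model$lower, model$upper, q_target, seed_pose),
               collapse = ",")
  hit <- .ik_cache[[key]]
  if (!is.null(hit)) return(hit)
  q <- solve_ik(model, q_target, seed_pose, tol)
  assign(key, q, envir = .ik_cache)
  q
}

solve_ik <- function(model, q_target, seed_pose, tol = 1e-6,
                     max_iter = 500L, damping = 1e-2) {
  # damped least squares from the seed pose; if it jams against the joint
  # limits, retry from a fixed ladder of deterministically jittered seeds
  best <- NULL
  for (attempt in 0:11) {
    jitter <- if (attempt == 0) rep(0, 7)
              else 0.35 * attempt / 4 * sin(attempt * (7 * seq_len(7) + 1))
    res <- ik_dls(model, q_target, seed_pose + jitter, tol, max_iter, damping)
    if (res$residual < tol) return(res$q)
    if (is.null(best) || res$residual < best$residual) best <- res
  }
  abort_no_solution(sprintf(
    "inverse kinematics did not reach target (residual %.2e m)",
    best$residual))
}

ik_dls <- function(model, q_target, seed_pose, tol, max_iter, damping) {
  mc <- model_cpp(model)
  q <- pmin(pmax(as.numeric(seed_pose), model$lower), model$upper)
  mid <- (model$lower + model$upper) / 2
  for (it in seq_len(max_iter)) {
    tip <- arm_fk_cpp(mc, q)
    e <- q_target - tip
    if (sqrt(sum(e^2)) < tol) break
    J <- arm_jacobian_cpp(mc, q)
    A <- J %*% t(J) + diag(damping^2, 3)
    dq <- as.numeric(t(J) %*% solve(A, e))
    # gentle null-space pull toward mid-range keeps joints off their
    # stops; switched off close to the solution so it cannot bias it
    if (sqrt(sum(e^2)) > 1e-3) {
      dq <- dq + 0.05 * (mid - q) -
        0.05 * as.numeric(t(J) %*% solve(A, J %*% (mid - q)))
    }
    step <- min(1, 0.3 / max(sqrt(sum(dq^2)), 1e-12))
    q <- pmin(pmax(q + step * dq, model$lower), model$upper)
  }
  tip <- arm_fk_cpp(mc, q)
  list(q = q, residual = sqrt(sum((q_target - tip)^2)))
}
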