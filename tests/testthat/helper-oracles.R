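# Independent oracles, written against the documented kinematic convention
# (not against the package's C++ implementation).

# homogeneous-transform-chain forward kinematics
oracle_rot <- function(axis, th) {
  c <- cos(th); s <- sin(th)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE),
    y = matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE),
    z = matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

oracle_fk <- function(model, q) {
  d <- model$lengths
  axes <- c("y", "x", "z", "y", "x", "y", "z")
  offsets <- list(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, -d[1]),
                  c(0, 0, 0), c(d[2], 0, 0), c(0, 0, 0))
  R <- oracle_rot("y", model$shoulder_tilt)
  o <- c(0, 0, 0)
  for (i in 1:7) {
    o <- o + R %*% offsets[[i]]
    R <- R %*% oracle_rot(axes[i], q[i])
  }
  as.numeric(o + R %*% c(d[3], 0, 0))
}

# brute-force GAE: A_t = sum_k (gamma*lambda)^k * delta_{t+k}
oracle_gae <- function(rewards, values, gamma, lambda) {
  Tn <- length(rewards)
  delta <- sapply(seq_len(Tn), function(t)
    rewards[t] + gamma * values[t + 1] - values[t])
  adv <- sapply(seq_len(Tn), function(t) {
    s <- 0
    for (k in 0:(Tn - t)) s <- s + (gamma * lambda)^k * delta[t + k]
    s
  })
  list(advantages = adv, returns = adv + values[seq_len(Tn)])
}

# closed-form energy of the distal (forearm + hand) pendulum swinging
# about the elbow flexion axis, all other joints locked at zero
oracle_pendulum_energy <- function(model, theta4, omega4) {
  mf <- model$masses[2]; mh <- model$masses[3]
  d2 <- model$lengths[2]; d3 <- model$lengths[3]
  If <- model$inertias[2, 2]   # forearm inertia about its COM, y-axis
  Ih <- model$inertias[3, 2]
  df <- d2 / 2
  dh <- d2 + d3 / 2
  I <- If + mf * df^2 + Ih + mh * dh^2
  alpha <- theta4 + model$shoulder_tilt  # angle below horizontal of forearm
  g <- -model$gravity[3]
  # COM heights relative to the elbow
  z <- -sin(alpha) * c(df, dh)
  ke <- 0.5 * I * omega4^2
  pe <- g * (mf * z[1] + mh * z[2])
  ke + pe
}

# sparse nonnegative ground-truth synergies for recovery checks:
# disjoint dominant supports across synergies (the identifiable regime)
# and, per channel-time cell, either the positive or the negative block
# active — so any nonnegative combination stacks canonically and the
# planted factorization is exactly recoverable
planted_factors <- function(rows, L) {
  half <- rows / 2
  W <- matrix(runif(rows * L)^2, rows, L)
  sign_mask <- runif(half) < 0.5
  W[seq_len(half), ][sign_mask, ] <- 0
  W[half + seq_len(half), ][!sign_mask, ] <- 0
  block <- split(seq_len(rows), rep(seq_len(L), length.out = rows))
  for (l in seq_len(L)) {
    off <- setdiff(seq_len(rows), block[[l]])
    W[off, l] <- W[off, l] * (runif(length(off)) < 0.15)
  }
  W
}

# tiny helpers reused across tests
desk_arm <- function(...) arm_model("original", ...)
desk_task <- function() task_spec()

# cache surrogate trial sets across test files (expensive to regenerate)
.trial_cache <- new.env()
surrogate_trials <- function(plane, arm = desk_arm(), task = desk_task()) {
  key <- paste(plane, arm$name)
  if (is.null(.trial_cache[[key]]))
    .trial_cache[[key]] <- expert_trajectory_set(
      arm, task, make_targets(plane, 8, task))
  .trial_cache[[key]]
}
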