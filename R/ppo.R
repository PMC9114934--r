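#' Policy network architecture
#'
#' The reference reaching configuration: 18 observation inputs, two hidden
#' layers of 256 tanh units, 7 torque means, plus a state-independent
#' log-standard-deviation vector for the diagonal Gaussian action
#' distribution.
#'
#' @param input_size observation dimension.
#' @param hidden integer vector of hidden layer widths.
#' @param output_size action dimension.
#' @param init_log_std initial log standard deviation of the action noise.
#' @return object of class `policy_network_spec`.
#' @export
policy_network_spec <- function(input_size = 18, hidden = c(256, 256),
                                output_size = 7, init_log_std = 0) {
  structure(list(input_size = input_size, hidden = hidden,
                 output_size = output_size, init_log_std = init_log_std),
            class = "policy_network_spec")
}

#' PPO hyperparameter configuration
#'
#' Defaults are the reference reaching-study values: 3000 training epochs
#' of 10000 environment steps, discount 0.99, clip ratio 0.2, GAE lambda
#' 0.97, policy/critic learning rates 3e-4 / 1e-3, and 80 gradient steps
#' per epoch for each network.
#'
#' @param n_epochs,steps_per_epoch training budget.
#' @param gamma discount factor.
#' @param clip_ratio PPO clipping parameter.
#' @param gae_lambda generalized-advantage-estimation lambda.
#' @param policy_lr,critic_lr Adam learning rates.
#' @param grad_steps_per_epoch minibatch gradient steps per epoch for the
#'   policy and, separately, for the critic.
#' @param minibatch_size minibatch size for the gradient steps.
#' @param entropy_coef optional entropy bonus coefficient (0 = off).
#' @param seed integer seed.
#' @return object of class `ppo_config`.
#' @export
ppo_config <- function(n_epochs = 3000, steps_per_epoch = 10000,
                       gamma = 0.99, clip_ratio = 0.2, gae_lambda = 0.97,
                       policy_lr = 3e-4, critic_lr = 1e-3,
                       grad_steps_per_epoch = 80, minibatch_size = 64,
                       entropy_coef = 0, seed = NULL) {
  if (n_epochs < 1 || steps_per_epoch < 1 || grad_steps_per_epoch < 1)
    abort_invalid("counts must be positive")
  if (gamma <= 0 || gamma > 1 || gae_lambda < 0 || gae_lambda > 1)
    abort_invalid("gamma and gae_lambda must lie in (0, 1]")
  structure(list(n_epochs = n_epochs, steps_per_epoch = steps_per_epoch,
                 gamma = gamma, clip_ratio = clip_ratio,
                 gae_lambda = gae_lambda, policy_lr = policy_lr,
                 critic_lr = critic_lr,
                 grad_steps_per_epoch = grad_steps_per_epoch,
                 minibatch_size = minibatch_size,
                 entropy_coef = entropy_coef, seed = seed),
            class = "ppo_config")
}

#' Generalized advantage estimation
#'
#' GAE(gamma, lambda) advantages over one episode:
#' \eqn{A_t = \sum_{k \ge 0} (\gamma\lambda)^k \delta_{t+k}} with TD errors
#' \eqn{\delta_t = r_t + \gamma V_{t+1} - V_t}.  Return targets are
#' `advantages + values[1:T]`.
#'
#' @param rewards reward sequence of length T.
#' @param values value estimates of length T + 1 (the last entry is the
#'   bootstrap value of the state after the final step).
#' @param gamma discount factor.
#' @param lambda GAE mixing parameter; `lambda = 0` gives one-step TD
#'   errors, `lambda = 1` full Monte-Carlo advantages.
#' @return list with `advantages` and `returns`, each of length T.
#' @export
compute_gae <- function(rewards, values, gamma = 0.99, lambda = 0.97) {
  check_finite(rewards, "rewards"); check_finite(values, "values")
  Tn <- length(rewards)
  if (length(values) != Tn + 1)
    abort_invalid("values must be one longer than rewards")
  delta <- rewards + gamma * values[-1] - values[-(Tn + 1)]
  adv <- numeric(Tn)
  acc <- 0
  for (t in rev(seq_len(Tn))) {
    acc <- delta[t] + gamma * lambda * acc
    adv[t] <- acc
  }
  list(advantages = adv, returns = adv + values[seq_len(Tn)])
}

# diagonal-Gaussian log density for a batch (n x k actions vs n x k means)
gaussian_logp <- function(actions, means, log_std) {
  std <- exp(log_std)
  z <- sweep(actions - means, 2, std, "/")
  -0.5 * rowSums(z^2) - sum(log_std) - 0.5 * ncol(actions) * log(2 * pi)
}

clipped_surrogate <- function(ratio, adv, clip_ratio) {
  pmin(ratio * adv, pmax(pmin(ratio, 1 + clip_ratio), 1 - clip_ratio) * adv)
}

new_gaussian_policy <- function(spec, seed = NULL) {
  net <- mlp_new(c(spec$input_size, spec$hidden, spec$output_size), seed)
  list(net = net, log_std = rep(spec$init_log_std, spec$output_size),
       spec = spec,
       obs_mean = rep(0, spec$input_size),
       obs_var = rep(1, spec$input_size), obs_count = 1e-4)
}

normalize_obs <- function(policy, obs) {
  if (is.null(dim(obs)))
    (obs - policy$obs_mean) / sqrt(policy$obs_var + 1e-8)
  else
    sweep(sweep(obs, 2, policy$obs_mean), 2, sqrt(policy$obs_var + 1e-8), "/")
}

update_obs_stats <- function(policy, obs_batch) {
  n <- nrow(obs_batch)
  m <- colMeans(obs_batch)
  v <- apply(obs_batch, 2, function(x) mean((x - mean(x))^2))
  tot <- policy$obs_count + n
  dm <- m - policy$obs_mean
  policy$obs_var <- (policy$obs_count * policy$obs_var + n * v +
                       policy$obs_count * n / tot * dm^2) / tot
  policy$obs_mean <- policy$obs_mean + dm * n / tot
  policy$obs_count <- tot
  policy
}

policy_action <- function(policy, obs, deterministic = FALSE) {
  x <- matrix(normalize_obs(policy, obs), 1)
  mu <- mlp_forward(policy$net, x)$out[1, ]
  if (deterministic) return(mu)
  mu + rnorm(length(mu)) * exp(policy$log_std)
}

#' One PPO update from a collected batch
#'
#' Performs `grad_steps_per_epoch` clipped-surrogate ascent minibatch steps
#' on the policy (means and log standard deviations) and the same number
#' of squared-error descent steps on the critic, both with Adam.
#' Advantages are normalized over the batch before the policy steps.
#'
#' @param policy policy object (as built inside [train_policy()]).
#' @param critic critic network list (`net` plus Adam state).
#' @param batch list with `obs` (n x d, already normalized), `actions`
#'   (n x k), `advantages`, `old_logp`, `returns`.
#' @param config a [ppo_config()].
#' @return list with updated `policy`, `critic` and `diagnostics`
#'   (`policy_loss`, `critic_loss`, `approx_kl`).
#' @export
ppo_update <- function(policy, critic, batch, config) {
  n <- nrow(batch$obs)
  adv <- batch$advantages
  adv <- (adv - mean(adv)) / (sd(adv) + 1e-8)
  if (is.null(policy$adam)) policy$adam <- adam_new(policy$net)
  if (is.null(policy$adam_std)) policy$adam_std <- adam_vec_new(policy$log_std)
  if (is.null(critic$adam)) critic$adam <- adam_new(critic$net)
  mb <- min(config$minibatch_size, n)
  pi_loss <- v_loss <- kl <- NA_real_
  for (s in seq_len(config$grad_steps_per_epoch)) {
    idx <- sample.int(n, mb)
    X <- batch$obs[idx, , drop = FALSE]
    A <- batch$actions[idx, , drop = FALSE]
    advm <- adv[idx]
    oldlp <- batch$old_logp[idx]
    fw <- mlp_forward(policy$net, X)
    std <- exp(policy$log_std)
    zd <- sweep(A - fw$out, 2, std, "/")
    logp <- -0.5 * rowSums(zd^2) - sum(policy$log_std) -
      0.5 * ncol(A) * log(2 * pi)
    ratio <- exp(logp - oldlp)
    unclipped <- ratio * advm
    clipped <- pmax(pmin(ratio, 1 + config$clip_ratio),
                    1 - config$clip_ratio) * advm
    active <- unclipped <= clipped   # gradient flows only when unclipped
    loss <- -mean(pmin(unclipped, clipped))
    if (!is.finite(loss))
      stop(errorCondition("PPO policy loss diverged",
                          class = c("motorsynergy_training_diverged", "error")))
    # d(-objective)/d logp_i
    dlogp <- -(active * ratio * advm) / mb
    if (config$entropy_coef > 0) {
      # entropy depends only on log_std; handled in its gradient below
    }
    # logp gradients: d logp / d mu = z / std ; d logp / d log_std = z^2 - 1
    dMu <- sweep(zd, 2, std, "/") * dlogp
    g_std <- colSums((zd^2 - 1) * dlogp) -
      config$entropy_coef * rep(1, length(std)) / length(std) * 0
    if (config$entropy_coef > 0)
      g_std <- g_std - config$entropy_coef  # d entropy/d log_std = 1 each
    grads <- mlp_backward(policy$net, fw$acts, dMu)
    up <- adam_step(policy$net, grads, policy$adam, config$policy_lr)
    policy$net <- up$net; policy$adam <- up$state
    us <- adam_vec_step(policy$log_std, g_std, policy$adam_std,
                        config$policy_lr)
    policy$log_std <- us$p; policy$adam_std <- us$state
    pi_loss <- loss
    kl <- mean(oldlp - logp)
  }
  for (s in seq_len(config$grad_steps_per_epoch)) {
    idx <- sample.int(n, mb)
    X <- batch$obs[idx, , drop = FALSE]
    fw <- mlp_forward(critic$net, X)
    err <- fw$out[, 1] - batch$returns[idx]
    v_loss <- mean(err^2)
    if (!is.finite(v_loss))
      stop(errorCondition("critic loss diverged",
                          class = c("motorsynergy_training_diverged", "error")))
    grads <- mlp_backward(critic$net, fw$acts, matrix(2 * err / mb))
    up <- adam_step(critic$net, grads, critic$adam, config$critic_lr)
    critic$net <- up$net; critic$adam <- up$state
  }
  list(policy = policy, critic = critic,
       diagnostics = list(policy_loss = pi_loss, critic_loss = v_loss,
                          approx_kl = kl))
}

# generic fixed-horizon episodic PPO loop over an environment object
# (list with obs_dim, act_dim, act_limit, horizon, reset(), step(a))
ppo_train <- function(env, config, network = NULL, verbose = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  spec <- network %||% policy_network_spec(input_size = env$obs_dim,
                                           output_size = env$act_dim)
  policy <- new_gaussian_policy(spec)
  critic <- list(net = mlp_new(c(spec$input_size, spec$hidden, 1)))
  n_ep <- max(1L, floor(config$steps_per_epoch / env$horizon))
  log <- tibble::tibble(epoch = integer(), mean_G = numeric())
  for (ep in seq_len(config$n_epochs)) {
    obs_l <- list(); act_l <- list(); adv_l <- list(); ret_l <- list()
    lp_l <- list(); Gs <- numeric(n_ep)
    for (k in seq_len(n_ep)) {
      o <- env$reset()
      O <- matrix(NA_real_, env$horizon, env$obs_dim)
      A <- matrix(NA_real_, env$horizon, env$act_dim)
      R <- numeric(env$horizon)
      for (t in seq_len(env$horizon)) {
        a <- policy_action(policy, o)
        sr <- env$step(pmin(pmax(a, -env$act_limit), env$act_limit))
        O[t, ] <- o; A[t, ] <- a; R[t] <- sr$reward
        o <- sr$obs
      }
      Gs[k] <- sum(R)
      policy <- update_obs_stats(policy, O)
      On <- normalize_obs(policy, O)
      V <- mlp_forward(critic$net, On)$out[, 1]
      gae <- compute_gae(R, c(V, 0), config$gamma, config$gae_lambda)
      mu <- mlp_forward(policy$net, On)$out
      lp <- gaussian_logp(A, mu, policy$log_std)
      obs_l[[k]] <- On; act_l[[k]] <- A
      adv_l[[k]] <- gae$advantages; ret_l[[k]] <- gae$returns
      lp_l[[k]] <- lp
    }
    batch <- list(obs = do.call(rbind, obs_l), actions = do.call(rbind, act_l),
                  advantages = unlist(adv_l), returns = unlist(ret_l),
                  old_logp = unlist(lp_l))
    up <- ppo_update(policy, critic, batch, config)
    policy <- up$policy; critic <- up$critic
    log <- rbind(log, tibble::tibble(epoch = ep, mean_G = mean(Gs)))
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %d  mean G = %.4f", ep, mean(Gs)))
  }
  list(policy = policy, critic = critic, log = log)
}

# the reaching task as a PPO environment
reaching_env <- function(model, task, targets) {
  mc <- model_cpp(model)
  q0 <- initial_pose(model, task$q_initial)
  state <- NULL; target <- NULL; tstep <- 0L
  list(
    obs_dim = 18L, act_dim = 7L, act_limit = model$torque_limit,
    horizon = task$T,
    reset = function() {
      i <- sample.int(nrow(targets$positions), 1)
      target <<- targets$positions[i, ]
      state <<- arm_state(q0)
      tstep <<- 0L
      task_observation(state, target, 0L, task)
    },
    step = function(a) {
      res <- arm_step_cpp(mc, state$q, state$qd, as.numeric(a), task$dt,
                          logical(0))
      if (!res$ok) abort_diverged("simulation diverged during training")
      state <<- arm_state(res$q, res$qd)
      tstep <<- tstep + 1L
      p <- arm_fk_cpp(mc, state$q)
      v <- as.numeric(arm_jacobian_cpp(mc, state$q) %*% state$qd)
      list(obs = task_observation(state, target, tstep, task),
           reward = task_reward(task, p, v, a, target, tstep))
    })
}

#' One-dimensional point-mass reaching environment
#'
#' A unit point mass on a line driven by a force action, with the same
#' reciprocating reward structure as the arm task (reach `x_target` at
#' `t_target`, return to 0 by `t_finish`, torque penalty throughout).
#' Observation: `(x, v, x_target, phi)`.  Used as a fast test bed for the
#' learning loop.
#'
#' @param x_targets candidate target positions (one sampled per episode).
#' @param task a [task_spec()] supplying timing and penalty coefficients.
#' @param act_limit force clamp.
#' @return an environment object usable by the internal PPO loop.
#' @export
point_mass_env <- function(x_targets = c(-0.15, 0.15), task = task_spec(),
                           act_limit = 20) {
  x <- 0; v <- 0; xt <- x_targets[1]; tstep <- 0L
  it <- checkpoint_sample(task, task$t_target)
  ifin <- checkpoint_sample(task, task$t_finish)
  list(
    obs_dim = 4L, act_dim = 1L, act_limit = act_limit, horizon = task$T,
    reset = function() {
      x <<- 0; v <<- 0; tstep <<- 0L
      xt <<- x_targets[sample.int(length(x_targets), 1)]
      c(x, v, xt, 0)
    },
    step = function(a) {
      a <- as.numeric(a)[1]
      v <<- v + a * task$dt
      x <<- x + v * task$dt
      tstep <<- tstep + 1L
      r <- -task$k2 * a^2 * task$dt
      if (tstep == it) r <- r - (x - xt)^2 - task$k1 * v^2
      if (tstep == ifin) r <- r - x^2 - task$k1 * v^2
      list(obs = c(x, v, xt, tstep * task$dt / task$t_finish), reward = r)
    })
}

#' Train a reaching policy with PPO
#'
#' Collects `steps_per_epoch` environment steps per epoch (episodes of
#' `task$T` samples, one training target sampled uniformly per episode),
#' computes GAE advantages with a zero terminal bootstrap (fixed horizon),
#' and applies clipped-surrogate updates.  Observations are normalized by
#' running mean/variance statistics stored with the policy.
#'
#' @param model an [arm_model()].
#' @param task a [task_spec()].
#' @param targets a `target_set` of training targets.
#' @param config a [ppo_config()].
#' @param network a [policy_network_spec()].
#' @param verbose print progress every 10 epochs.
#' @return list with `policy`, `critic` and `log` (tibble of epoch and
#'   mean accumulated reward G).
#' @export
train_policy <- function(model, task, targets, config = ppo_config(),
                         network = policy_network_spec(), verbose = FALSE) {
  if (nrow(targets$positions) < 1) abort_invalid("targets must be nonempty")
  ppo_train(reaching_env(model, task, targets), config, network, verbose)
}

#' Roll out a trained policy over a target set
#'
#' One episode per target; in deterministic mode the mean action is used,
#' otherwise actions are sampled from the policy distribution.
#'
#' @param policy a trained policy (from [train_policy()]).
#' @param model an [arm_model()].
#' @param task a [task_spec()].
#' @param targets a `target_set`.
#' @param deterministic use the mean action.
#' @param seed seed for stochastic rollouts.
#' @return list of `trajectory` objects.
#' @export
rollout_policy <- function(policy, model, task, targets,
                           deterministic = TRUE, seed = NULL) {
  lim <- model$torque_limit
  lapply(seq_len(nrow(targets$positions)), function(i) {
    controller <- function(obs)
      pmin(pmax(policy_action(policy, obs, deterministic), -lim), lim)
    run_episode(model, task, targets$positions[i, ], controller,
                seed = if (is.null(seed)) NULL else seed + i,
                source = "policy")
  })
}

#' Save / load a policy checkpoint
#'
#' Architecture, flattened parameters, observation-normalization
#' statistics and the log-std vector in one JSON document.
#'
#' @param trained list with at least `policy` (as from [train_policy()]).
#' @param path JSON file path.
#' @return `save_policy()` returns `path` invisibly; `load_policy()`
#'   returns a policy usable by [rollout_policy()].
#' @export
save_policy <- function(trained, path) {
  policy <- if (!is.null(trained$policy)) trained$policy else trained
  out <- list(
    sizes = policy$net$sizes,
    W = lapply(policy$net$W, as.numeric),
    b = policy$net$b,
    log_std = policy$log_std,
    obs_mean = policy$obs_mean, obs_var = policy$obs_var,
    obs_count = policy$obs_count,
    spec = unclass(policy$spec))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.numeric(x$sizes)
  net <- list(W = lapply(seq_along(x$W), function(i)
    matrix(as.numeric(x$W[[i]]), sizes[i], sizes[i + 1])),
    b = lapply(x$b, as.numeric), sizes = sizes)
  spec <- x$spec
  spec$hidden <- as.numeric(spec$hidden)
  class(spec) <- "policy_network_spec"
  list(net = net, log_std = as.numeric(x$log_std), spec = spec,
       obs_mean = as.numeric(x$obs_mean), obs_var = as.numeric(x$obs_var),
       obs_count = x$obs_count)
}
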