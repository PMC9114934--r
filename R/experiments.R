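#' Scale profiles for the experiment drivers
#'
#' Three declared problem sizes: `"paper"` (full training budgets and 500
#' CMA-ES generations), `"desk"` (surrogate experts, 200 generations, all
#' 8 directions — minutes on one CPU) and `"smoke"` (2 directions, 50
#' generations — seconds, for structural checks).
#'
#' @param scale one of `"paper"`, `"desk"`, `"smoke"`.
#' @return list with `expert_source`, `cma_generations`, `n_directions`,
#'   `nmf_restarts`.
#' @export
scale_profile <- function(scale = c("desk", "paper", "smoke")) {
  scale <- match.arg(scale)
  switch(scale,
    paper = list(expert_source = "policy", cma_generations = 500,
                 n_directions = 8, nmf_restarts = 10),
    desk  = list(expert_source = "surrogate", cma_generations = 200,
                 n_directions = 8, nmf_restarts = 10),
    smoke = list(expert_source = "surrogate", cma_generations = 50,
                 n_directions = 2, nmf_restarts = 3))
}

trajectory_errors <- function(trajectories, task, targets) {
  errs <- t(vapply(seq_along(trajectories), function(i)
    reaching_errors(trajectories[[i]], task, targets$positions[i, ]),
    numeric(2)))
  tibble::tibble(direction = seq_along(trajectories) - 1L,
                 angle = targets$direction_angles[seq_along(trajectories)],
                 error_at_target_cm = errs[, 1],
                 error_at_finish_cm = errs[, 2])
}

#' Summarize per-target reaching errors into a report
#'
#' Means and sample standard deviations (n - 1 denominator) in
#' centimetres per condition, with a flag marking conditions whose mean
#' error at the target checkpoint is below 1 cm.
#'
#' @param errors tibble with columns `condition`, `error_at_target_cm`,
#'   `error_at_finish_cm` (one row per target).
#' @return tibble classed `experiment_report` with one row per condition.
#' @export
summarize_report <- function(errors) {
  conds <- unique(errors$condition)
  rows <- lapply(conds, function(cd) {
    e <- errors[errors$condition == cd, ]
    if (nrow(e) == 0) {
      warning("empty condition omitted: ", cd)
      return(NULL)
    }
    tibble::tibble(
      condition = cd, n = nrow(e),
      mean_target_cm = mean(e$error_at_target_cm),
      sd_target_cm = if (nrow(e) > 1) sd(e$error_at_target_cm) else 0,
      mean_finish_cm = mean(e$error_at_finish_cm),
      sd_finish_cm = if (nrow(e) > 1) sd(e$error_at_finish_cm) else 0,
      below_1cm = mean(e$error_at_target_cm) < 1)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("experiment_report", class(out))
  out
}

#' Benchmark experts across target planes
#'
#' Rolls out an expert (surrogate controller or trained policies) on its
#' learned target sets — including a dense 32-direction interpolation sweep
#' — and on the frontal/upper sets it was never trained for, and reports
#' mean reaching errors per condition.
#'
#' @param model an [arm_model()].
#' @param task a [task_spec()].
#' @param expert_source `"surrogate"`, or a named list
#'   `list(horizontal = policy, sagittal = policy)` of trained policies.
#' @param planes target planes to evaluate.
#' @param n_dense direction count for the dense interpolation sweep over
#'   the learned planes (0 to skip).
#' @return list with `errors` (per-target tibble) and `report`
#'   (condition summary).
#' @export
run_policy_benchmark <- function(model, task, expert_source = "surrogate",
                                 planes = c("horizontal", "sagittal",
                                            "frontal", "upper"),
                                 n_dense = 0) {
  expert_for <- function(plane, targets) {
    if (identical(expert_source, "surrogate"))
      return(expert_trajectory_set(model, task, targets))
    pol <- expert_source[[plane]]
    if (is.null(pol))
      stop("no policy for plane '", plane,
           "'; train one with train_policy() and pass it in expert_source")
    rollout_policy(pol, model, task, targets)
  }
  rows <- list()
  for (expert_plane in intersect(c("horizontal", "sagittal"), planes)) {
    for (eval_plane in planes) {
      targets <- make_targets(eval_plane, 8, task)
      trajs <- if (identical(expert_source, "surrogate") &&
                   eval_plane != expert_plane)
        NULL else expert_for(expert_plane, targets)
      # a surrogate tracks any reachable target; cross-plane rows only
      # make sense for plane-specific experts (policies)
      if (is.null(trajs)) next
      e <- trajectory_errors(trajs, task, targets)
      e$condition <- paste(eval_plane, "targets /", expert_plane, "expert")
      rows[[length(rows) + 1]] <- e
    }
    if (n_dense > 0) {
      targets <- make_targets(expert_plane, n_dense, task)
      trajs <- expert_for(expert_plane, targets)
      e <- trajectory_errors(trajs, task, targets)
      e$condition <- paste0(expert_plane, " targets (", n_dense,
                            " directions) / ", expert_plane, " expert")
      rows[[length(rows) + 1]] <- e
    }
  }
  errors <- do.call(rbind, rows)
  list(errors = errors, report = summarize_report(errors))
}

# extract a family of repertoires at several L from one trial set
repertoire_family <- function(trials, Ls, seed = 1, source = "expert",
                              arm = NA_character_, n_restarts = 10) {
  X <- build_action_matrix(trials)
  setNames(lapply(Ls, function(L)
    extract_synergies(X, L, seed = seed + L, source = source, arm = arm,
                      n_restarts = n_restarts)),
    as.character(Ls))
}

#' Mean-error map over repertoire size combinations
#'
#' For every combination `(L_h, L_s)` in the given ranges (except (0, 0)),
#' extracts repertoires of those sizes from the two expert trial sets,
#' combines them, optimizes activities for every target of the evaluation
#' set and records the mean error at the target checkpoint.
#'
#' @param trials_h,trials_s lists of expert trajectories for the two
#'   learned planes.
#' @param model,task,targets evaluation arm, task and target set.
#' @param L_h_range,L_s_range synergy counts to sweep (may include 0).
#' @param config a [cma_config()].
#' @param seed master seed fanned out to extraction and optimization.
#' @return tibble classed `error_map` with columns `L_h`, `L_s`,
#'   `mean_error_cm`, `sd_error_cm`, `mean_finish_cm`.
#' @export
run_error_map <- function(trials_h, trials_s, model, task, targets,
                          L_h_range = 0:8, L_s_range = 0:8,
                          config = cma_config(), seed = 1) {
  reps_h <- repertoire_family(trials_h, setdiff(L_h_range, 0), seed,
                              source = "horizontal", arm = model$name)
  reps_s <- repertoire_family(trials_s, setdiff(L_s_range, 0), seed + 100,
                              source = "sagittal", arm = model$name)
  empty <- function(other) {
    r <- other[[1]]
    r$W <- r$W[, integer(0), drop = FALSE]
    r$H <- r$H[integer(0), , drop = FALSE]
    r$L <- 0L
    r
  }
  rows <- list()
  for (Lh in L_h_range) for (Ls in L_s_range) {
    if (Lh == 0 && Ls == 0) next
    rh <- if (Lh == 0) empty(reps_s) else reps_h[[as.character(Lh)]]
    rs <- if (Ls == 0) empty(reps_h) else reps_s[[as.character(Ls)]]
    comb <- combine_repertoires(list(rh, rs))
    cfg <- config
    cfg$seed <- seed + 1000 + 100 * Lh + Ls
    res <- optimize_target_set(comb, model, task, targets, cfg)
    s <- res$summary
    rows[[length(rows) + 1]] <- tibble::tibble(
      L_h = Lh, L_s = Ls,
      mean_error_cm = s$mean_error_cm[s$checkpoint == "target"],
      sd_error_cm = s$sd_error_cm[s$checkpoint == "target"],
      mean_finish_cm = s$mean_error_cm[s$checkpoint == "finish"])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("error_map", class(out))
  out
}

#' Cross-arm synergy transfer study
#'
#' Extracts synergy repertoires from experts running on arms with
#' different link lengths and optimizes their activities on the evaluation
#' arm (by default the original model), probing whether repertoires
#' transfer across body geometries.
#'
#' @param source_presets arm presets whose experts provide the synergies.
#' @param eval_preset arm preset on which activities are optimized.
#' @param task_eval a [task_spec()] for the evaluation arm.
#' @param L_h,L_s repertoire sizes taken from the horizontal/sagittal
#'   experts.
#' @param plane evaluation target plane.
#' @param config a [cma_config()].
#' @param seed master seed.
#' @return tibble classed `experiment_report`: one condition per source
#'   preset.
#' @export
run_transfer_study <- function(source_presets = c("shorter", "longer"),
                               eval_preset = "original",
                               task_eval = task_spec(),
                               L_h = 4, L_s = 4, plane = "frontal",
                               config = cma_config(), seed = 1) {
  eval_model <- arm_model(eval_preset)
  targets <- make_targets(plane, 8, task_eval)
  rows <- list()
  for (preset in source_presets) {
    src_model <- arm_model(preset)
    src_task <- task_spec(q_initial = default_q_initial(src_model))
    comb <- combine_repertoires(list(
      extract_synergies(
        expert_trajectory_set(src_model, src_task,
                              make_targets("horizontal", 8, src_task)),
        L_h, seed = seed, source = "horizontal", arm = preset),
      extract_synergies(
        expert_trajectory_set(src_model, src_task,
                              make_targets("sagittal", 8, src_task)),
        L_s, seed = seed + 1, source = "sagittal", arm = preset)))
    cfg <- config
    cfg$seed <- seed + 10
    res <- optimize_target_set(comb, eval_model, task_eval, targets, cfg)
    errs <- t(vapply(res$results, function(r) r$errors, numeric(2)))
    rows[[length(rows) + 1]] <- tibble::tibble(
      condition = paste0(preset, " synergies on ", eval_preset, " arm"),
      error_at_target_cm = errs[, 1], error_at_finish_cm = errs[, 2])
  }
  summarize_report(do.call(rbind, rows))
}
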