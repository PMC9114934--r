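#' Plot a reconstruction-quality curve
#'
#' @param object a `synergy_curve` from [reconstruction_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.synergy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$L, y = .data$r_squared)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
    ggplot2::labs(x = "number of synergies L",
                  y = expression(R^2),
                  title = "Reconstruction performance of motor synergies") +
    ggplot2::ylim(0, 1)
}

#' Plot an error map over repertoire size combinations
#'
#' @param object an `error_map` from [run_error_map()].
#' @param ... unused.
#' @return a ggplot heat map of mean reaching error (cm).
#' @export
autoplot.error_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$L_h, y = .data$L_s,
                                       fill = .data$mean_error_cm)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$mean_error_cm)), size = 2.6) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = expression(L[h]), y = expression(L[s]),
                  fill = "error (cm)",
                  title = "Mean reaching error at the target checkpoint")
}

#' Plot the optimization progress of a synergy activation search
#'
#' @param object a `synergy_optimization` from [optimize_activities()].
#' @param ... unused.
#' @return a ggplot of the best-so-far accumulated reward per generation.
#' @export
autoplot.synergy_optimization <- function(object, ...) {
  df <- tibble::tibble(generation = seq_along(object$best_curve),
                       best_G = object$best_curve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$best_G)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "best accumulated reward G",
                  title = "CMA-ES activation optimization")
}

#' Plot fingertip trajectories of one or more episodes
#'
#' Projects fingertip paths onto the plane of the target set.
#'
#' @param trajectories list of `trajectory` objects.
#' @param targets the `target_set` the episodes aimed at.
#' @param task a [task_spec()].
#' @return a ggplot object.
#' @export
plot_trajectories <- function(trajectories, targets, task = task_spec()) {
  axes <- switch(targets$plane_type,
    horizontal = c(1, 2), sagittal = c(1, 3), frontal = c(2, 3),
    upper = c(1, 2))
  lab <- c("x (m)", "y (m)", "z (m)")
  paths <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    p <- trajectories[[i]]$fingertip_positions
    tibble::tibble(episode = i, u = p[, axes[1]], v = p[, axes[2]])
  }))
  tg <- tibble::tibble(u = targets$positions[, axes[1]],
                       v = targets$positions[, axes[2]])
  home <- task$q_initial[axes]
  ggplot2::ggplot(paths, ggplot2::aes(x = .data$u, y = .data$v,
                                      group = .data$episode)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::geom_point(data = tg, ggplot2::aes(x = .data$u, y = .data$v),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::annotate("point", x = home[1], y = home[2], size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = lab[axes[1]], y = lab[axes[2]],
                  title = "Fingertip trajectories")
}

#' Plot synergy waveforms
#'
#' Shows each synergy's positive and negative torque components per joint
#' channel over the episode time course.
#'
#' @param repertoire a `synergy_repertoire`.
#' @param synergies which synergy columns to show.
#' @return a ggplot object faceted by synergy and channel.
#' @export
plot_synergy_waveforms <- function(repertoire,
                                   synergies = seq_len(repertoire$L)) {
  M <- repertoire$M; Tn <- repertoire$T
  df <- do.call(rbind, lapply(synergies, function(l) {
    w <- repertoire$W[, l]
    pos <- matrix(w[seq_len(M * Tn)], ncol = M, byrow = TRUE)
    neg <- matrix(w[M * Tn + seq_len(M * Tn)], ncol = M, byrow = TRUE)
    do.call(rbind, lapply(seq_len(M), function(m)
      tibble::tibble(synergy = l, channel = m, sample = seq_len(Tn),
                     positive = pos[, m], negative = -neg[, m])))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$positive), colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$negative), colour = "purple") +
    ggplot2::facet_grid(channel ~ synergy,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample", y = "torque component (N m)",
                  title = "Spatio-temporal synergy waveforms")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
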