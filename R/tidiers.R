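# broom-style tidiers and ggplot2 autoplot methods for the fitted objects

#' @export
tidy.stage_model <- function(x, ...) {
  tibble::tibble(
    term = c("k_h_nat", "k_i_nat", "k_p_nat", "k_h_act", "k_i_act", "k_p_act",
             "dt", "lqr_dt", "heal_threshold"),
    estimate = c(as.numeric(x$natural), as.numeric(x$actuated),
                 x$dt, x$lqr_dt, x$heal_threshold)
  )
}

#' @export
glance.stage_model <- function(x, ...) {
  ht <- healing_time(simulate_stages(x, horizon = 60))
  tibble::tibble(
    healing_days = ht,
    lqr_solved = !is.null(x$K),
    dare_residual = attr(x, "dare_residual") %||% NA_real_,
    closed_loop_radius = attr(x, "closed_loop_radius") %||% NA_real_
  )
}

#' @export
tidy.deep_mapper <- function(x, ...) {
  tibble::tibble(
    term = c("k_h_nat", "k_i_nat", "k_p_nat", "k_h_act", "k_i_act", "k_p_act"),
    estimate = c(as.numeric(x$natural), as.numeric(x$actuated))
  )
}

#' @export
glance.deep_mapper <- function(x, ...) {
  lc <- x$loss_curve
  if (is.null(lc)) {
    return(tibble::tibble(trained = FALSE, epochs = 0L,
                          final_loss = NA_real_, loss_ratio = NA_real_))
  }
  tibble::tibble(
    trained = TRUE, epochs = nrow(lc),
    final_loss = tail(lc$total, 1),
    loss_ratio = tail(lc$total, 1) / lc$total[1]
  )
}

#' @export
tidy.a2c_agent <- function(x, ...) x$evals

#' @export
glance.a2c_agent <- function(x, ...) {
  tibble::tibble(
    reward = x$reward,
    episodes = x$config$episodes,
    seed = x$config$seed,
    final_eval_healing_days = if (nrow(x$evals)) tail(x$evals$eval_healing_days, 1) else NA_real_,
    mean_return_last50 = mean(tail(x$returns$return_mean, 50))
  )
}

#' Plot a stage trajectory
#'
#' Lines for the four stage fractions over time, with the healing threshold
#' shown as a dashed reference.
#'
#' @param object A `stage_trajectory` tibble from [simulate_stages()] or
#'   [simulate_env()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stage_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = c("H", "I", "P", "M"),
                              names_to = "stage", values_to = "fraction")
  long$stage <- factor(long$stage, levels = c("H", "I", "P", "M"))
  thr <- attr(object, "heal_threshold")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_days,
                                          y = .data$fraction,
                                          colour = .data$stage)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (days)", y = "stage fraction", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot an agent's learning curve
#'
#' Per-episode returns (thin) with the periodic greedy-evaluation healing
#' times (points, right-hand panel).
#'
#' @param object An `a2c_agent`.
#' @param ... Unused.
#' @return A ggplot object of the evaluation healing times over episodes.
#' @export
autoplot.a2c_agent <- function(object, ...) {
  ggplot2::ggplot(object$evals,
                  ggplot2::aes(x = .data$episode, y = .data$eval_healing_days)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "training episode", y = "greedy-policy healing time (days)",
                  title = sprintf("A2C learning curve (%s reward)", object$reward)) +
    ggplot2::theme_minimal()
}

#' Plot a closed-loop episode log
#'
#' Stage fractions (solid) with their LQR references (dashed), coloured by
#' stage; the switch from EF to fluoxetine is marked.
#'
#' @param object An `episode_log` from [run_closed_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.episode_log <- function(object, ...) {
  obs <- tidyr::pivot_longer(object[, c("time_days", "H", "I", "P", "M")],
                             cols = -"time_days",
                             names_to = "stage", values_to = "fraction")
  ref <- tidyr::pivot_longer(object[, c("time_days", "H_ref", "I_ref", "P_ref", "M_ref")],
                             cols = -"time_days",
                             names_to = "stage", values_to = "fraction")
  ref$stage <- sub("_ref$", "", ref$stage)
  obs$kind <- "observed"; ref$kind <- "reference"
  long <- rbind(obs, ref)
  long$stage <- factor(long$stage, levels = c("H", "I", "P", "M"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_days,
                                          y = .data$fraction,
                                          colour = .data$stage,
                                          linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(observed = "solid",
                                              reference = "dashed")) +
    ggplot2::labs(x = "time (days)", y = "stage fraction",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
  sw <- which(object$modality == "Flx")
  if (length(sw)) {
    p <- p + ggplot2::geom_vline(xintercept = object$time_days[sw[1]],
                                 linetype = "dotted", colour = "grey30")
  }
  p
}

#' Display a wound image
#'
#' @param object A `wound_image`.
#' @param ... Unused.
#' @return A ggplot object rendering the raster.
#' @export
autoplot.wound_image <- function(object, ...) {
  px <- object$pixels
  d <- dim(px)
  df <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]))
  df$fill <- grDevices::rgb(px[, , 1][as.matrix(df[, c("y", "x")])],
                            px[, , 2][as.matrix(df[, c("y", "x")])],
                            px[, , 3][as.matrix(df[, c("y", "x")])])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
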