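# ggplot2 visualizations of the result types.

#' Plot a heading-bias table
#'
#' Mean realigned heading bias (degrees) as a function of visual speed,
#' one line per visual-motion condition, averaged over observers with
#' standard-error bars.
#'
#' @param object A `bias_table` from [heading_bias()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bias_table
#' @export
autoplot.bias_table <- function(object, ...) {
  d <- as_tibble(object) %>%
    group_by(.data$condition, .data$visual_speed) %>%
    summarise(sem = sd(.data$mean_bias) / sqrt(dplyr::n()),
              mean_bias = mean(.data$mean_bias), .groups = "drop")
  d$sem[is.na(d$sem)] <- 0
  ggplot2::ggplot(d, ggplot2::aes(.data$visual_speed, .data$mean_bias,
                                  colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_bias - .data$sem,
                                          ymax = .data$mean_bias + .data$sem)) +
    ggplot2::labs(x = "Visual speed (deg/s)", y = "Heading bias (deg)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Plot observed vs predicted condition means of a fitted model
#'
#' @param object A `heading_fit`.
#' @param data The dataset the model was fitted to.
#' @param n_sim Simulated estimates per condition for the prediction.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot heading_fit
#' @export
autoplot.heading_fit <- function(object, data, n_sim = 2000, seed = NULL, ...) {
  ct <- condition_table(data, object$reference_speed)
  z <- draw_z(nrow(ct$cond), n_sim, seed)
  sim <- simulate_condition_estimates(object$map_params, ct$cond, n_sim, z,
                                      object$reference_speed)
  d <- ct$cond %>%
    mutate(predicted = rowMeans(matrix(
             lateral_to_heading(sim, object$reference_speed), nrow = nrow(sim))),
           observed = as.numeric(tapply(
             lateral_to_heading(ct$resp, object$reference_speed),
             ct$resp_cond, mean)))
  ggplot2::ggplot(d, ggplot2::aes(.data$observed, .data$predicted,
                                  colour = .data$condition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Observed mean reported heading (deg)",
                  y = "Predicted mean reported heading (deg)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Dumbbell plot of adaptive weights over a cohort
#'
#' Shows each observer's fitted `alpha_1` (environment truly constant)
#' and `alpha_2` (environment changed); a systematic `alpha_1 > alpha_2`
#' gap is the adaptive-weight signature of causal inference.
#'
#' @param fits A list of `weight_fit` objects from
#'   [variable_weight_fit()].
#' @return A ggplot object.
#' @export
plot_weights <- function(fits) {
  d <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble(observer = f$observer, alpha_1 = f$alpha_1, alpha_2 = f$alpha_2)
  })) %>%
    tidyr::pivot_longer(c("alpha_1", "alpha_2"), names_to = "weight",
                        values_to = "value")
  avg <- d %>% group_by(.data$weight) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$weight, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$observer),
                       colour = "grey70") +
    ggplot2::geom_point(colour = "grey50") +
    ggplot2::geom_line(data = avg, ggplot2::aes(group = 1), linewidth = 1.2) +
    ggplot2::geom_point(data = avg, size = 3) +
    ggplot2::labs(x = NULL, y = "Weight on constant-structure estimate") +
    ggplot2::theme_minimal()
}

#' Plot a velocity profile
#'
#' @param object A `velocity_profile` from [raised_cosine_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot velocity_profile
#' @export
autoplot.velocity_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time, .data$velocity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Velocity (deg/s)") +
    ggplot2::theme_minimal()
}
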