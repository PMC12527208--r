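#' Heading-bias table with left/right realignment
#'
#' Per-trial heading bias is the reported minus the true heading angle
#' (degrees). Exploiting the left/right symmetry of the design, trials
#' with leftward (negative) visual motion have their bias sign flipped so
#' that positive bias always points in the direction of the visual
#' motion; 0 deg/s trials enter unflipped. Biases are then aggregated per
#' observer, condition and unsigned visual speed.
#'
#' @param data Per-trial dataset with `observer`, `condition`,
#'   `visual_velocity` (signed), `heading_angle`, `reported_heading`.
#' @return A tibble of class `bias_table`: `observer`, `condition`,
#'   `visual_speed`, `mean_bias` (deg), `sem`, `n`.
#' @examples
#' d <- build_design(reps = 1, seed = 1)
#' p <- observer_params("cci", sigma_self = 3, sigma_env = 3,
#'                      sigma_vest = 1.5, w_vis = 0.15, p_constant = 0.5)
#' heading_bias(simulate_observer(p, d, seed = 2))
#' @export
heading_bias <- function(data) {
  need <- c("condition", "visual_velocity", "heading_angle", "reported_heading")
  if (!all(need %in% names(data))) {
    abort(paste("dataset needs columns:", paste(need, collapse = ", ")))
  }
  d <- as_tibble(data)
  if (!"observer" %in% names(d)) d$observer <- "obs01"
  out <- d %>%
    mutate(
      bias = .data$reported_heading - .data$heading_angle,
      bias = ifelse(.data$visual_velocity < 0, -.data$bias, .data$bias),
      visual_speed = abs(.data$visual_velocity)
    ) %>%
    group_by(.data$observer, .data$condition, .data$visual_speed) %>%
    summarise(
      mean_bias = mean(.data$bias),
      sem = sd(.data$bias) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("bias_table", class(out))
  out
}

#' Regression decomposition of heading estimates into cue predictions
#'
#' Per observer, ordinary least squares of the reported estimate
#' (lateral-velocity scale) on the three candidate information sources:
#' the vestibular prediction `s_self`, the momentary-vision prediction
#' `s_self - s_env`, and the contextual-vision prediction
#' `s_self - s_env + s_env0`, plus an intercept. Signed predictors are
#' used directly (no mirroring). Group-level one-sample t statistics over
#' observers are returned for each coefficient.
#'
#' @param data Per-trial dataset; latent states are derived from the
#'   design columns if absent.
#' @param reference_speed Heading-to-lateral mapping speed (deg/s).
#' @return A list of class `heading_regression` with `coefficients`
#'   (tibble: observer, term, estimate, std.error) and `group_tests`
#'   (tibble: term, mean, t, df, p.value).
#' @export
regression_decomposition <- function(data, reference_speed = 8.5) {
  d <- as_tibble(data)
  if (!"observer" %in% names(d)) d$observer <- "obs01"
  if (!all(c("s_self", "s_env", "s_env0") %in% names(d))) {
    d <- d %>% mutate(
      s_self = heading_to_lateral(.data$heading_angle, reference_speed),
      s_env = .data$visual_velocity,
      s_env0 = dplyr::case_when(
        .data$condition == "Acceleration" ~ 0,
        .data$condition == "Constant" ~ .data$s_env,
        .data$condition == "Deceleration" ~ 2 * .data$s_env
      )
    )
  }
  # simulated datasets carry the unclamped lateral estimate; real data
  # only has the reported angle, which maps back through the arcsine
  if (!"estimate_lateral" %in% names(d)) {
    d$estimate_lateral <- heading_to_lateral(d$reported_heading,
                                             reference_speed)
  }
  d <- d %>% mutate(
    estimate_lat = .data$estimate_lateral,
    pred_vest = .data$s_self,
    pred_mom = .data$s_self - .data$s_env,
    pred_cont = .data$s_self - .data$s_env + .data$s_env0
  )
  coefs <- d %>%
    tidyr::nest(obs = -"observer") %>%
    mutate(fit = purrr::map(.data$obs, function(dd) {
      m <- lm(estimate_lat ~ pred_vest + pred_mom + pred_cont, data = dd)
      if (anyNA(coef(m))) {
        abort(paste("rank-deficient cue design: the three cue predictors",
                    "are collinear (e.g. a single-condition dataset);",
                    "coefficients are not identifiable"))
      }
      sm <- summary(m)$coefficients
      tibble(term = rownames(sm), estimate = unname(sm[, 1]),
             std.error = unname(sm[, 2]))
    })) %>%
    select("observer", "fit") %>%
    tidyr::unnest("fit")
  group <- coefs %>%
    group_by(.data$term) %>%
    summarise(mean = mean(.data$estimate), sd = sd(.data$estimate),
              n = dplyr::n(), .groups = "drop") %>%
    mutate(
      t = ifelse(.data$n > 1 & .data$sd > 0,
                 .data$mean / (.data$sd / sqrt(.data$n)), NA_real_),
      df = .data$n - 1,
      p.value = 2 * stats::pt(-abs(.data$t), .data$df)
    ) %>%
    select("term", "mean", "t", "df", "p.value")
  structure(list(coefficients = coefs, group_tests = group),
            class = "heading_regression")
}

#' @export
print.heading_regression <- function(x, ...) {
  cat("<heading_regression> per-observer OLS on cue predictions\n")
  print(x$group_tests)
  invisible(x)
}

#' Adaptive-weight (variable-weight) diagnostic fit
#'
#' Replaces the observer's structure posterior with one of two free
#' weights on the constant-structure estimate, selected by the *true*
#' state of the world: `alpha_1` on trials where environmental motion
#' really was constant (`s_env0 == s_env`, which includes all 0 deg/s
#' trials) and `alpha_2` where it changed. The six parameters
#' `{sigma_self, sigma_env, sigma_vest, w_vis, alpha_1, alpha_2}` are
#' fitted with the same Monte-Carlo/KDE machinery as [fit_model()].
#' This is a diagnostic, not an observer model: `alpha_1 > alpha_2` is
#' the signature of causal inference (adaptive weighting), while a
#' linear cue combiner yields `alpha_1` close to `alpha_2`.
#'
#' @inheritParams fit_model
#' @return A `heading_fit` of model `"variable_weight"`, additionally of
#'   class `weight_fit`, with `alpha_1`, `alpha_2` exposed at the top
#'   level.
#' @export
variable_weight_fit <- function(data, config = fit_config(),
                                reference_speed = 8.5) {
  fit <- fit_model(data, "variable_weight", config = config,
                   reference_speed = reference_speed)
  fit$alpha_1 <- fit$map_params$alpha_1
  fit$alpha_2 <- fit$map_params$alpha_2
  class(fit) <- c("weight_fit", class(fit))
  fit
}
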