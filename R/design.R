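#' Build the factorial trial design
#'
#' Full crossing of visual velocities, heading directions, visual-motion
#' conditions and repetitions, with trial order randomly interleaved.
#' Latent states are filled per condition: in `Acceleration` the
#' environment is still before self-motion (`s_env0 = 0`), in `Constant`
#' it moves the same way throughout (`s_env0 = s_env`), and in
#' `Deceleration` it starts at twice the during-motion velocity
#' (`s_env0 = 2 s_env`). The during-motion environmental motion always
#' equals the nominal visual velocity. Defaults reproduce the study
#' design: 5 velocities x 10 headings x 3 conditions x 5 reps = 750
#' trials over 150 distinct stimulus conditions.
#'
#' @param velocities Signed visual velocities during self-motion (deg/s).
#' @param headings Signed heading directions (degrees from vertical).
#' @param conditions Subset of `c("Acceleration", "Constant",
#'   "Deceleration")`.
#' @param reps Repetitions per distinct stimulus condition.
#' @param seed Integer seed for the trial-order shuffle.
#' @param reference_speed Peak self-motion speed used to map heading angle
#'   to its lateral component (deg/s).
#' @return A tibble of class `heading_design`, one row per trial, with
#'   columns `trial`, `condition`, `visual_velocity`, `heading_angle`,
#'   `rep`, and latent states `s_self`, `s_env`, `s_env0`.
#' @examples
#' d <- build_design(seed = 1)
#' nrow(d)                                   # 750
#' dplyr::n_distinct(d[c("condition", "visual_velocity", "heading_angle")])
#' @export
build_design <- function(velocities = c(-10, -5, 0, 5, 10),
                         headings = c(-45, -35, -25, -15, -5, 5, 15, 25, 35, 45),
                         conditions = c("Acceleration", "Constant", "Deceleration"),
                         reps = 5, seed = NULL, reference_speed = 8.5) {
  if (length(velocities) == 0 || length(headings) == 0 || length(conditions) == 0) {
    abort("factor sets must be non-empty")
  }
  if (anyDuplicated(velocities) || anyDuplicated(headings) ||
      anyDuplicated(conditions)) {
    abort("duplicate factor levels are not allowed")
  }
  conditions <- match.arg(conditions,
                          c("Acceleration", "Constant", "Deceleration"),
                          several.ok = TRUE)
  d <- tidyr::expand_grid(
    condition = conditions,
    visual_velocity = velocities,
    heading_angle = headings,
    rep = seq_len(reps)
  )
  d <- d %>%
    mutate(
      s_self = heading_to_lateral(.data$heading_angle, reference_speed),
      s_env = .data$visual_velocity,
      s_env0 = dplyr::case_when(
        .data$condition == "Acceleration" ~ 0,
        .data$condition == "Constant" ~ .data$s_env,
        .data$condition == "Deceleration" ~ 2 * .data$s_env
      )
    )
  ord <- with_seed(seed, sample.int(nrow(d)))
  d <- d[ord, , drop = FALSE]
  d <- mutate(d, trial = dplyr::row_number(), .before = 1)
  attr(d, "design_meta") <- list(seed = seed, reps = reps,
                                 velocities = velocities, headings = headings,
                                 conditions = conditions,
                                 reference_speed = reference_speed)
  class(d) <- c("heading_design", class(d))
  d
}

#' Simulate a model observer running the experiment
#'
#' For every trial of `design`, draws noisy measurements from the shared
#' generative model, applies the observer model's estimator, and maps the
#' lateral-velocity estimate back to a reported heading angle (clamped to
#' +/-90 degrees through the arcsine mapping). Per-trial diagnostics
#' (measurements, structure posterior, per-structure estimates) are
#' retained.
#'
#' @param params An [observer_params()] object (its `model_id` selects
#'   the estimator).
#' @param design A [build_design()] table.
#' @param seed Integer seed controlling the measurement noise.
#' @param observer Observer label stored in the output.
#' @return A tibble: the design columns plus `x_vest`, `x_vis`, `x_vis0`,
#'   `estimate_lateral`, `reported_heading`, `p_c1`, `s_hat_c1`,
#'   `s_hat_c2`, `observer`.
#' @export
simulate_observer <- function(params, design, seed = NULL, observer = "sim01") {
  validate_observer_params(params)
  ref <- design_reference_speed(design)
  meas <- sample_measurements(params, design, seed = seed)
  sds <- measurement_sds(params, design)
  est <- estimate_heading(params, meas, sds, s_env = design$s_env,
                          const_group = design$s_env0 == design$s_env)
  out <- dplyr::bind_cols(as_tibble(design), meas, est)
  out <- out %>%
    mutate(
      observer = observer,
      estimate_lateral = .data$s_hat,
      reported_heading = lateral_to_heading(.data$s_hat, ref)
    ) %>%
    select(-"s_hat")
  attr(out, "sim_meta") <- list(seed = seed, observer = observer,
                                model_id = params$model_id,
                                reference_speed = ref)
  out
}

design_reference_speed <- function(design) {
  meta <- attr(design, "design_meta")
  if (!is.null(meta$reference_speed)) meta$reference_speed else 8.5
}

#' Default cohort parameter sampler
#'
#' Draws observer parameters around field-plausible values: prior SDs of
#' a few deg/s, vestibular noise around 1.5 deg/s, a visual Weber
#' fraction around 0.15, and (for causal-inference models) a constancy
#' prior spread over the middle of the unit interval, giving observers
#' that genuinely differ from one another.
#'
#' @param model_id Observer model the sampled parameters must serve.
#' @return A function `(i)` returning an [observer_params()] draw; call
#'   it inside [make_cohort()], which seeds the stream.
#' @export
default_param_sampler <- function(model_id = "cci") {
  force(model_id)
  function(i) {
    base <- list(
      sigma_self = stats::rlnorm(1, log(3), 0.2),
      sigma_env = stats::rlnorm(1, log(3), 0.2),
      sigma_vest = stats::rlnorm(1, log(1.5), 0.3),
      w_vis = stats::rlnorm(1, log(0.15), 0.2)
    )
    extra <- switch(model_id,
      cci = , wta = list(p_constant = runif(1, 0.3, 0.8)),
      covariance = list(rho = runif(1, 0.3, 0.9)),
      mci = list(p_common = runif(1, 0.3, 0.8)),
      fixed = list(alpha_vest = runif(1, 0.3, 0.5),
                   alpha_mom = runif(1, 0.2, 0.4),
                   alpha_cont = runif(1, 0.1, 0.3)),
      variable_weight = list(alpha_1 = runif(1, 0.6, 0.9),
                             alpha_2 = runif(1, 0.1, 0.4)),
      list()
    )
    if (model_id == "fixed") base <- base[c("sigma_vest", "w_vis")]
    if (model_id == "mci") base <- base[c("sigma_self", "sigma_vest", "w_vis")]
    do.call(observer_params, c(list(model_id = model_id), base, extra))
  }
}

#' Simulate a cohort of observers with known parameters
#'
#' Draws independent true parameters per observer and simulates each one
#' through the design; the ground-truth parameters travel with the data,
#' making the list a ready-made parameter/model-recovery harness.
#'
#' @param n_observers Number of simulated observers (the study analyzed
#'   14).
#' @param design A [build_design()] table shared by all observers.
#' @param param_sampler A function `(i) -> observer_params`, e.g.
#'   [default_param_sampler()].
#' @param seed Integer seed; parameter draws and measurement noise are
#'   derived from it.
#' @return A list with one element per observer: `list(params, data)`.
#' @export
make_cohort <- function(n_observers = 14, design = build_design(seed = 1L),
                        param_sampler = default_param_sampler("cci"),
                        seed = NULL) {
  truth <- with_seed(seed, lapply(seq_len(n_observers), param_sampler))
  lapply(seq_len(n_observers), function(i) {
    lab <- sprintf("sim%02d", i)
    list(params = truth[[i]],
         data = simulate_observer(truth[[i]], design,
                                  seed = child_seed(seed, i), observer = lab))
  })
}
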