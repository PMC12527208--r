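# Closed-form observer models. All functions are vectorized over trials:
# `meas` is a data frame with columns x_vest, x_vis, x_vis0 and `sds` a
# data frame with sd_vest, sd_vis, sd_vis0 (see measurement_sds()).

#' Effective visual cue summary (mu_K, sigma2_K)
#'
#' Collapses the two visual signals into a single effective cue to
#' self-motion. Under the constant-environment structure (C = 1) the
#' pre-motion signal is used to estimate and subtract the environmental
#' motion from the during-motion signal ("contextual vision"); under the
#' changed-environment structure (C = 2) the pre-motion signal is
#' discarded and the during-motion signal is read at face value with
#' inflated uncertainty ("momentary vision"). The covariance variant
#' interpolates between the two through the correlation `rho` of the
#' bivariate environmental-motion prior.
#'
#' @param params An [observer_params()] object.
#' @param meas Data frame of measurements (`x_vest`, `x_vis`, `x_vis0`).
#' @param sds Data frame of measurement SDs (`sd_vest`, `sd_vis`,
#'   `sd_vis0`), typically from [measurement_sds()].
#' @param structure Causal structure, 1 (constant) or 2 (changed); used by
#'   `variant = "cci"`.
#' @param variant `"cci"` (per-structure summaries) or `"cov"`
#'   (correlated-prior summary using `params$rho`).
#' @return A tibble with columns `mu_K` (deg/s) and `sigma2_K` ((deg/s)^2).
#' @export
cue_summary <- function(params, meas, sds, structure = 1, variant = c("cci", "cov")) {
  variant <- match.arg(variant)
  s_env2 <- params$sigma_env^2
  v0_2 <- sds$sd_vis0^2
  v_2 <- sds$sd_vis^2
  if (any(v_2 <= 0) || any(v0_2 <= 0) || s_env2 <= 0) {
    abort("all variances entering the cue summary must be positive")
  }
  if (variant == "cov") {
    rho <- params$rho
    shrink <- s_env2 / (s_env2 + v0_2)
    return(tibble(
      mu_K = meas$x_vis - rho * shrink * meas$x_vis0,
      sigma2_K = v_2 + s_env2 * (1 - rho^2 * shrink)
    ))
  }
  if (!structure %in% c(1, 2)) abort("`structure` must be 1 or 2")
  if (structure == 1) {
    shrink <- s_env2 / (s_env2 + v0_2)
    tibble(mu_K = meas$x_vis - shrink * meas$x_vis0,
           sigma2_K = v_2 + s_env2 * v0_2 / (s_env2 + v0_2))
  } else {
    tibble(mu_K = meas$x_vis, sigma2_K = v_2 + s_env2)
  }
}

#' Per-structure optimal heading estimate
#'
#' Reliability-weighted combination of the vestibular cue, the effective
#' visual cue and the zero-mean slow-speed prior on self-motion:
#' `(x_vest/sd_vest^2 + mu_K/sigma2_K) / (1/sd_vest^2 + 1/sigma2_K +
#' 1/sigma_self^2)`.
#'
#' @inheritParams cue_summary
#' @param summary A cue summary tibble from [cue_summary()].
#' @return Numeric vector of self-motion estimates (deg/s).
#' @export
estimate_given_structure <- function(params, meas, sds, summary) {
  w_vest <- 1 / sds$sd_vest^2
  w_K <- 1 / summary$sigma2_K
  w_prior <- 1 / params$sigma_self^2
  (meas$x_vest * w_vest + summary$mu_K * w_K) / (w_vest + w_K + w_prior)
}

#' Log marginal likelihood of the measurements under a causal structure
#'
#' Analytic marginal likelihood of `(x_vest, x_vis, x_vis0)` given the
#' causal structure, up to a structure-independent factor (the marginal
#' density of `x_vis0` under its prior-predictive, which cancels in the
#' structure posterior and is omitted from both branches). Computed in
#' log space.
#'
#' @inheritParams cue_summary
#' @return Numeric vector of log-likelihood values.
#' @export
structure_loglik <- function(params, meas, sds, structure) {
  cs <- cue_summary(params, meas, sds, structure = structure, variant = "cci")
  s_self2 <- params$sigma_self^2
  v_vest2 <- sds$sd_vest^2
  D <- v_vest2 * cs$sigma2_K + v_vest2 * s_self2 + cs$sigma2_K * s_self2
  Q <- (meas$x_vest - cs$mu_K)^2 * s_self2 +
    meas$x_vest^2 * cs$sigma2_K + cs$mu_K^2 * v_vest2
  -log(2 * pi) - 0.5 * log(D) - 0.5 * Q / D
}

#' @rdname structure_loglik
#' @export
structure_likelihood <- function(params, meas, sds, structure) {
  exp(structure_loglik(params, meas, sds, structure))
}

#' Posterior probability that environmental motion stayed constant
#'
#' Bayes' rule over the two causal structures, combining the structure
#' likelihoods with the prior `p_constant`, evaluated in log space.
#'
#' @inheritParams cue_summary
#' @return A tibble with columns `p_c1` and `p_c2` (summing to 1).
#' @export
posterior_constant <- function(params, meas, sds) {
  pc <- params$p_constant
  n <- nrow(meas)
  if (pc == 1) return(tibble(p_c1 = rep(1, n), p_c2 = rep(0, n)))
  if (pc == 0) return(tibble(p_c1 = rep(0, n), p_c2 = rep(1, n)))
  l1 <- structure_loglik(params, meas, sds, 1) + log(pc)
  l2 <- structure_loglik(params, meas, sds, 2) + log(1 - pc)
  if (any(!is.finite(l1) & !is.finite(l2))) {
    abort("degenerate input: both structure likelihoods vanished")
  }
  p1 <- 1 / (1 + exp(l2 - l1))
  tibble(p_c1 = p1, p_c2 = 1 - p1)
}

# --- MCI internals (common-cause inference on x_vest, x_vis only) --------

mci_components <- function(params, meas, sd_vis) {
  s_self2 <- params$sigma_self^2
  v_vest2 <- params$sigma_vest^2
  v_vis2 <- sd_vis^2
  D1 <- v_vest2 * v_vis2 + v_vest2 * s_self2 + v_vis2 * s_self2
  Q1 <- (meas$x_vest - meas$x_vis)^2 * s_self2 +
    meas$x_vest^2 * v_vis2 + meas$x_vis^2 * v_vest2
  ll1 <- -log(2 * pi) - 0.5 * log(D1) - 0.5 * Q1 / D1
  ll2 <- -log(2 * pi) - 0.5 * log((v_vest2 + s_self2) * (v_vis2 + s_self2)) -
    0.5 * (meas$x_vest^2 / (v_vest2 + s_self2) + meas$x_vis^2 / (v_vis2 + s_self2))
  pc <- params$p_common
  p1 <- if (pc == 1) rep(1, nrow(meas)) else if (pc == 0) rep(0, nrow(meas)) else
    1 / (1 + exp(ll2 + log(1 - pc) - ll1 - log(pc)))
  w_vest <- 1 / v_vest2
  w_vis <- 1 / v_vis2
  w_prior <- 1 / s_self2
  s1 <- (meas$x_vest * w_vest + meas$x_vis * w_vis) / (w_vest + w_vis + w_prior)
  s2 <- (meas$x_vest * w_vest) / (w_vest + w_prior)
  list(p_c1 = p1, s_hat_c1 = s1, s_hat_c2 = s2)
}

#' Heading estimates from an observer model
#'
#' Applies one of the eight observer models, vectorized over trials.
#' Averaging models (cci, mci) combine the two per-structure estimates
#' weighted by the structure posterior; integration / segregation /
#' covariance are pure linear combinations; heuristic and winner-take-all
#' commit to a single structure; the fixed-weight model is a descriptive
#' weighted sum of the raw cues.
#'
#' For the mci model the observer's assumed visual noise follows its own
#' generative story, `sd_vis = w_vis * |s_env|` (floored), so `s_env`
#' must be supplied (it is taken from `stim` when using
#' [simulate_observer()]).
#'
#' @inheritParams cue_summary
#' @param s_env True environmental motion per trial (deg/s); required for
#'   `model_id = "mci"`, ignored otherwise.
#' @param heuristic_invert The heuristic rule as printed assigns the
#'   constant-environment branch when its cue discrepancy is the larger
#'   one; set `TRUE` to use the inverted (intuitive) direction.
#' @param const_group Logical vector, one per trial: whether the
#'   environmental motion truly was constant (`s_env0 == s_env`). Only
#'   used by `model_id = "variable_weight"`, the diagnostic rule that
#'   replaces the structure posterior with one of two fitted weights
#'   depending on the true state of the world.
#' @return A tibble with columns `s_hat`, `s_hat_c1`, `s_hat_c2`, `p_c1`
#'   (the latter `NA` for models without a structure posterior).
#' @examples
#' p <- observer_params("cci", sigma_self = 1, sigma_env = 1,
#'                      sigma_vest = 1, w_vis = 0, p_constant = 0.5)
#' m <- tibble::tibble(x_vest = 1, x_vis = 1, x_vis0 = 0)
#' s <- tibble::tibble(sd_vest = 1, sd_vis = 1, sd_vis0 = 1)
#' estimate_heading(p, m, s)  # s_hat ~ 0.613
#' @export
estimate_heading <- function(params, meas, sds = NULL, s_env = NULL,
                             heuristic_invert = FALSE, const_group = NULL) {
  validate_observer_params(params)
  model <- params$model_id
  n <- nrow(meas)
  na <- rep(NA_real_, n)

  if (model == "fixed") {
    s_hat <- params$alpha_vest * meas$x_vest + params$alpha_mom * meas$x_vis +
      params$alpha_cont * (meas$x_vis - meas$x_vis0)
    return(tibble(s_hat = s_hat, s_hat_c1 = na, s_hat_c2 = na, p_c1 = na))
  }
  if (model == "mci") {
    if (is.null(s_env)) abort("mci estimates need `s_env` (assumed Weber noise)")
    sd_vis <- pmax(params$noise_floor, params$w_vis * abs(s_env))
    mc <- mci_components(params, meas, sd_vis)
    return(tibble(
      s_hat = mc$p_c1 * mc$s_hat_c1 + (1 - mc$p_c1) * mc$s_hat_c2,
      s_hat_c1 = mc$s_hat_c1, s_hat_c2 = mc$s_hat_c2, p_c1 = mc$p_c1))
  }
  if (is.null(sds)) abort("`sds` is required for this model")
  if (model == "covariance") {
    cs <- cue_summary(params, meas, sds, variant = "cov")
    s_hat <- estimate_given_structure(params, meas, sds, cs)
    return(tibble(s_hat = s_hat, s_hat_c1 = na, s_hat_c2 = na, p_c1 = na))
  }

  cs1 <- cue_summary(params, meas, sds, structure = 1)
  cs2 <- cue_summary(params, meas, sds, structure = 2)
  s1 <- estimate_given_structure(params, meas, sds, cs1)
  s2 <- estimate_given_structure(params, meas, sds, cs2)

  switch(model,
    integration = tibble(s_hat = s1, s_hat_c1 = s1, s_hat_c2 = s2,
                         p_c1 = rep(1, n)),
    segregation = tibble(s_hat = s2, s_hat_c1 = s1, s_hat_c2 = s2,
                         p_c1 = rep(0, n)),
    heuristic = {
      pick1 <- abs(meas$x_vest - cs1$mu_K) >= abs(meas$x_vest - cs2$mu_K)
      if (heuristic_invert) pick1 <- abs(meas$x_vest - cs1$mu_K) <=
          abs(meas$x_vest - cs2$mu_K)
      tibble(s_hat = ifelse(pick1, s1, s2), s_hat_c1 = s1, s_hat_c2 = s2,
             p_c1 = na)
    },
    cci = {
      post <- posterior_constant(params, meas, sds)
      tibble(s_hat = post$p_c1 * s1 + post$p_c2 * s2,
             s_hat_c1 = s1, s_hat_c2 = s2, p_c1 = post$p_c1)
    },
    wta = {
      post <- posterior_constant(params, meas, sds)
      tibble(s_hat = ifelse(post$p_c1 >= 0.5, s1, s2),
             s_hat_c1 = s1, s_hat_c2 = s2, p_c1 = post$p_c1)
    },
    variable_weight = {
      if (is.null(const_group)) {
        abort("variable_weight needs `const_group` (true constancy per trial)")
      }
      a <- ifelse(const_group, params$alpha_1, params$alpha_2)
      tibble(s_hat = a * s1 + (1 - a) * s2, s_hat_c1 = s1, s_hat_c2 = s2,
             p_c1 = a)
    },
    abort(sprintf("unhandled model '%s'", model))
  )
}
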