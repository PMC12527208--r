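#' Weber-law measurement SDs for a set of trials
#'
#' The vestibular channel has constant noise `sigma_vest`. The two visual
#' channels follow Weber's law: the SD of the during-motion visual signal
#' is `w_vis * |s_self - s_env|` (retinal speed during self-motion), and
#' the SD of the pre-motion visual signal is `w_vis * |s_env0|`. Both are
#' floored at `params$noise_floor` so that physically noiseless signals
#' (zero retinal motion) keep a proper, if very narrow, density.
#'
#' @param params An [observer_params()] object.
#' @param stim A data frame of trials with columns `s_self`, `s_env`,
#'   `s_env0` (deg/s), e.g. a [build_design()] table.
#' @return A tibble with one row per trial: `sd_vest`, `sd_vis`, `sd_vis0`.
#' @examples
#' p <- observer_params("cci", sigma_self = 3, sigma_env = 3,
#'                      sigma_vest = 1.5, w_vis = 0.2, p_constant = 0.5)
#' measurement_sds(p, tibble::tibble(s_self = 10, s_env = 5, s_env0 = 0))
#' @export
measurement_sds <- function(params, stim) {
  validate_observer_params(params)
  if (!all(c("s_self", "s_env", "s_env0") %in% names(stim))) {
    abort("`stim` needs columns s_self, s_env, s_env0")
  }
  eps <- params$noise_floor
  tibble(
    sd_vest = rep(params$sigma_vest, nrow(stim)),
    sd_vis  = pmax(eps, params$w_vis * abs(stim$s_self - stim$s_env)),
    sd_vis0 = pmax(eps, params$w_vis * abs(stim$s_env0))
  )
}

#' Draw noisy sensory measurements for a set of trials
#'
#' Samples the three cues of the generative model, independently per
#' trial: `x_vest ~ N(s_self, sd_vest^2)` (vestibular),
#' `x_vis ~ N(s_self - s_env, sd_vis^2)` (retinal motion during
#' self-motion) and `x_vis0 ~ N(-s_env0, sd_vis0^2)` (retinal motion
#' before self-motion).
#'
#' @inheritParams measurement_sds
#' @param seed Optional integer seed for reproducible draws; the caller's
#'   RNG state is left untouched.
#' @return A tibble with columns `x_vest`, `x_vis`, `x_vis0`.
#' @export
sample_measurements <- function(params, stim, seed = NULL) {
  sds <- measurement_sds(params, stim)
  n <- nrow(stim)
  with_seed(seed, tibble(
    x_vest = rnorm(n, stim$s_self, sds$sd_vest),
    x_vis  = rnorm(n, stim$s_self - stim$s_env, sds$sd_vis),
    x_vis0 = rnorm(n, -stim$s_env0, sds$sd_vis0)
  ))
}
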