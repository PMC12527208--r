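#' Observer-model identifiers
#'
#' The eight observer models implemented by the package. `"cci"` is the
#' contextual causal-inference observer that infers whether environmental
#' motion stayed constant across the pre-motion and self-motion epochs;
#' the others are the alternatives it is compared against.
#'
#' @return Character vector of model ids.
#' @export
model_ids <- function() {
  c("cci", "integration", "segregation", "covariance",
    "fixed", "heuristic", "wta", "mci")
}

# Free parameters fitted for each model (Weber fraction and noise SDs enter
# every model's response distribution; priors/weights are model specific).
model_free_params <- function(model_id) {
  switch(model_id,
    cci         = c("sigma_self", "sigma_env", "sigma_vest", "w_vis", "p_constant"),
    wta         = c("sigma_self", "sigma_env", "sigma_vest", "w_vis", "p_constant"),
    integration = c("sigma_self", "sigma_env", "sigma_vest", "w_vis"),
    segregation = c("sigma_self", "sigma_env", "sigma_vest", "w_vis"),
    heuristic   = c("sigma_self", "sigma_env", "sigma_vest", "w_vis"),
    covariance  = c("sigma_self", "sigma_env", "sigma_vest", "w_vis", "rho"),
    fixed       = c("sigma_vest", "w_vis", "alpha_vest", "alpha_mom", "alpha_cont"),
    mci         = c("sigma_self", "sigma_vest", "w_vis", "p_common"),
    variable_weight = c("sigma_self", "sigma_env", "sigma_vest", "w_vis",
                        "alpha_1", "alpha_2"),
    abort(sprintf("unknown model id '%s'", model_id))
  )
}

#' Number of free parameters of an observer model
#'
#' Used for the AIC penalty 2k - 2 log L.
#'
#' @param model_id One of [model_ids()].
#' @return Integer count of free parameters.
#' @export
model_k <- function(model_id) {
  length(model_free_params(match.arg(model_id, c(model_ids(), "variable_weight"))))
}

#' Construct a validated observer parameter set
#'
#' Bundles every parameter used by the generative model and the observer
#' models. All signals live on a common lateral-velocity axis in degrees
#' per second. Sensory noise on the visual channels follows Weber's law
#' with fraction `w_vis`; the vestibular channel has constant SD
#' `sigma_vest`. `sigma_self` and `sigma_env` are the SDs of the zero-mean
#' (slow-speed) priors on self-motion and environmental motion.
#'
#' @param model_id Which observer model these parameters describe.
#' @param sigma_self,sigma_env,sigma_vest Prior / vestibular-noise SDs
#'   (deg/s), strictly positive.
#' @param w_vis Visual Weber fraction (dimensionless, >= 0).
#' @param p_constant Prior probability that environmental motion stays
#'   constant across epochs (cci / wta).
#' @param rho Correlation of pre- and during-motion environmental motion
#'   in the covariance model, in [0, 1].
#' @param alpha_vest,alpha_mom,alpha_cont Fixed cue weights (fixed-weight
#'   model only).
#' @param p_common Prior probability of a common cause (mci only).
#' @param alpha_1,alpha_2 Adaptive weights of the variable-weight
#'   diagnostic (not an observer model; see [variable_weight_fit()]).
#' @param noise_floor Lower bound (deg/s) applied to Weber-law SDs so that
#'   zero-magnitude signals keep a proper measurement density.
#' @return An object of class `observer_params` (a named list).
#' @examples
#' observer_params("cci", sigma_self = 3, sigma_env = 3, sigma_vest = 1.5,
#'                 w_vis = 0.15, p_constant = 0.5)
#' @export
observer_params <- function(model_id = "cci",
                            sigma_self = NULL, sigma_env = NULL,
                            sigma_vest = NULL, w_vis = NULL,
                            p_constant = NULL, rho = NULL,
                            alpha_vest = NULL, alpha_mom = NULL,
                            alpha_cont = NULL, p_common = NULL,
                            alpha_1 = NULL, alpha_2 = NULL,
                            noise_floor = 1e-3) {
  model_id <- match.arg(model_id, c(model_ids(), "variable_weight"))
  p <- list(model_id = model_id,
            sigma_self = sigma_self, sigma_env = sigma_env,
            sigma_vest = sigma_vest, w_vis = w_vis,
            p_constant = p_constant, rho = rho,
            alpha_vest = alpha_vest, alpha_mom = alpha_mom,
            alpha_cont = alpha_cont, p_common = p_common,
            alpha_1 = alpha_1, alpha_2 = alpha_2,
            noise_floor = noise_floor)
  class(p) <- "observer_params"
  validate_observer_params(p)
  p
}

validate_observer_params <- function(p) {
  need <- model_free_params(p$model_id)
  for (nm in need) {
    if (is.null(p[[nm]]) || !is.numeric(p[[nm]]) || length(p[[nm]]) != 1L ||
        !is.finite(p[[nm]])) {
      abort(sprintf("model '%s' requires a finite scalar `%s`", p$model_id, nm))
    }
  }
  for (nm in c("sigma_self", "sigma_env", "sigma_vest")) {
    if (!is.null(p[[nm]]) && p[[nm]] <= 0) {
      abort(sprintf("`%s` must be strictly positive", nm))
    }
  }
  if (!is.null(p$w_vis) && p$w_vis < 0) abort("`w_vis` must be >= 0")
  for (nm in c("p_constant", "p_common", "rho", "alpha_1", "alpha_2")) {
    if (!is.null(p[[nm]]) && (p[[nm]] < 0 || p[[nm]] > 1)) {
      abort(sprintf("`%s` must lie in [0, 1]", nm))
    }
  }
  if (!is.numeric(p$noise_floor) || p$noise_floor <= 0) {
    abort("`noise_floor` must be a positive number")
  }
  invisible(p)
}

#' @export
print.observer_params <- function(x, ...) {
  vals <- x[model_free_params(x$model_id)]
  cat("<observer_params> model:", x$model_id, "\n")
  cat(paste0("  ", names(vals), " = ", signif(unlist(vals), 4), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Serialize / deserialize observer parameters as JSON
#'
#' @param params An `observer_params` object.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `params_to_json()` returns the path (or the JSON string);
#'   `params_from_json()` returns an `observer_params` object.
#' @export
params_to_json <- function(params, path = NULL) {
  keep <- params[!vapply(params, is.null, logical(1))]
  json <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' @rdname params_to_json
#' @param json A JSON string or file path written by [params_to_json()].
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(observer_params, x)
}
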