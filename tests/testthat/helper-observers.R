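# Shared builders for test observers, measurements and random cases.

test_params <- function(model_id = "cci", ...) {
  defaults <- switch(model_id,
    cci = list(sigma_self = 3, sigma_env = 3, sigma_vest = 1.5,
               w_vis = 0.15, p_constant = 0.5),
    wta = list(sigma_self = 3, sigma_env = 3, sigma_vest = 1.5,
               w_vis = 0.15, p_constant = 0.5),
    integration = , segregation = , heuristic =
      list(sigma_self = 3, sigma_env = 3, sigma_vest = 1.5, w_vis = 0.15),
    covariance = list(sigma_self = 3, sigma_env = 3, sigma_vest = 1.5,
                      w_vis = 0.15, rho = 0.6),
    fixed = list(sigma_vest = 1.5, w_vis = 0.15, alpha_vest = 0.4,
                 alpha_mom = 0.3, alpha_cont = 0.2),
    mci = list(sigma_self = 3, sigma_vest = 1.5, w_vis = 0.15,
               p_common = 0.6),
    variable_weight = list(sigma_self = 3, sigma_env = 3, sigma_vest = 1.5,
                           w_vis = 0.15, alpha_1 = 0.8, alpha_2 = 0.3)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(observer_params, c(list(model_id = model_id), args))
}

# unit-sigma observer used by the hand-computed examples
unit_params <- function(model_id = "cci", ...) {
  base <- list(sigma_self = 1, sigma_env = 1, sigma_vest = 1, w_vis = 0)
  extra <- switch(model_id, cci = , wta = list(p_constant = 0.5),
                  covariance = list(rho = 0.5),
                  mci = list(p_common = 0.5), list())
  if (model_id == "mci") base$sigma_env <- NULL
  args <- utils::modifyList(c(base, extra), list(...))
  do.call(observer_params, c(list(model_id = model_id), args))
}

unit_meas <- function(x_vest = 1, x_vis = 1, x_vis0 = 0) {
  tibble::tibble(x_vest = x_vest, x_vis = x_vis, x_vis0 = x_vis0)
}

unit_sds <- function(sd_vest = 1, sd_vis = 1, sd_vis0 = 1) {
  tibble::tibble(sd_vest = sd_vest, sd_vis = sd_vis, sd_vis0 = sd_vis0)
}

# random measurement/SD draws with moderate scales, reproducible
random_cases <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    x_vest = runif(n, -8, 8),
    x_vis = runif(n, -12, 12),
    x_vis0 = runif(n, -12, 12),
    sd_vest = runif(n, 0.5, 3),
    sd_vis = runif(n, 0.5, 3),
    sd_vis0 = runif(n, 0.5, 3)
  ))
}

tiny_design <- function(reps = 2, seed = 1) {
  build_design(velocities = c(-10, 10), headings = c(-25, 25),
               reps = reps, seed = seed)
}
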