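# Model fitting: Monte-Carlo marginalization over unobservable sensory
# measurements, kernel-density response likelihood, MAP objective with
# log-normal priors, multi-start optimization, AIC.

#' Fitting configuration
#'
#' @param n_mc Monte-Carlo measurement samples per stimulus condition
#'   used to build the response density (>= 10).
#' @param n_final_evals Fresh-draw objective evaluations averaged after
#'   optimization to de-noise the reported log-likelihood.
#' @param n_restarts Number of optimizer restarts from Latin-hypercube
#'   initial points (>= 1).
#' @param maxit Nelder-Mead iteration budget per optimization pass.
#' @param n_passes Maximum Nelder-Mead passes per restart; passes after
#'   the first re-initialize the simplex at the current optimum and stop
#'   early once converged with negligible improvement.
#' @param density_floor Lower bound on any KDE density value so the log
#'   objective stays finite.
#' @param bw_floor Lower bound on the KDE bandwidth; reached only when
#'   the simulated estimates are (near-)degenerate, in which case the
#'   kernel collapses to a narrow Gaussian at that point.
#' @param seed Integer seed for the common-random-numbers draw and the
#'   restart points; `NULL` leaves the RNG stream alone.
#' @param compute_r2 If `TRUE`, [fit_model()] also computes the
#'   coefficient of determination via [model_r2()].
#' @param n_sim_r2 Simulated estimates per condition for the R^2
#'   prediction.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_mc = 1000, n_final_evals = 100, n_restarts = 5,
                       maxit = 400, n_passes = 3, density_floor = 1e-9,
                       bw_floor = 1e-6, seed = NULL, compute_r2 = FALSE,
                       n_sim_r2 = 10000) {
  stopifnot(n_mc >= 10, n_restarts >= 1, n_final_evals >= 1, n_passes >= 1)
  structure(list(n_mc = n_mc, n_final_evals = n_final_evals,
                 n_restarts = n_restarts, maxit = maxit, n_passes = n_passes,
                 density_floor = density_floor, bw_floor = bw_floor,
                 seed = seed, compute_r2 = compute_r2, n_sim_r2 = n_sim_r2),
            class = "fit_config")
}

# --- parameter space ------------------------------------------------------

# Bounds and scales of the free parameters of each model. Noise SDs and
# the Weber fraction are searched on a log scale; probabilities, the
# correlation and the adaptive weights on their natural bounded scale;
# the descriptive fixed weights may take either sign.
param_space <- function(model_id) {
  nm <- model_free_params(model_id)
  lower <- c(sigma_self = 1e-3, sigma_env = 1e-3, sigma_vest = 1e-3,
             w_vis = 1e-3, p_constant = 0, p_common = 0, rho = 0,
             alpha_vest = -2, alpha_mom = -2, alpha_cont = -2,
             alpha_1 = 0, alpha_2 = 0)
  upper <- c(sigma_self = 50, sigma_env = 50, sigma_vest = 50,
             w_vis = 2, p_constant = 1, p_common = 1, rho = 1,
             alpha_vest = 2, alpha_mom = 2, alpha_cont = 2,
             alpha_1 = 1, alpha_2 = 1)
  scale <- c(sigma_self = "log", sigma_env = "log", sigma_vest = "log",
             w_vis = "log", p_constant = "linear", p_common = "linear",
             rho = "linear", alpha_vest = "linear", alpha_mom = "linear",
             alpha_cont = "linear", alpha_1 = "linear", alpha_2 = "linear")
  tibble(name = nm, lower = unname(lower[nm]), upper = unname(upper[nm]),
         scale = unname(scale[nm]))
}

# natural value -> unbounded coordinate (scaled logit, log scale for SDs)
space_box <- function(space) {
  is_log <- space$scale == "log"
  lo <- space$lower
  hi <- space$upper
  lo[is_log] <- log(lo[is_log])
  hi[is_log] <- log(hi[is_log])
  list(lo = lo, hi = hi, is_log = is_log)
}

to_unbounded <- function(value, space) {
  b <- space_box(space)
  t <- value
  t[b$is_log] <- log(value[b$is_log])
  u <- (t - b$lo) / (b$hi - b$lo)
  stats::qlogis(pmin(1 - 1e-9, pmax(1e-9, u)))
}

from_unbounded <- function(u, space) {
  b <- space_box(space)
  t <- b$lo + stats::plogis(u) * (b$hi - b$lo)
  t[b$is_log] <- exp(t[b$is_log])
  t
}

vector_to_params <- function(v, model_id, noise_floor = 1e-3) {
  do.call(observer_params,
          c(list(model_id = model_id, noise_floor = noise_floor),
            as.list(setNames(v, model_free_params(model_id)))))
}

# Log-normal priors on the noise SDs (log-mean 1) and the Weber fraction
# (log-mean -2), both with unit log-SD; flat priors on the parameters
# that are bounded by definition.
log_prior <- function(params) {
  lp <- 0
  for (nm in intersect(model_free_params(params$model_id),
                       c("sigma_self", "sigma_env", "sigma_vest"))) {
    lp <- lp + stats::dlnorm(params[[nm]], meanlog = 1, sdlog = 1, log = TRUE)
  }
  if ("w_vis" %in% model_free_params(params$model_id)) {
    lp <- lp + stats::dlnorm(params$w_vis, meanlog = -2, sdlog = 1, log = TRUE)
  }
  lp
}

# --- condition table and the MC/KDE likelihood ----------------------------

# Collapse a per-trial dataset to its distinct stimulus conditions and
# express responses on the estimate (lateral-velocity) scale.
condition_table <- function(data, reference_speed = 8.5) {
  need <- c("condition", "visual_velocity", "heading_angle", "reported_heading")
  if (!all(need %in% names(data))) {
    abort(paste("dataset needs columns:", paste(need, collapse = ", ")))
  }
  d <- as_tibble(data)
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
  key <- paste(d$condition, d$visual_velocity, d$heading_angle)
  cond <- d[!duplicated(key),
            c("condition", "visual_velocity", "heading_angle",
              "s_self", "s_env", "s_env0")]
  cond$const_group <- cond$s_env0 == cond$s_env
  list(cond = as_tibble(cond),
       resp = heading_to_lateral(d$reported_heading, reference_speed),
       resp_cond = match(key, key[!duplicated(key)]),
       reference_speed = reference_speed)
}

# Simulate model estimates for every condition: matrix [n_cond x n_mc].
# `z` holds standard-normal draws (list of three [n_cond x n_mc]
# matrices) so that repeated calls share common random numbers.
simulate_condition_estimates <- function(params, cond, n_mc, z,
                                         reference_speed = 8.5) {
  nc <- nrow(cond)
  eps <- params$noise_floor
  sd_vest <- params$sigma_vest
  sd_vis <- pmax(eps, params$w_vis * abs(cond$s_self - cond$s_env))
  sd_vis0 <- pmax(eps, params$w_vis * abs(cond$s_env0))
  meas <- tibble(
    x_vest = as.vector(cond$s_self + sd_vest * z$vest),
    x_vis = as.vector((cond$s_self - cond$s_env) + sd_vis * z$vis),
    x_vis0 = as.vector(-cond$s_env0 + sd_vis0 * z$vis0)
  )
  sds <- tibble(sd_vest = rep(sd_vest, nc * n_mc),
                sd_vis = rep(sd_vis, n_mc),
                sd_vis0 = rep(sd_vis0, n_mc))
  est <- estimate_heading(params, meas, sds,
                          s_env = rep(cond$s_env, n_mc),
                          const_group = rep(cond$const_group, n_mc))
  # clamp to the representable response range (reports live on +/-90 deg)
  matrix(pmax(-reference_speed, pmin(reference_speed, est$s_hat)), nrow = nc)
}

draw_z <- function(nc, n_mc, seed = NULL) {
  with_seed(seed, list(vest = matrix(rnorm(nc * n_mc), nc),
                       vis = matrix(rnorm(nc * n_mc), nc),
                       vis0 = matrix(rnorm(nc * n_mc), nc)))
}

.model_code <- function(model_id) {
  match(model_id, c("cci", "integration", "segregation", "covariance",
                    "fixed", "heuristic", "wta", "mci", "variable_weight"))
}

# Compiled hot path of the objective: simulate estimates per condition
# under common random numbers and evaluate the KDE log-likelihood.
fast_loglik <- function(params, ct, z, density_floor, bw_floor) {
  par <- unclass(params)
  par <- par[!vapply(par, is.null, logical(1))]
  .mc_kde_loglik_cpp(.model_code(params$model_id), par,
                     ct$cond$s_self, ct$cond$s_env, ct$cond$s_env0,
                     ct$cond$const_group, z$vest, z$vis, z$vis0,
                     ct$resp, as.integer(ct$resp_cond),
                     ct$reference_speed, density_floor, bw_floor)
}

# Gaussian KDE log-likelihood of the observed responses given simulated
# estimates, Silverman-type bandwidth per condition.
kde_loglik <- function(sim, resp, resp_cond, density_floor, bw_floor) {
  n_mc <- ncol(sim)
  mu <- rowMeans(sim)
  s <- sqrt(pmax(rowMeans(sim^2) - mu^2, 0) * n_mc / (n_mc - 1))
  bw <- pmax(0.9 * s * n_mc^(-1 / 5), bw_floor)
  M <- sim[resp_cond, , drop = FALSE]
  B <- bw[resp_cond]
  dens <- rowMeans(dnorm((resp - M) / B)) / B
  sum(log(pmax(dens, density_floor)))
}

#' Monte-Carlo/KDE log-likelihood of responses in one stimulus condition
#'
#' Draws `n_mc` measurement triples from the condition's measurement
#' distributions, maps them through the observer model, fits a Gaussian
#' kernel density to the simulated estimates and sums the log density of
#' the observed responses. This marginalizes the unobservable internal
#' measurements out of the response likelihood.
#'
#' @param params An [observer_params()] object.
#' @param stim One-row data frame with `condition`, `visual_velocity`,
#'   `heading_angle` and the latent states `s_self`, `s_env`, `s_env0`.
#' @param responses Observed heading reports for this condition, on the
#'   lateral-velocity scale (deg/s).
#' @param config A [fit_config()].
#' @param seed Seed for the measurement draws.
#' @return Scalar log-likelihood.
#' @export
response_loglik <- function(params, stim, responses, config = fit_config(),
                            seed = NULL) {
  stim <- as_tibble(stim)
  stim$const_group <- stim$s_env0 == stim$s_env
  z <- draw_z(nrow(stim), config$n_mc, seed)
  ct <- list(cond = stim, resp = responses,
             resp_cond = rep(1L, length(responses)), reference_speed = 8.5)
  fast_loglik(params, ct, z, config$density_floor, config$bw_floor)
}

#' Total log posterior of model parameters given a dataset
#'
#' Sum of the per-condition Monte-Carlo/KDE log-likelihoods over all
#' distinct stimulus conditions plus the log prior over parameters.
#'
#' @param params An [observer_params()] object.
#' @param data Per-trial dataset (see [fit_model()]).
#' @param config A [fit_config()].
#' @param seed Seed for the measurement draws.
#' @param reference_speed Heading-to-lateral mapping speed (deg/s).
#' @return Scalar log posterior (unnormalized).
#' @export
total_log_posterior <- function(params, data, config = fit_config(),
                                seed = NULL, reference_speed = 8.5) {
  ct <- condition_table(data, reference_speed)
  z <- draw_z(nrow(ct$cond), config$n_mc, seed)
  fast_loglik(params, ct, z, config$density_floor, config$bw_floor) +
    log_prior(params)
}

# --- the fit --------------------------------------------------------------

#' Fit an observer model to a dataset by MAP estimation
#'
#' Maximizes the Monte-Carlo/KDE log posterior with a multi-start
#' Nelder-Mead search on transformed (unbounded) parameters. Within a
#' search, all objective evaluations share one set of standard-normal
#' draws (common random numbers), which turns the stochastic objective
#' into a smooth deterministic surface; the reported log-likelihood is
#' then re-estimated by averaging `n_final_evals` fresh-draw evaluations
#' at the optimum, and AIC = 2k - 2 log L with k the model's free
#' parameter count.
#'
#' @param data Per-trial dataset with columns `condition`,
#'   `visual_velocity`, `heading_angle`, `reported_heading` (degrees),
#'   e.g. from [simulate_observer()] or a read-in behavioral CSV.
#' @param model_id One of [model_ids()] (or `"variable_weight"`, but see
#'   [variable_weight_fit()]).
#' @param config A [fit_config()].
#' @param reference_speed Heading-to-lateral mapping speed (deg/s).
#' @return An object of class `heading_fit`: MAP parameters,
#'   `log_likelihood`, `log_posterior`, `aic`, `k`, optionally
#'   `r_squared`, a per-restart `trace` tibble, and the configuration.
#' @export
fit_model <- function(data, model_id = "cci", config = fit_config(),
                      reference_speed = 8.5) {
  model_id <- match.arg(model_id, c(model_ids(), "variable_weight"))
  ct <- condition_table(data, reference_speed)
  space <- param_space(model_id)
  k <- nrow(space)
  nc <- nrow(ct$cond)

  z <- draw_z(nc, config$n_mc, child_seed(config$seed, 1L))

  objective <- function(u) {
    v <- from_unbounded(u, space)
    params <- vector_to_params(v, model_id)
    ll <- fast_loglik(params, ct, z, config$density_floor, config$bw_floor)
    -(ll + log_prior(params))
  }

  # Restart points: the first sits at the prior's center (log-normal
  # medians for the SDs and Weber fraction, box midpoints for bounded
  # parameters) — a well-behaved start that usually converges fastest —
  # the rest are Latin-hypercube draws in the box (5% edge margin)
  u01 <- with_seed(child_seed(config$seed, 2L),
                   lhs::randomLHS(config$n_restarts, k))
  u01 <- 0.05 + 0.9 * u01
  box <- space_box(space)
  lo <- box$lo
  hi <- box$hi
  prior_center <- c(sigma_self = exp(1), sigma_env = exp(1),
                    sigma_vest = exp(1), w_vis = exp(-2))
  v_center <- vapply(seq_len(k), function(j) {
    nm <- space$name[j]
    if (nm %in% names(prior_center)) {
      min(max(prior_center[[nm]], space$lower[j]), space$upper[j])
    } else {
      (space$lower[j] + space$upper[j]) / 2
    }
  }, numeric(1))
  t_center <- v_center
  t_center[box$is_log] <- log(v_center[box$is_log])
  u01[1, ] <- (t_center - lo) / (hi - lo)

  trace <- vector("list", config$n_restarts)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    t0 <- lo + u01[r, ] * (hi - lo)
    v0 <- t0
    v0[box$is_log] <- exp(t0[box$is_log])
    u0 <- to_unbounded(v0, space)
    # repeated Nelder-Mead passes: re-initializing the simplex at the
    # current optimum escapes the collapsed-simplex stalls of a single run
    opt <- stats::optim(u0, objective, method = "Nelder-Mead",
                        control = list(maxit = config$maxit))
    for (pass in seq_len(config$n_passes - 1)) {
      nxt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                          control = list(maxit = config$maxit))
      improved <- opt$value - nxt$value
      opt <- nxt
      if (opt$convergence == 0 && improved < 0.01) break
    }
    trace[[r]] <- tibble(restart = r, value = -opt$value,
                         convergence = opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  converged <- any(vapply(trace, function(t) t$convergence == 0, logical(1)))

  map_v <- from_unbounded(best$par, space)
  map_params <- vector_to_params(map_v, model_id)
  lp <- log_prior(map_params)

  # de-noise the log-likelihood with fresh Monte-Carlo draws
  final <- vapply(seq_len(config$n_final_evals), function(i) {
    zf <- draw_z(nc, config$n_mc, child_seed(config$seed, 100L + i))
    fast_loglik(map_params, ct, zf, config$density_floor, config$bw_floor)
  }, numeric(1))
  log_lik <- mean(final)

  fit <- structure(list(
    model_id = model_id,
    observer = if ("observer" %in% names(data)) data$observer[1] else NA_character_,
    map_params = map_params,
    log_likelihood = log_lik,
    log_posterior = log_lik + lp,
    aic = 2 * k - 2 * log_lik,
    k = k,
    converged = converged,
    trace = dplyr::bind_rows(trace),
    config = config,
    reference_speed = reference_speed
  ), class = "heading_fit")

  if (isTRUE(config$compute_r2)) {
    fit$r_squared <- model_r2(fit, data, n_sim = config$n_sim_r2,
                              seed = child_seed(config$seed, 999L))
  }
  fit
}

#' @export
print.heading_fit <- function(x, ...) {
  cat("<heading_fit>", x$model_id,
      if (!is.na(x$observer)) paste0("(", x$observer, ")"), "\n")
  v <- unlist(x$map_params[model_free_params(x$model_id)])
  cat("  MAP:", paste0(names(v), "=", signif(v, 3), collapse = ", "), "\n")
  cat(sprintf("  logLik %.2f | AIC %.2f | k %d%s\n", x$log_likelihood,
              x$aic, x$k,
              if (!is.null(x$r_squared)) sprintf(" | R^2 %.3f", x$r_squared)
              else ""))
  invisible(x)
}

#' Coefficient of determination of a fitted model
#'
#' Simulates `n_sim` heading estimates per distinct stimulus condition
#' from the MAP parameters, averages them into a predicted mean reported
#' heading per condition, and returns `1 - SS_res / SS_tot` against the
#' observed condition means.
#'
#' @param fit A [fit_model()] result.
#' @param data The dataset the model was fitted to.
#' @param n_sim Simulated estimates per condition.
#' @param seed Integer seed.
#' @return Scalar R^2.
#' @export
model_r2 <- function(fit, data, n_sim = 10000, seed = NULL) {
  ct <- condition_table(data, fit$reference_speed)
  z <- draw_z(nrow(ct$cond), n_sim, seed)
  sim <- simulate_condition_estimates(fit$map_params, ct$cond, n_sim, z,
                                      fit$reference_speed)
  pred <- rowMeans(matrix(lateral_to_heading(sim, fit$reference_speed),
                          nrow = nrow(sim)))
  obs <- as.numeric(tapply(lateral_to_heading(ct$resp, fit$reference_speed),
                           ct$resp_cond, mean))
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Compare fitted models by AIC difference from a reference model
#'
#' Per observer and model, computes the AIC difference from the reference
#' model (positive = worse fit than the reference), then summarizes each
#' model over observers with the mean difference, a percentile bootstrap
#' confidence interval, and the number of observers whose data favor the
#' model over the reference.
#'
#' @param fits A list of `heading_fit` objects (each carrying `observer`
#'   and `model_id`), or a data frame with columns `observer`,
#'   `model_id`, `aic`.
#' @param reference Reference model id (default `"cci"`).
#' @param n_boot Bootstrap resamples over observers.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return A tibble of class `heading_compare`: per non-reference model,
#'   `mean_delta_aic`, `ci_lower`, `ci_upper`, `n_favoring_model`,
#'   `n_observers`.
#' @export
compare_models <- function(fits, reference = "cci", n_boot = 2000,
                           conf = 0.95, seed = NULL) {
  tab <- if (is.data.frame(fits)) as_tibble(fits) else {
    dplyr::bind_rows(lapply(fits, function(f) {
      tibble(observer = f$observer, model_id = f$model_id, aic = f$aic)
    }))
  }
  if (!reference %in% tab$model_id) {
    abort(sprintf("reference model '%s' absent from `fits`", reference))
  }
  ref <- tab %>% filter(.data$model_id == reference) %>%
    select("observer", ref_aic = "aic")
  delta <- tab %>% filter(.data$model_id != reference) %>%
    left_join(ref, by = "observer") %>%
    mutate(delta_aic = .data$aic - .data$ref_aic)
  alpha <- (1 - conf) / 2
  out <- with_seed(seed, {
    delta %>%
      tidyr::nest(obs = -"model_id") %>%
      mutate(summary = purrr::map(.data$obs, function(d) {
        boot_means <- vapply(seq_len(n_boot), function(b) {
          mean(sample(d$delta_aic, replace = TRUE))
        }, numeric(1))
        tibble(mean_delta_aic = mean(d$delta_aic),
               ci_lower = unname(stats::quantile(boot_means, alpha)),
               ci_upper = unname(stats::quantile(boot_means, 1 - alpha)),
               n_favoring_model = sum(d$delta_aic < 0),
               n_observers = nrow(d))
      })) %>%
      select("model_id", "summary") %>%
      tidyr::unnest("summary")
  })
  out <- mutate(out, reference = reference)
  class(out) <- c("heading_compare", class(out))
  out
}
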