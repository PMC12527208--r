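# Brute-force numerical oracle for the closed-form observer models.
# Everything here integrates the generative densities directly with
# adaptive quadrature and never touches the analytic shortcuts in
# estimators.R, so it can serve as an independent check.

# Integration window wide enough to contain every Gaussian factor.
.window <- function(means, sds, k = 12) {
  range(means - k * max(sds), means + k * max(sds))
}

.integrate <- function(f, lower, upper) {
  stats::integrate(f, lower, upper, rel.tol = 1e-9, abs.tol = 0,
                   subdivisions = 200L)$value
}

# Inner visual integral for the constant-environment structure:
# given s, integrate over e the product
#   N(x_vis; s - e, sd_vis) N(x_vis0; -e, sd_vis0) N(e; 0, sigma_env)
.inner_c1 <- function(s, meas, sds, sigma_env) {
  win <- .window(c(s - meas$x_vis, -meas$x_vis0, 0),
                 c(sds$sd_vis, sds$sd_vis0, sigma_env))
  .integrate(function(e) {
    dnorm(meas$x_vis, s - e, sds$sd_vis) *
      dnorm(meas$x_vis0, -e, sds$sd_vis0) *
      dnorm(e, 0, sigma_env)
  }, win[1], win[2])
}

# Inner visual integral for the changed-environment structure (prior only).
.inner_c2 <- function(s, meas, sds, sigma_env) {
  win <- .window(c(s - meas$x_vis, 0), c(sds$sd_vis, sigma_env))
  .integrate(function(e) {
    dnorm(meas$x_vis, s - e, sds$sd_vis) * dnorm(e, 0, sigma_env)
  }, win[1], win[2])
}

# Marginal likelihood and posterior mean of s under one structure.
# `moment` = 0 gives the marginal likelihood of (x_vest, x_vis) terms;
# `moment` = 1 the first-moment numerator.
.vest_vis_integral <- function(params, meas, sds, structure, moment) {
  inner <- if (structure == 1) .inner_c1 else .inner_c2
  win <- .window(c(meas$x_vest, 0), c(sds$sd_vest, params$sigma_self))
  f <- function(sv) {
    vapply(sv, function(s) {
      s^moment * dnorm(meas$x_vest, s, sds$sd_vest) *
        dnorm(s, 0, params$sigma_self) *
        inner(s, meas, sds, params$sigma_env)
    }, numeric(1))
  }
  .integrate(f, win[1], win[2])
}

# Marginal density of x_vis0 under an independent environmental prior
# (the factor shared by both structures when C = 2 is expanded).
.k0_numeric <- function(meas, sds, sigma_env) {
  win <- .window(c(-meas$x_vis0, 0), c(sds$sd_vis0, sigma_env))
  .integrate(function(e0) {
    dnorm(meas$x_vis0, -e0, sds$sd_vis0) * dnorm(e0, 0, sigma_env)
  }, win[1], win[2])
}

#' Numerically integrated structure likelihood
#'
#' Computes the marginal likelihood of the three measurements under a
#' causal structure by direct quadrature of the generative densities and
#' divides out the structure-independent marginal density of the
#' pre-motion visual signal, making the value directly comparable with
#' the analytic [structure_likelihood()].
#'
#' @inheritParams cue_summary
#' @return Scalar likelihood value (single-trial `meas`/`sds`).
#' @export
numeric_structure_likelihood <- function(params, meas, sds, structure) {
  L_vv <- .vest_vis_integral(params, meas, sds, structure, moment = 0)
  if (structure == 1) {
    # full triple integral couples x_vis0; divide by the shared factor
    k0 <- dnorm(meas$x_vis0, 0, sqrt(sds$sd_vis0^2 + params$sigma_env^2))
    L_vv / k0
  } else {
    # for C = 2 the x_vis0 factor is exactly the shared factor: it cancels
    L_vv
  }
}

#' Brute-force posterior-mean heading estimate
#'
#' Computes the posterior mean of self-motion under the stated generative
#' model by adaptive quadrature over the latent states (and, where the
#' model defines one, the causal structure). Slow by design; used as an
#' independent oracle for the closed-form estimators.
#'
#' @inheritParams estimate_heading
#' @param model_id Model to evaluate; defaults to `params$model_id`.
#'   Supported: cci, integration, segregation, covariance, mci.
#' @return Numeric vector of posterior-mean estimates, one per row of
#'   `meas`.
#' @export
numeric_posterior_mean <- function(params, meas, sds = NULL, s_env = NULL,
                                   model_id = params$model_id) {
  one <- function(i) {
    m <- lapply(meas, `[`, i)
    s <- if (!is.null(sds)) lapply(sds, `[`, i) else NULL
    switch(model_id,
      integration = {
        .vest_vis_integral(params, m, s, 1, 1) /
          .vest_vis_integral(params, m, s, 1, 0)
      },
      segregation = {
        .vest_vis_integral(params, m, s, 2, 1) /
          .vest_vis_integral(params, m, s, 2, 0)
      },
      cci = {
        L1 <- .vest_vis_integral(params, m, s, 1, 0)
        m1 <- .vest_vis_integral(params, m, s, 1, 1) / L1
        L2vv <- .vest_vis_integral(params, m, s, 2, 0)
        m2 <- .vest_vis_integral(params, m, s, 2, 1) / L2vv
        L2 <- L2vv * .k0_numeric(m, s, params$sigma_env)
        w1 <- params$p_constant * L1
        w2 <- (1 - params$p_constant) * L2
        (w1 * m1 + w2 * m2) / (w1 + w2)
      },
      covariance = .cov_posterior_mean(params, m, s),
      mci = .mci_posterior_mean(params, m, s_env[i]),
      abort(sprintf("no numeric oracle for model '%s'", model_id))
    )
  }
  vapply(seq_len(nrow(meas)), one, numeric(1))
}

# Covariance model: bivariate environmental prior with correlation rho.
# The three-deep integral is evaluated on dense uniform grids (trapezoid
# rule, vectorized); trapezoid quadrature converges spectrally for these
# smooth Gaussian integrands once the spacing is well below the smallest
# SD, and the grids here use ~1200 points per dimension over +/-10 SD
# windows.
.trapz_w <- function(g) {
  h <- g[2] - g[1]
  w <- rep(h, length(g))
  w[c(1, length(g))] <- h / 2
  w
}

.cov_posterior_mean <- function(params, m, s) {
  rho <- params$rho
  se <- params$sigma_env
  sd_cond <- se * sqrt(max(1 - rho^2, 0))
  n <- 1201L
  win_s <- .window(c(m$x_vest, 0), c(s$sd_vest, params$sigma_self), k = 10)
  gs <- seq(win_s[1], win_s[2], length.out = n)
  win_e <- .window(c(range(gs) - m$x_vis, 0), c(s$sd_vis, se), k = 10)
  ge <- seq(win_e[1], win_e[2], length.out = n)

  # marginal contribution of x_vis0 through the conditional prior e0 | e
  if (sd_cond == 0) {
    inner0 <- dnorm(m$x_vis0, -rho * ge, s$sd_vis0)
  } else {
    win_e0 <- .window(c(-m$x_vis0, range(rho * ge)), c(s$sd_vis0, sd_cond),
                      k = 10)
    ge0 <- seq(win_e0[1], win_e0[2], length.out = n)
    like0 <- dnorm(m$x_vis0, -ge0, s$sd_vis0) * .trapz_w(ge0)
    inner0 <- as.vector(like0 %*% outer(ge0, ge, function(a, b) {
      dnorm(a, rho * b, sd_cond)
    }))
  }

  vis_like <- outer(gs, ge, function(a, b) dnorm(m$x_vis, a - b, s$sd_vis))
  e_term <- .trapz_w(ge) * dnorm(ge, 0, se) * inner0
  inner_e <- as.vector(vis_like %*% e_term)
  g <- dnorm(m$x_vest, gs, s$sd_vest) * dnorm(gs, 0, params$sigma_self) *
    inner_e
  sum(gs * g * .trapz_w(gs)) / sum(g * .trapz_w(gs))
}

# MCI model: common-cause inference on (x_vest, x_vis) under its own
# generative story (both latents share the prior N(0, sigma_self^2)).
.mci_posterior_mean <- function(params, m, s_env) {
  sd_vis <- max(params$noise_floor, params$w_vis * abs(s_env))
  sp <- params$sigma_self
  sv <- params$sigma_vest
  win1 <- .window(c(m$x_vest, m$x_vis, 0), c(sv, sd_vis, sp))
  f1 <- function(s, moment) {
    s^moment * dnorm(m$x_vest, s, sv) * dnorm(m$x_vis, s, sd_vis) *
      dnorm(s, 0, sp)
  }
  L1 <- .integrate(function(s) f1(s, 0), win1[1], win1[2])
  m1 <- .integrate(function(s) f1(s, 1), win1[1], win1[2]) / L1
  win2 <- .window(c(m$x_vest, 0), c(sv, sp))
  f2 <- function(s, moment) {
    s^moment * dnorm(m$x_vest, s, sv) * dnorm(s, 0, sp)
  }
  Lv <- .integrate(function(s) f2(s, 0), win2[1], win2[2])
  m2 <- .integrate(function(s) f2(s, 1), win2[1], win2[2]) / Lv
  wine <- .window(c(m$x_vis, 0), c(sd_vis, sp))
  Le <- .integrate(function(e) dnorm(m$x_vis, e, sd_vis) * dnorm(e, 0, sp),
                   wine[1], wine[2])
  w1 <- params$p_common * L1
  w2 <- (1 - params$p_common) * Lv * Le
  (w1 * m1 + w2 * m2) / (w1 + w2)
}
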