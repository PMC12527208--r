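# MC/KDE likelihood machinery, parameter transforms, fitting, comparison.

test_that("parameter transforms round-trip inside the bounds", {
  for (mid in c("cci", "covariance", "fixed", "mci", "variable_weight")) {
    space <- headingci:::param_space(mid)
    set.seed(1)
    v <- space$lower + runif(nrow(space)) * (space$upper - space$lower) * 0.98 +
      0.01 * (space$upper - space$lower)
    u <- headingci:::to_unbounded(v, space)
    expect_equal(headingci:::from_unbounded(u, space), v, tolerance = 1e-8,
                 info = mid)
  }
})

test_that("compiled objective matches the reference R implementation", {
  p <- test_params("cci")
  sim <- simulate_observer(p, tiny_design(reps = 3), seed = 3)
  ct <- headingci:::condition_table(sim)
  z <- headingci:::draw_z(nrow(ct$cond), 200, seed = 7)
  for (mid in c("cci", "integration", "covariance", "fixed", "heuristic",
                "wta", "mci", "variable_weight")) {
    pp <- test_params(mid)
    rsim <- headingci:::simulate_condition_estimates(pp, ct$cond, 200, z)
    rll <- headingci:::kde_loglik(rsim, ct$resp, ct$resp_cond, 1e-9, 1e-6)
    cll <- headingci:::fast_loglik(pp, ct, z, 1e-9, 1e-6)
    expect_equal(cll, rll, tolerance = 1e-9, info = mid)
  }
})

test_that("response log-likelihood is reproducible and sane at the mode", {
  p <- test_params("cci")
  stim <- tibble::tibble(condition = "Constant", visual_velocity = 10,
                         heading_angle = 25,
                         s_self = heading_to_lateral(25), s_env = 10,
                         s_env0 = 10)
  cfg <- fit_config(n_mc = 500, seed = 1)
  resp <- heading_to_lateral(c(20, 24, 26))
  l1 <- response_loglik(p, stim, resp, cfg, seed = 5)
  l2 <- response_loglik(p, stim, resp, cfg, seed = 5)
  expect_identical(l1, l2)
  expect_true(is.finite(l1))

  # near-deterministic observer: density concentrates at its noiseless
  # estimate, so that response scores far higher than a distant one
  p0 <- test_params("cci", sigma_vest = 0.01, w_vis = 0.001,
                    noise_floor = 1e-4)
  est0 <- simulate_observer(p0, build_design(
    velocities = 10, headings = 25, conditions = "Constant", reps = 1,
    seed = 1), seed = 2)$estimate_lateral
  l_at <- response_loglik(p0, stim, est0, cfg, seed = 5)
  l_off <- response_loglik(p0, stim, est0 + 3, cfg, seed = 5)
  expect_gt(l_at, l_off + 10)
})

test_that("likelihood consistency: generating parameters beat mismatched ones", {
  p_true <- test_params("cci")
  p_wrong <- test_params("cci", sigma_vest = 4, w_vis = 0.4, p_constant = 0.1)
  d <- build_design(seed = 1)
  cfg <- fit_config(n_mc = 1000, seed = 1)
  wins <- 0
  for (i in 1:20) {
    sim <- simulate_observer(p_true, d, seed = 300 + i)
    ll_true <- total_log_posterior(p_true, sim, cfg, seed = 400 + i) -
      headingci:::log_prior(p_true)
    ll_wrong <- total_log_posterior(p_wrong, sim, cfg, seed = 400 + i) -
      headingci:::log_prior(p_wrong)
    wins <- wins + (ll_true > ll_wrong)
  }
  expect_gte(wins, 18)  # >= 90% of paired comparisons
})

test_that("log-normal priors concentrate where stated and stay out of bounded params", {
  # prior density at the log-scale mean beats 7x that value
  expect_gt(stats::dlnorm(exp(1), 1, 1, log = TRUE),
            stats::dlnorm(7 * exp(1), 1, 1, log = TRUE))
  p1 <- test_params("cci", p_constant = 0.2)
  p2 <- test_params("cci", p_constant = 0.9)
  expect_equal(headingci:::log_prior(p1), headingci:::log_prior(p2))
  # w_vis prior centered low (log-mean -2)
  expect_gt(stats::dlnorm(exp(-2), -2, 1, log = TRUE),
            stats::dlnorm(exp(0), -2, 1, log = TRUE))
  # objective finite for in-bounds params
  sim <- simulate_observer(test_params("cci"), tiny_design(), seed = 1)
  val <- total_log_posterior(test_params("cci", w_vis = 0.001), sim,
                             fit_config(n_mc = 100, seed = 1), seed = 2)
  expect_true(is.finite(val))
})

test_that("degenerate simulated estimates fall back to a narrow kernel", {
  # boundary-noise observer: simulated estimates collapse per condition
  p <- test_params("cci", sigma_vest = 1e-3, w_vis = 1e-3,
                   noise_floor = 1e-6)
  sim <- simulate_observer(p, tiny_design(reps = 1), seed = 1)
  val <- total_log_posterior(p, sim, fit_config(n_mc = 50, seed = 1), seed = 2)
  expect_true(is.finite(val))
})

test_that("model k bookkeeping and AIC identity", {
  expect_equal(model_k("cci"), 5)
  expect_equal(model_k("wta"), 5)
  expect_equal(model_k("integration"), 4)
  expect_equal(model_k("segregation"), 4)
  expect_equal(model_k("heuristic"), 4)
  expect_equal(model_k("covariance"), 5)
  expect_equal(model_k("fixed"), 5)
  expect_equal(model_k("mci"), 4)
})

test_that("fit_model is deterministic under a fixed seed and recovers roughly", {
  p <- test_params("cci", p_constant = 0.6)
  sim <- simulate_observer(p, build_design(seed = 2), seed = 3)
  cfg <- fit_config(n_mc = 200, n_restarts = 1, n_final_evals = 5,
                    maxit = 200, seed = 42)
  f1 <- fit_model(sim, "cci", cfg)
  f2 <- fit_model(sim, "cci", cfg)
  expect_identical(unclass(f1$map_params), unclass(f2$map_params))
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_equal(f1$aic, 2 * 5 - 2 * f1$log_likelihood)
  expect_s3_class(f1$trace, "tbl_df")
  # even a light search should land in the right region for the SDs
  expect_lt(abs(log(f1$map_params$sigma_vest / p$sigma_vest)), log(2))
  expect_lt(abs(log(f1$map_params$w_vis / p$w_vis)), log(2))
})

test_that("model_r2 trivial contracts hold", {
  p <- test_params("cci", sigma_vest = 0.05, w_vis = 0.005,
                   noise_floor = 1e-4)
  sim <- simulate_observer(p, build_design(reps = 2, seed = 4), seed = 5)
  fit <- structure(list(map_params = p, reference_speed = 8.5),
                   class = "heading_fit")
  # near-noiseless observer predicting its own data: R^2 ~ 1
  expect_gt(model_r2(fit, sim, n_sim = 500, seed = 6), 0.99)
  # constant predictions at the symmetric design's grand mean: R^2 ~ 0
  p_flat <- test_params("cci", sigma_self = 1e-3)
  fit0 <- structure(list(map_params = p_flat, reference_speed = 8.5),
                    class = "heading_fit")
  expect_lt(abs(model_r2(fit0, sim, n_sim = 500, seed = 6)), 0.05)
})

test_that("compare_models summarizes AIC differences with bootstrap CIs", {
  tab <- tibble::tibble(
    observer = rep(sprintf("o%02d", 1:6), each = 2),
    model_id = rep(c("cci", "integration"), 6),
    aic = rep(c(100, 130), 6)
  )
  cmp <- compare_models(tab, reference = "cci", n_boot = 200, seed = 1)
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$mean_delta_aic, 30)
  # constant shift: bootstrap CI collapses onto it
  expect_equal(cmp$ci_lower, 30)
  expect_equal(cmp$ci_upper, 30)
  expect_equal(cmp$n_favoring_model, 0)
  expect_error(compare_models(tab, reference = "mci"), "absent")
})

test_that("bootstrap CI covers a known mean at roughly the nominal rate", {
  # constant-shift population of per-observer AIC differences
  set.seed(99)
  true_mean <- 25
  cover <- 0
  for (r in 1:200) {
    delta <- rnorm(14, true_mean, 10)
    tab <- tibble::tibble(
      observer = rep(sprintf("o%02d", 1:14), 2),
      model_id = rep(c("cci", "alt"), each = 14),
      aic = c(rep(100, 14), 100 + delta)
    )
    cmp <- compare_models(tab, reference = "cci", n_boot = 300,
                          seed = 1000 + r)
    cover <- cover + (cmp$ci_lower <= true_mean && true_mean <= cmp$ci_upper)
  }
  expect_gte(cover / 200, 0.9)
})
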