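# Closed-form observer models against hand-computed values, special-case
# identities, structural properties, and the quadrature oracle.

test_that("cue summaries match hand-evaluated values", {
  p <- unit_params("cci")
  m <- unit_meas()
  s <- unit_sds()
  cs1 <- cue_summary(p, m, s, structure = 1)
  expect_equal(c(cs1$mu_K, cs1$sigma2_K), c(1, 1.5))
  cs2 <- cue_summary(p, m, s, structure = 2)
  expect_equal(c(cs2$mu_K, cs2$sigma2_K), c(1, 2))
})

test_that("covariance cue summary interpolates between the structures", {
  cases <- random_cases(100, seed = 3)
  m <- cases[, c("x_vest", "x_vis", "x_vis0")]
  s <- cases[, c("sd_vest", "sd_vis", "sd_vis0")]
  p1 <- test_params("covariance", rho = 1)
  pc <- test_params("cci")
  expect_equal(cue_summary(p1, m, s, variant = "cov"),
               cue_summary(pc, m, s, structure = 1))
  p0 <- test_params("covariance", rho = 0)
  expect_equal(cue_summary(p0, m, s, variant = "cov"),
               cue_summary(pc, m, s, structure = 2))
})

test_that("per-structure estimates match hand-evaluated values", {
  p <- unit_params("cci")
  m <- unit_meas()
  s <- unit_sds()
  expect_equal(estimate_given_structure(p, m, s, tibble::tibble(
    mu_K = 1, sigma2_K = 2)), 0.6)
  expect_equal(estimate_given_structure(p, m, s, tibble::tibble(
    mu_K = 1, sigma2_K = 1.5)), 0.625)
  expect_equal(estimate_given_structure(p, unit_meas(x_vest = 0), s,
                                        tibble::tibble(mu_K = 0, sigma2_K = 2)),
               0)
})

test_that("structure likelihood matches its closed form and the quadrature", {
  p <- unit_params("cci")
  m <- unit_meas()
  s <- unit_sds()
  expect_equal(structure_likelihood(p, m, s, 1), exp(-2.5 / 8) / (4 * pi),
               tolerance = 1e-12)
  expect_equal(structure_likelihood(p, m, s, 2),
               exp(-3 / 10) / (2 * pi * sqrt(5)), tolerance = 1e-12)
  # quick quadrature spot-check (full 50-case sweep in the acceptance suite)
  cases <- random_cases(5, seed = 11)
  p2 <- test_params("cci")
  for (i in seq_len(nrow(cases))) {
    m_i <- cases[i, c("x_vest", "x_vis", "x_vis0")]
    s_i <- cases[i, c("sd_vest", "sd_vis", "sd_vis0")]
    for (cc in 1:2) {
      expect_equal(structure_likelihood(p2, m_i, s_i, cc),
                   numeric_structure_likelihood(p2, as.list(m_i),
                                                as.list(s_i), cc),
                   tolerance = 1e-6)
    }
  }
})

test_that("structure posterior behaves at prior extremes and the hand case", {
  m <- unit_meas()
  s <- unit_sds()
  expect_equal(posterior_constant(unit_params("cci", p_constant = 1), m, s)$p_c1, 1)
  expect_equal(posterior_constant(unit_params("cci", p_constant = 0), m, s)$p_c1, 0)
  post <- posterior_constant(unit_params("cci"), m, s)
  expect_equal(post$p_c1, 0.5247, tolerance = 1e-3)
  expect_equal(post$p_c1 + post$p_c2, 1)
})

test_that("cci estimate composes its verified parts", {
  p <- unit_params("cci")
  m <- unit_meas()
  s <- unit_sds()
  est <- estimate_heading(p, m, s)
  expect_equal(est$s_hat_c1, 0.625)
  expect_equal(est$s_hat_c2, 0.6)
  expect_equal(est$s_hat, 0.6131, tolerance = 1e-3)
  # symmetry about zero
  z <- estimate_heading(p, unit_meas(0, 0, 0), s)
  expect_equal(z$s_hat, 0)
})

test_that("special-case identities hold exactly", {
  cases <- random_cases(100, seed = 5)
  m <- cases[, c("x_vest", "x_vis", "x_vis0")]
  s <- cases[, c("sd_vest", "sd_vis", "sd_vis0")]
  cci1 <- estimate_heading(test_params("cci", p_constant = 1), m, s)
  int <- estimate_heading(test_params("integration"), m, s)
  expect_equal(cci1$s_hat, int$s_hat)
  cci0 <- estimate_heading(test_params("cci", p_constant = 0), m, s)
  seg <- estimate_heading(test_params("segregation"), m, s)
  expect_equal(cci0$s_hat, seg$s_hat)
  cov1 <- estimate_heading(test_params("covariance", rho = 1), m, s)
  expect_equal(cov1$s_hat, int$s_hat)
  cov0 <- estimate_heading(test_params("covariance", rho = 0), m, s)
  expect_equal(cov0$s_hat, seg$s_hat)
})

test_that("integration ignores nulled contextual input, segregation ignores x_vis0", {
  p <- test_params("integration")
  s <- unit_sds(sd_vest = 1.5, sd_vis = 1, sd_vis0 = 2)
  # mu_K = 0 when x_vis0 = (sigma_env^2 + sd_vis0^2) / sigma_env^2 * x_vis
  m <- unit_meas(x_vest = 0, x_vis = 3, x_vis0 = (9 + 4) / 9 * 3)
  expect_equal(estimate_heading(p, m, s)$s_hat, 0, tolerance = 1e-12)

  pseg <- test_params("segregation")
  outs <- sapply(c(-100, -1, 0, 1, 100), function(v) {
    estimate_heading(pseg, unit_meas(1, 1, v), s)$s_hat
  })
  expect_true(all(outs == outs[1]))
})

test_that("covariance model matches the hand-evaluated case", {
  p <- unit_params("covariance", rho = 0.5)
  est <- estimate_heading(p, unit_meas(1, 1, 2), unit_sds())
  expect_equal(est$s_hat, 0.5, tolerance = 1e-12)
})

test_that("fixed-weight model is the stated weighted sum", {
  p <- test_params("fixed", alpha_vest = 0.5, alpha_mom = 0.3, alpha_cont = 0.2)
  expect_equal(estimate_heading(p, unit_meas(1, 1, 0))$s_hat, 1)
  expect_equal(estimate_heading(
    test_params("fixed", alpha_vest = 1, alpha_mom = 0, alpha_cont = 0),
    unit_meas(2.7, 1, 5))$s_hat, 2.7)
  expect_equal(estimate_heading(
    test_params("fixed", alpha_vest = 0, alpha_mom = 0, alpha_cont = 0),
    unit_meas(2.7, 1, 5))$s_hat, 0)
})

test_that("heuristic rule follows the printed inequality with ties to C=1", {
  p <- unit_params("heuristic")
  m <- unit_meas(1, 1, 0)
  s <- unit_sds()
  # tie: |x_vest - mu_K1| = |x_vest - mu_K2| = 0 -> C=1 branch
  expect_equal(estimate_heading(p, m, s)$s_hat, 0.625)
  # x_vis0 = 2 makes the C=1 cue conflict larger -> printed rule picks C=1
  m2 <- unit_meas(1, 1, 2)
  est <- estimate_heading(p, m2, s)
  expect_equal(est$s_hat, est$s_hat_c1)
  # inverted mode flips the selection when the inequality is strict
  est_inv <- estimate_heading(p, m2, s, heuristic_invert = TRUE)
  expect_equal(est_inv$s_hat, est_inv$s_hat_c2)
})

test_that("winner-take-all commits to the more probable structure", {
  p <- unit_params("wta")
  est <- estimate_heading(p, unit_meas(1, 1, 0), unit_sds())
  expect_equal(est$s_hat, 0.625)  # p_c1 ~ 0.525 >= 0.5
  cases <- random_cases(50, seed = 9)
  m <- cases[, c("x_vest", "x_vis", "x_vis0")]
  s <- cases[, c("sd_vest", "sd_vis", "sd_vis0")]
  est <- estimate_heading(test_params("wta"), m, s)
  expect_true(all(est$s_hat == est$s_hat_c1 | est$s_hat == est$s_hat_c2))
})

test_that("mci model matches hand values and ignores x_vis0", {
  p <- unit_params("mci", w_vis = 0.2)
  m <- unit_meas(1, 1, 0)
  # s_env = 5 gives the observer-assumed sd_vis = 1
  expect_equal(estimate_heading(p, m, s_env = 5)$s_hat, 0.5962,
               tolerance = 1e-3)
  # certainty of a common cause: equal-reliability fusion (x_vest + x_vis)/3
  p1 <- unit_params("mci", w_vis = 0.2, p_common = 1)
  expect_equal(estimate_heading(p1, unit_meas(2, 0.5, 0), s_env = 5)$s_hat,
               2.5 / 3)
  # invariance to the pre-motion signal
  outs <- sapply(c(-50, 0, 50), function(v) {
    estimate_heading(p, unit_meas(1, 1, v), s_env = 5)$s_hat
  })
  expect_true(all(outs == outs[1]))
})

test_that("averaging, symmetry and shrinkage properties hold on random draws", {
  cases <- random_cases(200, seed = 13)
  m <- cases[, c("x_vest", "x_vis", "x_vis0")]
  s <- cases[, c("sd_vest", "sd_vis", "sd_vis0")]
  neg <- -m
  for (mid in c("cci", "integration", "segregation", "covariance", "fixed",
                "heuristic", "wta")) {
    p <- test_params(mid)
    est <- estimate_heading(p, m, s, s_env = rep(5, nrow(m)))
    # odd symmetry: negating all measurements negates the estimate
    est_neg <- estimate_heading(p, neg, s, s_env = rep(5, nrow(m)))
    expect_equal(est_neg$s_hat, -est$s_hat, tolerance = 1e-12,
                 info = mid)
    if (mid %in% c("cci", "wta")) {
      lo <- pmin(est$s_hat_c1, est$s_hat_c2) - 1e-12
      hi <- pmax(est$s_hat_c1, est$s_hat_c2) + 1e-12
      expect_true(all(est$s_hat >= lo & est$s_hat <= hi), info = mid)
    }
  }
  # shrinkage for the Bayesian models: prior pulls toward zero
  for (mid in c("cci", "integration", "segregation", "covariance")) {
    p <- test_params(mid)
    est <- estimate_heading(p, m, s)
    cs1 <- cue_summary(p, m, s, structure = 1,
                       variant = if (mid == "covariance") "cov" else "cci")
    cs2 <- cue_summary(p, m, s, structure = 2,
                       variant = if (mid == "covariance") "cov" else "cci")
    bound <- abs(m$x_vest) + pmax(abs(cs1$mu_K), abs(cs2$mu_K)) + 1e-12
    expect_true(all(abs(est$s_hat) <= bound), info = mid)
  }
})

test_that("structure posterior peaks where the constant story fits best", {
  p <- test_params("cci")
  s <- unit_sds(1.5, 1, 2)
  m0 <- unit_meas(2, 1, 0)
  # x_vis0 maximizing the C=1 likelihood, found numerically
  grid <- seq(-30, 30, by = 0.05)
  ll <- sapply(grid, function(v) {
    structure_loglik(p, unit_meas(2, 1, v), s, 1)
  })
  x_star <- grid[which.max(ll)]
  offsets <- seq(0, 20, by = 0.5)
  p_up <- sapply(offsets, function(d) {
    posterior_constant(p, unit_meas(2, 1, x_star + d), s)$p_c1
  })
  p_dn <- sapply(offsets, function(d) {
    posterior_constant(p, unit_meas(2, 1, x_star - d), s)$p_c1
  })
  expect_true(all(diff(p_up) <= 1e-12))
  expect_true(all(diff(p_dn) <= 1e-12))
})

test_that("closed forms agree with the quadrature oracle on random draws", {
  # spot check; the full 100-draw sweep runs in the acceptance suite
  cases <- random_cases(8, seed = 17)
  m <- cases[, c("x_vest", "x_vis", "x_vis0")]
  s <- cases[, c("sd_vest", "sd_vis", "sd_vis0")]
  for (mid in c("cci", "integration", "segregation", "covariance", "mci")) {
    p <- test_params(mid)
    est <- estimate_heading(p, m, s, s_env = rep(4, nrow(m)))
    oracle <- numeric_posterior_mean(p, m, s, s_env = rep(4, nrow(m)),
                                     model_id = mid)
    expect_equal(est$s_hat, oracle, tolerance = 1e-3, info = mid)
  }
})
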