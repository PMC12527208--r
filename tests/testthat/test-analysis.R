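# Bias tables, regression decomposition, variable-weight rule.

test_that("perfect responses give zero bias everywhere", {
  d <- build_design(reps = 1, seed = 1)
  dat <- dplyr::mutate(tibble::as_tibble(d), observer = "o1",
                       reported_heading = heading_angle)
  b <- heading_bias(dat)
  expect_true(all(b$mean_bias == 0))
  expect_true(all(b$n > 0))
  expect_setequal(unique(b$visual_speed), c(0, 5, 10))
})

test_that("bias table is invariant to left/right mirroring of the dataset", {
  p <- test_params("cci")
  sim <- simulate_observer(p, build_design(reps = 2, seed = 2), seed = 3)
  mirrored <- sim
  mirrored$visual_velocity <- -mirrored$visual_velocity
  mirrored$heading_angle <- -mirrored$heading_angle
  mirrored$reported_heading <- -mirrored$reported_heading
  b1 <- heading_bias(sim)
  b2 <- heading_bias(mirrored)
  merged <- dplyr::inner_join(
    b1, b2, by = c("observer", "condition", "visual_speed"))
  expect_equal(nrow(merged), nrow(b1))
  # 0 deg/s cells flip sign under full mirroring (they are never realigned);
  # moving-stimulus cells are identical because the flip realigns them
  mv <- merged[merged$visual_speed > 0, ]
  expect_equal(mv$mean_bias.x, mv$mean_bias.y, tolerance = 1e-12)
  z <- merged[merged$visual_speed == 0, ]
  expect_equal(z$mean_bias.x, -z$mean_bias.y, tolerance = 1e-12)
})

test_that("noiseless momentary-vision observer shows the -s_env bias", {
  d <- build_design(reps = 1, seed = 4)
  p <- test_params("fixed", alpha_vest = 0, alpha_mom = 1, alpha_cont = 0,
                   sigma_vest = 1e-9, w_vis = 0, noise_floor = 1e-9)
  sim <- simulate_observer(p, d, seed = 5)
  b <- heading_bias(sim)
  # right visual motion at 10 deg/s: estimate centers on s_self - 10
  cell <- sim[sim$visual_velocity == 10 & sim$condition == "Constant", ]
  expected <- mean(lateral_to_heading(cell$s_self - cell$s_env) -
                     cell$heading_angle)
  got <- b$mean_bias[b$condition == "Constant" & b$visual_speed == 10]
  expect_equal(got, expected, tolerance = 1e-6)
  expect_lt(got, -10)  # strongly opposite to the visual motion
})

test_that("regression decomposition recovers noiseless weights exactly", {
  d <- tibble::as_tibble(build_design(reps = 2, seed = 6))
  d$observer <- "o1"
  est <- 0.2 * d$s_self + 0.3 * (d$s_self - d$s_env) +
    0.5 * (d$s_self - d$s_env + d$s_env0)
  d$estimate_lateral <- est
  d$reported_heading <- lateral_to_heading(est)
  # noiseless data: lm warns about a perfect fit, which is the point here
  reg <- suppressWarnings(regression_decomposition(d))
  co <- reg$coefficients
  expect_equal(co$estimate[co$term == "pred_vest"], 0.2, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "pred_mom"], 0.3, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "pred_cont"], 0.5, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "(Intercept)"], 0, tolerance = 1e-8)
})

test_that("vestibular-only observer loads on the vestibular predictor alone", {
  d <- build_design(reps = 4, seed = 7)
  p <- test_params("fixed", alpha_vest = 1, alpha_mom = 0, alpha_cont = 0,
                   sigma_vest = 0.5, w_vis = 0.1)
  sim <- simulate_observer(p, d, seed = 8)
  co <- regression_decomposition(sim)$coefficients
  expect_equal(co$estimate[co$term == "pred_vest"], 1, tolerance = 0.1)
  expect_lt(abs(co$estimate[co$term == "pred_mom"]), 0.05)
  expect_lt(abs(co$estimate[co$term == "pred_cont"]), 0.05)
})

test_that("single-condition datasets are rejected as rank-deficient", {
  d <- build_design(conditions = "Constant", reps = 2, seed = 9)
  dat <- dplyr::mutate(tibble::as_tibble(d), observer = "o1",
                       reported_heading = heading_angle)
  expect_error(regression_decomposition(dat), "rank-deficient")
})

test_that("variable-weight estimate rule interpolates per the true structure", {
  cases <- random_cases(50, seed = 10)
  m <- cases[, c("x_vest", "x_vis", "x_vis0")]
  s <- cases[, c("sd_vest", "sd_vis", "sd_vis0")]
  p <- test_params("variable_weight", alpha_1 = 0.9, alpha_2 = 0.2)
  flags <- rep(c(TRUE, FALSE), length.out = 50)
  est <- estimate_heading(p, m, s, const_group = flags)
  expect_equal(est$s_hat[flags],
               0.9 * est$s_hat_c1[flags] + 0.1 * est$s_hat_c2[flags])
  expect_equal(est$s_hat[!flags],
               0.2 * est$s_hat_c1[!flags] + 0.8 * est$s_hat_c2[!flags])
  expect_error(estimate_heading(p, m, s), "const_group")
})
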