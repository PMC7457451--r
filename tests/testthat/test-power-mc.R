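# the study's published summary inputs, reused across the power tests
published_inputs <- function() {
  sp <- (30.41 - 26.65) / (3.51 * sqrt(1 / 128 + 1 / 121))
  derive_power_inputs(t_stat = 3.51, df = 247, group_ns = c(128, 121),
                      slope_mediator_outcome = -0.009,
                      slope_predictor_outcome = -0.23,
                      sd_mediator = sp, sd_outcome = 0.50)
}

test_that("correlations are reconstructed from printed summaries", {
  pin <- published_inputs()
  R <- pin$correlations
  expect_equal(R["predictor", "mediator"], 3.51 / sqrt(3.51^2 + 247))
  expect_equal(round(R["predictor", "mediator"], 4), 0.2180)
  expect_equal(round(-0.009 * 8.45 / 0.50, 4), -0.1521)  # slope identity
  expect_equal(R["mediator", "outcome"], -0.009 * pin$sds[2] / 0.50)
  p1 <- 128 / 249
  expect_equal(pin$sds[1], sqrt(p1 * (1 - p1)))
  expect_equal(pin$n, 249)

  # t = 0 gives a zero point-biserial correlation
  z <- derive_power_inputs(0, 247, c(128, 121), -0.009, -0.23, 8.45, 0.5)
  expect_equal(z$correlations["predictor", "mediator"], 0)

  # df inconsistent with group sizes
  expect_error(derive_power_inputs(3.51, 200, c(128, 121), -0.009, -0.23,
                                   8.45, 0.5),
               class = "refersdt_invalid_config")
  # an impossible correlation pattern is rejected as not PSD
  expect_error(derive_power_inputs(50, 247, c(128, 121), 0.058, -4.9,
                                   8.45, 0.5),
               class = "refersdt_not_psd")
})

test_that("power_spec validates the correlation matrix", {
  R <- diag(3)
  expect_s3_class(power_spec(R, c(0.5, 8, 0.5), 100), "power_spec")
  R_bad <- R; R_bad[1, 2] <- 0.5  # asymmetric
  expect_error(power_spec(R_bad, c(0.5, 8, 0.5), 100),
               class = "refersdt_invalid_config")
  R_npsd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(power_spec(R_npsd, c(1, 1, 1), 100), class = "refersdt_not_psd")
})

test_that("a fixed seed gives bit-identical power", {
  pin <- published_inputs()
  spec <- power_spec(pin$correlations, pin$sds, n = 100, n_reps = 200,
                     n_draws = 500, seed = 77)
  expect_identical(mc_power_indirect(spec)$power, mc_power_indirect(spec)$power)
  r <- mc_power_indirect(spec)
  expect_equal(r$mc_se, sqrt(r$power * (1 - r$power) / 200))
})

test_that("the interval test keeps its size under a null indirect effect", {
  # a zero partial b-path (mediator-outcome correlation exactly what the
  # predictor induces, r_my = r_xm * r_xy): the indirect effect is zero and
  # the rejection rate stays at or below the interval's nominal size
  r_xm <- 0.218; r_xy <- -0.23
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- r_xm
  R[1, 3] <- R[3, 1] <- r_xy
  R[2, 3] <- R[3, 2] <- r_xm * r_xy
  spec <- power_spec(R, c(0.5, 8.45, 0.5), n = 249, n_reps = 600,
                     n_draws = 2000, seed = 11)
  r <- mc_power_indirect(spec)
  expect_lte(r$power, 0.05 + 2 * sqrt(0.05 * 0.95 / 600) + 0.02)
})

test_that("power increases with n and with the effect size", {
  pin <- published_inputs()
  pw <- function(n, reps = 800) {
    mc_power_indirect(power_spec(pin$correlations, pin$sds, n = n,
                                 n_reps = reps, n_draws = 2000,
                                 seed = 303))$power
  }
  p_small <- pw(100); p_mid <- pw(249); p_big <- pw(900)
  se2 <- 2 * sqrt(0.25 / 800)
  expect_gte(p_mid, p_small - se2)
  expect_gte(p_big, p_mid - se2)
  expect_gt(p_big, p_small)

  # doubling both path correlations raises power
  R2 <- pin$correlations
  R2["predictor", "mediator"] <- R2["mediator", "predictor"] <- 0.44
  R2["mediator", "outcome"] <- R2["outcome", "mediator"] <- -0.30
  p_strong <- mc_power_indirect(power_spec(R2, pin$sds, n = 249, n_reps = 800,
                                           n_draws = 2000, seed = 303))$power
  expect_gt(p_strong, p_mid + se2)
})

test_that("required_n_for_power finds the smallest grid n; unreachable errors", {
  pin <- published_inputs()
  search <- required_n_for_power(pin$correlations, pin$sds, 0.5,
                                 n_grid = seq(100, 900, by = 100),
                                 n_reps = 400, n_draws = 1000, seed = 17)
  expect_true(search$n %in% seq(100, 900, by = 100))
  expect_gte(search$power_at_n, 0.5)
  # the previous grid point (if evaluated) fell short
  ev <- search$evaluations
  below <- ev$n[ev$n < search$n]
  if (length(below) > 0) expect_lt(max(ev$power[ev$n == max(below)]), 0.5)

  # target 0 -> smallest grid n
  t0 <- required_n_for_power(pin$correlations, pin$sds, 0,
                             n_grid = c(50, 100), n_reps = 50,
                             n_draws = 200, seed = 1)
  expect_equal(t0$n, 50)

  # zero indirect effect never reaches 80%
  R0 <- diag(3)
  expect_error(
    required_n_for_power(R0, c(0.5, 8, 0.5), 0.8, n_grid = c(100, 500),
                         n_reps = 200, n_draws = 500, seed = 2),
    class = "refersdt_target_unreachable"
  )
})
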