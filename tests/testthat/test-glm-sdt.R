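test_that("saturated probit reproduces empirical probits for one responder", {
  # fixed-effects probit on a single responder's 48 trials equals the
  # closed-form indices computed on the UNCORRECTED rates
  set.seed(123)
  for (i in 1:10) {
    hits <- sample(1:23, 1); fas <- sample(1:23, 1)
    ds <- make_count_study(hits, fas)
    fit <- fit_probit_sdt(ds, random_effects = "none")
    expect_true(fit$converged)
    H <- hits / 24; FA <- fas / 24
    co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
    expect_equal(unname(co["signal"]), qnorm(H) - qnorm(FA), tolerance = 1e-3)
    expect_equal(unname(-co["(Intercept)"]), -0.5 * (qnorm(H) + qnorm(FA)),
                 tolerance = 1e-3)
    expect_equal(fit$n_obs, 48)
  }
})

test_that("population d-prime and criterion from the GLM track the closed form", {
  # comparability of the two routes on a full design with modest responder
  # heterogeneity (strong unmodeled heterogeneity attenuates the marginal
  # probit, which is why the routes are comparable but not identical)
  sim <- generate_study(sim_config(n_responders = 200, dprime_sd = 0.15,
                                   beta_ppv = 0, beta_gender = 0,
                                   criterion_noise_sd = 0.15, seed = 5))
  fit <- fit_probit_sdt(sim$study, random_effects = "none")
  sdt <- glm_to_sdt(fit)
  idx <- compute_indices(sim$study)
  d_glm <- sdt$estimate[sdt$effect_on == "d_prime"]
  c_glm <- sdt$estimate[sdt$effect_on == "criterion"]
  expect_lt(abs(d_glm - mean(idx$d_prime)), 0.05)
  expect_lt(abs(c_glm - mean(idx$criterion)), 0.05)
})

test_that("coefficient mapping follows the +/-0.5 signal coding convention", {
  sim <- generate_study(sim_config(n_responders = 60, seed = 9))
  fit <- fit_probit_sdt(sim$study, covariates = "gender",
                        random_effects = "none")
  sdt <- glm_to_sdt(fit)
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  # intercept-side terms act on -c; signal-side terms act on d'
  expect_equal(sdt$estimate[sdt$term == "(reference)" &
                              sdt$effect_on == "criterion"],
               unname(-co["(Intercept)"]))
  expect_equal(sdt$estimate[sdt$term == "(reference)" &
                              sdt$effect_on == "d_prime"],
               unname(co["signal"]))
  expect_equal(sdt$estimate[sdt$term == "female" &
                              sdt$effect_on == "criterion"],
               unname(-co["female"]))
  expect_equal(sdt$estimate[sdt$term == "female" &
                              sdt$effect_on == "d_prime"],
               unname(co["signal:female"]))

  # sign contract: a level that refers more gets a lower criterion. The
  # generator makes women refer more (beta_gender < 0 on c), so the female
  # main effect on the linear predictor is positive and the mapped criterion
  # shift negative.
  expect_gt(unname(co["female"]), 0)
  expect_lt(sdt$estimate[sdt$term == "female" & sdt$effect_on == "criterion"], 0)
})

test_that("simulation truth is covered by fixed-effects probit CIs", {
  # data generated with known population b0 = -c, b1 = d'
  set.seed(77)
  covered_b0 <- covered_b1 <- 0
  reps <- 25
  for (i in seq_len(reps)) {
    sim <- generate_study(sim_config(
      n_responders = 100, dprime_mean = 1.0, dprime_sd = 0,
      criterion_mean = 0.3, beta_ppv = 0, beta_gender = 0,
      criterion_noise_sd = 0, seed = 1000 + i))
    fit <- fit_probit_sdt(sim$study, random_effects = "none")
    co <- fit$coefficients
    b0 <- co[co$term == "(Intercept)", ]
    b1 <- co[co$term == "signal", ]
    covered_b0 <- covered_b0 + (b0$ci_low <= -0.3 && -0.3 <= b0$ci_high)
    covered_b1 <- covered_b1 + (b1$ci_low <= 1.0 && 1.0 <= b1$ci_high)
  }
  expect_gte(covered_b0 / reps, 0.8)
  expect_gte(covered_b1 / reps, 0.8)
})

test_that("mixed-effects probit estimates responder-level deviations", {
  sim <- generate_study(sim_config(n_responders = 40, seed = 21))
  fit <- fit_probit_sdt(sim$study, random_effects = "intercept")
  expect_s4_class(fit$fit, "glmerMod")
  expect_equal(fit$n_obs, 40 * 48)
  vc <- as.data.frame(lme4::VarCorr(fit$fit))
  # responders genuinely differ in criterion, so the intercept variance is > 0
  expect_gt(vc$sdcor[1], 0.05)
  sdt <- glm_to_sdt(fit)
  expect_true(all(c("d_prime", "criterion") %in% sdt$effect_on))
})

test_that("complete separation is a named error; non-convergence is flagged", {
  # one gender level never refers urgently
  dec <- list(
    R1 = c("urgent", "urgent", "none", "none"),
    R2 = rep("none", 4),
    R3 = c("urgent", "none", "urgent", "none"),
    R4 = rep("none", 4)
  )
  ds <- make_study(dec, genders = c("female", "male", "female", "male"))
  expect_error(fit_probit_sdt(ds, covariates = "gender",
                              random_effects = "none"),
               regexp = "female|male",
               class = "refersdt_separation")

  fake <- fit_probit_sdt(make_count_study(20, 10), random_effects = "none")
  fake$converged <- FALSE
  expect_error(glm_to_sdt(fake), class = "refersdt_not_converged")
})
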