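test_that("count_rates counts urgent decisions by vignette class", {
  ds <- make_count_study(hits = 20, fas = 10)
  rt <- count_rates(ds, "R1")
  expect_equal(unclass(rt)[c("n_positive", "n_negative", "hits", "false_alarms")],
               list(n_positive = 24, n_negative = 24, hits = 20, false_alarms = 10))

  # routine decisions collapse into non-urgent
  ds_routine <- make_study(list(R1 = rep("routine", 48)), n_pos = 24, n_neg = 24)
  rt2 <- count_rates(ds_routine, "R1")
  expect_equal(rt2$hits, 0)
  expect_equal(rt2$false_alarms, 0)

  # a responder seeing only positive vignettes has undefined rates
  only_pos <- make_study(list(R1 = rep("urgent", 4)), n_pos = 4, n_neg = 0)
  expect_error(count_rates(only_pos, "R1"), class = "refersdt_undefined_rates")
})

test_that("the 0.5 correction gives (h+0.5)/(N+1) and stays interior", {
  rt <- function(h, f) list(n_positive = 24, n_negative = 24, hits = h,
                            false_alarms = f)
  expect_equal(corrected_rates(rt(20, 10)),
               c(hit_rate = 20.5 / 25, fa_rate = 10.5 / 25))
  expect_equal(corrected_rates(rt(24, 0)), c(hit_rate = 0.98, fa_rate = 0.02))
  expect_equal(corrected_rates(rt(0, 0)), c(hit_rate = 0.02, fa_rate = 0.02))

  # property: all integer counts 0..N map strictly inside (0, 1)
  for (N in c(1, 5, 24, 100)) {
    r <- (0:N + 0.5) / (N + 1)
    expect_true(all(r > 0 & r < 1))
  }
})

test_that("dprime and criterion match the independent inverse-normal oracle", {
  cases <- rbind(
    c(0.82, 0.42), c(0.8, 0.2), c(0.3, 0.1), c(0.5, 0.5), c(0.98, 0.02)
  )
  for (i in seq_len(nrow(cases))) {
    h <- cases[i, 1]; f <- cases[i, 2]
    zh <- z_oracle(h); zf <- z_oracle(f)
    expect_equal(dprime(h, f), zh - zf, tolerance = 1e-4)
    expect_equal(criterion(h, f), -0.5 * (zh + zf), tolerance = 1e-4)
  }
  # frozen oracle values (1e-4 absolute)
  expect_lt(abs(dprime(0.82, 0.42) - 1.1173), 1e-4)
  expect_lt(abs(criterion(0.82, 0.42) - (-0.3567)), 1e-4)
  expect_lt(abs(dprime(0.8, 0.2) - 1.6832), 1e-4)
  expect_equal(criterion(0.8, 0.2), 0)
  expect_lt(abs(criterion(0.3, 0.1) - 0.9030), 1e-4)
  expect_equal(dprime(0.5, 0.5), 0)

  expect_error(dprime(1, 0.5), class = "refersdt_domain_error")
  expect_error(criterion(0.5, 0), class = "refersdt_domain_error")
})

test_that("dprime/criterion obey antisymmetry, symmetry and monotonicity", {
  r <- seq(0.05, 0.95, by = 0.05)
  for (a in r) for (b in r) {
    expect_equal(dprime(a, b), -dprime(b, a), tolerance = 1e-12)
    expect_equal(criterion(a, b), criterion(b, a), tolerance = 1e-12)
  }
  # c == 0 on the H = 1 - FA diagonal
  expect_equal(criterion(r, 1 - r), rep(0, length(r)), tolerance = 1e-10)
  # strict monotonicity along the grid
  for (b in r) {
    expect_true(all(diff(dprime(r, b)) > 0))
    expect_true(all(diff(criterion(r, b)) < 0))
  }
  for (a in r) {
    expect_true(all(diff(dprime(a, r)) < 0))
    expect_true(all(diff(criterion(a, r)) < 0))
  }
})

test_that("compute_indices applies correction and the defining formulas", {
  # all 48 decisions urgent: corrected rates (0.98, 0.98)
  all_urgent <- make_count_study(24, 24)
  idx <- compute_indices(all_urgent)
  expect_equal(idx$d_prime, 0, tolerance = 1e-4)
  expect_equal(idx$criterion, -2.0537, tolerance = 1e-4)
  expect_true(idx$corrected)

  # perfect responder: urgent on all positives, none on negatives
  perfect <- make_count_study(24, 0)
  idx2 <- compute_indices(perfect)
  expect_equal(idx2$d_prime, 4.1075, tolerance = 1e-4)
  expect_equal(idx2$criterion, 0, tolerance = 1e-10)

  # indices satisfy the defining formulas exactly given the corrected rates
  sim <- generate_study(sim_config(n_responders = 20, seed = 11))
  idx3 <- compute_indices(sim$study)
  expect_equal(idx3$d_prime, qnorm(idx3$hit_rate) - qnorm(idx3$fa_rate))
  expect_equal(idx3$criterion, -0.5 * (qnorm(idx3$hit_rate) + qnorm(idx3$fa_rate)))
  expect_equal(idx3$hit_rate, (idx3$hits + 0.5) / (idx3$n_positive + 1))

  empty <- all_urgent
  empty$responses <- empty$responses[0, ]
  expect_error(compute_indices(empty), class = "refersdt_empty_input")
})

test_that("pooled rates are raw ratios over the combined pool", {
  ds <- make_table1_study()
  pr <- pooled_rates(ds)
  expect_equal(unname(pr["hit_rate"]), 4474 / 6048, tolerance = 1e-12)
  expect_equal(unname(pr["fa_rate"]), 2802 / 6048, tolerance = 1e-12)
  expect_equal(round(unname(pr), 2), c(0.74, 0.46))

  expect_equal(unname(pooled_rates(make_count_study(24, 24))), c(1, 1))
  expect_equal(unname(pooled_rates(make_study(list(R1 = rep("none", 4))))), c(0, 0))
})

test_that("summaries use sample SD and the midpoint median", {
  idx <- compute_indices(generate_study(sim_config(n_responders = 4, seed = 3))$study)
  idx$d_prime <- c(0, 1, 0.5, 0.5)
  idx$criterion <- rep(0.5, 4)
  s <- summarize_indices(idx)
  expect_equal(s$mean, c(0.5, 0.5))
  expect_equal(s$sd[2], 0)
  expect_equal(s$median[1], 0.5)
  expect_equal(s$sd[1], sd(c(0, 1, 0.5, 0.5)))
  expect_equal(s$n, c(4, 4))
  expect_true(all(s$min <= s$median & s$median <= s$max))
  expect_error(summarize_indices(idx[1, ]), class = "refersdt_empty_input")
})

test_that("summaries recover a generating d-prime mean at n = 252", {
  # truth-level check: estimation adds noise but not (much) bias
  reps <- 20
  means <- numeric(reps)
  for (i in seq_len(reps)) {
    sim <- generate_study(sim_config(seed = 100 + i))
    means[i] <- summarize_indices(compute_indices(sim$study))$mean[1]
  }
  # small attenuation from the 0.5 correction is expected; 3 MC SEs around it
  mc_se <- sd(means) / sqrt(reps)
  expect_lt(abs(mean(means) - 0.79), 0.06 + 3 * mc_se)
})

test_that("theoretical ROC curves satisfy the isosensitivity identity", {
  roc0 <- theoretical_roc(0, n_points = 25)
  expect_equal(roc0$hit_rate, roc0$fa_rate)

  roc <- theoretical_roc(c(1, 2, 3), n_points = 50)
  expect_equal(qnorm(roc$hit_rate) - qnorm(roc$fa_rate), roc$d_prime,
               tolerance = 1e-10)
  expect_equal(nrow(roc), 150)

  expect_equal(theoretical_roc(1.6832425, fa_rates = 0.2)$hit_rate, 0.8,
               tolerance = 1e-6)
  expect_equal(theoretical_roc(3, fa_rates = 0.5)$hit_rate, pnorm(3))
})

test_that("generative probabilities invert exactly through dprime/criterion", {
  # round-trip: H = pnorm(d/2 - c), FA = pnorm(-d/2 - c) recovers (d, c)
  set.seed(42)
  for (i in 1:25) {
    d <- runif(1, 0, 3); cc <- runif(1, -1.5, 1.5)
    H <- pnorm(d / 2 - cc); FA <- pnorm(-d / 2 - cc)
    expect_equal(dprime(H, FA), d, tolerance = 1e-10)
    expect_equal(criterion(H, FA), cc, tolerance = 1e-10)
  }
})
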