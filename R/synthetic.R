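#' Simulation configuration
#'
#' Defines the generating model for a synthetic referral signal-detection
#' study. Defaults emulate a 252-responder x 48-vignette colorectal-cancer
#' vignette study: 24 positive and 24 negative vignettes (risk above/below the
#' 3% threshold), 52% female responders, positively skewed experience
#' (median ~13 years), true discrimination d' ~ Normal(0.79, 0.32), and a true
#' criterion built from practice PPV and gender,
#' `c = b0 + 0.05 * ppv - 0.17 * female + noise`, with the intercept chosen so
#' the mean criterion is `criterion_mean` and the noise SD chosen so
#' SD(c) is about 0.50. Non-urgent decisions are split into routine vs. no
#' referral at the fixed share 1024/4820. Stress-from-uncertainty scores are
#' gender-linked (male mean 26.65, female +3.76, SD 8.45, truncated to
#' [8, 48]) with 3 missing values among women. A second (prior) task shares
#' the criterion at correlation 0.39 and d' at correlation 0.
#'
#' @param n_responders Number of responders.
#' @param n_positive_vignettes,n_negative_vignettes Vignettes per class.
#' @param prop_female Proportion of female responders (count is rounded).
#' @param experience_meanlog,experience_sdlog,experience_range Log-normal
#'   parameters and truncation range (years) for experience; defaults target
#'   median 13 with quartiles near 8 and 24.
#' @param ppv_range,sensitivity_range Uniform ranges (percentage points) for
#'   practice PPV and sensitivity.
#' @param dprime_mean,dprime_sd True d' distribution.
#' @param criterion_mean Target mean of the true criterion.
#' @param beta_ppv,beta_gender Generating coefficients of the criterion on PPV
#'   (per percentage point) and on female gender.
#' @param criterion_noise_sd Residual SD of the criterion model (default 0.449
#'   so that the marginal SD of c is about 0.50 under the default covariates).
#' @param routine_share_of_nonurgent Probability a non-urgent decision is a
#'   routine (rather than no) referral.
#' @param stress_mean_male,stress_gender_effect,stress_sd,stress_range,stress_n_missing
#'   Stress-score model: male mean, additive female effect, residual SD,
#'   truncation range of the scale, and number of missing scores (assigned to
#'   women, emulating non-completion).
#' @param prop_prior_task Proportion of responders flagged as having done the
#'   prior task (used by [generate_cross_task()]).
#' @param cross_task_criterion_r,cross_task_dprime_r Cross-task correlations
#'   of criterion and d'.
#' @param cross_task_criterion_mean,cross_task_criterion_sd,cross_task_dprime_mean,cross_task_dprime_sd
#'   Marginal distribution of the prior task's indices (defaults emulate a
#'   more conservative lung-cancer task: mean c 0.50, SD 0.75; mean d' 0.77,
#'   SD 0.36).
#' @param seed Optional integer seed; when given, generation is deterministic.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_responders = 252,
                       n_positive_vignettes = 24,
                       n_negative_vignettes = 24,
                       prop_female = 0.52,
                       experience_meanlog = log(13),
                       experience_sdlog = 0.8144,
                       experience_range = c(1, 42),
                       ppv_range = c(2, 16),
                       sensitivity_range = c(30, 70),
                       dprime_mean = 0.79,
                       dprime_sd = 0.32,
                       criterion_mean = -0.29,
                       beta_ppv = 0.05,
                       beta_gender = -0.17,
                       criterion_noise_sd = 0.449,
                       routine_share_of_nonurgent = 1024 / 4820,
                       stress_mean_male = 26.65,
                       stress_gender_effect = 3.76,
                       stress_sd = 8.45,
                       stress_range = c(8, 48),
                       stress_n_missing = 3,
                       prop_prior_task = 165 / 252,
                       cross_task_criterion_r = 0.39,
                       cross_task_dprime_r = 0,
                       cross_task_criterion_mean = 0.50,
                       cross_task_criterion_sd = 0.75,
                       cross_task_dprime_mean = 0.77,
                       cross_task_dprime_sd = 0.36,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (cfg$n_responders < 1 || cfg$n_positive_vignettes < 1 ||
      cfg$n_negative_vignettes < 1) {
    refersdt_abort("counts of responders and vignettes must be positive",
                   "refersdt_invalid_config")
  }
  for (p in c("prop_female", "routine_share_of_nonurgent", "prop_prior_task")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      refersdt_abort(sprintf("%s must lie in [0, 1]", p), "refersdt_invalid_config")
    }
  }
  if (abs(cfg$cross_task_criterion_r) > 1 || abs(cfg$cross_task_dprime_r) > 1) {
    refersdt_abort("cross-task correlations must lie in [-1, 1]",
                   "refersdt_invalid_config")
  }
  if (cfg$dprime_sd < 0 || cfg$criterion_noise_sd < 0 || cfg$stress_sd < 0) {
    refersdt_abort("standard deviations must be non-negative",
                   "refersdt_invalid_config")
  }
  structure(cfg, class = "sim_config")
}

#' Probability of an urgent referral under the generative SDT model
#'
#' Equal-variance Gaussian model with the signal and noise distributions
#' placed symmetrically at +/- d'/2: the probability of an urgent referral is
#' `pnorm(d'/2 - c)` on a positive vignette and `pnorm(-d'/2 - c)` on a
#' negative one. This placement makes [dprime()] and [criterion()] exact
#' inverses of the generator at the population level. Vectorized; recycles
#' arguments.
#'
#' @param d_prime,criterion True per-responder parameters.
#' @param signal_class `"positive"` or `"negative"` (vector allowed).
#' @return Probability of an urgent referral.
#' @export
decision_probability <- function(d_prime, criterion, signal_class) {
  sgn <- ifelse(tolower(as.character(signal_class)) == "positive", 0.5, -0.5)
  stats::pnorm(sgn * d_prime - criterion)
}

# log-uniform draw on (lo, hi)
rloguniform <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# truncated log-normal via inverse-CDF, avoiding boundary atoms
rlnorm_trunc <- function(n, meanlog, sdlog, range) {
  p <- stats::runif(n, stats::plnorm(range[1], meanlog, sdlog),
                    stats::plnorm(range[2], meanlog, sdlog))
  stats::qlnorm(p, meanlog, sdlog)
}

#' Generate a synthetic referral study
#'
#' Simulates a full study under a [sim_config()]: responder covariates, a
#' vignette table with risks sampled log-uniformly on (3, 18.04]% for positive
#' and [0.18, 3)% for negative vignettes, per-responder true (d', c), and
#' trial-level trichotomous decisions (urgent with probability
#' [decision_probability()]; non-urgent decisions split routine vs. none at
#' the configured share). The generating parameters are returned alongside
#' the dataset so recovery can be tested.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study`: `study` (a [study_dataset()]),
#'   `truth` (data.frame: responder_id, true_d_prime, true_criterion),
#'   `coefficients` (named generating coefficients of the criterion model),
#'   and `config`.
#' @export
generate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_responders
  ids <- sprintf("R%03d", seq_len(n))

  n_female <- round(config$prop_female * n)
  female <- rep(0L, n)
  female[sample.int(n, n_female)] <- 1L
  experience <- rlnorm_trunc(n, config$experience_meanlog, config$experience_sdlog,
                             config$experience_range)
  ppv <- stats::runif(n, config$ppv_range[1], config$ppv_range[2])
  sens <- stats::runif(n, config$sensitivity_range[1], config$sensitivity_range[2])

  stress <- config$stress_mean_male + config$stress_gender_effect * female +
    stats::rnorm(n, 0, config$stress_sd)
  stress <- pmin(pmax(stress, config$stress_range[1]), config$stress_range[2])
  if (config$stress_n_missing > 0) {
    pool <- which(female == 1L)
    if (length(pool) < config$stress_n_missing) pool <- seq_len(n)
    stress[sample(pool, min(config$stress_n_missing, length(pool)))] <- NA_real_
  }
  prior <- rep(FALSE, n)
  prior[sample.int(n, round(config$prop_prior_task * n))] <- TRUE

  intercept <- config$criterion_mean -
    config$beta_ppv * mean(config$ppv_range) -
    config$beta_gender * config$prop_female
  true_d <- stats::rnorm(n, config$dprime_mean, config$dprime_sd)
  true_c <- intercept + config$beta_ppv * ppv + config$beta_gender * female +
    stats::rnorm(n, 0, config$criterion_noise_sd)

  npos <- config$n_positive_vignettes
  nneg <- config$n_negative_vignettes
  vignettes <- data.frame(
    vignette_id = sprintf("V%02d", seq_len(npos + nneg)),
    cancer_risk_percent = c(rloguniform(npos, 3.0001, 18.04),
                            rloguniform(nneg, 0.18, 2.9999)),
    signal_class = rep(c("positive", "negative"), c(npos, nneg)),
    stringsAsFactors = FALSE
  )

  idx_r <- rep(seq_len(n), each = npos + nneg)
  idx_v <- rep(seq_len(npos + nneg), times = n)
  p_urgent <- decision_probability(true_d[idx_r], true_c[idx_r],
                                   vignettes$signal_class[idx_v])
  urgent <- stats::rbinom(length(p_urgent), 1L, p_urgent)
  routine <- stats::rbinom(length(p_urgent), 1L,
                           config$routine_share_of_nonurgent)
  decision <- ifelse(urgent == 1L, "urgent",
                     ifelse(routine == 1L, "routine", "none"))

  responders <- data.frame(
    responder_id = ids,
    gender = ifelse(female == 1L, "female", "male"),
    experience_years = experience,
    practice_ppv_percent = ppv,
    practice_sensitivity_percent = sens,
    stress_score = stress,
    prior_task = prior,
    stringsAsFactors = FALSE
  )
  responses <- data.frame(
    responder_id = ids[idx_r],
    vignette_id = vignettes$vignette_id[idx_v],
    task_label = "colorectal",
    decision = decision,
    stringsAsFactors = FALSE
  )

  structure(list(
    study = study_dataset(responses, vignettes, responders,
                          stress_range = config$stress_range),
    truth = data.frame(responder_id = ids, true_d_prime = true_d,
                       true_criterion = true_c, stringsAsFactors = FALSE),
    coefficients = c(intercept = intercept, beta_ppv = config$beta_ppv,
                     beta_gender = config$beta_gender),
    config = config
  ), class = "sim_study")
}

#' Generate correlated prior-task SDT indices
#'
#' Draws second-task (e.g. prior lung-cancer study) true indices for a set of
#' responders from the configured marginals, with the criterion correlated at
#' `cross_task_criterion_r` with the first task's true criterion and d'
#' correlated at `cross_task_dprime_r` (default 0, i.e. independent).
#' Conditioning standardizes the first-task values empirically, so with
#' `cross_task_criterion_r = 1` and matching SDs the second-task criteria
#' equal the first-task ones up to the configured mean offset.
#'
#' @param truth A `sim_study` or its `truth` data.frame (responder_id,
#'   true_d_prime, true_criterion).
#' @param config A [sim_config()]; uses its `cross_task_*` fields.
#' @param responder_ids Optional subset of responders to generate for. When
#'   `truth` is a `sim_study`, defaults to its `prior_task = TRUE` responders;
#'   otherwise to all rows.
#' @return data.frame of class `sdt_indices`-like: `responder_id`, `d_prime`,
#'   `criterion`.
#' @export
generate_cross_task <- function(truth, config = sim_config(),
                                responder_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (abs(config$cross_task_criterion_r) > 1 || abs(config$cross_task_dprime_r) > 1) {
    refersdt_abort("cross-task correlations must lie in [-1, 1]",
                   "refersdt_invalid_config")
  }
  if (inherits(truth, "sim_study")) {
    if (is.null(responder_ids)) {
      responder_ids <- truth$study$responders$responder_id[
        truth$study$responders$prior_task]
    }
    truth <- truth$truth
  }
  if (is.null(responder_ids)) responder_ids <- truth$responder_id
  truth <- truth[match(responder_ids, truth$responder_id), , drop = FALSE]
  if (anyNA(truth$responder_id) || nrow(truth) == 0) {
    refersdt_abort("responder_ids not found in the truth table",
                   "refersdt_orphan_reference")
  }
  n <- nrow(truth)
  cond_draw <- function(x, r, mu, sigma) {
    z <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else rep(0, n)
    mu + sigma * (r * z + sqrt(1 - r^2) * stats::rnorm(n))
  }
  data.frame(
    responder_id = truth$responder_id,
    d_prime = cond_draw(truth$true_d_prime, config$cross_task_dprime_r,
                        config$cross_task_dprime_mean, config$cross_task_dprime_sd),
    criterion = cond_draw(truth$true_criterion, config$cross_task_criterion_r,
                          config$cross_task_criterion_mean,
                          config$cross_task_criterion_sd),
    stringsAsFactors = FALSE
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic referral study\n")
  print(x$study)
  cat(sprintf("criterion model: c = %.3f + %.3f*ppv %+.3f*female + N(0, %.3f)\n",
              x$coefficients["intercept"], x$coefficients["beta_ppv"],
              x$coefficients["beta_gender"], x$config$criterion_noise_sd))
  invisible(x)
}
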