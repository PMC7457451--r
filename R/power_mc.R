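#' Specification for a Monte Carlo power analysis of an indirect effect
#'
#' Bundles the population inputs — the 3 x 3 correlation matrix among
#' predictor, mediator and outcome and their standard deviations — with the
#' simulation settings: sample size per replication, number of replications,
#' Monte Carlo draws per replication, confidence level and seed.
#'
#' @param correlations 3 x 3 symmetric correlation matrix, unit diagonal,
#'   positive semidefinite, ordered (predictor, mediator, outcome).
#' @param sds Positive standard deviations of the three variables.
#' @param n Sample size per replication (>= 10).
#' @param n_reps Number of replications (default 5000).
#' @param n_draws Monte Carlo draws per replication for the product's
#'   interval (default 20000).
#' @param ci_level Monte Carlo confidence level (default 0.95).
#' @param seed Integer seed (default 1234).
#' @return A list of class `power_spec`.
#' @export
power_spec <- function(correlations, sds, n, n_reps = 5000, n_draws = 20000,
                       ci_level = 0.95, seed = 1234) {
  correlations <- as.matrix(correlations)
  if (!all(dim(correlations) == c(3, 3)) ||
      max(abs(correlations - t(correlations))) > 1e-8 ||
      max(abs(diag(correlations) - 1)) > 1e-8) {
    refersdt_abort("correlations must be a symmetric 3 x 3 matrix with unit diagonal",
                   "refersdt_invalid_config")
  }
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    refersdt_abort(
      sprintf("correlation matrix is not positive semidefinite (smallest eigenvalue %.3g)",
              min(ev)),
      "refersdt_not_psd"
    )
  }
  stopifnot(length(sds) == 3, all(sds > 0), n >= 10, n_reps >= 1, n_draws >= 1,
            ci_level > 0, ci_level < 1)
  if (is.null(dimnames(correlations))) {
    dimnames(correlations) <- list(c("predictor", "mediator", "outcome"),
                                   c("predictor", "mediator", "outcome"))
  }
  structure(list(correlations = correlations, sds = sds, n = as.integer(n),
                 n_reps = as.integer(n_reps), n_draws = as.integer(n_draws),
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "power_spec")
}

#' Reconstruct the trivariate correlation inputs from printed summaries
#'
#' When the raw data behind a mediation analysis are unavailable but the
#' summary statistics are printed, the correlation matrix a power analysis
#' needs can be recovered: the binary predictor-mediator correlation is the
#' point-biserial identity `r = t / sqrt(t^2 + df)` applied to the two-group
#' t statistic; the predictor-outcome and mediator-outcome correlations come
#' from regression slopes via `r = b * sd_x / sd_y`, with the binary
#' predictor's SD taken as `sqrt(p * (1 - p))` from the group sizes.
#'
#' @param t_stat Two-group t statistic for predictor -> mediator.
#' @param df Its degrees of freedom; must equal `sum(group_ns) - 2`.
#' @param group_ns Group sizes `c(n_predictor_1, n_predictor_0)`.
#' @param slope_mediator_outcome Simple-regression slope of outcome on
#'   mediator.
#' @param slope_predictor_outcome Slope of outcome on predictor (the total
#'   effect).
#' @param sd_mediator,sd_outcome Standard deviations of mediator and outcome.
#' @return A list: `correlations` (3 x 3 matrix, order predictor, mediator,
#'   outcome), `sds` (the three SDs, predictor first), `n`
#'   (`sum(group_ns)`). Errors if the reconstructed matrix is not positive
#'   semidefinite.
#' @export
derive_power_inputs <- function(t_stat, df, group_ns,
                                slope_mediator_outcome,
                                slope_predictor_outcome,
                                sd_mediator, sd_outcome) {
  stopifnot(length(group_ns) == 2, all(group_ns > 0),
            sd_mediator > 0, sd_outcome > 0)
  if (df != sum(group_ns) - 2) {
    refersdt_abort(sprintf("df (%d) must equal sum(group_ns) - 2 (%d)",
                           df, sum(group_ns) - 2),
                   "refersdt_invalid_config")
  }
  p1 <- group_ns[1] / sum(group_ns)
  sd_x <- sqrt(p1 * (1 - p1))
  r_xm <- t_stat / sqrt(t_stat^2 + df)
  r_my <- slope_mediator_outcome * sd_mediator / sd_outcome
  r_xy <- slope_predictor_outcome * sd_x / sd_outcome
  R <- matrix(c(1, r_xm, r_xy,
                r_xm, 1, r_my,
                r_xy, r_my, 1), 3, 3,
              dimnames = list(c("predictor", "mediator", "outcome"),
                              c("predictor", "mediator", "outcome")))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    refersdt_abort(
      sprintf("reconstructed correlations are not positive semidefinite (det of the 3x3 minor = %.4g, smallest eigenvalue %.3g)",
              det(R), min(ev)),
      "refersdt_not_psd"
    )
  }
  list(correlations = R, sds = c(sd_x, sd_mediator, sd_outcome),
       n = sum(group_ns))
}

#' Monte Carlo power for an indirect effect
#'
#' Estimates the power (1 - beta) to detect the indirect (a*b) effect of a
#' single-mediator model by simulation. Per replication: draw `n`
#' observations from the trivariate normal implied by the spec's correlations
#' and SDs; fit mediator ~ predictor and outcome ~ predictor + mediator by
#' OLS; draw `n_draws` (a, b) pairs from the normal approximations to the two
#' coefficients' sampling distributions; form the `ci_level` percentile
#' interval of the products; count a rejection when the interval excludes 0.
#' Power is the rejection fraction over replications; results are
#' deterministic given the seed. A replication whose design is singular is
#' redrawn and logged.
#'
#' @param spec A [power_spec()].
#' @return A list of class `power_result`: `power`, `mc_se`
#'   (`sqrt(power * (1 - power) / n_reps)`), `n_redrawn`, `spec`.
#' @export
mc_power_indirect <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  set.seed(spec$seed)
  Sigma <- diag(spec$sds) %*% spec$correlations %*% diag(spec$sds)
  cs <- chol(Sigma + diag(1e-12, 3))
  n <- spec$n
  alpha <- (1 - spec$ci_level) / 2
  hits <- 0L
  redrawn <- 0L
  for (rep in seq_len(spec$n_reps)) {
    repeat {
      X <- matrix(stats::rnorm(n * 3L), n, 3L) %*% cs
      est <- ab_estimates(X[, 1L], X[, 2L], X[, 3L], n)
      if (!is.null(est)) break
      redrawn <- redrawn + 1L
    }
    ab <- stats::rnorm(spec$n_draws, est$a, est$se_a) *
      stats::rnorm(spec$n_draws, est$b, est$se_b)
    qs <- stats::quantile(ab, c(alpha, 1 - alpha), names = FALSE)
    if (qs[1] > 0 || qs[2] < 0) hits <- hits + 1L
  }
  if (redrawn > 0) {
    message(sprintf("mc_power_indirect: %d singular replication(s) redrawn", redrawn))
  }
  power <- hits / spec$n_reps
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / spec$n_reps),
                 n_redrawn = redrawn, spec = spec),
            class = "power_result")
}

# OLS estimates and standard errors of the a and b paths, closed form.
# Returns NULL on a singular design (constant predictor or collinearity).
ab_estimates <- function(x, m, y, n) {
  xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
  sxx <- sum(xc * xc); sxm <- sum(xc * mc); smm <- sum(mc * mc)
  det <- sxx * smm - sxm * sxm
  if (sxx <= 0 || det <= 0) return(NULL)
  sxy <- sum(xc * yc); smy <- sum(mc * yc)

  a <- sxm / sxx
  rss_a <- smm - a * sxm
  se_a <- sqrt(rss_a / (n - 2) / sxx)

  bx <- (smm * sxy - sxm * smy) / det
  bm <- (sxx * smy - sxm * sxy) / det
  rss_y <- sum(yc * yc) - bx * sxy - bm * smy
  se_b <- sqrt(rss_y / (n - 3) * sxx / det)
  list(a = a, se_a = se_a, b = bm, se_b = se_b)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Monte Carlo power for the indirect effect: %.3f (MC SE %.4f)\n",
              x$power, x$mc_se))
  cat(sprintf("  n = %d, %d replications x %d draws, %g%% CI, seed %d\n",
              x$spec$n, x$spec$n_reps, x$spec$n_draws,
              100 * x$spec$ci_level, x$spec$seed))
  invisible(x)
}

#' Smallest sample size reaching a target power
#'
#' Bisection over a monotone grid of candidate sample sizes: returns the
#' smallest grid n whose estimated Monte Carlo power (via
#' [mc_power_indirect()], with the same seed re-used at every n) reaches the
#' target. Relies on power being non-decreasing in n.
#'
#' @param correlations,sds Population inputs as in [power_spec()].
#' @param target_power Target power in (0, 1) (e.g. 0.80).
#' @param n_grid Increasing grid of candidate sample sizes.
#' @param n_reps,n_draws,ci_level,seed Simulation settings per evaluation.
#' @return A list of class `power_search`: `n` (the answer), `power_at_n`,
#'   `evaluations` (data.frame of every (n, power) evaluated), plus the
#'   settings. Errors if even the largest grid n misses the target, reporting
#'   the maximum achieved power.
#' @export
required_n_for_power <- function(correlations, sds, target_power, n_grid,
                                 n_reps = 5000, n_draws = 20000,
                                 ci_level = 0.95, seed = 1234) {
  stopifnot(target_power >= 0, target_power < 1, length(n_grid) >= 1,
            !is.unsorted(n_grid))
  n_grid <- as.integer(n_grid)
  evals <- list()
  power_at <- function(n) {
    key <- as.character(n)
    if (is.null(evals[[key]])) {
      res <- mc_power_indirect(power_spec(correlations, sds, n,
                                          n_reps = n_reps, n_draws = n_draws,
                                          ci_level = ci_level, seed = seed))
      evals[[key]] <<- res$power
    }
    evals[[key]]
  }
  if (power_at(n_grid[1]) >= target_power) {
    hi <- 1L
  } else {
    p_max <- power_at(n_grid[length(n_grid)])
    if (p_max < target_power) {
      refersdt_abort(
        sprintf("target power %.2f unreachable on the grid: maximum achieved %.3f at n = %d",
                target_power, p_max, n_grid[length(n_grid)]),
        "refersdt_target_unreachable"
      )
    }
    lo <- 1L; hi <- length(n_grid)
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (power_at(n_grid[mid]) >= target_power) hi <- mid else lo <- mid
    }
  }
  ev <- data.frame(n = as.integer(names(evals)),
                   power = unlist(evals, use.names = FALSE))
  ev <- ev[order(ev$n), , drop = FALSE]
  structure(list(n = n_grid[hi], power_at_n = power_at(n_grid[hi]),
                 target_power = target_power, evaluations = ev,
                 n_reps = n_reps, n_draws = n_draws, ci_level = ci_level,
                 seed = seed),
            class = "power_search")
}

#' @export
print.power_search <- function(x, ...) {
  cat(sprintf("Smallest n with power >= %.2f: %d (estimated power %.3f)\n",
              x$target_power, x$n, x$power_at_n))
  invisible(x)
}
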