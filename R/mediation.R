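#' Simple mediation model with a bootstrap indirect-effect interval
#'
#' Fits the three ordinary regressions of a single-mediator model — mediator
#' ~ predictor (a path), outcome ~ predictor + mediator (b path and direct
#' effect), outcome ~ predictor (total effect) — on the complete cases
#' (listwise deletion on all three variables). The indirect effect is the
#' product a*b, with a nonparametric percentile bootstrap confidence interval;
#' the OLS identity total = direct + indirect holds on every complete-case
#' dataset. The default use is gender (female = 1) -> stress-from-uncertainty
#' -> criterion.
#'
#' @param data data.frame containing the three columns. A `gender` column, if
#'   named as the predictor, is recoded to a 0/1 female indicator.
#' @param predictor,mediator,outcome Column names.
#' @param n_boot Bootstrap resamples for the indirect-effect CI (default
#'   5000). Fewer than 100 triggers a warning recorded in the result.
#' @param seed Integer seed for the bootstrap (default 1234); results are
#'   reproducible for a fixed seed and `n_boot`.
#' @param ci_level Confidence level (default 0.95) for all intervals.
#' @return A list of class `mediation_result`: `paths` (data.frame with rows
#'   a, b, direct, indirect, total: estimate, ci_low, ci_high, p — the
#'   indirect row's interval is the bootstrap percentile interval and its p is
#'   NA), `proportion_mediated`, `inconsistent` (TRUE when indirect and total
#'   have opposite signs), `n`, `n_boot`, `seed`, `warnings`.
#' @export
fit_mediation <- function(data, predictor = "gender", mediator = "stress_score",
                          outcome = "criterion", n_boot = 5000, seed = 1234,
                          ci_level = 0.95) {
  data <- as.data.frame(data)
  for (col in c(predictor, mediator, outcome)) {
    if (!col %in% names(data)) {
      refersdt_abort(sprintf("column '%s' not found", col),
                     "refersdt_missing_column")
    }
  }
  x <- data[[predictor]]
  if (predictor == "gender" || is.character(x) || is.factor(x)) {
    x <- as.integer(as.character(x) == "female")
  }
  m <- as.numeric(data[[mediator]])
  y <- as.numeric(data[[outcome]])
  cc <- stats::complete.cases(x, m, y)
  x <- x[cc]; m <- m[cc]; y <- y[cc]
  n <- length(y)
  if (n < 10) {
    refersdt_abort("fewer than 10 complete cases", "refersdt_empty_input")
  }
  if (stats::sd(m) == 0 || stats::sd(y) == 0) {
    refersdt_abort("constant mediator or outcome", "refersdt_degenerate_input")
  }
  warnings <- character(0)
  if (n_boot < 100) {
    warnings <- c(warnings,
                  sprintf("n_boot = %d is too small for a stable percentile interval",
                          n_boot))
    warning(warnings[length(warnings)], call. = FALSE)
  }

  fit_a <- stats::lm(m ~ x)
  fit_y <- stats::lm(y ~ x + m)
  fit_t <- stats::lm(y ~ x)
  row_of <- function(fit, term) {
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit, term, level = ci_level)
    c(estimate = sm[term, "Estimate"], ci_low = ci[1], ci_high = ci[2],
      p = sm[term, "Pr(>|t|)"])
  }
  a <- row_of(fit_a, "x")
  b <- row_of(fit_y, "m")
  direct <- row_of(fit_y, "x")
  total <- row_of(fit_t, "x")
  indirect_est <- unname(a["estimate"] * b["estimate"])

  set.seed(seed)
  boot_ind <- boot_indirect(x, m, y, n_boot)
  alpha <- (1 - ci_level) / 2
  ci_ind <- stats::quantile(boot_ind, c(alpha, 1 - alpha), names = FALSE)

  paths <- rbind(
    a = a, b = b, direct = direct,
    indirect = c(estimate = indirect_est, ci_low = ci_ind[1],
                 ci_high = ci_ind[2], p = NA_real_),
    total = total
  )
  paths <- data.frame(path = rownames(paths), paths, row.names = NULL,
                      stringsAsFactors = FALSE)
  prop <- proportion_mediated(indirect_est, unname(total["estimate"]))
  structure(list(
    paths = paths,
    proportion_mediated = as.numeric(prop),
    inconsistent = isTRUE(attr(prop, "inconsistent")),
    n = n, n_boot = n_boot, seed = seed, warnings = warnings
  ), class = "mediation_result")
}

# Percentile bootstrap of the indirect effect: refit both path regressions on
# each resample with closed-form OLS (centered cross-products), which keeps
# 5000 resamples cheap.
boot_indirect <- function(x, m, y, n_boot) {
  n <- length(x)
  out <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    xi <- x[idx]; mi <- m[idx]; yi <- y[idx]
    xc <- xi - mean(xi); mc <- mi - mean(mi); yc <- yi - mean(yi)
    sxx <- sum(xc * xc); sxm <- sum(xc * mc); smm <- sum(mc * mc)
    det <- sxx * smm - sxm * sxm
    if (sxx == 0 || det == 0) { out[i] <- NA_real_; next }
    a_i <- sxm / sxx
    b_i <- (sxx * sum(mc * yc) - sxm * sum(xc * yc)) / det
    out[i] <- a_i * b_i
  }
  out[!is.na(out)]
}

#' Proportion of the total effect mediated
#'
#' The ratio indirect / total, exactly as conventionally reported. When the
#' indirect and total effects have opposite signs (inconsistent mediation)
#' the ratio is still returned, flagged via the `"inconsistent"` attribute;
#' a zero total effect leaves the proportion undefined.
#'
#' @param indirect_b,total_b Point estimates of the indirect and total
#'   effects.
#' @return Numeric proportion with logical attribute `inconsistent`.
#' @export
proportion_mediated <- function(indirect_b, total_b) {
  if (total_b == 0) {
    refersdt_abort("total effect is zero: proportion mediated is undefined",
                   "refersdt_undefined_proportion")
  }
  structure(indirect_b / total_b,
            inconsistent = indirect_b != 0 && sign(indirect_b) != sign(total_b))
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  cat(sprintf("Mediation model (n = %d complete cases, %d bootstrap resamples, seed %d)\n",
              x$n, x$n_boot, x$seed))
  tab <- x$paths
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("proportion mediated: %.3f%s\n", x$proportion_mediated,
              if (x$inconsistent) " (inconsistent mediation: opposite signs)" else ""))
  invisible(x)
}
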