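#' Regress an SDT index on responder covariates
#'
#' Ordinary least squares of a per-responder index (d' or criterion) on
#' organizational and demographic covariates — by default practice PPV,
#' practice sensitivity, gender and experience. Gender is coded female = 1,
#' male = 0, so a negative coefficient on the criterion means women are more
#' inclined to refer. Covariates stay on their natural scales (PPV and
#' sensitivity in percentage points, experience in years). Analytic 95%
#' confidence intervals and two-sided p-values; listwise deletion of
#' incomplete cases; no multiple-testing adjustment.
#'
#' @param indices `sdt_indices` data.frame from [compute_indices()] (or any
#'   data.frame with `responder_id` and the outcome column).
#' @param profiles Responder table (as in a `study_dataset`).
#' @param outcome `"d_prime"` or `"criterion"`.
#' @param terms Covariates to enter; `"gender"` is recoded to `female`.
#' @param categorize_experience If TRUE, experience enters as quartile groups
#'   instead of continuous years (off by default).
#' @return A list of class `index_regression`: `outcome`, `terms` (data.frame:
#'   term, b, ci_low, ci_high, p), `n`, `r_squared`, and the `fit`.
#' @export
regress_index <- function(indices, profiles,
                          outcome = c("criterion", "d_prime"),
                          terms = c("practice_ppv_percent",
                                    "practice_sensitivity_percent",
                                    "gender", "experience_years"),
                          categorize_experience = FALSE) {
  outcome <- match.arg(outcome)
  dat <- merge(as.data.frame(indices)[, c("responder_id", outcome)],
               as.data.frame(profiles), by = "responder_id")
  rhs <- character(0)
  for (tm in terms) {
    if (tm == "gender") {
      dat$female <- as.integer(as.character(dat$gender) == "female")
      rhs <- c(rhs, "female")
    } else if (tm == "experience_years" && categorize_experience) {
      q <- stats::quantile(dat$experience_years, probs = seq(0, 1, 0.25),
                           na.rm = TRUE)
      dat$experience_group <- cut(dat$experience_years, unique(q),
                                  include.lowest = TRUE)
      rhs <- c(rhs, "experience_group")
    } else {
      if (!tm %in% names(dat)) {
        refersdt_abort(sprintf("term '%s' not found in the responder table", tm),
                       "refersdt_missing_column")
      }
      rhs <- c(rhs, tm)
    }
  }
  form <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  dat <- dat[stats::complete.cases(dat[, c(outcome, rhs)]), , drop = FALSE]
  if (nrow(dat) < length(rhs) + 2) {
    refersdt_abort("too few complete cases for the requested terms",
                   "refersdt_empty_input")
  }
  mm <- stats::model.matrix(form, dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    refersdt_abort(sprintf("rank-deficient design: term(s) %s are collinear",
                           paste(dropped, collapse = ", ")),
                   "refersdt_rank_deficient")
  }
  fit <- stats::lm(form, data = dat)
  ci <- stats::confint(fit, level = 0.95)
  sm <- summary(fit)
  tab <- data.frame(
    term = rownames(sm$coefficients),
    b = sm$coefficients[, "Estimate"],
    ci_low = ci[, 1], ci_high = ci[, 2],
    p = sm$coefficients[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(outcome = outcome, terms = tab, n = nrow(dat),
                 r_squared = sm$r.squared, fit = fit),
            class = "index_regression")
}

#' @export
print.index_regression <- function(x, digits = 4, ...) {
  cat(sprintf("OLS of %s on covariates (n = %d, R^2 = %.3f)\n",
              x$outcome, x$n, x$r_squared))
  tab <- x$terms
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Cross-task stability correlation of an SDT index
#'
#' Pearson correlation of a per-responder index between two tasks, paired on
#' the responder ids present in both tables (e.g. the responders who
#' participated in both a lung and a colorectal study).
#'
#' @param indices_a,indices_b data.frames with `responder_id` and the index
#'   column (e.g. `sdt_indices` objects, or the output of
#'   [generate_cross_task()]).
#' @param index Column to correlate, `"criterion"` or `"d_prime"`.
#' @return A list of class `correlation_result`: `r`, `p`, `n`, `index`.
#' @export
stability_correlation <- function(indices_a, indices_b,
                                  index = c("criterion", "d_prime")) {
  index <- match.arg(index)
  a <- as.data.frame(indices_a); b <- as.data.frame(indices_b)
  shared <- intersect(a$responder_id, b$responder_id)
  if (length(shared) < 3) {
    refersdt_abort("need at least 3 shared responders for a correlation",
                   "refersdt_empty_input")
  }
  va <- a[[index]][match(shared, a$responder_id)]
  vb <- b[[index]][match(shared, b$responder_id)]
  ct <- stats::cor.test(va, vb, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(shared),
                 index = index),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation of %s across tasks: r = %.3f, p = %.3g, n = %d\n",
              x$index, x$r, x$p, x$n))
  invisible(x)
}

#' Two-group comparison of means (pooled-variance t-test)
#'
#' Student's two-sample t-test with pooled variance, df = n1 + n2 - 2 (the
#' convention matching a reported t with df = n - 2 on the complete cases).
#'
#' @param values Numeric vector.
#' @param group_labels Factor/character with exactly two levels; pairs with
#'   `values`. NA values (in either) are dropped.
#' @return A list of class `group_comparison`: `mean_a`, `mean_b` (in level
#'   order), `t`, `df`, `p`, `n_a`, `n_b`, `pooled_sd`, `levels`.
#' @export
compare_groups <- function(values, group_labels) {
  keep <- !is.na(values) & !is.na(group_labels)
  values <- values[keep]
  g <- factor(group_labels[keep])
  if (nlevels(g) != 2) {
    refersdt_abort("exactly two groups are required", "refersdt_empty_input")
  }
  n <- table(g)
  if (any(n < 2)) {
    refersdt_abort("each group needs at least 2 observations",
                   "refersdt_empty_input")
  }
  v <- tapply(values, g, stats::var)
  if (all(v == 0)) {
    refersdt_abort("zero pooled variance: the t statistic is undefined",
                   "refersdt_degenerate_input")
  }
  tt <- stats::t.test(values ~ g, var.equal = TRUE)
  sp <- sqrt(((n[1] - 1) * v[1] + (n[2] - 1) * v[2]) / (sum(n) - 2))
  structure(list(
    mean_a = unname(tt$estimate[1]), mean_b = unname(tt$estimate[2]),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    n_a = unname(n[1]), n_b = unname(n[2]), pooled_sd = unname(sp),
    levels = levels(g)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: mean %.3f (n = %d) vs %s: mean %.3f (n = %d); t(%d) = %.3f, p = %.3g\n",
              x$levels[1], x$mean_a, x$n_a, x$levels[2], x$mean_b, x$n_b,
              x$df, x$t, x$p))
  invisible(x)
}
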