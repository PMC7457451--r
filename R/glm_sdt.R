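#' Probit-GLM estimation of SDT parameters
#'
#' Estimates discrimination and response bias — together with responder-level
#' covariate effects on both — in a single probit regression on the
#' trial-level dichotomized decisions. The vignette class is coded
#' `signal = +0.5` (positive) / `-0.5` (negative), so that at the covariate
#' reference the model `P(urgent) = pnorm(b0 + b1 * signal + ...)` maps
#' directly onto the closed-form indices: the intercept estimates `-c` and the
#' signal slope estimates `d'`. Covariate main effects shift `-c`; covariate x
#' signal interactions shift `d'`. The nested structure (multiple decisions
#' per responder) can be modeled with per-responder random effects.
#'
#' No count correction is needed here: the likelihood handles responders with
#' zero hits or false alarms, which is one motivation for this route alongside
#' the closed-form one. The two approaches should be comparable, though not
#' identical.
#'
#' @param ds A `study_dataset`.
#' @param covariates Character vector of responder-table covariates to enter
#'   (both as main effects and in interaction with the signal). `gender` is
#'   recoded `female` = 1, `male` = 0. Covariates are kept on their natural
#'   scales. Default none.
#' @param random_effects `"intercept_and_signal_slope"` (each responder gets
#'   their own criterion and d' deviation; the default), `"intercept"`
#'   (criterion only), or `"none"` (plain fixed-effects probit, suited to
#'   small fixtures and single responders).
#' @param task_label Optional task restriction.
#' @param epsilon,maxit Convergence tolerance on the (log-)likelihood and
#'   iteration cap for the fixed-effects fit (defaults 1e-6 and 200).
#' @return A list of class `glm_sdt`: `coefficients` (data.frame: term,
#'   estimate, se, ci_low, ci_high, p — Wald 95% intervals), `n_obs`,
#'   `converged`, `random_effects`, and the underlying `fit`.
#' @seealso [glm_to_sdt()] to translate coefficients into (d', c) effects.
#' @export
fit_probit_sdt <- function(ds, covariates = character(),
                           random_effects = c("intercept_and_signal_slope",
                                              "intercept", "none"),
                           task_label = NULL, epsilon = 1e-6, maxit = 200) {
  stopifnot(inherits(ds, "study_dataset"))
  random_effects <- match.arg(random_effects)

  dat <- trial_frame(ds, covariates, task_label)
  check_separation(dat, covariates)

  fixed <- if (length(covariates) > 0) {
    sprintf("urgent ~ signal * (%s)",
            paste(covariate_term(covariates), collapse = " + "))
  } else "urgent ~ signal"

  if (random_effects == "none") {
    fit <- stats::glm(stats::as.formula(fixed), family = stats::binomial("probit"),
                      data = dat,
                      control = stats::glm.control(epsilon = epsilon, maxit = maxit))
    converged <- isTRUE(fit$converged)
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; p <- sm[, "Pr(>|z|)"]
  } else {
    re <- if (random_effects == "intercept") "(1 | responder_id)" else
      "(1 + signal | responder_id)"
    form <- stats::as.formula(paste(fixed, re, sep = " + "))
    fit <- lme4::glmer(form, family = stats::binomial("probit"), data = dat)
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- fit@optinfo$conv$opt == 0 && is.null(msgs)
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; p <- sm[, "Pr(>|z|)"]
  }
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = rownames(sm), estimate = est, se = se,
    ci_low = est - z * se, ci_high = est + z * se, p = p,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefs, n_obs = nrow(dat), converged = converged,
                 random_effects = random_effects, fit = fit),
            class = "glm_sdt")
}

# Trial-level model frame: dichotomized decision, +/-0.5 signal coding,
# responder covariates merged in (gender recoded to a 0/1 female indicator).
trial_frame <- function(ds, covariates, task_label = NULL) {
  resp <- ds$responses
  if (!is.null(task_label)) resp <- resp[resp$task_label == task_label, , drop = FALSE]
  if (nrow(resp) == 0) {
    refersdt_abort("no responses to model", "refersdt_empty_input")
  }
  cls <- as.character(ds$vignettes$signal_class)[
    match(resp$vignette_id, ds$vignettes$vignette_id)]
  dat <- data.frame(
    responder_id = resp$responder_id,
    urgent = dichotomize(resp$decision),
    signal = ifelse(cls == "positive", 0.5, -0.5),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(covariates, names(ds$responders))
  if (length(bad) > 0) {
    refersdt_abort(sprintf("covariate(s) not in the responder table: %s",
                           paste(bad, collapse = ", ")),
                   "refersdt_missing_column")
  }
  ri <- match(dat$responder_id, ds$responders$responder_id)
  for (cv in covariates) {
    if (cv == "gender") {
      dat$female <- as.integer(ds$responders$gender[ri] == "female")
    } else {
      dat[[cv]] <- ds$responders[[cv]][ri]
    }
  }
  dat
}

covariate_term <- function(covariates) {
  ifelse(covariates == "gender", "female", covariates)
}

# Pre-fit complete-separation check for discrete covariates: a level on which
# the response is constant makes its coefficient diverge.
check_separation <- function(dat, covariates) {
  for (cv in covariate_term(covariates)) {
    v <- dat[[cv]]
    if (length(unique(v)) <= 10) {
      means <- tapply(dat$urgent, v, mean)
      flat <- means %in% c(0, 1)
      if (any(flat)) {
        refersdt_abort(
          sprintf("complete separation: covariate '%s' level(s) %s have an all-%s response",
                  cv, paste(names(means)[flat], collapse = ", "),
                  ifelse(means[flat][1] == 1, "urgent", "non-urgent")),
          "refersdt_separation"
        )
      }
    }
  }
  invisible(TRUE)
}

#' Translate probit-GLM coefficients into SDT effects
#'
#' Applies the coding convention of [fit_probit_sdt()]: the intercept-side
#' coefficients act on `-c` (so criterion effects are their negation) and the
#' signal-side coefficients act on `d'`. The reference-level d' is the signal
#' main effect; covariate x signal interactions are d' shifts; covariate main
#' effects are criterion shifts (negated).
#'
#' @param result A converged `glm_sdt` object.
#' @return data.frame with columns `term`, `effect_on` (`"d_prime"` or
#'   `"criterion"`), `estimate`, `ci_low`, `ci_high`, `p`. The intercept row
#'   is reported as the reference-level criterion, the signal row as the
#'   reference-level d'.
#' @export
glm_to_sdt <- function(result) {
  stopifnot(inherits(result, "glm_sdt"))
  if (!isTRUE(result$converged)) {
    refersdt_abort("model did not converge; SDT mapping would be unreliable",
                   "refersdt_not_converged")
  }
  co <- result$coefficients
  is_signal <- co$term == "signal" | grepl("(^signal:)|(:signal$)", co$term)
  out <- data.frame(
    term = sub("signal:", "", sub(":signal", "", co$term)),
    effect_on = ifelse(is_signal, "d_prime", "criterion"),
    estimate = ifelse(is_signal, co$estimate, -co$estimate),
    ci_low = ifelse(is_signal, co$ci_low, -co$ci_high),
    ci_high = ifelse(is_signal, co$ci_high, -co$ci_low),
    p = co$p,
    stringsAsFactors = FALSE
  )
  out$term[out$term == "(Intercept)"] <- "(reference)"
  out$term[out$term == "signal"] <- "(reference)"
  out
}

#' @export
print.glm_sdt <- function(x, digits = 4, ...) {
  cat(sprintf("Probit SDT model (%s random effects), n_obs = %d, converged = %s\n",
              x$random_effects, x$n_obs, x$converged))
  co <- x$coefficients
  co[, -1] <- lapply(co[, -1], function(v) signif(v, digits))
  print(co, row.names = FALSE)
  invisible(x)
}
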