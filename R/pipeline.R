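#' Run the full referral SDT analysis pipeline
#'
#' Orchestrates the study analyses in sequence: decision tabulation,
#' per-responder SDT indices and their summaries, the probit-GLM estimation,
#' multivariable regressions of d' and criterion on covariates, and the
#' optional stages — cross-task stability (when prior-task indices are
#' supplied), the stress group comparison plus gender -> stress -> criterion
#' mediation (when stress scores are present), and the Monte Carlo power
#' analysis for the observed indirect effect, with its correlation inputs
#' taken from the data's complete cases. Optional stages that cannot run are
#' marked skipped with a reason; failures in mandatory stages abort with the
#' stage name. With `out_dir` set, each section is written as CSV alongside a
#' human-readable `report.md`; outputs are byte-identical for the same inputs
#' and seed.
#'
#' @param study A `study_dataset`, or a named list/vector of the three CSV
#'   paths `c(responses, vignettes, responders)` as read by [read_study()].
#' @param out_dir Optional output directory for the CSV bundle and report.
#' @param prior_indices Optional data.frame of prior-task indices
#'   (responder_id, d_prime, criterion) for the stability stage.
#' @param covariates Covariates for both the GLM and the index regressions.
#' @param glm_random_effects Random-effects structure for [fit_probit_sdt()].
#' @param do_mediation,do_power Logical switches for the optional stages.
#' @param n_boot Bootstrap resamples for the mediation indirect CI.
#' @param n_reps,n_draws Monte Carlo settings for the power stage.
#' @param seed Seed used for the bootstrap and the power simulation.
#' @param verbose Log stage progress (with row counts) to standard error.
#' @return A list of class `analysis_report` whose `sections` element holds
#'   each stage's result (or a `skipped` marker with a reason), plus
#'   `provenance` (seed, config hash, package version).
#' @export
run_analysis <- function(study, out_dir = NULL, prior_indices = NULL,
                         covariates = c("practice_ppv_percent",
                                        "practice_sensitivity_percent",
                                        "gender", "experience_years"),
                         glm_random_effects = "intercept_and_signal_slope",
                         do_mediation = TRUE, do_power = TRUE,
                         n_boot = 5000, n_reps = 5000, n_draws = 20000,
                         seed = 1234, verbose = TRUE) {
  if (!inherits(study, "study_dataset")) {
    study <- read_study(study[[1]], study[[2]], study[[3]])
  }
  log_stage <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[refersdt] ", fmt), ...))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      refersdt_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                     "refersdt_stage_failure")
    })
  }
  skipped <- function(reason) list(skipped = TRUE, reason = reason)
  sections <- list()

  log_stage("tabulation: %d responses", nrow(study$responses))
  sections$decision_table <- run_stage("tabulation", tabulate_decisions(study))
  sections$pooled_rates <- run_stage("tabulation", pooled_rates(study))

  indices <- run_stage("indices", compute_indices(study))
  log_stage("indices: %d responders", nrow(indices))
  sections$indices <- indices
  sections$summaries <- run_stage("summaries", summarize_indices(indices))

  log_stage("glm_sdt: probit with %s random effects", glm_random_effects)
  sections$glm_sdt <- run_stage("glm_sdt",
    fit_probit_sdt(study, covariates = covariates,
                   random_effects = glm_random_effects))

  log_stage("regressions: %d covariate terms", length(covariates))
  sections$regression_d_prime <- run_stage("regressions",
    regress_index(indices, study$responders, "d_prime", covariates))
  sections$regression_criterion <- run_stage("regressions",
    regress_index(indices, study$responders, "criterion", covariates))

  if (is.null(prior_indices)) {
    sections$stability <- skipped("no prior-task indices supplied")
    log_stage("stability: skipped (no prior-task indices)")
  } else {
    sections$stability <- run_stage("stability", list(
      criterion = stability_correlation(indices, prior_indices, "criterion"),
      d_prime = stability_correlation(indices, prior_indices, "d_prime")
    ))
    log_stage("stability: n = %d shared responders",
              sections$stability$criterion$n)
  }

  med_data <- merge(indices[, c("responder_id", "criterion")],
                    study$responders, by = "responder_id")
  have_stress <- sum(stats::complete.cases(
    med_data[, c("gender", "stress_score", "criterion")])) >= 10
  if (!do_mediation) {
    sections$group_comparison <- skipped("mediation disabled")
    sections$mediation <- skipped("mediation disabled")
  } else if (!have_stress) {
    sections$group_comparison <- skipped("fewer than 10 complete stress scores")
    sections$mediation <- skipped("fewer than 10 complete stress scores")
    log_stage("mediation: skipped (insufficient stress scores)")
  } else {
    sections$group_comparison <- run_stage("group_comparison",
      compare_groups(med_data$stress_score, med_data$gender))
    sections$mediation <- run_stage("mediation",
      fit_mediation(med_data, predictor = "gender", mediator = "stress_score",
                    outcome = "criterion", n_boot = n_boot, seed = seed))
    log_stage("mediation: n = %d complete cases", sections$mediation$n)
  }

  if (!do_power) {
    sections$power <- skipped("power analysis disabled")
  } else if (!have_stress) {
    sections$power <- skipped("fewer than 10 complete stress scores")
  } else {
    sections$power <- run_stage("power", {
      cc <- stats::complete.cases(med_data[, c("gender", "stress_score",
                                               "criterion")])
      x <- as.integer(as.character(med_data$gender[cc]) == "female")
      m <- med_data$stress_score[cc]
      y <- med_data$criterion[cc]
      R <- stats::cor(cbind(predictor = x, mediator = m, outcome = y))
      spec <- power_spec(R, sds = c(stats::sd(x), stats::sd(m), stats::sd(y)),
                         n = length(y), n_reps = n_reps, n_draws = n_draws,
                         seed = seed)
      mc_power_indirect(spec)
    })
    log_stage("power: %.3f at n = %d", sections$power$power,
              sections$power$spec$n)
  }

  report <- structure(list(
    sections = sections,
    provenance = list(
      seed = seed,
      config_hash = options_hash(list(covariates, glm_random_effects,
                                      do_mediation, do_power, n_boot, n_reps,
                                      n_draws, seed)),
      version = as.character(utils::packageVersion("refersdt"))
    )
  ), class = "analysis_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# md5 of the serialized option list; stable across sessions for the same options
options_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE, version = 3)
  unname(tools::md5sum(f))
}

#' Write an analysis report to a directory of CSVs and a markdown summary
#'
#' @param report An `analysis_report` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  s <- report$sections
  wcsv <- function(df, file) {
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
  }
  is_skipped <- function(x) is.list(x) && isTRUE(x$skipped)

  dt <- s$decision_table
  wcsv(data.frame(decision = dt$breakdown$decision, count = dt$breakdown$count,
                  percent = dt$breakdown$percent), "decision_table.csv")
  wcsv(as.data.frame(s$indices), "indices.csv")
  wcsv(s$summaries, "summaries.csv")
  wcsv(s$glm_sdt$coefficients, "glm_sdt.csv")
  wcsv(rbind(cbind(outcome = "d_prime", s$regression_d_prime$terms),
             cbind(outcome = "criterion", s$regression_criterion$terms)),
       "regressions.csv")
  if (!is_skipped(s$stability)) {
    wcsv(data.frame(index = c("criterion", "d_prime"),
                    r = c(s$stability$criterion$r, s$stability$d_prime$r),
                    p = c(s$stability$criterion$p, s$stability$d_prime$p),
                    n = c(s$stability$criterion$n, s$stability$d_prime$n)),
         "stability.csv")
  }
  if (!is_skipped(s$mediation)) wcsv(s$mediation$paths, "mediation.csv")
  if (!is_skipped(s$power)) {
    wcsv(data.frame(n = s$power$spec$n, power = s$power$power,
                    mc_se = s$power$mc_se), "power.csv")
  }

  lines <- c(
    "# Referral SDT analysis report", "",
    sprintf("- package version: %s", report$provenance$version),
    sprintf("- seed: %d", report$provenance$seed),
    sprintf("- config hash: %s", report$provenance$config_hash), "",
    sprintf("Total decisions: %d (urgent %.2f%%, routine %.2f%%, none %.2f%%)",
            dt$total, dt$breakdown$percent[1], dt$breakdown$percent[2],
            dt$breakdown$percent[3]),
    sprintf("Pooled rates: H = %.4f, FA = %.4f",
            s$pooled_rates["hit_rate"], s$pooled_rates["fa_rate"]),
    sprintf("Mean d' = %.3f (SD %.3f); mean c = %.3f (SD %.3f); n = %d",
            s$summaries$mean[1], s$summaries$sd[1],
            s$summaries$mean[2], s$summaries$sd[2], s$summaries$n[1]),
    ""
  )
  for (nm in c("stability", "group_comparison", "mediation", "power")) {
    if (is_skipped(s[[nm]])) {
      lines <- c(lines, sprintf("Section %s: skipped (%s)", nm, s[[nm]]$reason))
    }
  }
  if (!is_skipped(s$mediation)) {
    ind <- s$mediation$paths[s$mediation$paths$path == "indirect", ]
    lines <- c(lines, sprintf(
      "Mediation: indirect = %.4f [%.4f, %.4f], proportion mediated = %.3f (n = %d)",
      ind$estimate, ind$ci_low, ind$ci_high, s$mediation$proportion_mediated,
      s$mediation$n))
  }
  if (!is_skipped(s$power)) {
    lines <- c(lines, sprintf("Power for the indirect effect: %.3f (MC SE %.4f) at n = %d",
                              s$power$power, s$power$mc_se, s$power$spec$n))
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Referral SDT analysis report\n")
  s <- x$sections
  cat(sprintf("  decisions: %d | responders: %d\n",
              s$decision_table$total, nrow(s$indices)))
  for (nm in names(s)) {
    if (is.list(s[[nm]]) && isTRUE(s[[nm]]$skipped)) {
      cat(sprintf("  %s: skipped (%s)\n", nm, s[[nm]]$reason))
    }
  }
  cat(sprintf("  provenance: seed %d, hash %s, version %s\n",
              x$provenance$seed, substr(x$provenance$config_hash, 1, 8),
              x$provenance$version))
  invisible(x)
}
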