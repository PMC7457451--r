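# Fixture builders shared across the test files. All data are constructed in
# code; nothing is read from disk except round-trip temporaries.

# A small balanced study: each responder's decisions are given as a character
# vector over the vignettes (length n_pos + n_neg, positives first).
make_study <- function(decisions_by_responder, n_pos = 2, n_neg = 2,
                       genders = NULL, ppv = NULL, sens = NULL, exp_years = NULL,
                       stress = NULL, prior = NULL) {
  n <- length(decisions_by_responder)
  ids <- names(decisions_by_responder) %||% sprintf("R%02d", seq_len(n))
  vids <- sprintf("V%02d", seq_len(n_pos + n_neg))
  vignettes <- data.frame(
    vignette_id = vids,
    cancer_risk_percent = c(seq(4, 15, length.out = n_pos),
                            seq(0.5, 2.5, length.out = n_neg)),
    signal_class = rep(c("positive", "negative"), c(n_pos, n_neg))
  )
  responses <- data.frame(
    responder_id = rep(ids, each = n_pos + n_neg),
    vignette_id = rep(vids, n),
    task_label = "colorectal",
    decision = unlist(decisions_by_responder, use.names = FALSE)
  )
  responders <- data.frame(
    responder_id = ids,
    gender = genders %||% rep(c("female", "male"), length.out = n),
    experience_years = exp_years %||% seq(5, 25, length.out = n),
    practice_ppv_percent = ppv %||% seq(3, 12, length.out = n),
    practice_sensitivity_percent = sens %||% rep(50, n),
    stress_score = stress %||% rep(NA_real_, n),
    prior_task = prior %||% rep(FALSE, n)
  )
  study_dataset(responses, vignettes, responders)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Single responder with the given hit / false-alarm counts in a 24+24 design.
make_count_study <- function(hits, fas, n_pos = 24, n_neg = 24) {
  dec <- c(rep("urgent", hits), rep("none", n_pos - hits),
           rep("urgent", fas), rep("none", n_neg - fas))
  make_study(list(R1 = dec), n_pos = n_pos, n_neg = n_neg)
}

# A dataset reproducing the study's printed decision table: cell counts of
# urgent decisions on positive/negative vignettes and the routine/none split,
# distributed over a 252 x 48 grid.
make_table1_study <- function() {
  n_resp <- 252; n_pos <- 24; n_neg <- 24
  pos_urgent <- 4474; neg_urgent <- 2802; routine_total <- 1024
  # distribute urgent counts as evenly as possible across responders
  split_counts <- function(total, n, cap) {
    base <- rep(total %/% n, n)
    extra <- total %% n
    base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    stopifnot(all(base <= cap), sum(base) == total)
    base
  }
  hp <- split_counts(pos_urgent, n_resp, n_pos)
  hn <- split_counts(neg_urgent, n_resp, n_neg)
  decisions <- vector("list", n_resp)
  for (i in seq_len(n_resp)) {
    decisions[[i]] <- c(rep("urgent", hp[i]), rep("none", n_pos - hp[i]),
                        rep("urgent", hn[i]), rep("none", n_neg - hn[i]))
  }
  names(decisions) <- sprintf("R%03d", seq_len(n_resp))
  ds <- make_study(decisions, n_pos = n_pos, n_neg = n_neg)
  # relabel the first `routine_total` non-urgent decisions as routine
  non_urgent <- which(ds$responses$decision != "urgent")
  ds$responses$decision[non_urgent[seq_len(routine_total)]] <- "routine"
  ds
}

# Independent inverse-normal oracle: solves pnorm(z) = p by bisection-backed
# root finding, never calling qnorm.
z_oracle <- function(p) {
  vapply(p, function(pi) {
    stats::uniroot(function(z) stats::pnorm(z) - pi, c(-10, 10),
                   tol = 1e-12)$root
  }, numeric(1))
}

# Vector with exact mean and exact sample SD (n >= 2).
exact_mean_sd <- function(n, mean, sd) {
  z <- seq_len(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}
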