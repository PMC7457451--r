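#' Per-responder hit and false-alarm counts
#'
#' Counts, for one responder, the urgent referrals on positive vignettes
#' (hits) and on negative vignettes (false alarms), after dichotomizing the
#' decision (urgent vs. not urgent).
#'
#' @param ds A `study_dataset`.
#' @param responder_id Responder identifier.
#' @param task_label Optional task to restrict to (e.g. `"colorectal"`);
#'   `NULL` uses all of the responder's responses.
#' @return A list of class `rate_table`: `n_positive`, `n_negative`, `hits`,
#'   `false_alarms`.
#' @export
count_rates <- function(ds, responder_id, task_label = NULL) {
  stopifnot(inherits(ds, "study_dataset"))
  keep <- ds$responses$responder_id == responder_id
  if (!is.null(task_label)) keep <- keep & ds$responses$task_label == task_label
  if (!any(keep)) {
    refersdt_abort(sprintf("no responses for responder '%s'", responder_id),
                   "refersdt_undefined_rates")
  }
  cls <- vignette_class_of(ds)[keep]
  y <- dichotomize(ds$responses$decision[keep])
  pos <- cls == "positive"
  if (!any(pos) || all(pos)) {
    refersdt_abort(
      sprintf("responder '%s' lacks positive or negative vignette responses; hit/false-alarm rates are undefined",
              responder_id),
      "refersdt_undefined_rates"
    )
  }
  structure(list(n_positive = sum(pos), n_negative = sum(!pos),
                 hits = sum(y[pos]), false_alarms = sum(y[!pos])),
            class = "rate_table")
}

#' Corrected hit and false-alarm rates
#'
#' Applies the 0.5 count correction to a rate table: 0.5 is added to every
#' response cell (urgent and non-urgent, for both vignette classes), so the
#' corrected rates are `(hits + 0.5) / (n_positive + 1)` and
#' `(false_alarms + 0.5) / (n_negative + 1)`. The correction is applied to all
#' responders, not only those at a 0 or 1 boundary, and always yields rates
#' strictly inside (0, 1).
#'
#' @param rt A `rate_table` from [count_rates()], or any list with fields
#'   `n_positive`, `n_negative`, `hits`, `false_alarms`.
#' @return Named numeric vector `c(hit_rate, fa_rate)`.
#' @export
corrected_rates <- function(rt) {
  stopifnot(rt$hits >= 0, rt$hits <= rt$n_positive,
            rt$false_alarms >= 0, rt$false_alarms <= rt$n_negative,
            rt$n_positive >= 1, rt$n_negative >= 1)
  c(hit_rate = (rt$hits + 0.5) / (rt$n_positive + 1),
    fa_rate = (rt$false_alarms + 0.5) / (rt$n_negative + 1))
}

check_rates_interior <- function(hit_rate, fa_rate) {
  if (any(hit_rate <= 0 | hit_rate >= 1 | fa_rate <= 0 | fa_rate >= 1)) {
    refersdt_abort(
      "rates must lie strictly in (0, 1); apply corrected_rates() to boundary counts first",
      "refersdt_domain_error"
    )
  }
}

#' Discrimination index d'
#'
#' Equal-variance Gaussian signal-detection discrimination:
#' `d' = z(H) - z(FA)`, where `z` is the inverse of the cumulative standard
#' normal distribution function, `H` the hit rate and `FA` the false-alarm
#' rate. Vectorized.
#'
#' @param hit_rate,fa_rate Rates strictly in (0, 1).
#' @return Numeric d' value(s).
#' @export
dprime <- function(hit_rate, fa_rate) {
  check_rates_interior(hit_rate, fa_rate)
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Response-bias criterion c
#'
#' Equal-variance Gaussian response bias: `c = -0.5 * [z(H) + z(FA)]`.
#' Negative values indicate a lenient (refer-prone) criterion, positive a
#' conservative one; `c = 0` weighs misses and false alarms equally.
#' Vectorized.
#'
#' @inheritParams dprime
#' @return Numeric criterion value(s).
#' @export
criterion <- function(hit_rate, fa_rate) {
  check_rates_interior(hit_rate, fa_rate)
  -0.5 * (stats::qnorm(hit_rate) + stats::qnorm(fa_rate))
}

#' Per-responder SDT indices
#'
#' Computes, for every responder in the dataset, the corrected hit and
#' false-alarm rates and the derived d' and criterion. The 0.5 correction is
#' applied to all responders.
#'
#' @param ds A `study_dataset`.
#' @param task_label Optional task restriction.
#' @return A data.frame of class `sdt_indices` with one row per responder:
#'   `responder_id`, `n_positive`, `n_negative`, `hits`, `false_alarms`,
#'   `hit_rate`, `fa_rate`, `d_prime`, `criterion`, `corrected` (TRUE).
#' @export
compute_indices <- function(ds, task_label = NULL) {
  stopifnot(inherits(ds, "study_dataset"))
  resp <- ds$responses
  if (!is.null(task_label)) resp <- resp[resp$task_label == task_label, , drop = FALSE]
  if (nrow(resp) == 0) {
    refersdt_abort("no responses to compute indices from", "refersdt_empty_input")
  }
  cls <- as.character(ds$vignettes$signal_class)[
    match(resp$vignette_id, ds$vignettes$vignette_id)]
  y <- dichotomize(resp$decision)
  pos <- cls == "positive"
  id <- factor(resp$responder_id)

  np <- as.vector(rowsum(as.integer(pos), id))
  nn <- as.vector(rowsum(as.integer(!pos), id))
  hits <- as.vector(rowsum(as.integer(y == 1L & pos), id))
  fas <- as.vector(rowsum(as.integer(y == 1L & !pos), id))
  ids <- levels(id)

  bad <- np == 0 | nn == 0
  if (any(bad)) {
    refersdt_abort(
      sprintf("rates undefined (no positive or no negative responses) for responder(s): %s",
              paste(ids[bad], collapse = ", ")),
      "refersdt_undefined_rates"
    )
  }
  h <- (hits + 0.5) / (np + 1)
  f <- (fas + 0.5) / (nn + 1)
  out <- data.frame(
    responder_id = ids, n_positive = np, n_negative = nn,
    hits = hits, false_alarms = fas,
    hit_rate = h, fa_rate = f,
    d_prime = dprime(h, f), criterion = criterion(h, f),
    corrected = TRUE, stringsAsFactors = FALSE
  )
  class(out) <- c("sdt_indices", "data.frame")
  out
}

#' Pooled (uncorrected) hit and false-alarm rates
#'
#' Sample-level rates over all responses combined: total urgent referrals on
#' positive cases divided by positive-case responses, and likewise for
#' negative cases. Reported uncorrected (raw ratios), matching how pooled
#' rates are tabulated from the full decision table.
#'
#' @param ds A `study_dataset`.
#' @return Named numeric vector `c(hit_rate, fa_rate)`.
#' @export
pooled_rates <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  if (nrow(ds$responses) == 0) {
    refersdt_abort("empty response pool", "refersdt_empty_input")
  }
  cls <- vignette_class_of(ds)
  y <- dichotomize(ds$responses$decision)
  pos <- cls == "positive"
  if (!any(pos) || all(pos)) {
    refersdt_abort("pool must contain both positive- and negative-case responses",
                   "refersdt_undefined_rates")
  }
  c(hit_rate = sum(y[pos]) / sum(pos), fa_rate = sum(y[!pos]) / sum(!pos))
}

#' Distribution summaries of the SDT indices
#'
#' Mean, sample SD (n - 1 denominator), median (midpoint convention for even
#' n), minimum, maximum and n for d' and the criterion across responders.
#'
#' @param indices An `sdt_indices` data.frame from [compute_indices()].
#' @return A data.frame with rows `d_prime` and `criterion` and columns
#'   `index`, `mean`, `sd`, `median`, `min`, `max`, `n`.
#' @export
summarize_indices <- function(indices) {
  if (nrow(indices) < 2) {
    refersdt_abort("at least 2 responders are needed to summarize the indices",
                   "refersdt_empty_input")
  }
  one <- function(v, name) {
    data.frame(index = name, mean = mean(v), sd = stats::sd(v),
               median = stats::median(v), min = min(v), max = max(v),
               n = length(v))
  }
  rbind(one(indices$d_prime, "d_prime"), one(indices$criterion, "criterion"))
}

#' Theoretical (isosensitivity) ROC curves
#'
#' Points on the equal-variance Gaussian ROC curve of fixed d': for each
#' false-alarm rate on an even grid in (0, 1),
#' `hit_rate = pnorm(qnorm(fa_rate) + d_prime)`. Useful for overlaying curves
#' at d' = 0, 1, 2, 3 on a hit/false-alarm scatterplot of responders.
#'
#' @param d_prime Numeric vector of d' values (one curve each).
#' @param n_points Number of grid points per curve (>= 2).
#' @param fa_rates Optional explicit false-alarm rates in (0, 1), overriding
#'   the even grid.
#' @return data.frame with columns `d_prime`, `fa_rate`, `hit_rate`.
#' @export
theoretical_roc <- function(d_prime, n_points = 99, fa_rates = NULL) {
  if (is.null(fa_rates)) {
    stopifnot(n_points >= 2)
    fa_rates <- seq(0, 1, length.out = n_points + 2)[-c(1, n_points + 2)]
  }
  stopifnot(all(fa_rates > 0 & fa_rates < 1))
  grid <- expand.grid(fa_rate = fa_rates, d_prime = d_prime,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(d_prime = grid$d_prime, fa_rate = grid$fa_rate,
             hit_rate = stats::pnorm(stats::qnorm(grid$fa_rate) + grid$d_prime))
}
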