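#' Decision categories
#'
#' A referral decision on a vignette is one of three categories: an urgent
#' (two-week-wait) referral to a specialist, a routine referral, or no
#' referral at this stage. Labels are parsed case-insensitively.
#'
#' @format Character vector of the three canonical labels.
#' @export
decision_levels <- c("urgent", "routine", "none")

signal_levels <- c("positive", "negative")
gender_levels <- c("male", "female")

parse_enum <- function(x, levels, what) {
  v <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(v[!is.na(v) & v != ""]), levels)
  if (length(bad) > 0) {
    refersdt_abort(
      sprintf("unknown %s label(s): %s", what, paste(bad, collapse = ", ")),
      "refersdt_unknown_label"
    )
  }
  factor(v, levels = levels)
}

#' Assemble and validate a study dataset
#'
#' Bundles the three tables of a referral signal-detection study — trial-level
#' responses, the vignette table, and the responder table — into a validated
#' `study_dataset` object. Validation enforces the documented schemas:
#' decision/gender/class labels must be known (case-insensitive), every
#' response must reference an existing vignette and responder, the
#' (responder, vignette, task) key must be unique, and each vignette's stored
#' class must agree with the 3% risk threshold (positive iff risk > 3%).
#'
#' @param responses data.frame with columns `responder_id`, `vignette_id`,
#'   `task_label`, `decision`.
#' @param vignettes data.frame with columns `vignette_id`,
#'   `cancer_risk_percent`, `signal_class`.
#' @param responders data.frame with columns `responder_id`, `gender`,
#'   `experience_years`, `practice_ppv_percent`, `practice_sensitivity_percent`,
#'   `stress_score` (NA/blank = missing), `prior_task` (logical).
#' @param stress_range Permitted range of the stress-from-uncertainty scale;
#'   non-missing scores outside it are a validation error. `NULL` disables the
#'   check. Default `c(8, 48)` (8 items, 6-point scoring).
#' @param risk_threshold_percent Cancer-risk threshold (in %) separating
#'   positive from negative vignettes; default 3, the NICE urgent-referral
#'   threshold.
#'
#' @return An object of class `study_dataset`: a list with elements
#'   `responses`, `vignettes`, `responders` (cleaned data.frames).
#' @seealso [read_study()], [write_study()], [tabulate_decisions()]
#' @export
study_dataset <- function(responses, vignettes, responders,
                          stress_range = c(8, 48),
                          risk_threshold_percent = 3) {
  check_columns(responses, c("responder_id", "vignette_id", "task_label", "decision"),
                "responses")
  check_columns(vignettes, c("vignette_id", "cancer_risk_percent", "signal_class"),
                "vignettes")
  check_columns(responders,
                c("responder_id", "gender", "experience_years",
                  "practice_ppv_percent", "practice_sensitivity_percent"),
                "responders")

  responses <- as.data.frame(responses)
  vignettes <- as.data.frame(vignettes)
  responders <- as.data.frame(responders)

  responses$responder_id <- as.character(responses$responder_id)
  responses$vignette_id <- as.character(responses$vignette_id)
  responses$task_label <- as.character(responses$task_label)
  responses$decision <- parse_enum(responses$decision, decision_levels, "decision")
  if (anyNA(responses$decision)) {
    refersdt_abort("missing decision values in responses", "refersdt_unknown_label")
  }

  vignettes$vignette_id <- as.character(vignettes$vignette_id)
  vignettes$cancer_risk_percent <- as.numeric(vignettes$cancer_risk_percent)
  vignettes$signal_class <- parse_enum(vignettes$signal_class, signal_levels,
                                       "signal_class")
  if (any(duplicated(vignettes$vignette_id))) {
    refersdt_abort("duplicate vignette_id in vignette table", "refersdt_duplicate_key")
  }
  implied <- ifelse(vignettes$cancer_risk_percent > risk_threshold_percent,
                    "positive", "negative")
  mism <- which(implied != as.character(vignettes$signal_class))
  if (length(mism) > 0) {
    refersdt_abort(
      sprintf("signal_class disagrees with the %g%% risk threshold for vignette(s): %s",
              risk_threshold_percent,
              paste(vignettes$vignette_id[mism], collapse = ", ")),
      "refersdt_class_mismatch"
    )
  }

  responders$responder_id <- as.character(responders$responder_id)
  responders$gender <- parse_enum(responders$gender, gender_levels, "gender")
  for (col in c("experience_years", "practice_ppv_percent",
                "practice_sensitivity_percent")) {
    responders[[col]] <- as.numeric(responders[[col]])
  }
  if (!"stress_score" %in% names(responders)) responders$stress_score <- NA_real_
  responders$stress_score <- as.numeric(responders$stress_score)
  if (!"prior_task" %in% names(responders)) responders$prior_task <- FALSE
  responders$prior_task <- parse_logical(responders$prior_task)
  if (any(duplicated(responders$responder_id))) {
    refersdt_abort("duplicate responder_id in responder table", "refersdt_duplicate_key")
  }
  if (!is.null(stress_range)) {
    s <- responders$stress_score
    out <- !is.na(s) & (s < stress_range[1] | s > stress_range[2])
    if (any(out)) {
      refersdt_abort(
        sprintf("stress_score outside [%g, %g] for responder(s): %s",
                stress_range[1], stress_range[2],
                paste(responders$responder_id[out], collapse = ", ")),
        "refersdt_out_of_range"
      )
    }
  }

  key <- paste(responses$responder_id, responses$vignette_id, responses$task_label,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- responses[duplicated(key), , drop = FALSE]
    refersdt_abort(
      sprintf("duplicate (responder, vignette, task) key(s), e.g. (%s, %s, %s)",
              dup$responder_id[1], dup$vignette_id[1], dup$task_label[1]),
      "refersdt_duplicate_key"
    )
  }

  orphan_r <- setdiff(responses$responder_id, responders$responder_id)
  if (length(orphan_r) > 0) {
    refersdt_abort(
      sprintf("responses reference responder(s) absent from the responder table: %s",
              paste(orphan_r, collapse = ", ")),
      "refersdt_orphan_reference"
    )
  }
  orphan_v <- setdiff(responses$vignette_id, vignettes$vignette_id)
  if (length(orphan_v) > 0) {
    refersdt_abort(
      sprintf("responses reference vignette(s) absent from the vignette table: %s",
              paste(orphan_v, collapse = ", ")),
      "refersdt_orphan_reference"
    )
  }

  # Incomplete response grids are tolerated (flagged, not fatal): the analysis
  # only assumes each responder saw at least one positive and one negative case.
  n_per <- table(responses$responder_id)
  n_vig <- nrow(vignettes)
  silent <- setdiff(responders$responder_id, responses$responder_id)
  if (length(silent) > 0) {
    warning(sprintf("responder(s) with no responses: %s",
                    paste(silent, collapse = ", ")), call. = FALSE)
  }
  incomplete <- names(n_per)[n_per < n_vig * length(unique(responses$task_label))]
  if (length(incomplete) > 0 && length(unique(responses$task_label)) == 1) {
    warning(sprintf("%d responder(s) answered fewer than %d vignettes",
                    length(incomplete), n_vig), call. = FALSE)
  }

  structure(
    list(responses = responses, vignettes = vignettes, responders = responders),
    class = "study_dataset"
  )
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    refersdt_abort(
      sprintf("%s table is missing column(s): %s", what,
              paste(missing, collapse = ", ")),
      "refersdt_missing_column"
    )
  }
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  out[is.na(x) | v == ""] <- FALSE
  if (anyNA(out)) {
    refersdt_abort("prior_task values must be logical (true/false/1/0)",
                   "refersdt_unknown_label")
  }
  out
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset: %d responses | %d vignettes (%d positive / %d negative) | %d responders\n",
              nrow(x$responses), nrow(x$vignettes),
              sum(x$vignettes$signal_class == "positive"),
              sum(x$vignettes$signal_class == "negative"),
              nrow(x$responders)))
  invisible(x)
}

#' Read a study from its three CSV files
#'
#' Reads and validates the documented CSV schemas (comma-separated, UTF-8,
#' header row, decimal point): `responses.csv` (responder_id, vignette_id,
#' task_label, decision), `vignettes.csv` (vignette_id, cancer_risk_percent,
#' signal_class) and `responders.csv` (responder_id, gender, experience_years,
#' practice_ppv_percent, practice_sensitivity_percent, stress_score,
#' prior_task). Blank `stress_score` cells are missing values.
#'
#' @param responses_path,vignettes_path,responders_path Paths to the CSV files.
#' @param ... Passed to [study_dataset()] (e.g. `stress_range`).
#' @return A validated [study_dataset()].
#' @export
read_study <- function(responses_path, vignettes_path, responders_path, ...) {
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  study_dataset(rd(responses_path), rd(vignettes_path), rd(responders_path), ...)
}

#' Write a study to CSV files
#'
#' Inverse of [read_study()]: writes `responses.csv`, `vignettes.csv` and
#' `responders.csv` under `dir` in the documented schema, so that
#' `read_study()` on the output reproduces the dataset.
#'
#' @param ds A `study_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_study <- function(ds, dir) {
  stopifnot(inherits(ds, "study_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("responses.csv", "vignettes.csv", "responders.csv"))
  utils::write.csv(ds$responses, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$vignettes, paths[2], row.names = FALSE, quote = FALSE)
  resp <- ds$responders
  resp$prior_task <- tolower(as.character(resp$prior_task))
  utils::write.csv(resp, paths[3], row.names = FALSE, quote = FALSE, na = "")
  invisible(paths)
}

#' Dichotomize a referral decision
#'
#' Collapses the trichotomous decision to the binary variable the
#' signal-detection analysis uses: urgent referral = 1; routine referral and
#' no referral = 0 (no urgent referral).
#'
#' @param decision Character or factor vector of decisions
#'   (`"urgent"`, `"routine"`, `"none"`, case-insensitive).
#' @return Integer vector of 0/1.
#' @export
dichotomize <- function(decision) {
  d <- parse_enum(decision, decision_levels, "decision")
  as.integer(d == "urgent")
}

#' Tabulate decisions by vignette class
#'
#' Produces the study's decision tabulation: the 2 x 2 table of urgent /
#' non-urgent decisions against positive / negative vignettes (with margins),
#' and the three-way decision breakdown with percentages of the grand total
#' (reported to 2 decimal places).
#'
#' @param ds A `study_dataset`.
#' @return An object of class `decision_table` with elements `dichotomous`
#'   (3 x 3 matrix including margins), `breakdown` (data.frame: decision,
#'   count, percent), and `total`.
#' @export
tabulate_decisions <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  if (nrow(ds$responses) == 0) {
    refersdt_abort("cannot tabulate an empty dataset", "refersdt_empty_input")
  }
  cls <- vignette_class_of(ds)
  urgent <- dichotomize(ds$responses$decision)
  pos <- cls == "positive"

  m <- matrix(0L, 3, 3,
              dimnames = list(c("urgent", "non_urgent", "total"),
                              c("positive", "negative", "total")))
  m["urgent", "positive"] <- sum(urgent == 1L & pos)
  m["urgent", "negative"] <- sum(urgent == 1L & !pos)
  m["non_urgent", "positive"] <- sum(urgent == 0L & pos)
  m["non_urgent", "negative"] <- sum(urgent == 0L & !pos)
  m["total", ] <- colSums(m[1:2, ])
  m[, "total"] <- rowSums(m[, 1:2])

  counts <- table(factor(ds$responses$decision, levels = decision_levels))
  total <- sum(counts)
  breakdown <- data.frame(
    decision = decision_levels,
    count = as.integer(counts),
    percent = round(100 * as.integer(counts) / total, 2)
  )
  structure(list(dichotomous = m, breakdown = breakdown, total = total),
            class = "decision_table")
}

# signal class of each response's vignette, aligned with ds$responses rows
vignette_class_of <- function(ds) {
  as.character(ds$vignettes$signal_class)[
    match(ds$responses$vignette_id, ds$vignettes$vignette_id)]
}

#' @export
print.decision_table <- function(x, ...) {
  cat("Decisions by vignette class (after dichotomization):\n")
  print(x$dichotomous)
  cat("\nThree-way breakdown:\n")
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}
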