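#' GAD-7 outcome table
#'
#' Loads a subject-by-time-point table of 7-item Generalized Anxiety
#' Disorder questionnaire scores (0-21) with columns `subject_id`, `age`,
#' `gender`, and the four time points `pre`, `post`, `week1`, `month1`
#' (missing follow-ups as NA). With no argument, loads the bundled
#' 28-participant open-label anxiety cohort.
#'
#' @param path TSV path; `NULL` loads the bundled cohort.
#' @return A data frame of class `outcome_table`.
#' @export
read_outcomes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gad7_cohort.tsv", package = "agiletms")
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "gender", "pre", "post", "week1", "month1")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    config_error("outcome table missing column(s): ",
                 paste(missing, collapse = ", "))
  for (tp in time_point_cols()) {
    v <- tab[[tp]]
    if (any(!is.na(v) & (v < 0 | v > 21 | v != round(v))))
      config_error("GAD-7 scores must be integers in [0, 21] (column ", tp, ")")
  }
  class(tab) <- c("outcome_table", "data.frame")
  tab
}

time_point_cols <- function() c("pre", "post", "week1", "month1")

#' Time-point mean imputation
#'
#' Replaces each missing score with the mean of the observed scores at the
#' same time point, carried at full precision. Observed cells are never
#' touched, so no time point's mean changes under imputation. The pattern
#' of imputed cells is recorded in the `"imputed"` attribute.
#'
#' @param tab an `outcome_table`.
#' @param time_points columns to impute (default all four).
#' @return The imputed `outcome_table`.
#' @export
impute_time_point_mean <- function(tab, time_points = time_point_cols()) {
  flags <- list()
  for (tp in time_points) {
    v <- tab[[tp]]
    if (all(is.na(v)))
      degenerate_error("time point ", tp, " has no observed values")
    flags[[tp]] <- is.na(v)
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    tab[[tp]] <- v
  }
  attr(tab, "imputed") <- flags
  tab
}

#' Paired t-test between two time points
#'
#' Two-sided paired t-test of the scores at time points `a` and `b`. By
#' default missing values are first replaced by the time-point mean
#' ([impute_time_point_mean()]); with `complete_case = TRUE` the test is
#' restricted to subjects observed at both time points and no imputation is
#' applied.
#'
#' @param tab an `outcome_table`.
#' @param a,b time-point column names (e.g. `"pre"`, `"post"`).
#' @param complete_case drop subjects with a missing value instead of
#'   imputing.
#' @return A list of class `stat_result`: `statistic`, `df`, `p_value`,
#'   `mean_diff`, `sd_diff`, `n_used`, `imputation_applied`, plus per-time
#'   means/SDs (`mean_a`, `sd_a`, `mean_b`, `sd_b`).
#' @export
paired_t <- function(tab, a, b, complete_case = FALSE) {
  stopifnot(a %in% names(tab), b %in% names(tab))
  if (complete_case) {
    keep <- !is.na(tab[[a]]) & !is.na(tab[[b]])
    x <- tab[[a]][keep]; y <- tab[[b]][keep]
    imputed <- FALSE
  } else {
    it <- impute_time_point_mean(tab, c(a, b))
    x <- it[[a]]; y <- it[[b]]
    imputed <- any(unlist(attr(it, "imputed")))
  }
  if (length(x) < 2) degenerate_error("need at least 2 paired observations")
  if (stats::var(x - y) <= 0)
    degenerate_error("paired differences have zero variance")
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = unname(tt$estimate),
                 sd_diff = stats::sd(x - y), n_used = length(x),
                 imputation_applied = imputed,
                 mean_a = mean(x), sd_a = stats::sd(x),
                 mean_b = mean(y), sd_b = stats::sd(y),
                 method = sprintf("paired t (%s vs %s%s)", a, b,
                                  if (complete_case) ", complete case"
                                  else ", imputed")),
            class = "stat_result")
}

#' One-way repeated-measures ANOVA across time points
#'
#' Classical univariate within-subject decomposition with subjects as
#' blocks: `SS_total = SS_subjects + SS_time + SS_error`, giving
#' `F = MS_time / MS_error` on (k - 1, (k - 1)(n - 1)) degrees of freedom.
#' No sphericity correction is applied. Missing values are imputed with the
#' time-point mean first (or dropped subject-wise with
#' `complete_case = TRUE`).
#'
#' @param tab an `outcome_table`.
#' @param time_points two or more time-point columns.
#' @param complete_case restrict to subjects observed at all time points.
#' @return A `stat_result` with `statistic` (F), `df` (length 2), and
#'   `p_value`.
#' @export
rm_anova <- function(tab, time_points = time_point_cols(),
                     complete_case = FALSE) {
  if (length(time_points) < 2)
    config_error("need at least 2 time points")
  if (complete_case) {
    keep <- stats::complete.cases(tab[time_points])
    y <- as.matrix(tab[keep, time_points])
    imputed <- FALSE
  } else {
    it <- impute_time_point_mean(tab, time_points)
    y <- as.matrix(it[time_points])
    imputed <- any(unlist(attr(it, "imputed")))
  }
  n <- nrow(y); k <- ncol(y)
  if (n < 2) degenerate_error("need at least 2 subjects")
  grand <- mean(y)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_time <- n * sum((colMeans(y) - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_subj - ss_time
  df_time <- k - 1; df_err <- (k - 1) * (n - 1)
  ms_time <- ss_time / df_time; ms_err <- ss_err / df_err
  if (ms_err <= 0) degenerate_error("zero within-subject error variance")
  f <- ms_time / ms_err
  structure(list(statistic = f, df = c(df_time, df_err),
                 p_value = stats::pf(f, df_time, df_err, lower.tail = FALSE),
                 n_used = n, imputation_applied = imputed,
                 method = sprintf("repeated-measures ANOVA (%s)",
                                  paste(time_points, collapse = ", "))),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$method, "\n")
  if (length(x$df) == 2)
    cat(sprintf("  F(%g, %g) = %.3f, p = %.4g, n = %d\n",
                x$df[1], x$df[2], x$statistic, x$p_value, x$n_used))
  else
    cat(sprintf("  t(%g) = %.3f, p = %.4g, n = %d\n",
                x$df, x$statistic, x$p_value, x$n_used))
  if (!is.null(x$mean_a))
    cat(sprintf("  M_a = %.2f (SD %.2f), M_b = %.2f (SD %.2f)\n",
                x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  invisible(x)
}

#' Cohort descriptives
#'
#' Sample size by gender, mean and SD of age, and per-time-point mean/SD of
#' the observed scores and of the imputed scores, with observed counts.
#'
#' @param tab an `outcome_table`.
#' @return A list of class `cohort_descriptives`.
#' @export
cohort_descriptives <- function(tab) {
  if (!nrow(tab))
    return(structure(list(n = 0L, n_by_gender = table(character()),
                          age_mean = NA_real_, age_sd = NA_real_,
                          time_points = NULL),
                     class = "cohort_descriptives"))
  imp <- impute_time_point_mean(tab)
  tps <- do.call(rbind, lapply(time_point_cols(), function(tp) {
    obs <- tab[[tp]][!is.na(tab[[tp]])]
    data.frame(time_point = tp, n_observed = length(obs),
               mean_observed = mean(obs), sd_observed = stats::sd(obs),
               mean_imputed = mean(imp[[tp]]), sd_imputed = stats::sd(imp[[tp]]))
  }))
  structure(list(n = nrow(tab), n_by_gender = table(tab$gender),
                 age_mean = mean(tab$age), age_sd = stats::sd(tab$age),
                 time_points = tps),
            class = "cohort_descriptives")
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  cat(sprintf("Cohort: n = %d (%s), age %.1f +/- %.1f\n", x$n,
              paste(names(x$n_by_gender), x$n_by_gender, sep = " = ",
                    collapse = ", "),
              x$age_mean, x$age_sd))
  if (!is.null(x$time_points)) {
    tp <- x$time_points
    for (i in seq_len(nrow(tp)))
      cat(sprintf("  %-7s n=%2d  observed %.2f (SD %.2f)  imputed %.2f (SD %.2f)\n",
                  tp$time_point[i], tp$n_observed[i], tp$mean_observed[i],
                  tp$sd_observed[i], tp$mean_imputed[i], tp$sd_imputed[i]))
  }
  invisible(x)
}

#' Prescribed-target table
#'
#' Loads a long-format table of prescribed stimulation targets with columns
#' `subject_id`, `parcel_id`, `protocol`. With no argument, loads the
#' bundled cohort's prescriptions.
#'
#' @param path TSV path; `NULL` loads the bundled table.
#' @return A data frame of class `prescription_table`.
#' @export
read_prescription_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cohort_prescriptions.tsv",
                        package = "agiletms")
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", "parcel_id", "protocol"), names(tab))
  if (length(missing))
    config_error("prescription table missing column(s): ",
                 paste(missing, collapse = ", "))
  if (!all(tab$protocol %in% c("cTBS", "iTBS")))
    config_error("protocol must be cTBS or iTBS")
  class(tab) <- c("prescription_table", "data.frame")
  tab
}

#' Target frequency tabulation
#'
#' Per-parcel participant counts and within-parcel protocol percentages
#' (rounded to whole percent), plus the number of participants with no 8Av
#' or PGs target in either hemisphere.
#'
#' @param presc a `prescription_table` (long format, one row per
#'   subject-target).
#' @return A list of class `target_frequencies`: `by_parcel` (data frame
#'   with `parcel_id`, `n_subjects`, `n_ctbs`, `pct_ctbs`),
#'   `n_without_8av_pgs`, and `n_subjects`.
#' @export
target_frequencies <- function(presc = read_prescription_table()) {
  subjects <- unique(presc$subject_id)
  by_parcel <- do.call(rbind, lapply(split(presc, presc$parcel_id),
    function(d) {
      data.frame(parcel_id = d$parcel_id[1],
                 n_subjects = length(unique(d$subject_id)),
                 n_ctbs = sum(d$protocol == "cTBS"),
                 pct_ctbs = round(100 * mean(d$protocol == "cTBS")))
    }))
  by_parcel <- by_parcel[order(-by_parcel$n_subjects, by_parcel$parcel_id), ]
  rownames(by_parcel) <- NULL
  core <- c("L_8Av", "R_8Av", "L_PGs", "R_PGs")
  with_core <- unique(presc$subject_id[presc$parcel_id %in% core])
  structure(list(by_parcel = by_parcel,
                 n_without_8av_pgs = length(setdiff(subjects, with_core)),
                 n_subjects = length(subjects)),
            class = "target_frequencies")
}

#' @export
print.target_frequencies <- function(x, ...) {
  cat(sprintf("Target frequencies over %d participants\n", x$n_subjects))
  top <- utils::head(x$by_parcel, 8)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-8s %2d participants (%d%% cTBS)\n", top$parcel_id[i],
                top$n_subjects[i], top$pct_ctbs[i]))
  cat(sprintf("  participants with neither 8Av nor PGs: %d\n",
              x$n_without_8av_pgs))
  invisible(x)
}
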