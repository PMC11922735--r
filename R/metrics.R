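# Cohort-level accuracy statistics --------------------------------------------

#' Confusion-matrix statistics
#'
#' Standard ratios on TP/FP/FN/TN counts, reported in percent. The F1 score
#' is the harmonic mean of PPV and sensitivity. Ratios with a zero
#' denominator are reported as `NA`, never coerced to 0 or 100.
#'
#' @param tp,fp,fn,tn Non-negative counts (vectorized).
#' @return Data.frame with columns `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`, `f1`, all in percent.
#' @examples
#' confusion_stats(tp = 8, fp = 2, fn = 2, tn = 88)
#' @export
confusion_stats <- function(tp, fp, fn, tn) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0), all(tn >= 0))
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  sens <- pct(tp, tp + fn)
  spc <- pct(tn, tn + fp)
  ppv <- pct(tp, tp + fp)
  npv <- pct(tn, tn + fn)
  acc <- pct(tp + tn, tp + fp + fn + tn)
  f1 <- f1_score(ppv, sens)
  data.frame(sensitivity = sens, specificity = spc, ppv = ppv, npv = npv,
             accuracy = acc, f1 = f1)
}

#' F1 score from PPV and sensitivity
#'
#' @param ppv,sensitivity In percent (or any common scale).
#' @return `2 * ppv * sensitivity / (ppv + sensitivity)` on the same scale;
#'   `NA` when either input is missing or the denominator is zero.
#' @examples
#' f1_score(27.2, 98.0)
#' @export
f1_score <- function(ppv, sensitivity) {
  ifelse(!is.na(ppv) & !is.na(sensitivity) & (ppv + sensitivity) > 0,
         2 * ppv * sensitivity / (ppv + sensitivity), NA_real_)
}

#' Tabulate verdict counts per reader and class
#'
#' @param verdicts Data.frame of verdicts ([match_strip()]); rows with
#'   verdict "excluded" are ignored.
#' @return Data.frame with one row per (reader, class): `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
verdict_counts <- function(verdicts) {
  v <- verdicts[verdicts$verdict != "excluded", , drop = FALSE]
  key <- interaction(v$reader, v$class, drop = TRUE, sep = "\r")
  cnt <- function(what) as.numeric(tapply(v$verdict == what, key, sum))
  ks <- strsplit(levels(key), "\r", fixed = TRUE)
  data.frame(reader = vapply(ks, `[`, "", 1), class = vapply(ks, `[`, "", 2),
             tp = cnt("true_positive"), fp = cnt("false_positive"),
             fn = cnt("false_negative"), tn = cnt("true_negative"))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the rows (or elements) of `data` with replacement `n_reps`
#' times and returns the percentile interval of the statistic. Replicates
#' on which the statistic is undefined (`NA`/`NaN`/infinite) are dropped;
#' their count is attached as attribute `dropped`.
#'
#' @param data A vector or data.frame of patient-level observations.
#' @param statistic Function of `data` returning one number.
#' @param n_reps Number of bootstrap replications (default 1,000).
#' @param seed Integer seed (mandatory; results are deterministic given it).
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector `c(point, lower, upper)` with attribute
#'   `dropped`.
#' @export
bootstrap_ci <- function(data, statistic, n_reps = 1000, seed,
                         conf_level = 0.95) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for the bootstrap")
  n <- NROW(data)
  if (n < 1) stop("bootstrap needs at least one observation")
  set.seed(seed)
  point <- statistic(data)
  take <- if (is.data.frame(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) data[idx]
  }
  reps <- numeric(n_reps)
  for (b in seq_len(n_reps)) {
    reps[b] <- statistic(take(sample.int(n, n, replace = TRUE)))
  }
  ok <- is.finite(reps)
  q <- stats::quantile(reps[ok], c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2),
                       names = FALSE)
  structure(c(point = point, lower = q[1], upper = q[2]),
            dropped = sum(!ok))
}

#' Relative risk with Fisher's exact test
#'
#' Compares the event rate of method B to method A:
#' `RR = (fn_b / n_b) / (fn_a / n_a)`. The confidence interval uses the
#' standard normal approximation on the log relative risk; the p-value is
#' the two-sided Fisher exact test on the 2x2 table. With zero events in
#' both arms the relative risk is undefined and reported as `NA`.
#'
#' @param fn_a,n_a Events and group size for the reference method A.
#' @param fn_b,n_b Events and group size for method B.
#' @param conf_level Confidence level for the CI.
#' @return List with `rr`, `lower`, `upper`, `p_value`.
#' @examples
#' relative_risk(1, 10, 5, 10)
#' @export
relative_risk <- function(fn_a, n_a, fn_b, n_b, conf_level = 0.95) {
  stopifnot(fn_a >= 0, fn_b >= 0, fn_a <= n_a, fn_b <= n_b, n_a > 0, n_b > 0)
  rr <- if (fn_a == 0 && fn_b == 0) NA_real_
        else (fn_b / n_b) / (fn_a / n_a)
  if (!is.na(rr) && is.finite(rr) && fn_a > 0 && fn_b > 0) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / fn_a - 1 / n_a + 1 / fn_b - 1 / n_b)
    lo <- exp(log(rr) - z * se)
    hi <- exp(log(rr) + z * se)
  } else {
    lo <- NA_real_
    hi <- NA_real_
  }
  tab <- matrix(c(fn_a, n_a - fn_a, fn_b, n_b - fn_b), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  list(rr = rr, lower = lo, upper = hi, p_value = p)
}

#' Scale class counts found in a partial cohort search to the full cohort
#'
#' Counts observed after searching `recordings_searched` of `cohort_size`
#' recordings are multiplied by `cohort_size / recordings_searched`. When
#' the whole cohort was searched the weight is exactly 1.
#'
#' @param counts Numeric vector of counts.
#' @param recordings_searched Source population size for the class (> 0).
#' @param cohort_size Full cohort size.
#' @return Weighted counts.
#' @examples
#' weight_to_population(12, 7303, 14606)  # exactly doubled
#' @export
weight_to_population <- function(counts, recordings_searched, cohort_size) {
  if (any(recordings_searched <= 0)) stop("recordings_searched must be positive")
  if (any(recordings_searched > cohort_size)) {
    stop("recordings_searched cannot exceed the cohort size")
  }
  counts * cohort_size / recordings_searched
}

# Patient-level outcomes -------------------------------------------------------

#' Collapse strip verdicts to patient-level outcomes
#'
#' For each sampled strip, the verdicts of its trigger class define the
#' patient-level outcome for that (patient, class): the panel confirmed the
#' class if any reader's verdict is TP or FN, and a reader detected it if
#' that reader's verdict is TP. Because at most one strip per class is
#' sampled per patient, the result has one row per (patient, class,
#' reader).
#'
#' @param strips Strips data.frame from [sample_strips()].
#' @param verdicts Verdicts data.frame from [adjudicate_strips()].
#' @param recordings Recordings data.frame (for `duration_days`).
#' @return Data.frame: `patient_id`, `recording_id`, `class`, `reader`,
#'   `verdict`, `misclassified_as`, `panel_confirmed_present`, `detected`,
#'   `recording_days`.
#' @export
patient_outcomes <- function(strips, verdicts, recordings) {
  cols <- c("strip_id", setdiff(c("recording_id", "patient_id", "trigger_class"),
                                names(verdicts)))
  v <- merge(verdicts, strips[, cols, drop = FALSE], by = "strip_id")
  v <- v[v$class == v$trigger_class, , drop = FALSE]
  conf <- tapply(v$verdict %in% c("true_positive", "false_negative"),
                 v$strip_id, any)
  v$panel_confirmed_present <- as.logical(conf[as.character(v$strip_id)])
  v$detected <- v$verdict == "true_positive"
  days <- stats::setNames(recordings$duration_days, recordings$recording_id)
  v$recording_days <- as.numeric(days[as.character(v$recording_id)])
  v$trigger_class <- NULL
  rownames(v) <- NULL
  v
}

#' Patient-level false negatives and rates per 1,000 patients
#'
#' A patient counts as a false negative for reader R and class c when the
#' panel confirmed the class, R detected no concordant episode over the
#' whole recording, and at least one other reader detected one (patients
#' missed by every reader are undetectable by construction and counted for
#' nobody). Rates are per 1,000 patients of the effective population: the
#' class's source population from the sampling ledger, scaled to the full
#' cohort by prevalence weighting when `cohort_size` is given.
#'
#' @param outcomes Data.frame from [patient_outcomes()].
#' @param ledger Sampling ledger from [sample_strips()], or `NULL` to use
#'   the number of distinct patients in `outcomes` as the population.
#' @param cohort_size Full cohort size for weighting; defaults to the
#'   ledger population (weight 1).
#' @return Data.frame per (class, reader): `fn`, `tp`, `fp`,
#'   `fn_weighted`, `population`, `fn_per_1000`, `tp_per_1000`,
#'   `fp_per_1000`.
#' @export
patient_false_negatives <- function(outcomes, ledger = NULL,
                                    cohort_size = NULL) {
  readers <- sort(unique(outcomes$reader))
  classes <- sort(unique(outcomes$class))
  out <- list()
  for (cl in classes) {
    oc <- outcomes[outcomes$class == cl, , drop = FALSE]
    det <- tapply(oc$detected, oc$patient_id, any)
    pop <- if (!is.null(ledger)) {
      ledger$recordings_searched[match(cl, ledger$class)]
    } else {
      length(unique(outcomes$patient_id))
    }
    if (is.na(pop) || pop <= 0) stop("zero population for class ", cl)
    w <- if (is.null(cohort_size)) 1 else cohort_size / pop
    eff_pop <- if (is.null(cohort_size)) pop else cohort_size
    for (rd in readers) {
      orc <- oc[oc$reader == rd, , drop = FALSE]
      other_det <- as.logical(det[as.character(orc$patient_id)]) & !orc$detected
      fn <- sum(orc$panel_confirmed_present & !orc$detected & other_det)
      tp <- sum(orc$detected)
      fp <- sum(orc$verdict == "false_positive")
      out[[paste(cl, rd)]] <- data.frame(
        class = cl, reader = rd, fn = fn, tp = tp, fp = fp,
        fn_weighted = fn * w, population = eff_pop,
        fn_per_1000 = 1000 * fn * w / eff_pop,
        tp_per_1000 = 1000 * tp * w / eff_pop,
        fp_per_1000 = 1000 * fp * w / eff_pop)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' False-positive events per 1,000 patient-days
#'
#' The point rate is 1,000 times the (optionally prevalence-weighted) total
#' number of false-positive events divided by the total patient-days of
#' monitoring; the median and IQR are taken across the per-class rates.
#'
#' @param verdicts Verdicts data.frame; all `false_positive` rows count as
#'   events.
#' @param recordings Recordings data.frame; `duration_days` summed over the
#'   cohort gives the denominator.
#' @param ledger Optional sampling ledger for prevalence weighting.
#' @param cohort_size Full cohort size (required when `ledger` is given).
#' @param reader Optional reader to restrict to.
#' @return List with `rate_per_1000_patient_days`, `median`, `iqr`
#'   (length-2), and `per_class` (data.frame of per-class rates).
#' @export
fp_rate_per_1000_patient_days <- function(verdicts, recordings, ledger = NULL,
                                          cohort_size = NULL, reader = NULL) {
  total_days <- sum(recordings$duration_days)
  if (total_days <= 0) stop("total patient-days must be positive")
  v <- verdicts[verdicts$verdict == "false_positive", , drop = FALSE]
  if (!is.null(reader)) v <- v[v$reader == reader, , drop = FALSE]
  classes <- sort(unique(verdicts$class))
  fp <- vapply(classes, function(cl) sum(v$class == cl), numeric(1))
  w <- rep(1, length(classes))
  if (!is.null(ledger) && !is.null(cohort_size)) {
    m <- match(classes, ledger$class)
    w <- ifelse(is.na(m), 1,
                cohort_size / ledger$recordings_searched[m])
  }
  rate_c <- 1000 * fp * w / total_days
  per_class <- data.frame(class = classes, fp = unname(fp),
                          rate_per_1000_patient_days = unname(rate_c))
  list(rate_per_1000_patient_days = 1000 * sum(fp * w) / total_days,
       median = stats::median(rate_c),
       iqr = unname(stats::quantile(rate_c, c(0.25, 0.75), type = 1)),
       per_class = per_class)
}
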