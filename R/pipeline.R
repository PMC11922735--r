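# End-to-end evaluation pipeline ----------------------------------------------

#' Adjudicate sampled strips for every reader against the panel
#'
#' Runs [match_strip()] for each strip and reader, using the panel episode
#' set as the gold standard. Episodes are filtered to those overlapping
#' each strip window; beat tracks, when supplied, refine the beat-type
#' overlap criterion.
#'
#' @param strips Strips from [sample_strips()].
#' @param episodes Episode table containing `reader == "panel"` rows and
#'   one reader value per method.
#' @param rules An [overlap_rules()].
#' @param taxonomy A [rhythm_taxonomy()].
#' @param classes Classes to adjudicate in every strip; defaults to the
#'   critical and noncritical classes present in `episodes`.
#' @param readers Reader methods; defaults to all non-panel readers.
#' @param tracks Optional beat-record table (columns `recording_id`,
#'   `annotator`, `sample`, `beat_class`) covering the strip windows.
#' @return Verdict data.frame (one row per strip, reader, class) with
#'   `recording_id` and `patient_id` attached.
#' @export
adjudicate_strips <- function(strips, episodes, rules = overlap_rules(),
                              taxonomy = rhythm_taxonomy(), classes = NULL,
                              readers = NULL, tracks = NULL) {
  if (is.null(readers)) readers <- setdiff(sort(unique(episodes$reader)), "panel")
  if (is.null(classes)) {
    cand <- unique(episodes$class)
    classes <- sort(cand[criticality(cand) %in% c("critical", "noncritical")])
  }
  eps_by_rec <- split(episodes, episodes$recording_id)
  trk_by_rec <- if (!is.null(tracks)) split(tracks, tracks$recording_id) else NULL
  out <- vector("list", nrow(strips) * length(readers))
  pos <- 0L
  for (i in seq_len(nrow(strips))) {
    st <- strips[i, , drop = FALSE]
    e <- eps_by_rec[[as.character(st$recording_id)]]
    w0 <- st$start_sample
    w1 <- st$end_sample
    ew <- if (is.null(e)) NULL else
      e[e$start_sample < w1 & e$end_sample > w0, , drop = FALSE]
    p_eps <- if (is.null(ew)) .empty_episodes_min() else
      ew[ew$reader == "panel", , drop = FALSE]
    tw <- if (!is.null(trk_by_rec)) trk_by_rec[[as.character(st$recording_id)]] else NULL
    p_trk <- if (!is.null(tw)) {
      tt <- tw[tw$annotator == "panel" & tw$sample >= w0 & tw$sample < w1, , drop = FALSE]
      if (nrow(tt)) tt else NULL
    } else NULL
    for (rd in readers) {
      r_eps <- if (is.null(ew)) .empty_episodes_min() else
        ew[ew$reader == rd, , drop = FALSE]
      r_trk <- if (!is.null(tw)) {
        tt <- tw[tw$annotator == rd & tw$sample >= w0 & tw$sample < w1, , drop = FALSE]
        if (nrow(tt)) tt else NULL
      } else NULL
      v <- match_strip(st, p_eps, r_eps, rules = rules, taxonomy = taxonomy,
                       classes = classes, panel_track = p_trk,
                       reader_track = r_trk, reader = rd)
      v$recording_id <- st$recording_id
      v$patient_id <- st$patient_id
      pos <- pos + 1L
      out[[pos]] <- v
    }
  }
  res <- do.call(rbind, out[seq_len(pos)])
  rownames(res) <- NULL
  res
}

.empty_episodes_min <- function() {
  data.frame(class = character(0), start_sample = numeric(0),
             end_sample = numeric(0))
}

# patient-resampling weights: one multinomial draw per bootstrap replicate
.boot_weights <- function(n, n_boot) {
  stats::rmultinom(n_boot, n, rep(1, n))
}

# per-patient verdict-count columns for one (reader, class) stratum
.patient_counts <- function(vsub, patients) {
  pi <- match(vsub$patient_id, patients)
  mk <- function(what) {
    x <- numeric(length(patients))
    if (nrow(vsub)) {
      t <- tapply(vsub$verdict == what, pi, sum)
      x[as.integer(names(t))] <- t
    }
    x
  }
  rbind(tp = mk("true_positive"), fp = mk("false_positive"),
        fn = mk("false_negative"), tn = mk("true_negative"))
}

.ci_from_reps <- function(reps, conf_level) {
  a <- (1 - conf_level) / 2
  stats::quantile(reps, c(a, 1 - a), names = FALSE, na.rm = TRUE)
}

#' Aggregate verdicts into cohort-level accuracy statistics
#'
#' Produces, per reader and class (plus a pooled "critical_overall"
#' stratum), the confusion-matrix statistics in percent with
#' patient-resampling percentile bootstrap confidence intervals, and the
#' patient-level FN/TP/FP rates per 1,000 patients with prevalence
#' weighting from the sampling ledger.
#'
#' @param verdicts Verdicts from [adjudicate_strips()] (a variant may have
#'   been applied first).
#' @param outcomes Patient outcomes from [patient_outcomes()].
#' @param recordings Recordings data.frame.
#' @param ledger Sampling ledger from [sample_strips()].
#' @param cohort_size Full cohort size for weighting (`NULL`: the searched
#'   population itself).
#' @param n_boot Bootstrap replications (default 1,000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return List with `confusion` (tidy data.frame: reader, class, metric,
#'   point, lower, upper), `rates` (per-1,000-patient rates with CIs) and
#'   `fp_per_1000_patient_days` (per reader).
#' @export
cohort_metrics <- function(verdicts, outcomes, recordings, ledger = NULL,
                           cohort_size = NULL, n_boot = 1000, seed = 1,
                           conf_level = 0.95) {
  v <- verdicts[verdicts$verdict != "excluded", , drop = FALSE]
  readers <- sort(unique(v$reader))
  classes <- sort(unique(v$class))
  patients <- sort(unique(v$patient_id))
  np <- length(patients)
  set.seed(seed)
  W <- .boot_weights(np, n_boot)

  strata <- c(as.list(classes),
              if (any(criticality(classes) == "critical"))
                list(rhythm_classes("critical")))
  strata_names <- c(classes,
                    if (any(criticality(classes) == "critical"))
                      "critical_overall")
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "accuracy", "f1")
  conf_rows <- list()
  for (rd in readers) {
    vr <- v[v$reader == rd, , drop = FALSE]
    for (si in seq_along(strata)) {
      vs <- vr[vr$class %in% strata[[si]], , drop = FALSE]
      C <- .patient_counts(vs, patients)
      tot <- rowSums(C)
      point <- confusion_stats(tot["tp"], tot["fp"], tot["fn"], tot["tn"])
      B <- C %*% W
      reps <- confusion_stats(B["tp", ], B["fp", ], B["fn", ], B["tn", ])
      for (m in metrics) {
        ci <- .ci_from_reps(reps[[m]], conf_level)
        conf_rows[[length(conf_rows) + 1L]] <- data.frame(
          reader = rd, class = strata_names[si], metric = m,
          point = point[[m]], lower = ci[1], upper = ci[2])
      }
    }
  }
  confusion <- do.call(rbind, conf_rows)
  rownames(confusion) <- NULL

  rates <- patient_false_negatives(outcomes, ledger, cohort_size)
  rate_rows <- list()
  for (cl in unique(rates$class)) {
    oc <- outcomes[outcomes$class == cl, , drop = FALSE]
    pts <- sort(unique(oc$patient_id))
    if (length(pts) == 0) next
    Wc <- .boot_weights(length(pts), n_boot)
    det_any <- tapply(oc$detected, oc$patient_id, any)
    pop_raw <- if (!is.null(ledger)) {
      ledger$recordings_searched[match(cl, ledger$class)]
    } else {
      length(unique(outcomes$patient_id))
    }
    w <- if (is.null(cohort_size)) 1 else cohort_size / pop_raw
    pop <- if (is.null(cohort_size)) pop_raw else cohort_size
    for (rd in readers) {
      orc <- oc[oc$reader == rd, , drop = FALSE]
      m <- match(orc$patient_id, pts)
      fn_i <- tp_i <- fp_i <- numeric(length(pts))
      fn_i[m] <- as.numeric(orc$panel_confirmed_present & !orc$detected &
                              as.logical(det_any[as.character(orc$patient_id)]))
      tp_i[m] <- as.numeric(orc$detected)
      fp_i[m] <- as.numeric(orc$verdict == "false_positive")
      pr <- rates[rates$class == cl & rates$reader == rd, , drop = FALSE]
      for (met in c("fn", "tp", "fp")) {
        ind <- switch(met, fn = fn_i, tp = tp_i, fp = fp_i)
        reps <- 1000 * as.numeric(ind %*% Wc) * w / pop
        ci <- .ci_from_reps(reps, conf_level)
        rate_rows[[length(rate_rows) + 1L]] <- data.frame(
          reader = rd, class = cl,
          metric = paste0(met, "_per_1000"),
          point = pr[[paste0(met, "_per_1000")]],
          lower = ci[1], upper = ci[2])
      }
    }
  }
  rate_ci <- do.call(rbind, rate_rows)
  if (!is.null(rate_ci)) rownames(rate_ci) <- NULL

  fp_days <- lapply(stats::setNames(readers, readers), function(rd) {
    fp_rate_per_1000_patient_days(v, recordings, ledger, cohort_size,
                                  reader = rd)
  })

  list(confusion = confusion, rates = rates, rate_ci = rate_ci,
       fp_per_1000_patient_days = fp_days)
}

#' Relative risk of a patient-level missed diagnosis between two readers
#'
#' Computes the ratio of reader B's to reader A's prevalence-weighted
#' patient-level false-negative rate over the given classes (default: all
#' critical classes present), with a patient-resampling percentile
#' bootstrap CI, a log-normal approximation CI on the raw counts, and a
#' two-sided Fisher exact p-value.
#'
#' @param outcomes Patient outcomes from [patient_outcomes()].
#' @param reader_a Reference method (denominator).
#' @param reader_b Comparison method (numerator).
#' @param classes Classes to pool; default the critical classes present.
#' @param ledger,cohort_size Prevalence weighting inputs as in
#'   [patient_false_negatives()].
#' @param n_boot Bootstrap replications.
#' @param seed Integer seed.
#' @param conf_level Confidence level.
#' @return List with `rr`, `lower`, `upper` (bootstrap CI),
#'   `lower_normal`, `upper_normal`, `p_value`, `fn_a`, `fn_b`,
#'   `rate_a_per_1000`, `rate_b_per_1000`, `dropped` replicates.
#' @export
rr_missed_diagnosis <- function(outcomes, reader_a, reader_b, classes = NULL,
                                ledger = NULL, cohort_size = NULL,
                                n_boot = 1000, seed = 1, conf_level = 0.95) {
  if (is.null(classes)) {
    classes <- intersect(unique(outcomes$class), rhythm_classes("critical"))
  }
  oc <- outcomes[outcomes$class %in% classes, , drop = FALSE]
  if (nrow(oc) == 0) stop("no outcomes for the requested classes")
  pf <- patient_false_negatives(oc, ledger, cohort_size)
  pa <- pf[pf$reader == reader_a, , drop = FALSE]
  pb <- pf[pf$reader == reader_b, , drop = FALSE]
  rate_a <- sum(pa$fn_per_1000)
  rate_b <- sum(pb$fn_per_1000)
  fn_a <- sum(pa$fn)
  fn_b <- sum(pb$fn)
  pops <- if (!is.null(ledger)) {
    sum(ledger$recordings_searched[match(unique(oc$class), ledger$class)])
  } else {
    length(unique(oc$patient_id)) * length(unique(oc$class))
  }
  raw <- relative_risk(fn_a, pops, fn_b, pops, conf_level)

  # per-patient weighted FN contributions for the bootstrap
  pts <- sort(unique(oc$patient_id))
  ca <- cb <- numeric(length(pts))
  for (cl in unique(oc$class)) {
    occ <- oc[oc$class == cl, , drop = FALSE]
    det_any <- tapply(occ$detected, occ$patient_id, any)
    w <- if (is.null(cohort_size)) 1 else {
      pop_c <- if (!is.null(ledger))
        ledger$recordings_searched[match(cl, ledger$class)]
      else length(unique(oc$patient_id))
      cohort_size / pop_c
    }
    for (side in c("a", "b")) {
      rd <- if (side == "a") reader_a else reader_b
      orc <- occ[occ$reader == rd, , drop = FALSE]
      fn_flag <- orc$panel_confirmed_present & !orc$detected &
        as.logical(det_any[as.character(orc$patient_id)])
      m <- match(orc$patient_id, pts)
      if (side == "a") ca[m] <- ca[m] + w * as.numeric(fn_flag)
      else cb[m] <- cb[m] + w * as.numeric(fn_flag)
    }
  }
  set.seed(seed)
  W <- .boot_weights(length(pts), n_boot)
  fa <- as.numeric(ca %*% W)
  fb <- as.numeric(cb %*% W)
  rr_reps <- ifelse(fa > 0, fb / fa, NA_real_)
  ok <- is.finite(rr_reps)
  ci <- .ci_from_reps(rr_reps[ok], conf_level)
  list(rr = if (rate_a > 0) rate_b / rate_a else NA_real_,
       lower = ci[1], upper = ci[2],
       lower_normal = raw$lower, upper_normal = raw$upper,
       p_value = raw$p_value, fn_a = fn_a, fn_b = fn_b,
       rate_a_per_1000 = rate_a, rate_b_per_1000 = rate_b,
       dropped = sum(!ok))
}

#' Run the full evaluation pipeline on a synthetic cohort
#'
#' Convenience wrapper: samples strips from the reader annotations,
#' adjudicates them against the panel, applies the requested verdict
#' variant, collapses to patient outcomes and computes cohort metrics and
#' the between-reader relative risk of a missed critical diagnosis.
#'
#' @param cohort A `rhythm_cohort` from [generate_cohort()], or a list
#'   with `recordings` and `episodes` in the same shape.
#' @param config A [pipeline_config()].
#' @param classes Classes to adjudicate (default: those in the episodes).
#' @param tracks Optional beat-record table for beat-level adjudication.
#' @return List with `strips`, `ledger`, `verdicts`, `outcomes`,
#'   `metrics`, `rr` (when exactly two readers are present) and `manifest`.
#' @export
evaluate_cohort <- function(cohort, config = pipeline_config(),
                            classes = NULL, tracks = NULL) {
  recordings <- cohort$recordings
  episodes <- cohort$episodes
  tax <- config$taxonomy
  readers <- setdiff(sort(unique(episodes$reader)), "panel")

  reader_eps <- episodes[episodes$reader != "panel" &
                           criticality(episodes$class) %in%
                             c("critical", "noncritical"), , drop = FALSE]
  sampled_classes <- classes
  if (is.null(sampled_classes)) {
    cand <- unique(reader_eps$class)
    sampled_classes <- sort(cand[criticality(cand) %in%
                                   c("critical", "noncritical")])
  }
  quotas <- default_quotas(sampled_classes, critical = config$quota_critical,
                           noncritical = config$quota_noncritical)
  samp <- sample_strips(recordings, reader_eps, quotas = quotas,
                        seed = config$seed, classes = sampled_classes,
                        taxonomy = tax)
  verdicts <- adjudicate_strips(samp$strips, episodes, rules = config$rules,
                                taxonomy = tax, classes = sampled_classes,
                                readers = readers, tracks = tracks)
  if (config$variant != "primary") {
    verdicts <- apply_variant(verdicts, config$variant, tax)
  }
  outcomes <- patient_outcomes(samp$strips,
                               verdicts[verdicts$verdict != "excluded", ,
                                        drop = FALSE], recordings)
  metrics <- cohort_metrics(verdicts, outcomes, recordings,
                            ledger = samp$ledger,
                            cohort_size = config$cohort_size %||%
                              nrow(recordings),
                            n_boot = config$n_boot, seed = config$seed + 1)
  rr <- NULL
  if (length(readers) == 2 &&
      any(criticality(unique(outcomes$class)) == "critical")) {
    rr <- rr_missed_diagnosis(outcomes, readers[1], readers[2],
                              ledger = samp$ledger,
                              cohort_size = config$cohort_size %||%
                                nrow(recordings),
                              n_boot = config$n_boot,
                              seed = config$seed + 2)
  }
  manifest <- list(n_recordings = nrow(recordings), readers = readers,
                   classes = sampled_classes, variant = config$variant,
                   seed = config$seed, n_boot = config$n_boot,
                   quotas = as.list(quotas))
  list(strips = samp$strips, ledger = samp$ledger, verdicts = verdicts,
       outcomes = outcomes, metrics = metrics, rr = rr, manifest = manifest)
}

#' Run the evaluation pipeline from beat-annotation tracks
#'
#' Derives episodes from every (recording, annotator) beat track (the
#' annotator "panel" is the gold standard), then runs strip sampling,
#' adjudication and metric aggregation. When `out_dir` is given, all
#' artifacts are written as CSV/JSON together with a run manifest.
#'
#' @param tracks Beat-record table (columns `recording_id`, `annotator`,
#'   `sample`, `beat_class`) or a file path readable by
#'   [read_beat_track()].
#' @param recordings Recordings data.frame (`recording_id`, `patient_id`,
#'   `duration_days`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return As [evaluate_cohort()], plus `episodes`.
#' @export
run_pipeline <- function(tracks, recordings, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(tracks)) tracks <- read_beat_track(tracks)
  rep_v <- validate_inputs(tracks)
  if (nrow(rep_v) > 0) {
    stop("input validation failed (", nrow(rep_v), " problem(s)); ",
         "see validate_inputs()")
  }
  eps <- list()
  for (rid in unique(tracks$recording_id)) {
    tr <- tracks[tracks$recording_id == rid, , drop = FALSE]
    for (ann in unique(tr$annotator)) {
      ta <- tr[tr$annotator == ann, , drop = FALSE]
      e <- derive_episodes(ta[order(ta$sample), c("sample", "beat_class")],
                           config$taxonomy)
      if (nrow(e)) {
        e$recording_id <- rid
        e$patient_id <- recordings$patient_id[
          match(rid, recordings$recording_id)]
        e$reader <- ann
        eps[[paste(rid, ann)]] <- e
      }
    }
  }
  episodes <- do.call(rbind, eps)
  rownames(episodes) <- NULL
  res <- evaluate_cohort(list(recordings = recordings, episodes = episodes),
                         config = config, tracks = tracks)
  res$episodes <- episodes
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(episodes, file.path(out_dir, "episodes.csv"))
    write_table_csv(res$strips, file.path(out_dir, "strips.csv"))
    write_table_csv(res$verdicts, file.path(out_dir, "verdicts.csv"))
    write_table_csv(res$metrics$confusion, file.path(out_dir, "metrics.csv"))
    jsonlite::write_json(res$ledger, file.path(out_dir, "ledger.json"),
                         dataframe = "rows")
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  res
}
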