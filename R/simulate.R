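# Synthetic cohort generation -------------------------------------------------

#' Default episode-process parameters per rhythm
#'
#' One row per generative rhythm process: a Poisson event rate per
#' monitored day and a log-normal episode-duration distribution whose
#' support deliberately straddles the taxonomy threshold for that rhythm
#' (AF and SVT around 30 s, VT around 10 s, gaps around the 2.0/3.5 s
#' bands), plus a normal mean-rate distribution for the tachyarrhythmias.
#' PAC/PVC are instantaneous single-beat events.
#'
#' @return Data.frame with columns `rhythm`, `rate_per_day`, `dur_meanlog`,
#'   `dur_sdlog`, `bpm_mean`, `bpm_sd`, `instant`.
#' @export
class_process_defaults <- function() {
  data.frame(
    rhythm  = c("af",  "svt", "vt",  "gap", "avb2", "avb3", "ear", "ivr",
                "pac", "pvc", "noise"),
    rate_per_day = c(0.02, 0.03, 0.03, 0.03, 0.01, 0.005, 0.02, 0.01,
                     1.5, 1.5, 0.2),
    dur_meanlog = c(log(45), log(22), log(9), log(3.0), log(15), log(25),
                    log(25), log(18), NA, NA, log(60)),
    dur_sdlog = c(1.0, 1.0, 0.7, 0.35, 0.6, 0.8, 0.6, 0.6, NA, NA, 0.8),
    bpm_mean = c(110, 160, 140, NA, 70, 42, 95, 55, NA, NA, NA),
    bpm_sd = c(15, 20, 25, NA, 5, 5, 10, 15, NA, NA, NA),
    instant = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                TRUE, TRUE, FALSE)
  )
}

#' Synthetic cohort configuration
#'
#' Describes the cohort the generator emulates: recording durations drawn
#' from a normal distribution truncated to the device's 1-31 day range
#' (default mean 14, sd 10 days), per-rhythm episode processes, and the
#' baseline sinus RR process used when beats are rendered.
#'
#' @param n_patients Number of patients (one recording each).
#' @param duration_mean_days,duration_sd_days Normal distribution of
#'   recording duration before truncation.
#' @param duration_range Truncation bounds in days.
#' @param classes Episode-process table, see [class_process_defaults()].
#' @param sinus_rr_s Mean sinus RR interval in seconds.
#' @param sinus_rr_sdlog Log-normal sd of the sinus RR process.
#' @param af_rr_sdlog Log-normal sd of the AF RR process (high, for the
#'   irregularly irregular rhythm).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 500, duration_mean_days = 14,
                          duration_sd_days = 10, duration_range = c(1, 31),
                          classes = class_process_defaults(),
                          sinus_rr_s = 0.8, sinus_rr_sdlog = 0.08,
                          af_rr_sdlog = 0.35) {
  stopifnot(n_patients >= 1, duration_range[1] >= 1, duration_range[2] <= 31,
            duration_range[1] < duration_range[2],
            all(classes$rate_per_day >= 0), sinus_rr_s > 0)
  structure(list(n_patients = n_patients,
                 duration_mean_days = duration_mean_days,
                 duration_sd_days = duration_sd_days,
                 duration_range = duration_range, classes = classes,
                 sinus_rr_s = sinus_rr_s, sinus_rr_sdlog = sinus_rr_sdlog,
                 af_rr_sdlog = af_rr_sdlog),
            class = "cohort_config")
}

#' Imperfect reader model
#'
#' Describes one annotation method: the probability of detecting each
#' ground-truth episode, the rate of false events it invents, how it
#' mislabels detected episodes, and how much it jitters episode
#' boundaries.
#'
#' @param name Reader label (e.g. "ai", "technician").
#' @param detection_prob Episode-level detection probability; a scalar, or
#'   a named vector keyed by reported class with an optional `.default`.
#' @param false_events_per_day False-event rate; a scalar applied to every
#'   generative rhythm process, or a named vector keyed by process name
#'   (see [class_process_defaults()]).
#' @param misclass Optional misclassification table: a named list mapping a
#'   reported class to a named probability vector over the classes the
#'   reader reports instead (each vector must sum to 1).
#' @param jitter_sd_s Gaussian sd (seconds) added independently to the
#'   start and end of each detected episode.
#' @param beat_label_noise Probability that a rendered beat carries an
#'   "unknown" label instead of its true one.
#' @return An object of class `reader_model`.
#' @export
reader_model <- function(name, detection_prob = 1, false_events_per_day = 0,
                         misclass = NULL, jitter_sd_s = 0,
                         beat_label_noise = 0) {
  stopifnot(all(detection_prob >= 0), all(detection_prob <= 1),
            all(false_events_per_day >= 0), jitter_sd_s >= 0,
            beat_label_noise >= 0, beat_label_noise <= 1)
  if (!is.null(misclass)) {
    for (cl in names(misclass)) {
      if (abs(sum(misclass[[cl]]) - 1) > 1e-8) {
        stop("misclassification probabilities for '", cl, "' must sum to 1")
      }
    }
  }
  structure(list(name = name, detection_prob = detection_prob,
                 false_events_per_day = false_events_per_day,
                 misclass = misclass, jitter_sd_s = jitter_sd_s,
                 beat_label_noise = beat_label_noise),
            class = "reader_model")
}

.lookup <- function(params, key) {
  if (is.null(names(params))) return(params[[1]])
  if (key %in% names(params)) return(unname(params[[key]]))
  if (".default" %in% names(params)) return(unname(params[[".default"]]))
  0
}

# truncated-normal draw by rejection
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# draw episode intervals for one rhythm process over a set of recordings;
# returns a data.frame in absolute samples, overlap-free within recording
.draw_events <- function(rec_idx, end_sample, proc, fs) {
  n_ev <- length(rec_idx)
  if (n_ev == 0) return(NULL)
  if (proc$instant) {
    start <- floor(stats::runif(n_ev, 0, end_sample[rec_idx] - 1))
    dur_smp <- rep(1, n_ev)
    bpm <- rep(NA_real_, n_ev)
    nb <- rep(1L, n_ev)
  } else {
    dur <- stats::rlnorm(n_ev, proc$dur_meanlog, proc$dur_sdlog)
    dur <- pmin(dur, end_sample[rec_idx] / fs / 2)
    dur_smp <- pmax(round(dur * fs), 2)
    start <- floor(stats::runif(n_ev, 0, end_sample[rec_idx] - dur_smp))
    bpm <- if (is.na(proc$bpm_mean)) rep(NA_real_, n_ev)
           else pmax(stats::rnorm(n_ev, proc$bpm_mean, proc$bpm_sd), 20)
    nb <- if (proc$rhythm == "gap" || proc$rhythm == "noise") rep(0L, n_ev)
          else as.integer(pmax(round(dur_smp / fs * bpm / 60), 1))
  }
  df <- data.frame(rec = rec_idx, rhythm = proc$rhythm,
                   start_sample = start, end_sample = start + dur_smp,
                   n_beats = nb, mean_rate_bpm = bpm)
  # drop same-class overlaps within a recording (keep earlier starts)
  df <- df[order(df$rec, df$start_sample), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  last_end <- -Inf; last_rec <- -1L
  for (i in seq_len(nrow(df))) {
    if (df$rec[i] == last_rec && df$start_sample[i] < last_end) {
      keep[i] <- FALSE
    } else {
      last_rec <- df$rec[i]; last_end <- df$end_sample[i]
    }
  }
  df[keep, , drop = FALSE]
}

#' Generate a synthetic cohort with ground truth and imperfect readers
#'
#' Draws recording durations, ground-truth episodes per rhythm process,
#' and one annotation track per reader model. The consensus panel track
#' equals the ground truth (the panel is the gold standard). Each reader
#' track is obtained by thinning the truth with the reader's per-class
#' detection probability, jittering episode boundaries, re-classifying the
#' jittered interval through the taxonomy, applying the misclassification
#' table, and adding false events placed uniformly over event-free time.
#' Fully reproducible given the seed.
#'
#' @param config A [cohort_config()].
#' @param reader_models List of [reader_model()]s.
#' @param seed Integer seed (mandatory).
#' @param taxonomy A [rhythm_taxonomy()].
#' @return A list of class `rhythm_cohort`: `recordings` (data.frame),
#'   `episodes` (data.frame with `reader` = "panel" plus one value per
#'   reader model), `config`, `models`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), reader_models = list(),
                            seed, taxonomy = rhythm_taxonomy()) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (!all(config$classes$rhythm %in% c("af", "svt", "vt", "gap", "avb2",
                                        "avb3", "ear", "ivr", "pac", "pvc",
                                        "noise"))) {
    stop("config class set is inconsistent with the taxonomy's rhythm processes")
  }
  set.seed(seed)
  fs <- taxonomy$fs
  n <- config$n_patients
  days <- .rtruncnorm(n, config$duration_mean_days, config$duration_sd_days,
                      config$duration_range[1], config$duration_range[2])
  recordings <- data.frame(recording_id = sprintf("R%05d", seq_len(n)),
                           patient_id = sprintf("P%05d", seq_len(n)),
                           duration_days = days)
  end_sample <- days * 86400 * fs

  truth <- list()
  for (k in seq_len(nrow(config$classes))) {
    proc <- config$classes[k, ]
    counts <- stats::rpois(n, proc$rate_per_day * days)
    rec_idx <- rep(seq_len(n), counts)
    truth[[proc$rhythm]] <- .draw_events(rec_idx, end_sample, proc, fs)
  }
  truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  truth <- .finalize_episodes(truth, recordings, "panel", taxonomy)

  episodes <- list(panel = truth)
  for (m in reader_models) {
    episodes[[m$name]] <- .apply_reader(truth, m, recordings, end_sample,
                                        config, taxonomy)
  }
  episodes <- do.call(rbind, episodes)
  rownames(episodes) <- NULL
  structure(list(recordings = recordings, episodes = episodes,
                 config = config, models = reader_models, seed = seed),
            class = "rhythm_cohort")
}

# attach ids/classes, classify through the taxonomy, drop sub-threshold gaps
.finalize_episodes <- function(df, recordings, reader, taxonomy) {
  if (is.null(df) || nrow(df) == 0) return(.empty_reader_episodes(reader))
  fs <- taxonomy$fs
  lab <- classify_episode(df$rhythm, (df$end_sample - df$start_sample) / fs,
                          df$n_beats, df$mean_rate_bpm, taxonomy)
  out <- data.frame(recording_id = recordings$recording_id[df$rec],
                    patient_id = recordings$patient_id[df$rec],
                    reader = reader, rhythm = df$rhythm,
                    class = lab$class, criticality = lab$criticality,
                    start_sample = df$start_sample,
                    end_sample = df$end_sample,
                    duration_s = (df$end_sample - df$start_sample) / fs,
                    n_beats = df$n_beats, mean_rate_bpm = df$mean_rate_bpm)
  out <- out[out$class != "subthreshold_gap", , drop = FALSE]
  out <- out[order(out$recording_id, out$start_sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_reader_episodes <- function(reader) {
  data.frame(recording_id = character(0), patient_id = character(0),
             reader = character(0), rhythm = character(0),
             class = character(0), criticality = character(0),
             start_sample = numeric(0), end_sample = numeric(0),
             duration_s = numeric(0), n_beats = integer(0),
             mean_rate_bpm = numeric(0))
}

.apply_reader <- function(truth, model, recordings, end_sample, config,
                          taxonomy) {
  fs <- taxonomy$fs
  n <- nrow(recordings)

  # detection thinning on the truth
  if (nrow(truth) > 0) {
    p <- vapply(truth$class, function(cl) .lookup(model$detection_prob, cl),
                numeric(1))
    det <- truth[stats::runif(nrow(truth)) < p, , drop = FALSE]
  } else {
    det <- truth
  }

  # boundary jitter, then re-classification of the jittered interval
  if (nrow(det) > 0 && model$jitter_sd_s > 0) {
    rec_end <- end_sample[match(det$recording_id, recordings$recording_id)]
    s <- det$start_sample + round(stats::rnorm(nrow(det), 0,
                                               model$jitter_sd_s * fs))
    e <- det$end_sample + round(stats::rnorm(nrow(det), 0,
                                             model$jitter_sd_s * fs))
    det$start_sample <- pmax(0, pmin(s, rec_end - 2))
    det$end_sample <- pmax(det$start_sample + 2, pmin(e, rec_end))
    det$duration_s <- (det$end_sample - det$start_sample) / fs
    det$n_beats <- ifelse(det$n_beats > 0,
                          pmax(1L, as.integer(round(det$duration_s *
                                 ifelse(is.na(det$mean_rate_bpm), 75,
                                        det$mean_rate_bpm) / 60))),
                          det$n_beats)
    lab <- classify_episode(det$rhythm, det$duration_s, det$n_beats,
                            det$mean_rate_bpm, taxonomy)
    det$class <- lab$class
    det$criticality <- lab$criticality
  }

  # misclassification of the reported class
  if (nrow(det) > 0 && !is.null(model$misclass)) {
    for (i in which(det$class %in% names(model$misclass))) {
      pr <- model$misclass[[det$class[i]]]
      det$class[i] <- sample(names(pr), 1, prob = pr)
    }
    det$criticality <- criticality(det$class)
  }

  # false events, uniform over the recording; draws that land on a truth
  # episode of the same rhythm are dropped
  fe <- list()
  for (k in seq_len(nrow(config$classes))) {
    proc <- config$classes[k, ]
    rate <- .lookup(model$false_events_per_day, proc$rhythm)
    if (rate <= 0) next
    counts <- stats::rpois(n, rate * recordings$duration_days)
    rec_idx <- rep(seq_len(n), counts)
    ev <- .draw_events(rec_idx, end_sample, proc, fs)
    if (is.null(ev) || nrow(ev) == 0) next
    tr <- truth[truth$rhythm == proc$rhythm, , drop = FALSE]
    if (nrow(tr) > 0) {
      rid <- recordings$recording_id[ev$rec]
      clash <- vapply(seq_len(nrow(ev)), function(i) {
        tt <- tr[tr$recording_id == rid[i], , drop = FALSE]
        any(tt$start_sample < ev$end_sample[i] &
            tt$end_sample > ev$start_sample[i])
      }, logical(1))
      ev <- ev[!clash, , drop = FALSE]
    }
    fe[[proc$rhythm]] <- ev
  }
  fe <- if (length(fe)) do.call(rbind, fe) else NULL

  if (nrow(det) > 0) det$reader <- model$name
  detected <- det[det$class != "subthreshold_gap", , drop = FALSE]
  false_eps <- .finalize_episodes(fe, recordings, model$name, taxonomy)
  out <- rbind(detected, false_eps)
  out <- out[order(out$recording_id, out$start_sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}
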