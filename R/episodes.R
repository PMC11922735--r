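# Episode derivation from beat-level annotation tracks ------------------------

.episode_cols <- c("class", "criticality", "start_sample", "end_sample",
                   "duration_s", "n_beats", "mean_rate_bpm")

.empty_episodes <- function() {
  data.frame(class = character(0), criticality = character(0),
             start_sample = numeric(0), end_sample = numeric(0),
             duration_s = numeric(0), n_beats = integer(0),
             mean_rate_bpm = numeric(0))
}

.validate_track <- function(track) {
  if (!is.data.frame(track) || !all(c("sample", "beat_class") %in% names(track))) {
    stop("a beat track needs columns 'sample' and 'beat_class'")
  }
  if (nrow(track) == 0) return(invisible(track))
  s <- track$sample
  if (any(s < 0)) stop("beat samples must be non-negative")
  if (is.unsorted(s, strictly = TRUE)) {
    bad <- which(diff(s) <= 0)[1] + 1L
    stop("beat track is not strictly increasing in sample (row ", bad, ")")
  }
  known <- track$beat_class %in% .beat_classes
  if (!all(known)) {
    bad <- which(!known)[1]
    stop("unknown beat_class '", track$beat_class[bad], "' at row ", bad)
  }
  invisible(track)
}

# beat label -> rhythm run group
.run_group <- c(sinus = "sinus", atrial_ectopic = "atrial_run",
                ventricular_ectopic = "pvc_run", af_beat = "af",
                svt_beat = "svt", vt_beat = "vt",
                idioventricular_beat = "ivr", blocked_beat = "avb2",
                avb3_beat = "avb3", noise = "noise", unknown = "unknown")

#' Mean heart rate of a run of beats
#'
#' Computed as 60 divided by the mean RR interval (in seconds) over the run.
#'
#' @param beat_samples Sample indices of the beats, strictly increasing.
#' @param fs Sampling clock (samples per second).
#' @return Mean rate in beats per minute.
#' @examples
#' mean_heart_rate(c(0, 150, 300))  # RR = 0.5 s -> 120 bpm
#' @export
mean_heart_rate <- function(beat_samples, fs = 300) {
  if (length(beat_samples) < 2) {
    stop("mean heart rate is undefined for fewer than 2 beats")
  }
  60 / (mean(diff(beat_samples)) / fs)
}

#' Derive rhythm episodes from a beat-level annotation track
#'
#' Turns a strictly increasing stream of labelled beats into a list of
#' rhythm episodes. Maximal runs of beats sharing a rhythm label become one
#' episode; runs of one or two atrial ectopics (and all ventricular
#' ectopics) are emitted as individual PAC/PVC episodes, while runs of
#' `ear_min_beats` or more atrial ectopics become one ectopic atrial rhythm
#' episode. Independently of the runs, every inter-beat gap of at least
#' `pause_min_s` seconds becomes one pause or asystole episode according to
#' its duration. Episodes use half-open `[start_sample, end_sample)`
#' intervals; a run's end is its last beat onset plus one median RR so that
#' duration grows monotonically with beat count.
#'
#' @param track Data.frame with columns `sample` (0-based sample index on
#'   the taxonomy's clock, strictly increasing) and `beat_class` (see
#'   [beat_classes()]).
#' @param taxonomy A [rhythm_taxonomy()].
#' @return Data.frame of episodes sorted by `start_sample` with columns
#'   `class`, `criticality`, `start_sample`, `end_sample`, `duration_s`,
#'   `n_beats`, `mean_rate_bpm`.
#' @examples
#' trk <- data.frame(sample = c(0, 240, 1320, 1560),
#'                   beat_class = "sinus")
#' derive_episodes(trk)  # the 3.6-s gap becomes an asystole episode
#' @export
derive_episodes <- function(track, taxonomy = rhythm_taxonomy()) {
  .validate_track(track)
  if (nrow(track) == 0) return(.empty_episodes())
  fs <- taxonomy$fs
  s <- as.numeric(track$sample)
  g <- unname(.run_group[as.character(track$beat_class)])
  r <- rle(g)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L

  rhythm <- character(0)
  start <- numeric(0)
  end <- numeric(0)
  nb <- integer(0)
  rate <- numeric(0)
  add <- function(rh, st, en, n, rt) {
    rhythm <<- c(rhythm, rh); start <<- c(start, st); end <<- c(end, en)
    nb <<- c(nb, n); rate <<- c(rate, rt)
  }

  for (k in seq_along(r$values)) {
    idx <- run_start[k]:run_end[k]
    ss <- s[idx]
    n <- length(ss)
    rc <- r$values[k]
    if (rc == "pvc_run" || (rc == "atrial_run" && n < taxonomy$ear_min_beats)) {
      cl <- if (rc == "pvc_run") "pvc" else "pac"
      add(rep(cl, n), ss, ss + 1, rep(1L, n), rep(NA_real_, n))
      next
    }
    if (rc == "atrial_run") rc <- "ear"
    pad <- if (n >= 2) stats::median(diff(ss)) else 1
    rt <- if (n >= 2) mean_heart_rate(ss, fs) else NA_real_
    # the pad never extends past the next annotated event
    nxt <- if (run_end[k] < length(s)) s[run_end[k] + 1L] else Inf
    add(rc, ss[1], min(ss[n] + pad, nxt), n, rt)
  }

  gaps <- diff(s)
  gi <- which(gaps >= taxonomy$pause_min_s * fs)
  if (length(gi)) {
    add(rep("gap", length(gi)), s[gi], s[gi + 1L],
        rep(0L, length(gi)), rep(NA_real_, length(gi)))
  }

  lab <- classify_episode(rhythm, (end - start) / fs, nb, rate, taxonomy)
  ep <- data.frame(class = lab$class, criticality = lab$criticality,
                   start_sample = start, end_sample = end,
                   duration_s = (end - start) / fs,
                   n_beats = nb, mean_rate_bpm = rate)
  ep <- ep[ep$class != "subthreshold_gap", , drop = FALSE]
  ep <- ep[order(ep$start_sample, ep$class), , drop = FALSE]
  rownames(ep) <- NULL
  ep
}
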