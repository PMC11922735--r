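# Class vocabulary ------------------------------------------------------------

.beat_classes <- c("sinus", "atrial_ectopic", "ventricular_ectopic", "af_beat",
                   "svt_beat", "vt_beat", "idioventricular_beat",
                   "blocked_beat", "avb3_beat", "noise", "unknown")

.critical_classes <- c("af", "svt", "vt", "asystole", "avb3")

.noncritical_classes <- c("avb2", "pause", "vt_short", "svt_short",
                          "ear", "ivr", "aivr", "pac", "pvc")

.other_classes <- c("af_short", "subthreshold_gap", "sinus", "sinus_brady",
                    "noise", "unknown")

#' Beat-level annotation classes
#'
#' The vocabulary of beat labels accepted in annotation tracks. Each QRS (or
#' non-QRS event such as a noise marker) carries exactly one of these labels.
#'
#' @return Character vector of valid `beat_class` values.
#' @export
beat_classes <- function() .beat_classes

#' Reported rhythm classes by criticality tier
#'
#' Critical arrhythmias are those whose presence anywhere in a multi-day
#' recording must reach a physician: sustained AF, sustained SVT, fast
#' sustained VT, asystole and third-degree AV block. Noncritical classes are
#' reportable findings below those thresholds (short VT/SVT runs, pauses,
#' second-degree AV block, ectopy, ectopic atrial and idioventricular
#' rhythms). "other" holds classes excluded from both accuracy tiers
#' (sinus rhythm, noise, sub-threshold AF).
#'
#' @param tier One of "all", "critical", "noncritical", "other".
#' @return Character vector of rhythm class names.
#' @export
rhythm_classes <- function(tier = c("all", "critical", "noncritical", "other")) {
  tier <- match.arg(tier)
  switch(tier,
         all = c(.critical_classes, .noncritical_classes, .other_classes),
         critical = .critical_classes,
         noncritical = .noncritical_classes,
         other = .other_classes)
}

#' Criticality tier of a reported rhythm class
#'
#' @param class Character vector of rhythm class names.
#' @return Character vector: "critical", "noncritical" or "other".
#' @export
criticality <- function(class) {
  out <- rep(NA_character_, length(class))
  out[class %in% .critical_classes] <- "critical"
  out[class %in% .noncritical_classes] <- "noncritical"
  out[class %in% .other_classes] <- "other"
  if (anyNA(out)) {
    stop("unknown rhythm class(es): ",
         paste(unique(class[is.na(out)]), collapse = ", "))
  }
  out
}

# Taxonomy --------------------------------------------------------------------

#' Arrhythmia taxonomy thresholds
#'
#' Bundles the duration, rate and beat-count thresholds that separate
#' reported rhythm classes and their criticality tiers. Defaults encode the
#' clinical convention used throughout the package: AF and SVT are critical
#' from 30 s, VT is critical from 10 s at a mean rate of at least 120 bpm,
#' inter-beat gaps of 2.0-3.5 s are pauses and gaps of 3.5 s or more are
#' asystole, third-degree AV block is critical at any duration, and runs of
#' at least 3 beats define the short (noncritical) tachyarrhythmia classes
#' and ectopic atrial rhythm. Comparisons are inclusive (">=") at lower
#' bounds and exclusive ("<") at upper bounds.
#'
#' @param af_min_s Minimum AF duration (s) for the critical tier.
#' @param svt_min_s Minimum SVT duration (s) for the critical tier.
#' @param svt_min_beats Minimum run length (beats) for noncritical SVT.
#' @param vt_min_s Minimum VT duration (s) for the critical tier.
#' @param vt_min_bpm Minimum VT mean rate (bpm) for the critical tier.
#' @param vt_min_beats Minimum run length (beats) for noncritical VT.
#' @param asystole_min_s Minimum gap duration (s) called asystole.
#' @param pause_min_s Minimum gap duration (s) called a pause; gaps in
#'   `[pause_min_s, asystole_min_s)` are pauses.
#' @param ear_min_beats Minimum run of atrial ectopics forming an ectopic
#'   atrial rhythm; shorter runs are reported as single PACs.
#' @param aivr_min_bpm Idioventricular runs at or above this mean rate are
#'   reported as accelerated idioventricular rhythm (AIVR), below as IVR.
#' @param sinus_brady_max_bpm Sinus runs below this mean rate are labelled
#'   sinus bradycardia (an "other"-tier class used for blinding strips).
#' @param strip_length_s Adjudication strip length in seconds.
#' @param fs Sampling clock in samples per second.
#' @return An object of class `rhythm_taxonomy`.
#' @examples
#' tax <- rhythm_taxonomy()
#' classify_episode("af", duration_s = 31, taxonomy = tax)
#' @export
rhythm_taxonomy <- function(af_min_s = 30, svt_min_s = 30, svt_min_beats = 3,
                            vt_min_s = 10, vt_min_bpm = 120, vt_min_beats = 3,
                            asystole_min_s = 3.5, pause_min_s = 2.0,
                            ear_min_beats = 3, aivr_min_bpm = 60,
                            sinus_brady_max_bpm = 50,
                            strip_length_s = 34, fs = 300) {
  if (!(pause_min_s < asystole_min_s)) {
    stop("pause_min_s must be below asystole_min_s (the pause band's upper ",
         "bound is the asystole lower bound)")
  }
  stopifnot(af_min_s > 0, svt_min_s > 0, vt_min_s > 0, vt_min_bpm > 0,
            pause_min_s > 0, strip_length_s > 0, fs > 0,
            svt_min_beats >= 1, vt_min_beats >= 1, ear_min_beats >= 1)
  structure(list(af_min_s = af_min_s, svt_min_s = svt_min_s,
                 svt_min_beats = svt_min_beats, vt_min_s = vt_min_s,
                 vt_min_bpm = vt_min_bpm, vt_min_beats = vt_min_beats,
                 asystole_min_s = asystole_min_s, pause_min_s = pause_min_s,
                 ear_min_beats = ear_min_beats, aivr_min_bpm = aivr_min_bpm,
                 sinus_brady_max_bpm = sinus_brady_max_bpm,
                 strip_length_s = strip_length_s, fs = fs),
            class = "rhythm_taxonomy")
}

#' @export
print.rhythm_taxonomy <- function(x, ...) {
  cat("Arrhythmia taxonomy (", x$fs, " Hz clock, ", x$strip_length_s,
      "-s strips)\n", sep = "")
  cat(sprintf("  AF >= %g s, SVT >= %g s (critical) / >= %d beats (noncritical)\n",
              x$af_min_s, x$svt_min_s, x$svt_min_beats))
  cat(sprintf("  VT >= %g s at >= %g bpm (critical) / >= %d beats, < %g s (noncritical)\n",
              x$vt_min_s, x$vt_min_bpm, x$vt_min_beats, x$vt_min_s))
  cat(sprintf("  gaps: pause [%g, %g) s, asystole >= %g s\n",
              x$pause_min_s, x$asystole_min_s, x$asystole_min_s))
  invisible(x)
}

#' Classify a rhythm episode into a reported class and criticality tier
#'
#' Maps a raw rhythm run (or inter-beat gap) with its duration, beat count
#' and mean rate onto the reported class vocabulary. Threshold comparisons
#' are inclusive at lower bounds: an AF run of exactly 30 s is critical, a
#' gap of exactly 3.5 s is asystole, a gap of exactly 2.0 s is a pause. VT
#' requires both the duration and the 120 bpm rate floor for the critical
#' tier; sustained VT below the rate floor belongs to neither tier. AF runs
#' under 30 s have no reporting tier and are returned with criticality
#' "other".
#'
#' @param rhythm Character vector of raw run types: "af", "svt", "vt",
#'   "gap", "avb2", "avb3", "ear", "ivr", "pac", "pvc", "sinus", "noise",
#'   "unknown".
#' @param duration_s Episode duration in seconds.
#' @param n_beats Number of beats in the run (0 for gaps).
#' @param mean_rate_bpm Mean heart rate over the run, `NA` when undefined.
#' @param taxonomy A [rhythm_taxonomy()].
#' @return A data.frame with columns `class` and `criticality`, one row per
#'   input episode.
#' @export
classify_episode <- function(rhythm, duration_s, n_beats = NA_integer_,
                             mean_rate_bpm = NA_real_,
                             taxonomy = rhythm_taxonomy()) {
  n <- length(rhythm)
  duration_s <- rep_len(duration_s, n)
  n_beats <- rep_len(n_beats, n)
  mean_rate_bpm <- rep_len(mean_rate_bpm, n)
  tax <- taxonomy
  cls <- character(n)
  crit <- character(n)
  for (i in seq_len(n)) {
    dur <- duration_s[i]
    nb <- n_beats[i]
    rate <- mean_rate_bpm[i]
    res <- switch(rhythm[i],
      af = if (dur >= tax$af_min_s) c("af", "critical")
           else c("af_short", "other"),
      svt = if (dur >= tax$svt_min_s) c("svt", "critical")
            else if (!is.na(nb) && nb >= tax$svt_min_beats)
              c("svt_short", "noncritical")
            else c("svt_short", "other"),
      vt = if (dur >= tax$vt_min_s && !is.na(rate) && rate >= tax$vt_min_bpm)
             c("vt", "critical")
           else if (dur < tax$vt_min_s && !is.na(nb) && nb >= tax$vt_min_beats)
             c("vt_short", "noncritical")
           else c("vt_short", "other"),
      gap = if (dur >= tax$asystole_min_s) c("asystole", "critical")
            else if (dur >= tax$pause_min_s) c("pause", "noncritical")
            else c("subthreshold_gap", "other"),
      avb2 = c("avb2", "noncritical"),
      avb3 = c("avb3", "critical"),
      ear = if (!is.na(nb) && nb >= tax$ear_min_beats) c("ear", "noncritical")
            else c("pac", "noncritical"),
      ivr = if (!is.na(nb) && nb >= 3) {
              if (!is.na(rate) && rate >= tax$aivr_min_bpm)
                c("aivr", "noncritical")
              else c("ivr", "noncritical")
            } else c("ivr", "other"),
      pac = c("pac", "noncritical"),
      pvc = c("pvc", "noncritical"),
      sinus = if (!is.na(rate) && rate < tax$sinus_brady_max_bpm &&
                  !is.na(nb) && nb >= 3) c("sinus_brady", "other")
              else c("sinus", "other"),
      noise = c("noise", "other"),
      unknown = c("unknown", "other"),
      stop("unknown rhythm run type: ", rhythm[i])
    )
    cls[i] <- res[1]
    crit[i] <- res[2]
  }
  data.frame(class = cls, criticality = crit)
}
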