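# Reader-versus-panel concordance within adjudication strips ------------------

#' Overlap acceptance rules for strip adjudication
#'
#' A reader's annotation of a strip is concordant with the panel's when it
#' overlaps the panel annotation sufficiently: sustained tachyarrhythmias
#' require at least `tachy_overlap` of the panel episode covered in both
#' duration and beat type; asystole and pauses require `gap_overlap` of the
#' panel duration; second- and third-degree AV block require only the
#' presence of such an event anywhere within the strip; single ectopic
#' beats must fall within `ectopic_tol_samples` of a panel ectopic; noise
#' marks require `noise_overlap` of the panel duration. Readers listed in
#' `missed_beat_alias_readers` (by convention the technician method) get
#' credit for second-degree AV block from an unspecified "missed beat"
#' annotation, i.e. any blocked-beat label in the strip.
#'
#' @param tachy_overlap Duration and beat-type overlap fraction required for
#'   sustained tachyarrhythmias (default 0.80).
#' @param gap_overlap Duration overlap fraction for asystole/pauses (0.90).
#' @param ectopic_tol_samples Tolerance for single ectopic beats, in samples
#'   (45 samples = 150 ms at 300 Hz).
#' @param noise_overlap Duration overlap fraction for noise annotations.
#' @param missed_beat_alias_readers Readers whose bare blocked-beat
#'   ("missed beat") annotations count as concordant second-degree AV block.
#' @return An object of class `overlap_rules`.
#' @export
overlap_rules <- function(tachy_overlap = 0.80, gap_overlap = 0.90,
                          ectopic_tol_samples = 45, noise_overlap = 0.80,
                          missed_beat_alias_readers = "technician") {
  stopifnot(tachy_overlap > 0, tachy_overlap <= 1,
            gap_overlap > 0, gap_overlap <= 1,
            noise_overlap > 0, noise_overlap <= 1,
            ectopic_tol_samples >= 0)
  structure(list(tachy_overlap = tachy_overlap, gap_overlap = gap_overlap,
                 ectopic_tol_samples = ectopic_tol_samples,
                 noise_overlap = noise_overlap,
                 missed_beat_alias_readers = missed_beat_alias_readers),
            class = "overlap_rules")
}

#' Rule family of a rhythm class
#'
#' @param class Character vector of rhythm classes.
#' @return One of "tachy", "gap", "avblock", "ectopic", "noise", "other"
#'   per class.
#' @export
class_family <- function(class) {
  fam <- c(af = "tachy", af_short = "tachy", svt = "tachy",
           svt_short = "tachy", vt = "tachy", vt_short = "tachy",
           ear = "tachy", ivr = "tachy", aivr = "tachy",
           asystole = "gap", pause = "gap", subthreshold_gap = "gap",
           avb2 = "avblock", avb3 = "avblock",
           pac = "ectopic", pvc = "ectopic", noise = "noise",
           sinus = "other", sinus_brady = "other", unknown = "other")
  out <- unname(fam[class])
  if (anyNA(out)) stop("unknown rhythm class(es): ",
                       paste(unique(class[is.na(out)]), collapse = ", "))
  out
}

# total length of the union of half-open intervals
.union_length <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > ce) { tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i] }
    else ce <- max(ce, end[i])
  }
  tot + (ce - cs)
}

# merge a set of half-open intervals into disjoint ones
.merge_intervals <- function(start, end) {
  if (length(start) == 0) return(list(start = start, end = end))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > me[length(me)]) {
      ms <- c(ms, start[i]); me <- c(me, end[i])
    } else {
      me[length(me)] <- max(me[length(me)], end[i])
    }
  }
  list(start = ms, end = me)
}

# length of the intersection of interval-set A with interval-set B
.intersect_length <- function(a_start, a_end, b_start, b_end) {
  a <- .merge_intervals(a_start, a_end)
  tot <- 0
  for (i in seq_along(a$start)) {
    lo <- pmax(a$start[i], b_start)
    hi <- pmin(a$end[i], b_end)
    tot <- tot + .union_length(lo[hi > lo], hi[hi > lo])
  }
  tot
}

.clip_eps <- function(eps, w0, w1) {
  if (nrow(eps) == 0) return(eps)
  s <- pmax(eps$start_sample, w0)
  e <- pmin(eps$end_sample, w1)
  keep <- e > s
  eps <- eps[keep, , drop = FALSE]
  eps$start_sample <- s[keep]
  eps$end_sample <- e[keep]
  eps
}

#' Duration and beat-type overlap between panel and reader episodes
#'
#' The denominator is always the panel annotation: `duration_fraction` is
#' the fraction of the panel episode's span covered by the union of the
#' reader's episodes of the class; `beat_type_fraction` is the share of
#' panel beats within the panel span whose reader beat label agrees (a
#' reader beat of identical class within the ectopic tolerance). When beat
#' tracks are not supplied, beat-type agreement is taken from the episode
#' class labels themselves (episodes under comparison already share a
#' class, so the fraction is 1 wherever there is any overlap).
#'
#' @param panel_eps Data.frame of panel episodes of one class (columns
#'   `start_sample`, `end_sample`), already clipped to the strip.
#' @param reader_eps Data.frame of reader episodes of the same class.
#' @param panel_track,reader_track Optional beat tracks (columns `sample`,
#'   `beat_class`) restricted to the strip.
#' @param rules An [overlap_rules()].
#' @return Named numeric vector `c(duration_fraction, beat_type_fraction)`.
#' @export
episode_overlap <- function(panel_eps, reader_eps, panel_track = NULL,
                            reader_track = NULL, rules = overlap_rules()) {
  panel_len <- .union_length(panel_eps$start_sample, panel_eps$end_sample)
  if (panel_len == 0) return(c(duration_fraction = 0, beat_type_fraction = 0))
  inter <- .intersect_length(panel_eps$start_sample, panel_eps$end_sample,
                             reader_eps$start_sample, reader_eps$end_sample)
  dur_frac <- inter / panel_len
  if (is.null(panel_track) || is.null(reader_track)) {
    beat_frac <- if (dur_frac > 0) 1 else 0
  } else {
    in_span <- rep(FALSE, nrow(panel_track))
    for (i in seq_len(nrow(panel_eps))) {
      in_span <- in_span | (panel_track$sample >= panel_eps$start_sample[i] &
                            panel_track$sample < panel_eps$end_sample[i])
    }
    pb <- panel_track[in_span & panel_track$beat_class != "noise", , drop = FALSE]
    if (nrow(pb) == 0) {
      beat_frac <- if (dur_frac > 0) 1 else 0
    } else {
      tol <- rules$ectopic_tol_samples
      ok <- vapply(seq_len(nrow(pb)), function(i) {
        near <- abs(reader_track$sample - pb$sample[i]) <= tol
        any(near & reader_track$beat_class == pb$beat_class[i])
      }, logical(1))
      beat_frac <- mean(ok)
    }
  }
  c(duration_fraction = dur_frac, beat_type_fraction = beat_frac)
}

# reader/panel class with maximal overlap of a span, used for the
# misclassified_as attribution; ties broken critical-first then alphabetical
.best_overlapping_class <- function(eps, span_start, span_end, exclude) {
  if (nrow(eps) == 0) return(NA_character_)
  eps <- eps[eps$class != exclude, , drop = FALSE]
  if (nrow(eps) == 0) return(NA_character_)
  ov <- vapply(unique(eps$class), function(cl) {
    ec <- eps[eps$class == cl, , drop = FALSE]
    .intersect_length(ec$start_sample, ec$end_sample, span_start, span_end)
  }, numeric(1))
  ov <- ov[ov > 0]
  if (length(ov) == 0) return(NA_character_)
  cand <- names(ov)[ov == max(ov)]
  if (length(cand) > 1) {
    crit <- criticality(cand) == "critical"
    if (any(crit)) cand <- cand[crit]
    cand <- sort(cand)
  }
  cand[1]
}

#' Adjudicate one reader's annotations of one strip against the panel
#'
#' Produces exactly one verdict per class: true positive when the panel
#' found the class and the reader's annotation is concordant under the
#' overlap rules; false negative when the panel found it and the reader's
#' annotation is absent or discordant (with `misclassified_as` set to the
#' reader class with maximal temporal overlap of the panel event, if any);
#' false positive when the reader annotated a class the panel did not find
#' (with `misclassified_as` set to the panel class at that locus, if any);
#' true negative otherwise. AV-block classes are scored on presence within
#' the strip. Minor beat-to-beat discrepancies below the overlap thresholds
#' never flip a verdict.
#'
#' @param strip One-row data.frame with `strip_id`, `start_sample`,
#'   `end_sample`.
#' @param panel_eps Panel (gold standard) episodes overlapping the strip.
#' @param reader_eps Reader episodes; an episode entirely outside the strip
#'   window is an input error.
#' @param rules An [overlap_rules()].
#' @param taxonomy A [rhythm_taxonomy()].
#' @param classes Classes to adjudicate; defaults to the critical and
#'   noncritical classes present in either episode set.
#' @param panel_track,reader_track Optional beat tracks for beat-type
#'   overlap scoring.
#' @param reader Reader label written into the verdicts.
#' @return Data.frame of verdicts: `strip_id`, `reader`, `class`,
#'   `verdict`, `misclassified_as`, `variant` (= "primary").
#' @export
match_strip <- function(strip, panel_eps, reader_eps, rules = overlap_rules(),
                        taxonomy = rhythm_taxonomy(), classes = NULL,
                        panel_track = NULL, reader_track = NULL,
                        reader = "reader") {
  w0 <- strip$start_sample
  w1 <- strip$end_sample
  if (nrow(reader_eps) > 0 &&
      any(reader_eps$end_sample <= w0 | reader_eps$start_sample >= w1)) {
    stop("reader episode outside the strip window")
  }
  p <- .clip_eps(panel_eps, w0, w1)
  r <- .clip_eps(reader_eps, w0, w1)
  if (is.null(classes)) {
    cand <- unique(c(p$class, r$class))
    classes <- sort(cand[criticality(cand) %in% c("critical", "noncritical")])
  }

  verdict <- character(length(classes))
  miscl <- rep(NA_character_, length(classes))
  for (j in seq_along(classes)) {
    cl <- classes[j]
    fam <- class_family(cl)
    pc <- p[p$class == cl, , drop = FALSE]
    rc <- r[r$class == cl, , drop = FALSE]
    present_p <- nrow(pc) > 0
    present_r <- nrow(rc) > 0

    # "missed beat" alias: a bare blocked-beat annotation anywhere in the
    # strip counts as second-degree AV block for the aliased readers
    if (cl == "avb2" && !present_r &&
        reader %in% rules$missed_beat_alias_readers &&
        !is.null(reader_track) &&
        any(reader_track$beat_class == "blocked_beat")) {
      present_r <- TRUE
      rc <- data.frame(class = "avb2",
                       start_sample = w0, end_sample = w1)
    }

    concordant <- FALSE
    if (present_p && present_r) {
      concordant <- switch(fam,
        avblock = TRUE,
        ectopic = {
          tol <- rules$ectopic_tol_samples
          any(vapply(pc$start_sample, function(s0)
            any(abs(rc$start_sample - s0) <= tol), logical(1)))
        },
        tachy = {
          fr <- episode_overlap(pc, rc, panel_track, reader_track, rules)
          fr[["duration_fraction"]] >= rules$tachy_overlap &&
            fr[["beat_type_fraction"]] >= rules$tachy_overlap
        },
        gap = {
          fr <- episode_overlap(pc, rc, NULL, NULL, rules)
          fr[["duration_fraction"]] >= rules$gap_overlap
        },
        noise = {
          fr <- episode_overlap(pc, rc, NULL, NULL, rules)
          fr[["duration_fraction"]] >= rules$noise_overlap
        },
        FALSE)
    }

    if (present_p && concordant) {
      verdict[j] <- "true_positive"
    } else if (present_p) {
      verdict[j] <- "false_negative"
      miscl[j] <- .best_overlapping_class(r, pc$start_sample, pc$end_sample, cl)
    } else if (present_r) {
      verdict[j] <- "false_positive"
      miscl[j] <- .best_overlapping_class(p, rc$start_sample, rc$end_sample, cl)
    } else {
      verdict[j] <- "true_negative"
    }
  }
  data.frame(strip_id = strip$strip_id, reader = reader, class = classes,
             verdict = verdict, misclassified_as = miscl,
             variant = "primary")
}

#' Apply a reporting variant to primary verdicts
#'
#' The primary variant returns the verdicts unchanged. Under the
#' misclassification-insensitive variant, false positives and false
#' negatives of a critical class that the other track annotated as a
#' different critical class are excluded from event counts (such events
#' would still have reached a physician), and second-degree AV block false
#' positives are excluded. Verdict rows are retained with verdict
#' "excluded" so the one-verdict-per-(strip, reader, class) partition is
#' preserved; metric aggregation ignores excluded rows.
#'
#' @param verdicts Data.frame of primary verdicts from [match_strip()].
#' @param variant "primary" or "misclassification_insensitive".
#' @param taxonomy A [rhythm_taxonomy()].
#' @return The verdicts under the requested variant.
#' @export
apply_variant <- function(verdicts,
                          variant = c("primary", "misclassification_insensitive"),
                          taxonomy = rhythm_taxonomy()) {
  variant <- match.arg(variant)
  if (variant == "primary") return(verdicts)
  out <- verdicts
  is_err <- out$verdict %in% c("false_positive", "false_negative")
  crit_cls <- criticality(out$class) == "critical"
  crit_mis <- !is.na(out$misclassified_as) &
    criticality(ifelse(is.na(out$misclassified_as), "sinus",
                       out$misclassified_as)) == "critical"
  drop <- is_err & crit_cls & crit_mis
  drop <- drop | (out$verdict == "false_positive" & out$class == "avb2")
  out$verdict[drop] <- "excluded"
  out$variant <- "misclassification_insensitive"
  out
}
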