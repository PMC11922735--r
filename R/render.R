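# Beat-level rendering of an episode plan -------------------------------------

# class -> rendered beat label
.render_label <- c(af = "af_beat", af_short = "af_beat",
                   svt = "svt_beat", svt_short = "svt_beat",
                   vt = "vt_beat", vt_short = "vt_beat",
                   ear = "atrial_ectopic",
                   ivr = "idioventricular_beat", aivr = "idioventricular_beat",
                   avb2 = "blocked_beat", avb3 = "avb3_beat",
                   noise = "noise", pac = "atrial_ectopic",
                   pvc = "ventricular_ectopic")

# beats from t0 (inclusive) stepping by draws of rr_fun until t1 (exclusive),
# in samples
.beats_between <- function(t0, t1, rr_fun, fs) {
  span <- (t1 - t0) / fs
  if (span <= 0) return(numeric(0))
  rr <- rr_fun(ceiling(span / 0.25) + 2)
  cum <- cumsum(c(0, rr))
  while (cum[length(cum)] < span) {
    rr <- rr_fun(ceiling(span / 0.25) + 2)
    cum <- c(cum, cum[length(cum)] + cumsum(rr))
  }
  s <- floor(t0 + cum * fs)
  s[s < t1]
}

#' Render a beat-annotation track from an episode plan
#'
#' Produces the beat stream an annotator asserting the given episodes would
#' have written: sinus beats with a log-normal RR process wherever no
#' episode applies; irregular `af_beat`s over AF episodes; fast regular
#' `svt_beat`/`vt_beat`/`idioventricular_beat` runs at each episode's mean
#' rate; `blocked_beat`/`avb3_beat` runs for AV block; noise markers over
#' noise episodes; single ectopic beats for PAC/PVC; and beat-free spans for
#' pauses and asystole, with anchor beats at both gap edges so the gap
#' duration is exactly the planned one.
#'
#' @param episodes Episode plan for one recording and one annotator
#'   (columns `class`, `start_sample`, `end_sample`, `mean_rate_bpm`).
#'   Non-gap episodes must not overlap each other. A pause-class episode
#'   shorter than the taxonomy's pause floor is a plan error.
#' @param end_sample Recording end bound (samples).
#' @param config A [cohort_config()] (RR process parameters).
#' @param seed Integer seed (mandatory).
#' @param window Optional half-open `c(start, end)` window to render
#'   (e.g. one adjudication strip) instead of the whole recording.
#' @param label_noise Probability that a beat label is replaced by
#'   "unknown", emulating imperfect beat typing.
#' @param taxonomy A [rhythm_taxonomy()].
#' @return Beat track data.frame: `sample` (strictly increasing),
#'   `beat_class`.
#' @export
render_beats <- function(episodes, end_sample, config = cohort_config(),
                         seed, window = NULL, label_noise = 0,
                         taxonomy = rhythm_taxonomy()) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  fs <- taxonomy$fs
  set.seed(seed)
  w0 <- if (is.null(window)) 0 else window[[1]]
  w1 <- if (is.null(window)) end_sample else window[[2]]

  bad <- episodes$class == "pause" &
    (episodes$end_sample - episodes$start_sample) / fs < taxonomy$pause_min_s
  if (any(bad)) stop("plan error: pause-labelled episode shorter than the pause floor")

  eps <- .clip_eps(episodes, w0, w1)
  fam <- if (nrow(eps)) class_family(eps$class) else character(0)
  gap_eps <- eps[fam == "gap", , drop = FALSE]
  ect_eps <- eps[fam == "ectopic", , drop = FALSE]
  run_eps <- eps[!(fam %in% c("gap", "ectopic", "other")), , drop = FALSE]
  run_eps <- run_eps[order(run_eps$start_sample), , drop = FALSE]
  if (nrow(run_eps) > 1 &&
      any(run_eps$start_sample[-1] < run_eps$end_sample[-nrow(run_eps)])) {
    stop("plan error: overlapping non-gap episodes")
  }

  sinus_rr <- function(k) stats::rlnorm(k, log(config$sinus_rr_s),
                                        config$sinus_rr_sdlog)
  samples <- numeric(0)
  labels <- character(0)
  emit <- function(s, lab) {
    samples <<- c(samples, s)
    labels <<- c(labels, rep_len(lab, length(s)))
  }

  t <- w0
  for (i in seq_len(nrow(run_eps))) {
    e0 <- run_eps$start_sample[i]
    e1 <- run_eps$end_sample[i]
    cl <- run_eps$class[i]
    if (e0 > t) emit(.beats_between(t, e0, sinus_rr, fs), "sinus")
    bpm <- run_eps$mean_rate_bpm[i]
    rr_fun <- switch(class_family(cl),
      tachy = if (cl %in% c("af", "af_short")) {
        mu <- log(60 / (if (is.na(bpm)) 110 else bpm))
        function(k) stats::rlnorm(k, mu, config$af_rr_sdlog)
      } else {
        rr <- 60 / (if (is.na(bpm)) 120 else bpm)
        function(k) rep(rr, k)
      },
      avblock = if (cl == "avb2") sinus_rr else {
        rr <- 60 / (if (is.na(bpm)) 42 else bpm)
        function(k) rep(rr, k)
      },
      noise = function(k) rep(1, k),
      sinus_rr)
    emit(.beats_between(e0, e1, rr_fun, fs), .render_label[[cl]])
    t <- e1
  }
  if (t < w1) emit(.beats_between(t, w1, sinus_rr, fs), "sinus")

  # single ectopic beats replace any base beat within a quarter second
  for (i in seq_len(nrow(ect_eps))) {
    s0 <- ect_eps$start_sample[i]
    near <- abs(samples - s0) <= 0.25 * fs
    samples <- samples[!near]
    labels <- labels[!near]
    emit(s0, .render_label[[ect_eps$class[i]]])
  }

  # gaps: clear the span, anchor a beat at each edge
  for (i in seq_len(nrow(gap_eps))) {
    g0 <- gap_eps$start_sample[i]
    g1 <- gap_eps$end_sample[i]
    inside <- samples > g0 & samples < g1
    samples <- samples[!inside]
    labels <- labels[!inside]
    # anchors carry the label of the run they sit in, so a gap does not
    # split an enclosing rhythm run with a stray label
    lab_at <- function(s, side) {
      cand <- if (side == "before") which(samples <= s) else which(samples >= s)
      if (!length(cand)) return("sinus")
      idx <- if (side == "before") cand[which.max(samples[cand])]
             else cand[which.min(samples[cand])]
      labels[idx]
    }
    lab0 <- lab_at(g0, "before")
    if (!any(samples == g0) && g0 >= w0) emit(g0, lab0)
    lab1 <- lab_at(g1, "after")
    if (!any(samples == g1) && g1 < w1) emit(g1, lab1)
  }

  o <- order(samples)
  samples <- samples[o]
  labels <- labels[o]
  dup <- duplicated(samples)
  samples <- samples[!dup]
  labels <- labels[!dup]
  if (label_noise > 0) {
    flip <- stats::runif(length(labels)) < label_noise & labels != "noise"
    labels[flip] <- "unknown"
  }
  track <- data.frame(sample = as.numeric(samples), beat_class = labels)
  rownames(track) <- NULL
  track
}
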