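# Adjudication strip sampling -------------------------------------------------

#' Place a fixed-length adjudication window around an episode
#'
#' Windows are centred on the episode midpoint and clamped to the recording
#' bounds; episodes longer than the strip are represented by a window
#' anchored at their onset (so the onset and the following strip-length of
#' signal are adjudicated). Windows are shifted, never truncated.
#'
#' @param start_sample,end_sample Episode bounds (half-open, samples).
#' @param recording_end_sample Last valid sample bound of the recording.
#' @param taxonomy A [rhythm_taxonomy()]; fixes strip length and clock.
#' @return Named numeric vector `c(start, end)`, a half-open window of
#'   exactly `strip_length_s * fs` samples.
#' @export
place_window <- function(start_sample, end_sample, recording_end_sample,
                         taxonomy = rhythm_taxonomy()) {
  len <- taxonomy$strip_length_s * taxonomy$fs
  dur <- end_sample - start_sample
  w0 <- if (dur >= len) start_sample
        else round((start_sample + end_sample) / 2 - len / 2)
  w0 <- min(w0, recording_end_sample - len)
  w0 <- max(0, w0)
  c(start = w0, end = w0 + len)
}

#' Default per-class strip quotas
#'
#' @param classes Character vector of rhythm classes.
#' @param critical,noncritical,other Quota per criticality tier.
#' @return Named numeric vector of quotas.
#' @export
default_quotas <- function(classes, critical = 500, noncritical = 250,
                           other = 250) {
  tier <- criticality(classes)
  q <- ifelse(tier == "critical", critical,
              ifelse(tier == "noncritical", noncritical, other))
  stats::setNames(q, classes)
}

#' Sample adjudication strips from a cohort
#'
#' Visits recordings in a seeded uniform-random permutation. For each
#' recording and still-open rhythm class, if any reader annotated an episode
#' of that class, one strip window containing the earliest such episode is
#' emitted (at most one strip per recording and class; when several readers
#' flag the class the single strip serves all of them, with
#' `trigger_reader = "both"`). The search for a class stops when its quota
#' is met or the cohort is exhausted; the number of recordings visited up to
#' that point is recorded as the class's source population size, the
#' denominator later used for prevalence weighting.
#'
#' @param recordings Data.frame with columns `recording_id`, `patient_id`,
#'   `duration_days`.
#' @param episodes Data.frame of reader episodes with columns
#'   `recording_id`, `reader`, `class`, `start_sample`, `end_sample`.
#'   Panel/ground-truth episodes must not be included.
#' @param quotas Named numeric vector of per-class quotas, or `NULL` for
#'   [default_quotas()] (500 critical / 250 noncritical).
#' @param seed Integer seed for the search permutation (mandatory).
#' @param classes Classes to search for; defaults to the critical and
#'   noncritical classes present in `episodes`.
#' @param taxonomy A [rhythm_taxonomy()].
#' @return A list with `strips` (data.frame: `strip_id`, `recording_id`,
#'   `patient_id`, `start_sample`, `end_sample`, `trigger_class`,
#'   `trigger_reader`) and `ledger` (data.frame: `class`, `quota`,
#'   `strips_selected`, `recordings_searched`).
#' @export
sample_strips <- function(recordings, episodes, quotas = NULL, seed,
                          classes = NULL, taxonomy = rhythm_taxonomy()) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for strip sampling")
  if (is.null(classes)) {
    keep <- criticality(unique(episodes$class)) %in% c("critical", "noncritical")
    classes <- sort(unique(episodes$class)[keep])
  }
  if (length(classes) == 0) {
    return(list(strips = .empty_strips(),
                ledger = data.frame(class = character(0), quota = numeric(0),
                                    strips_selected = numeric(0),
                                    recordings_searched = numeric(0))))
  }
  if (is.null(quotas)) quotas <- default_quotas(classes)
  quotas <- quotas[classes]
  if (any(is.na(quotas)) || any(quotas <= 0)) {
    stop("every searched class needs a positive quota")
  }

  fs <- taxonomy$fs
  rec_end <- recordings$duration_days * 86400 * fs
  n_rec <- nrow(recordings)

  eps <- episodes[episodes$class %in% classes, , drop = FALSE]
  eps_by_rec <- split(eps, factor(eps$recording_id,
                                  levels = recordings$recording_id))

  set.seed(seed)
  perm <- sample.int(n_rec)

  remaining <- quotas
  searched <- stats::setNames(rep(NA_real_, length(classes)), classes)
  out <- vector("list", n_rec)

  for (v in seq_len(n_rec)) {
    active <- names(searched)[is.na(searched)]
    if (length(active) == 0) break
    ri <- perm[v]
    e <- eps_by_rec[[ri]]
    if (is.null(e) || nrow(e) == 0) next
    rows <- list()
    for (cl in intersect(active, unique(e$class))) {
      ec <- e[e$class == cl, , drop = FALSE]
      readers <- sort(unique(ec$reader))
      trig <- if (length(readers) >= 2) "both" else readers
      first <- ec[which.min(ec$start_sample), , drop = FALSE]
      w <- place_window(first$start_sample, first$end_sample, rec_end[ri],
                        taxonomy)
      rows[[cl]] <- data.frame(recording_id = recordings$recording_id[ri],
                               patient_id = recordings$patient_id[ri],
                               start_sample = w[["start"]],
                               end_sample = w[["end"]],
                               trigger_class = cl, trigger_reader = trig)
      remaining[cl] <- remaining[cl] - 1
      if (remaining[cl] <= 0) searched[cl] <- v
    }
    if (length(rows)) out[[v]] <- do.call(rbind, rows)
  }
  searched[is.na(searched)] <- n_rec

  strips <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(strips)) strips <- .empty_strips()
  else {
    strips <- cbind(strip_id = sprintf("S%05d", seq_len(nrow(strips))), strips)
    rownames(strips) <- NULL
  }
  ledger <- data.frame(class = classes, quota = unname(quotas),
                       strips_selected = unname(quotas - remaining),
                       recordings_searched = unname(searched))
  list(strips = strips, ledger = ledger)
}

.empty_strips <- function() {
  data.frame(strip_id = character(0), recording_id = character(0),
             patient_id = character(0), start_sample = numeric(0),
             end_sample = numeric(0), trigger_class = character(0),
             trigger_reader = character(0))
}
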