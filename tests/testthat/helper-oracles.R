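# Independent oracles and small fixture builders used across the suite.

# Build a beat track from runs: each element list(class=, rr_s=, n=) or
# list(gap_s=). Returns data.frame(sample, beat_class).
make_track <- function(runs, fs = 300, t0 = 0) {
  samples <- numeric(0)
  labels <- character(0)
  t <- t0
  for (r in runs) {
    if (!is.null(r$gap_s)) {
      t <- t + r$gap_s * fs
      next
    }
    s <- t + (seq_len(r$n) - 1) * r$rr_s * fs
    samples <- c(samples, s)
    labels <- c(labels, rep(r$class, r$n))
    t <- s[length(s)] + r$rr_s * fs
  }
  data.frame(sample = samples, beat_class = labels)
}

# Two-sided Fisher exact p-value by exhaustive hypergeometric enumeration:
# the sum of the probabilities of all tables (with the observed margins) no
# more probable than the observed one.
fisher_oracle <- function(fn_a, n_a, fn_b, n_b) {
  k <- fn_a + fn_b
  support <- max(0, k - n_b):min(k, n_a)
  probs <- stats::dhyper(support, n_a, n_b, k)
  p_obs <- stats::dhyper(fn_a, n_a, n_b, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force strip matcher working on explicit integer sample sets rather
# than interval arithmetic; applies the overlap rules exhaustively per class.
brute_match <- function(strip, panel, reader, classes,
                        rules = rhythmconcord::overlap_rules()) {
  w0 <- strip$start_sample
  w1 <- strip$end_sample
  set_of <- function(eps) {
    s <- integer(0)
    for (i in seq_len(nrow(eps))) {
      lo <- max(eps$start_sample[i], w0)
      hi <- min(eps$end_sample[i], w1)
      if (hi > lo) s <- union(s, seq.int(lo, hi - 1))
    }
    s
  }
  best_other <- function(eps, span_set, excl) {
    cls <- setdiff(unique(eps$class), excl)
    if (length(cls) == 0) return(NA_character_)
    ov <- vapply(cls, function(cl) {
      length(intersect(set_of(eps[eps$class == cl, , drop = FALSE]), span_set))
    }, numeric(1))
    ov <- ov[ov > 0]
    if (length(ov) == 0) return(NA_character_)
    cand <- names(ov)[ov == max(ov)]
    if (length(cand) > 1) {
      is_crit <- rhythmconcord::criticality(cand) == "critical"
      if (any(is_crit)) cand <- cand[is_crit]
      cand <- sort(cand)
    }
    cand[1]
  }
  in_win <- function(eps) {
    eps[eps$start_sample < w1 & eps$end_sample > w0, , drop = FALSE]
  }
  p_all <- in_win(panel)
  r_all <- in_win(reader)
  rows <- list()
  for (cl in classes) {
    fam <- rhythmconcord::class_family(cl)
    pset <- set_of(p_all[p_all$class == cl, , drop = FALSE])
    rset <- set_of(r_all[r_all$class == cl, , drop = FALSE])
    present_p <- length(pset) > 0
    present_r <- length(rset) > 0
    conc <- FALSE
    if (present_p && present_r) {
      frac <- length(intersect(pset, rset)) / length(pset)
      conc <- switch(fam,
        avblock = TRUE,
        ectopic = {
          ps <- p_all$start_sample[p_all$class == cl]
          rs <- r_all$start_sample[r_all$class == cl]
          any(outer(ps, rs, function(a, b) abs(a - b)) <=
                rules$ectopic_tol_samples)
        },
        tachy = frac >= rules$tachy_overlap,
        gap = frac >= rules$gap_overlap,
        noise = frac >= rules$noise_overlap,
        FALSE)
    }
    verdict <- if (present_p && conc) "true_positive"
               else if (present_p) "false_negative"
               else if (present_r) "false_positive"
               else "true_negative"
    mis <- NA_character_
    if (verdict == "false_negative") mis <- best_other(r_all, pset, cl)
    if (verdict == "false_positive") mis <- best_other(p_all, rset, cl)
    rows[[cl]] <- data.frame(class = cl, verdict = verdict,
                             misclassified_as = mis)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random episode set for the oracle comparison, confined to one strip window
random_strip_episodes <- function(n_eps, w0, w1, classes) {
  if (n_eps == 0) {
    return(data.frame(class = character(0), start_sample = numeric(0),
                      end_sample = numeric(0)))
  }
  cls <- sample(classes, n_eps, replace = TRUE)
  len <- ifelse(cls %in% c("pac", "pvc"), 1,
                sample(30:6000, n_eps, replace = TRUE))
  start <- w0 + sample.int(w1 - w0 - 1, n_eps, replace = TRUE) - 1
  data.frame(class = cls, start_sample = start,
             end_sample = pmin(start + len, w1))
}
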