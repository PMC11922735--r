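eps_df <- function(class, start, end) {
  data.frame(class = class, start_sample = start, end_sample = end)
}
win_strip <- function(w0 = 0, w1 = 10200, id = "S1") {
  data.frame(strip_id = id, start_sample = w0, end_sample = w1)
}

test_that("overlap fractions use the panel episode as denominator", {
  # identical episodes
  fr <- episode_overlap(eps_df("af", 0, 9000), eps_df("af", 0, 9000))
  expect_equal(unname(fr), c(1, 1))
  # panel AF 30 s, reader covers 24 s of it: exactly the 80% bound
  fr <- episode_overlap(eps_df("af", 0, 9000), eps_df("af", 0, 7200))
  expect_equal(fr[["duration_fraction"]], 0.80)
  # panel asystole 4.0 s, nested reader asystole 3.5 s: 0.875 < 0.90
  fr <- episode_overlap(eps_df("asystole", 0, 1200), eps_df("asystole", 75, 1125))
  expect_equal(fr[["duration_fraction"]], 0.875)
  # fragmentation: two reader pieces are united before the fraction
  fr <- episode_overlap(eps_df("af", 0, 9000),
                        eps_df(c("af", "af"), c(0, 4500), c(3600, 8100)))
  expect_equal(fr[["duration_fraction"]], 0.80)
})

test_that("strip verdicts follow the overlap rules per class family", {
  st <- win_strip()
  # identical annotation: TP for the present class, TN elsewhere
  p <- eps_df("af", 1000, 10000)
  v <- match_strip(st, p, p, classes = c("af", "vt", "asystole"))
  expect_equal(v$verdict[v$class == "af"], "true_positive")
  expect_equal(sort(unique(v$verdict[v$class != "af"])), "true_negative")
  # AV block scored on presence anywhere within the strip
  v <- match_strip(st, eps_df("avb3", 5000, 5600), eps_df("avb3", 100, 400),
                   classes = "avb3")
  expect_equal(v$verdict, "true_positive")
  # ectopics concordant within +/-45 samples only
  v_in <- match_strip(st, eps_df("pac", 5000, 5001), eps_df("pac", 5044, 5045),
                      classes = "pac")
  v_at <- match_strip(st, eps_df("pac", 5000, 5001), eps_df("pac", 5045, 5046),
                      classes = "pac")
  v_out <- match_strip(st, eps_df("pac", 5000, 5001), eps_df("pac", 5046, 5047),
                       classes = "pac")
  expect_equal(v_in$verdict, "true_positive")
  expect_equal(v_at$verdict, "true_positive")
  expect_equal(v_out$verdict, "false_negative")
  # discordant sustained rhythm: FN with the covering reader class recorded
  v <- match_strip(st, eps_df("af", 0, 9000), eps_df("svt", 0, 9000),
                   classes = c("af", "svt"))
  expect_equal(v$verdict[v$class == "af"], "false_negative")
  expect_equal(v$misclassified_as[v$class == "af"], "svt")
  expect_equal(v$verdict[v$class == "svt"], "false_positive")
  expect_equal(v$misclassified_as[v$class == "svt"], "af")
  # reader episode entirely outside the window is an input error
  expect_error(match_strip(st, p, eps_df("af", 20000, 21000), classes = "af"),
               "outside the strip window")
})

test_that("beat-type overlap below threshold breaks tachyarrhythmia concordance", {
  st <- win_strip()
  p <- eps_df("af", 0, 9000)
  panel_track <- data.frame(sample = seq(0, 8999, by = 150),
                            beat_class = "af_beat")
  # reader labels 30% of the panel beats as something else
  rt <- panel_track
  flip <- seq_len(nrow(rt)) %% 10 < 3
  rt$beat_class[flip] <- "svt_beat"
  v <- match_strip(st, p, p, classes = "af",
                   panel_track = panel_track, reader_track = rt)
  expect_equal(v$verdict, "false_negative")
  # 10% disagreement is a minor beat-level discrepancy: still concordant
  rt2 <- panel_track
  rt2$beat_class[seq_len(nrow(rt2)) %% 10 == 0] <- "unknown"
  v2 <- match_strip(st, p, p, classes = "af",
                    panel_track = panel_track, reader_track = rt2)
  expect_equal(v2$verdict, "true_positive")
})

test_that("a missed-beat annotation is concordant second-degree AV block for aliased readers", {
  st <- win_strip()
  p <- eps_df("avb2", 3000, 6000)
  none <- eps_df("af", 1, 2)[0, ]
  trk <- data.frame(sample = c(1000, 1300), beat_class = "blocked_beat")
  v_tech <- match_strip(st, p, none, classes = "avb2", reader_track = trk,
                        reader = "technician")
  v_ai <- match_strip(st, p, none, classes = "avb2", reader_track = trk,
                      reader = "ai")
  expect_equal(v_tech$verdict, "true_positive")
  expect_equal(v_ai$verdict, "false_negative")
})

test_that("enlarging a covering reader episode never turns TP into FN", {
  st <- win_strip()
  p <- eps_df("af", 2000, 8000)
  grow <- seq(0, 2000, by = 400)
  verdicts <- vapply(grow, function(g) {
    r <- eps_df("af", max(0, 2000 - g), min(10200, 8000 + g))
    match_strip(st, p, r, classes = "af")$verdict
  }, "")
  expect_true(all(verdicts == "true_positive"))
})

test_that("the misclassification-insensitive variant drops only the stated events", {
  v <- data.frame(
    strip_id = "S1", reader = "ai",
    class = c("af", "af", "avb2", "vt", "pause"),
    verdict = c("false_negative", "false_negative", "false_positive",
                "false_positive", "false_negative"),
    misclassified_as = c("svt", NA, NA, "pause", "asystole"),
    variant = "primary")
  out <- apply_variant(v, "misclassification_insensitive")
  # critical FN misread as another critical class: excluded
  expect_equal(out$verdict[1], "excluded")
  # critical FN with no covering class: retained
  expect_equal(out$verdict[2], "false_negative")
  # second-degree AV block FP: excluded
  expect_equal(out$verdict[3], "excluded")
  # critical FP whose panel truth was noncritical: retained
  expect_equal(out$verdict[4], "false_positive")
  # noncritical FN: retained even though covered by a critical class
  expect_equal(out$verdict[5], "false_negative")
  # the variant never increases error counts
  n_err <- function(x) sum(x$verdict %in% c("false_positive", "false_negative"))
  expect_lte(n_err(out), n_err(v))
})
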