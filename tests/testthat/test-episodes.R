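test_that("an empty track yields an empty episode list", {
  ep <- derive_episodes(data.frame(sample = numeric(0),
                                   beat_class = character(0)))
  expect_equal(nrow(ep), 0)
})

test_that("inter-beat gaps become pause or asystole episodes by duration", {
  # 1,080 samples = 3.6 s >= 3.5 s: asystole
  ep <- derive_episodes(data.frame(sample = c(0, 1080),
                                   beat_class = "sinus"))
  expect_equal(ep$class[ep$n_beats == 0], "asystole")
  expect_equal(ep$duration_s[ep$class == "asystole"], 3.6)
  # 750 samples = 2.5 s: pause
  ep <- derive_episodes(data.frame(sample = c(0, 750), beat_class = "sinus"))
  expect_equal(ep$class[ep$n_beats == 0], "pause")
  # 570 samples = 1.9 s: no gap episode
  ep <- derive_episodes(data.frame(sample = c(0, 570), beat_class = "sinus"))
  expect_false(any(ep$n_beats == 0))
})

test_that("rhythm runs become single episodes with rate and padded duration", {
  trk <- make_track(list(list(class = "sinus", rr_s = 0.8, n = 10),
                         list(class = "af_beat", rr_s = 0.5, n = 20),
                         list(class = "sinus", rr_s = 0.8, n = 10)))
  ep <- derive_episodes(trk)
  af <- ep[ep$class %in% c("af", "af_short"), ]
  expect_equal(nrow(af), 1)
  expect_equal(af$n_beats, 20)
  expect_equal(af$mean_rate_bpm, 120)
  # duration = (n-1) RR spans + one median RR pad
  expect_equal(af$duration_s, 20 * 0.5)
})

test_that("short atrial runs are PACs, longer runs one ectopic atrial rhythm", {
  two <- make_track(list(list(class = "sinus", rr_s = 0.8, n = 5),
                         list(class = "atrial_ectopic", rr_s = 0.6, n = 2),
                         list(class = "sinus", rr_s = 0.8, n = 5)))
  ep2 <- derive_episodes(two)
  expect_equal(sum(ep2$class == "pac"), 2)
  three <- make_track(list(list(class = "sinus", rr_s = 0.8, n = 5),
                           list(class = "atrial_ectopic", rr_s = 0.6, n = 3),
                           list(class = "sinus", rr_s = 0.8, n = 5)))
  ep3 <- derive_episodes(three)
  expect_equal(sum(ep3$class == "pac"), 0)
  expect_equal(sum(ep3$class == "ear"), 1)
  expect_equal(ep3$n_beats[ep3$class == "ear"], 3)
})

test_that("derivation is deterministic and idempotent", {
  set.seed(11)
  trk <- make_track(list(list(class = "sinus", rr_s = 0.8, n = 40),
                         list(class = "vt_beat", rr_s = 0.4, n = 30),
                         list(gap_s = 2.6),
                         list(class = "sinus", rr_s = 0.8, n = 40)))
  expect_identical(derive_episodes(trk), derive_episodes(trk))
})

test_that("splitting at a run boundary preserves episodes away from the cut", {
  trk <- make_track(list(list(class = "sinus", rr_s = 0.8, n = 20),
                         list(class = "af_beat", rr_s = 0.5, n = 80),
                         list(class = "sinus", rr_s = 0.8, n = 20)))
  cut <- trk$sample[21]  # first AF beat
  left <- trk[trk$sample < cut, ]
  right <- trk[trk$sample >= cut, ]
  whole <- derive_episodes(trk)
  halves <- rbind(derive_episodes(left), derive_episodes(right))
  key <- function(e) e[order(e$start_sample),
                       c("class", "start_sample", "end_sample", "n_beats")]
  expect_equal(key(whole), key(halves), ignore_attr = TRUE)
})

test_that("invalid tracks are rejected with the offending record", {
  expect_error(derive_episodes(data.frame(sample = c(100, 50),
                                          beat_class = "sinus")),
               "not strictly increasing")
  expect_error(derive_episodes(data.frame(sample = c(0, 100),
                                          beat_class = c("sinus", "wide_qrs"))),
               "wide_qrs")
})

test_that("mean heart rate is 60 over the mean RR", {
  expect_equal(mean_heart_rate(c(0, 150, 300)), 120)    # constant 0.5 s
  expect_equal(mean_heart_rate(c(0, 120, 270, 450)), 120)  # 0.4/0.5/0.6 s
  expect_error(mean_heart_rate(100), "fewer than 2")
})

test_that("every beat joins at most one tachyarrhythmia episode", {
  set.seed(21)
  for (rep in 1:5) {
    runs <- list()
    for (k in 1:8) {
      cl <- sample(c("sinus", "af_beat", "vt_beat", "svt_beat"), 1)
      runs[[k]] <- list(class = cl, rr_s = stats::runif(1, 0.4, 0.9),
                        n = sample(3:25, 1))
    }
    trk <- make_track(runs)
    ep <- derive_episodes(trk)
    tachy <- ep[class_family(ep$class) == "tachy", , drop = FALSE]
    hits <- rep(0, nrow(trk))
    for (i in seq_len(nrow(tachy))) {
      hits <- hits + (trk$sample >= tachy$start_sample[i] &
                        trk$sample < tachy$end_sample[i] &
                        trk$beat_class != "sinus")
    }
    expect_true(all(hits <= 1))
  }
})
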