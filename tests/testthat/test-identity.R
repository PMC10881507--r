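# small hand-built tracklet table on a 1 Hz grid
toy_tracklets <- function() {
  data.frame(tick = rep(0:9, 2), t = rep(0:9, 2),
             tracklet_id = rep(1:2, each = 10),
             x = c(rep(100, 10), rep(700, 10)),
             y = 300, z = 800, source = "video")
}

obs_at <- function(t, x, id, conf = 1)
  data.frame(t = t, x = x, y = 300, z = 800, predicted_id = id,
             confidence = conf)

test_that("majority vote labels tracklets; ties and unknowns are discarded", {
  tr <- toy_tracklets()
  obs <- rbind(obs_at(1, 100, "A"), obs_at(3, 100, "A"), obs_at(5, 100, "A"),
               obs_at(2, 700, "B"), obs_at(4, 700, "unknown"))
  idf <- link_identities(tr, obs, tick_rate = 1)
  expect_true(all(idf$individual_id[idf$tracklet_id == 1] == "A"))
  expect_true(all(idf$individual_id[idf$tracklet_id == 2] == "B"))

  # 5 vs 2 -> majority; 2 vs 2 -> unidentified
  obs2 <- rbind(do.call(rbind, lapply(1:5, function(i) obs_at(i, 100, "A"))),
                do.call(rbind, lapply(6:7, function(i) obs_at(i, 100, "B"))))
  idf2 <- link_identities(tr[tr$tracklet_id == 1, ], obs2, tick_rate = 1,
                          vote = "tracklet")
  expect_true(all(idf2$individual_id == "A"))
  obs3 <- rbind(do.call(rbind, lapply(1:2, function(i) obs_at(i, 100, "A"))),
                do.call(rbind, lapply(3:4, function(i) obs_at(i, 100, "B"))))
  idf3 <- link_identities(tr[tr$tracklet_id == 1, ], obs3, tick_rate = 1,
                          vote = "tracklet")
  expect_true(all(is.na(idf3$individual_id)))
})

test_that("concurrent claims of one individual resolve to the stronger vote", {
  tr <- toy_tracklets()
  obs <- rbind(obs_at(1, 100, "A"), obs_at(3, 100, "A"),
               obs_at(2, 700, "A"))
  idf <- link_identities(tr, obs, tick_rate = 1)
  expect_true(all(idf$individual_id[idf$tracklet_id == 1] == "A"))
  expect_true(all(is.na(idf$individual_id[idf$tracklet_id == 2])))
})

test_that("events beyond the match gate or below the confidence floor never vote", {
  tr <- toy_tracklets()
  far <- obs_at(1, 400, "B")           # 300+ mm from both tracklets
  far$y <- 800
  weak <- obs_at(2, 700, "B", conf = 0.1)
  idf <- link_identities(tr, rbind(far, weak), tick_rate = 1,
                         match_gate = 300, min_confidence = 0.5)
  expect_true(all(is.na(idf$individual_id)))
})

test_that("classification metrics reproduce one-vs-rest arithmetic", {
  # perfect classifier: all metrics 100
  perfect <- data.frame(class = "A", tp = 50, fp = 0, fn = 0, tn = 150)
  m <- classification_metrics(perfect)
  expect_equal(unlist(m[1, -1]), c(specificity = 100, accuracy = 100,
                                   recall = 100, precision = 100,
                                   f_measure = 100))
  # hand-computed mixed case
  mixed <- data.frame(class = "B", tp = 80, fp = 5, fn = 20, tn = 395)
  m2 <- classification_metrics(mixed)
  expect_equal(m2$recall, 100 * 80 / 100)
  expect_equal(m2$precision, 100 * 80 / 85)
  expect_equal(m2$specificity, 100 * 395 / 400)
  expect_equal(m2$accuracy, 100 * 475 / 500)
  expect_equal(m2$f_measure,
               100 * 2 * (80 / 85) * (80 / 100) / (80 / 85 + 80 / 100))
  # zero denominator reported as NaN
  degenerate <- data.frame(class = "C", tp = 0, fp = 0, fn = 10, tn = 490)
  expect_true(is.nan(classification_metrics(degenerate)$precision))
})

test_that("F-measure and overall accuracy match published-table arithmetic", {
  # family-group classifier: P 96.1 / R 98.8 -> F 97.4
  expect_equal(percent_round(f_measure(96.1, 98.8)), 97.4)
  # five-animal classifier: P 99.0 / R 98.0 -> F 98.5
  expect_equal(percent_round(f_measure(99.0, 98.0)), 98.5)
  # five animals, 100 eval images each, recalls 99/99/98/100/100 -> 99.2
  expect_equal(percent_round(overall_accuracy(c(99, 99, 98, 100, 100),
                                              rep(100, 5))), 99.2)
  # four classes x 1400 images, recalls 98.8/96.1/97.6/99.6 -> 98.0
  correct <- round(c(98.8, 96.1, 97.6, 99.6) / 100 * 1400)
  expect_equal(percent_round(overall_accuracy(correct, rep(1400, 4))), 98.0)
  expect_equal(overall_accuracy(c(10, 20), c(10, 20)), 100)
})

test_that("percent rounding is half-up to one decimal", {
  expect_equal(percent_round(2.25), 2.3)
  expect_equal(percent_round(2.24), 2.2)
  expect_equal(percent_round(97.35), 97.4)
})

test_that("identity switches are counted from wrong runs at least min_duration long", {
  # truth: two animals far apart on a 1 Hz grid, 600 s
  ticks <- 0:599
  truth <- rbind(
    data.frame(tick = ticks, individual_id = "A", x = 100, y = 300, z = 800),
    data.frame(tick = ticks, individual_id = "B", x = 700, y = 300, z = 800))
  est <- data.frame(tick = rep(ticks, 2), t = rep(ticks, 2),
                    tracklet_id = rep(1:2, each = 600),
                    x = c(rep(100, 600), rep(700, 600)),
                    y = 300, z = 800, source = "video",
                    individual_id = rep(c("A", "B"), each = 600))
  # exact estimate: no switches
  rep0 <- id_switch_report(est, truth, tick_rate = 1)
  expect_identical(rep0$n_switches, 0L)
  expect_equal(rep0$wrong_id_fraction, 0)
  expect_equal(rep0$correct_tick_fraction, 1)

  # swap the labels for 10 s: two wrong runs, 20 s wrong time over 600 s
  est2 <- est
  swap <- est2$tick >= 100 & est2$tick < 110
  est2$individual_id[swap] <-
    ifelse(est2$individual_id[swap] == "A", "B", "A")
  rep2 <- id_switch_report(est2, truth, tick_rate = 1, min_duration = 5)
  expect_identical(rep2$n_switches, 2L)
  expect_equal(rep2$wrong_id_fraction, 20 / 600)

  # wrong runs of 3 s are below the 5 s gate
  est3 <- est
  swap3 <- est3$tick >= 100 & est3$tick < 103
  est3$individual_id[swap3] <-
    ifelse(est3$individual_id[swap3] == "A", "B", "A")
  rep3 <- id_switch_report(est3, truth, tick_rate = 1, min_duration = 5)
  expect_identical(rep3$n_switches, 0L)
  expect_equal(rep3$wrong_id_fraction, 0)
})

test_that("wrong-id fraction is invariant under a joint relabeling of truth and estimate", {
  ticks <- 0:99
  truth <- rbind(
    data.frame(tick = ticks, individual_id = "A", x = 100, y = 300, z = 800),
    data.frame(tick = ticks, individual_id = "B", x = 700, y = 300, z = 800))
  est <- data.frame(tick = rep(ticks, 2), t = rep(ticks, 2),
                    tracklet_id = rep(1:2, each = 100),
                    x = c(rep(100, 100), rep(700, 100)),
                    y = 300, z = 800, source = "video",
                    individual_id = rep(c("B", "A"), each = 100))
  r1 <- id_switch_report(est, truth, tick_rate = 1)
  relabel <- c(A = "X", B = "Y")
  truth2 <- truth; truth2$individual_id <- relabel[truth$individual_id]
  est2 <- est; est2$individual_id <- relabel[est$individual_id]
  r2 <- id_switch_report(est2, truth2, tick_rate = 1)
  expect_equal(r1$wrong_id_fraction, r2$wrong_id_fraction)
  expect_identical(r1$n_switches, r2$n_switches)
})
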