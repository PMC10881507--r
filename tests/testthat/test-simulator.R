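test_that("simulation is bit-identical under a fixed seed", {
  s1 <- family3_scene(horizon = 10, seed = 4)
  s2 <- family3_scene(horizon = 10, seed = 4)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$streams$detections, s2$streams$detections)
  expect_identical(s1$streams$face_events, s2$streams$face_events)
  expect_identical(s1$streams$grooming, s2$streams$grooming)
  expect_identical(s1$streams$lidar$clouds, s2$streams$lidar$clouds)
  s3 <- family3_scene(horizon = 10, seed = 5)
  expect_false(identical(s1$truth, s2$truth) &&
                 identical(s1$streams$detections, s3$streams$detections))
})

test_that("a purely resting agent stays put", {
  ag <- agent_spec("solo", state_probs = c(rest = 1, locomote = 0, jump = 0))
  tr <- simulate_trajectories(list(ag), horizon = 20, seed = 2)
  expect_identical(length(unique(tr$x)), 1L)
  expect_identical(length(unique(tr$z)), 1L)
})

test_that("a scripted zone stay is recovered by occupancy within a percent", {
  # 100 s scripted stay at a lower-floor spot in a 600 s run, using a
  # huddle event to pin the agent there; occupancy must recover ~16.7%
  ag <- agent_spec("solo", home_zones = list(
    list(min = c(100, 100, 700), max = c(700, 500, 1400))))
  script <- behavior_script(data.frame(
    event = "huddle", participants = "solo",
    x = 400, y = 300, z = 60, start = 100, duration = 100))
  tr <- simulate_trajectories(list(ag), script, horizon = 600, seed = 6)
  occ <- zone_occupancy(tr, default_zones())
  got <- occ$percent[occ$zone == "lower_floor"]
  expect_gt(got, 100 / 6 - 2.5)
  expect_lt(got, 100 / 6 + 2.5)
})

test_that("scripted event participants converge to the event location", {
  sc <- family3_scene(horizon = 60, seed = 8)
  script <- sc$script
  g <- script[script$event == "groom", ][1, ]
  mid <- g$start + g$duration / 2
  tr <- sc$truth[abs(sc$truth$t - mid) < 0.5 &
                   sc$truth$individual_id %in%
                     cagetrack:::script_participants(g), ]
  d <- sqrt((tr$x - g$x)^2 + (tr$y - g$y)^2 + (tr$z - g$z)^2)
  expect_true(all(d <= 150))
})

test_that("overlapping exclusive events for one agent are rejected", {
  bad <- behavior_script(data.frame(
    event = c("huddle", "groom"), participants = c("A,B", "A,C"),
    x = 400, y = 300, z = 800, start = c(10, 15), duration = c(20, 20)))
  expect_error(
    simulate_trajectories(list(agent_spec("A"), agent_spec("B"),
                               agent_spec("C")), bad, horizon = 60,
                          seed = 1),
    "infeasible script")
})

test_that("every rendered true detection corresponds to a truth position", {
  sc <- family3_scene(horizon = 10, seed = 10)
  det <- sc$streams$detections
  genuine <- det[det$truth_id != "", ]
  truth_keys <- paste(round(sc$truth$t, 6), sc$truth$individual_id)
  expect_true(all(paste(round(genuine$t, 6), genuine$truth_id) %in%
                    truth_keys))
  # false positives are labelled in the hidden truth channel
  expect_true(any(det$truth_id == "") || nrow(det) == 0)
})

test_that("zero-noise zero-miss rendering reconstructs truth end to end", {
  quiet <- sensor_spec(pixel_noise = 0, miss_base = 0,
                       miss_speed_coef = 0, false_positive_rate = 0,
                       false_cluster_rate = 0, face_rate = 1,
                       face_accuracy = 1, face_unknown_rate = 0,
                       groom_false_rate = 0)
  zones <- list(list(min = c(80, 80, 30), max = c(740, 530, 320)),
                list(min = c(80, 80, 600), max = c(400, 530, 1000)),
                list(min = c(420, 80, 1100), max = c(740, 530, 1500)))
  agents <- lapply(1:3, function(i)
    agent_spec(c("A", "B", "C")[i], home_zones = zones[i]))
  sc <- simulate_scene(agents, horizon = 15, seed = 12, sensors = quiet)
  res <- run_pipeline(sc)
  # every video point lies on a truth position
  tb <- split(sc$truth, sc$truth$tick)
  err <- vapply(seq_len(nrow(res$video)), function(i) {
    tt <- tb[[as.character(res$video$tick[i])]]
    min(sqrt((tt$x - res$video$x[i])^2 + (tt$y - res$video$y[i])^2 +
               (tt$z - res$video$z[i])^2), na.rm = TRUE)
  }, numeric(1))
  expect_lt(stats::quantile(err, 0.99), 1e-4)
  # identity linking is perfect under the perfect face classifier
  rep <- id_switch_report(res$identified, sc$truth)
  expect_gte(rep$correct_tick_fraction, 0.99)
})

test_that("tracking error grows with pixel noise", {
  err_at <- function(noise, seed) {
    sc <- family3_scene(horizon = 10, seed = seed,
                        sensors = sensor_spec(pixel_noise = noise,
                                              false_positive_rate = 0))
    vp <- video_points(sc$streams$detections, sc$cameras, sc$cage)
    tb <- split(sc$truth, sc$truth$tick)
    median(vapply(seq_len(nrow(vp)), function(i) {
      tt <- tb[[as.character(vp$tick[i])]]
      min(sqrt((tt$x - vp$x[i])^2 + (tt$y - vp$y[i])^2 +
                 (tt$z - vp$z[i])^2), na.rm = TRUE)
    }, numeric(1)))
  }
  for (seed in c(31, 32, 33)) {
    e <- vapply(c(0, 2, 6), err_at, numeric(1), seed = seed)
    expect_true(all(diff(e) > 0))
  }
})

test_that("fixture bundles round-trip and regenerate bit-identically", {
  dir1 <- file.path(tempdir(), "fix1")
  dir2 <- file.path(tempdir(), "fix2")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE), add = TRUE)
  sc <- family3_scene(horizon = 5, seed = 20)
  m1 <- make_fixture(sc, dir1, "family3")
  m2 <- make_fixture(family3_scene(horizon = 5, seed = 20), dir2, "family3")
  for (f in setdiff(names(m1$files), "manifest.json"))
    expect_identical(m1$files[[f]], m2$files[[f]])
  # round-trip: truth reads back equal
  tr <- utils::read.csv(file.path(dir1, "truth.csv"))
  expect_equal(nrow(tr), nrow(sc$truth))
  expect_equal(tr$x, sc$truth$x, tolerance = 1e-9)
})
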