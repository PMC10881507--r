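tick_grid <- function(horizon, dt = 1 / 7.4) seq(0, horizon, by = dt)

test_that("Gaussian smoothing preserves constants and annihilates zeros", {
  t <- tick_grid(300)
  p <- smooth_params()
  expect_true(all(smooth_series(t, rep(0, length(t)), p)$value == 0))
  s <- smooth_series(t, rep(0.37, length(t)), p)
  expect_equal(s$value, rep(0.37, nrow(s)), tolerance = 1e-12)
  # output bounded by input range
  set.seed(5)
  v <- runif(length(t))
  s2 <- smooth_series(t, v, p)
  expect_true(all(s2$value >= min(v) - 1e-12 & s2$value <= max(v) + 1e-12))
})

test_that("smoothed boxcar crosses 0.5 within half a window of each pulse edge", {
  t <- tick_grid(600)
  v <- as.numeric(t >= 200 & t < 260)  # 60 s rectangular pulse
  p <- smooth_params(window = 50, slide = 5)
  s <- smooth_series(t, v, p)

  # independent oracle: closed-form convolution of the boxcar with the
  # truncated, renormalised Gaussian kernel evaluated by quadrature
  kernel_mean <- function(center) {
    tt <- seq(center - 25, center + 25, by = 0.01)
    w <- exp(-((tt - center)^2) / (2 * p$sigma^2))
    sum(w * as.numeric(tt >= 200 & tt < 260)) / sum(w)
  }
  ref <- vapply(s$t, kernel_mean, numeric(1))
  expect_equal(s$value, ref, tolerance = 0.02)

  above <- s$t[!is.na(s$value) & s$value > 0.5]
  expect_lt(abs(min(above) - 200), p$window / 2 + p$slide)
  expect_lt(abs(max(above) - 260), p$window / 2 + p$slide)
})

test_that("camera averaging is the exact pointwise mean and rejects grid mismatch", {
  t <- tick_grid(100)
  set.seed(6)
  a <- smooth_series(t, rbinom(length(t), 1, 0.3))
  b <- smooth_series(t, rbinom(length(t), 1, 0.6))
  m <- combine_cameras(a, b)
  expect_equal(m$value, (a$value + b$value) / 2)
  expect_equal(combine_cameras(a, a)$value, a$value)
  expect_error(combine_cameras(a, b[-1, ]), "different slide grids")
})

test_that("bout extraction does run-length arithmetic and merges near runs", {
  grid <- data.frame(t = seq(0, 200, by = 5), value = 0)
  expect_identical(nrow(extract_bouts(grid, 0.5)), 0L)
  # 6 supra-threshold slide points -> one 30 s bout
  s <- grid
  s$value[s$t >= 100 & s$t < 130] <- 0.9
  b <- extract_bouts(s, 0.5)
  expect_identical(nrow(b), 1L)
  expect_equal(b$end - b$start, 30)
})

test_that("bout count is nonincreasing and bouts nest as the threshold rises", {
  set.seed(7)
  t <- tick_grid(900)
  v <- as.numeric(runif(length(t)) <
                    0.5 * (1 + sin(t / 40)) * 0.8)
  s <- smooth_series(t, v, smooth_params())
  ths <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  bouts <- lapply(ths, function(th) extract_bouts(s, th))
  counts <- vapply(bouts, nrow, integer(1))
  expect_true(all(diff(counts) <= 0))
  for (i in 2:length(ths)) {
    hi <- bouts[[i]]; lo <- bouts[[i - 1]]
    for (j in seq_len(nrow(hi)))
      expect_true(any(lo$start <= hi$start[j] + 1e-9 &
                        lo$end >= hi$end[j] - 1e-9))
  }
})

test_that("bouts are attributed to the nearest at most two individuals", {
  ticks <- 0:60
  mk <- function(id, x) data.frame(tick = ticks, t = ticks,
                                   tracklet_id = 1, x = x, y = 300, z = 800,
                                   source = "video", individual_id = id)
  idf <- rbind(mk("A", 395), mk("B", 410), mk("C", 2000))
  got <- attribute_bout(list(start = 10, end = 50), idf, c(400, 300, 800))
  expect_setequal(got, c("A", "B"))
  # nobody present -> empty with warning
  idf2 <- mk("A", 2000)
  expect_warning(got2 <- attribute_bout(list(start = 10, end = 50), idf2,
                                        c(400, 300, 800)), "gate")
  expect_length(got2, 0)
})

test_that("unit evaluation reproduces count arithmetic and the swap symmetry", {
  # randomized bout sets vs brute-force per-unit oracle
  set.seed(8)
  for (rep in 1:5) {
    horizon <- 1800
    mk_bouts <- function(n) {
      st <- sort(runif(n, 0, horizon - 60))
      data.frame(start = st, end = st + runif(n, 10, 60))
    }
    m <- mk_bouts(8); tr <- mk_bouts(9)
    ev <- evaluate_units(m, tr, horizon, unit = 30)
    # oracle
    units <- seq(0, horizon - 1, by = 30)
    pos <- function(b, s) any(b$start < s + 30 & b$end > s)
    mp <- vapply(units, function(s) pos(m, s), logical(1))
    tp <- vapply(units, function(s) pos(tr, s), logical(1))
    expect_equal(ev$recall, 100 * sum(mp & tp) / sum(tp))
    expect_equal(ev$precision, 100 * sum(mp & tp) / sum(mp))
    # symmetry: swapping machine and truth swaps recall and precision
    sw <- evaluate_units(tr, m, horizon, unit = 30)
    expect_equal(sw$recall, ev$precision)
    expect_equal(sw$precision, ev$recall)
  }
  # machine = truth -> both 100
  b <- data.frame(start = c(30, 300), end = c(90, 360))
  ev2 <- evaluate_units(b, b, 600)
  expect_equal(ev2$recall, 100)
  expect_equal(ev2$precision, 100)
  # zero machine positives -> precision undefined
  none <- data.frame(start = numeric(0), end = numeric(0))
  expect_true(is.nan(evaluate_units(none, b, 600)$precision))
})

test_that("scripted grooming is detected and attributed on simulated scenes", {
  hits <- 0; total <- 0
  for (seed in 1:6) {
    horizon <- 300
    sc <- family3_scene(horizon = horizon, seed = seed,
                        render = "grooming")
    # perfect tracking stand-in: truth as identified trajectories
    idf <- sc$truth
    idf$tracklet_id <- as.integer(factor(idf$individual_id))
    idf$individual_id <- idf$individual_id
    idf$source <- "video"
    g <- sc$streams$grooming
    det <- detect_grooming(g$t, g$left, g$right, smooth_params(),
                           identified = idf)
    script <- sc$script[sc$script$event == "groom", ]
    for (i in seq_len(nrow(script))) {
      total <- total + 1
      ov <- det$bouts$start < script$start[i] + script$duration[i] &
        det$bouts$end > script$start[i]
      if (!any(ov)) next
      parts <- strsplit(det$bouts$participants[which(ov)[1]], "\\+")[[1]]
      if (setequal(parts, cagetrack:::script_participants(script[i, ]))) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})
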