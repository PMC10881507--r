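make_blob <- function(n, center, sd = 30) {
  cbind(rnorm(n, center[1], sd), rnorm(n, center[2], sd),
        rnorm(n, center[3], sd))
}

test_that("background model is a deterministic idempotent union and coarser voxels cover more", {
  set.seed(1)
  scan <- random_interior(300)
  bg1 <- build_background(list(scan), 50)
  bg2 <- build_background(list(scan, scan), 50)
  expect_identical(bg1$occupied, bg2$occupied)

  coarse <- build_background(list(scan), 50)
  fine <- build_background(list(scan), 25)
  # every fine-occupied point is inside a coarse-occupied voxel
  expect_identical(nrow(remove_background(scan, coarse)), 0L)
  expect_identical(nrow(remove_background(scan, fine)), 0L)
  # coarser model occupies a superset volume: probe points near the scan
  probes <- scan + matrix(runif(length(scan), -24, 24), nrow(scan))
  kept_coarse <- nrow(remove_background(probes, coarse))
  kept_fine <- nrow(remove_background(probes, fine))
  expect_lte(kept_coarse, kept_fine)
  expect_error(build_background(list()), "at least one")
})

test_that("background subtraction is an exact voxel set difference", {
  set.seed(2)
  scan <- random_interior(400)
  bg <- build_background(list(scan), 40)
  expect_identical(nrow(remove_background(scan, bg)), 0L)
  blob <- make_blob(200, c(400, 300, 750), 30)
  # keep only blob points in voxels untouched by the background scan
  fg <- remove_background(rbind(scan, blob), bg)
  oracle <- blob[!(cagetrack:::voxel_key(blob, 40) %in% cagetrack:::voxel_key(scan, 40)), ,
                 drop = FALSE]
  expect_equal(nrow(fg), nrow(oracle))
  expect_equal(sort(fg[, 1]), sort(oracle[, 1]))
  empty <- remove_background(matrix(numeric(0), 0, 3), bg)
  expect_identical(nrow(empty), 0L)
})

test_that("cluster extraction matches a brute-force connected-components oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(2:4, 1)
    centers <- random_interior(k, margin = 300)
    pts <- do.call(rbind, lapply(seq_len(k), function(i)
      make_blob(sample(60:150, 1), centers[i, ], sd = 28)))
    tol <- 50
    lab_oracle <- bfs_components(pts, tol)
    cl <- extract_clusters(pts, cluster_params(tolerance = tol))
    # oracle side: apply the same S1/S2 gates to oracle components
    keep <- list()
    for (comp in split(seq_len(nrow(pts)), lab_oracle)) {
      ext <- max(apply(pts[comp, , drop = FALSE], 2,
                       function(v) diff(range(v))))
      if (ext >= 100 && ext <= 500) keep[[length(keep) + 1]] <- sort(comp)
    }
    expect_equal(nrow(cl), length(keep))
    got <- lapply(cl$members, sort)
    got <- got[order(vapply(got, `[`, numeric(1), 1))]
    keep <- keep[order(vapply(keep, `[`, numeric(1), 1))]
    expect_equal(got, keep)
    # centroids are the member means
    for (i in seq_len(nrow(cl)))
      expect_equal(unname(unlist(cl[i, c("cx", "cy", "cz")])),
                   unname(colMeans(pts[cl$members[[i]], , drop = FALSE])))
  }
})

test_that("size gates reject clusters outside [S1, S2]", {
  set.seed(9)
  # extent > S2: a 600 mm rod of closely spaced points
  rod <- cbind(seq(100, 700, by = 10), 300, 800)
  expect_identical(nrow(extract_clusters(rod, cluster_params())), 0L)
  # extent < S1: a tight 40 mm clump
  clump <- make_blob(50, c(400, 300, 800), sd = 6)
  expect_identical(nrow(extract_clusters(clump, cluster_params())), 0L)
  # empty input
  expect_identical(nrow(extract_clusters(matrix(numeric(0), 0, 3),
                                         cluster_params())), 0L)
})

test_that("clusters partition the retained points", {
  set.seed(12)
  pts <- rbind(make_blob(120, c(200, 200, 400)),
               make_blob(120, c(600, 400, 1200)))
  cl <- extract_clusters(pts, cluster_params())
  all_members <- unlist(cl$members)
  expect_identical(anyDuplicated(all_members), 0L)
})

test_that("enlarging the tolerance never increases the pre-gate component count", {
  set.seed(13)
  pts <- do.call(rbind, lapply(1:4, function(i)
    make_blob(60, random_interior(1, margin = 250), sd = 35)))
  tols <- c(30, 60, 120, 240)
  counts <- vapply(tols, function(tol)
    max(cagetrack:::connected_components_tol(pts, tol)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster tracking extends within gate, renumbers on breaks, never reuses serials", {
  cl1 <- data.frame(cx = 400, cy = 300, cz = 800)
  st <- track_clusters(NULL, cl1, 0)
  st <- track_clusters(st, data.frame(cx = 450, cy = 300, cz = 800), 0.1)
  expect_identical(unique(st$tracks$serial_id), 1L)
  # jump of 2x gate: old track closes, new serial issued
  st <- track_clusters(st, data.frame(cx = 1050, cy = 300, cz = 800), 0.2)
  expect_identical(st$tracks$serial_id, c(1L, 1L, 2L))
  expect_true(all(diff(st$tracks$serial_id) >= 0))
})

test_that("crossing assignment minimises total distance like the exhaustive oracle", {
  # two tracks approaching, two clusters: optimal pairing beats the swap
  st <- NULL
  st <- track_clusters(st, data.frame(cx = c(100, 700), cy = 300,
                                      cz = 800), 0)
  heads <- rbind(c(100, 300, 800), c(700, 300, 800))
  cl <- data.frame(cx = c(380, 420), cy = 300, cz = 800)
  # exhaustive 2-permutation oracle
  cen <- as.matrix(cl)
  perms <- list(c(1, 2), c(2, 1))
  costs <- vapply(perms, function(p)
    sum(sqrt(rowSums((heads - cen[p, ])^2))), numeric(1))
  best <- perms[[which.min(costs)]]
  st <- track_clusters(st, cl, 0.1, gate = 500)
  got <- st$tracks[st$tracks$t == 0.1, ]
  expect_equal(got$cx[match(1:2, got$serial_id)], cl$cx[order(best)])
})

test_that("stale tracks close after the dropout window", {
  st <- track_clusters(NULL, data.frame(cx = 400, cy = 300, cz = 800), 0)
  # nothing for 2 s (dropout 1 s), then a cluster at the same spot
  st <- track_clusters(st, data.frame(cx = 400, cy = 300, cz = 800), 2.5)
  expect_identical(st$tracks$serial_id, c(1L, 2L))
})
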