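#' Video detection pipeline
#'
#' Turns per-camera 2D object detections into per-tick 3D body positions.
#' Detections arrive as a data.frame with columns camera_id, t, class,
#' x, y, w, h, conf — bounding boxes in pixels, class one of "face",
#' "body", "grooming", "ball", "hammock".  Body boxes are reduced to their
#' centres, bucketed onto a common tick grid, associated across cameras by
#' triangulation residual, and triangulated into cage-frame positions.
#'
#' @name video_pipeline
NULL

#' Assign detections to the common tick grid
#'
#' Each detection snaps to the nearest tick centre `k / tick_rate`;
#' detections farther than `sync_tol` from every tick centre are dropped
#' (their count is reported as an attribute).
#'
#' @param detections Detection data.frame (needs at least camera_id, t).
#' @param tick_rate Analysis tick rate in Hz (default 7.4, the effective
#'   fused rate of the reference acquisition setup).
#' @param sync_tol Maximum |t - tick| in seconds; defaults to half a tick.
#' @return The detections with an added integer `tick` column and a
#'   `tick_t` column (tick centre in seconds); attribute `n_dropped` counts
#'   discarded rows.
#' @export
bucket_ticks <- function(detections, tick_rate = 7.4,
                         sync_tol = 0.5 / tick_rate) {
  stopifnot(tick_rate > 0, sync_tol > 0)
  tick <- round(detections$t * tick_rate)
  off <- abs(detections$t - tick / tick_rate)
  keep <- off <= sync_tol + 1e-12
  out <- detections[keep, , drop = FALSE]
  out$tick <- as.integer(tick[keep])
  out$tick_t <- out$tick / tick_rate
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Associate body detections across cameras at one tick
#'
#' Hypothesises cross-camera correspondences by triangulation residual.
#' All two-view pairs are triangulated; pairs are accepted greedily in
#' order of increasing residual, then extended with the remaining cameras'
#' detections whose reprojection error is below `max_residual`.  Each
#' detection is used at most once and groups need at least two views.
#'
#' @param tick_detections Body detections at one tick (data.frame with
#'   camera_id, x, y, w, h).
#' @param cameras Named list of [camera_model()]s keyed by camera_id.
#' @param max_residual Pixel gate on group RMS reprojection error
#'   (default 8 px).
#' @return A list of groups; each group is a list with `pixels` (k x 2
#'   matrix of bbox centres), `camera_ids`, and `rows` (row indices into
#'   `tick_detections`).
#' @export
associate_views <- function(tick_detections, cameras, max_residual = 8) {
  d <- tick_detections
  if (is.null(d$u)) d$u <- d$x + d$w / 2
  if (is.null(d$v)) d$v <- d$y + d$h / 2
  n <- nrow(d)
  if (n == 0) return(list())
  cam_of <- as.character(d$camera_id)
  if (length(unique(cam_of)) < 2) return(list())

  # candidate two-view seeds scored by a closed-form two-ray midpoint
  # (cheap; the accepted groups are re-triangulated by full DLT later)
  rays <- lapply(seq_len(n), function(i)
    pixel_ray(cameras[[cam_of[i]]], c(d$u[i], d$v[i])))
  seeds <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (cam_of[i] == cam_of[j]) next
    mid <- ray_midpoint(rays[[i]], rays[[j]])
    if (is.null(mid)) next
    res <- ray_pair_residual(mid, d, i, j, cameras, cam_of)
    if (res <= max_residual)
      seeds[[length(seeds) + 1]] <- list(rows = c(i, j), res = res)
  }
  if (length(seeds) == 0) return(list())
  seeds <- seeds[order(vapply(seeds, `[[`, numeric(1), "res"))]

  # extend every seed pair into a maximal candidate group, then accept
  # candidates greedily by (view count desc, residual asc): genuine
  # animals collect 3-4 consistent views, chance two-view pairings do not.
  # Extension membership is tested by cheap reprojection against the seed
  # midpoint; each candidate is DLT-triangulated once at the end.
  candidates <- list()
  for (s in seeds) {
    rows <- s$rows
    mid <- ray_midpoint(rays[[rows[1]]], rays[[rows[2]]])
    for (cid in setdiff(names(cameras), cam_of[rows])) {
      cand <- setdiff(which(cam_of == cid), rows)
      if (length(cand) == 0) next
      err <- vapply(cand, function(k)
        reproject_error(cameras[[cid]], mid, c(d$u[k], d$v[k])),
        numeric(1))
      if (min(err) <= max_residual) rows <- c(rows, cand[which.min(err)])
    }
    tr <- triangulate(cbind(d$u[rows], d$v[rows]), cameras[cam_of[rows]],
                      reject_outliers = FALSE)
    if (tr$residual > max_residual && length(rows) > 2) {
      rows <- s$rows   # fall back to the gated seed pair
      tr <- triangulate(cbind(d$u[rows], d$v[rows]),
                        cameras[cam_of[rows]], reject_outliers = FALSE)
    }
    if (tr$residual > max_residual) next
    candidates[[length(candidates) + 1]] <-
      list(rows = rows, n = length(rows), res = tr$residual)
  }
  if (length(candidates) == 0) return(list())
  ord <- order(-vapply(candidates, `[[`, integer(1), "n"),
               vapply(candidates, `[[`, numeric(1), "res"))
  used <- rep(FALSE, n)
  groups <- list()
  for (g in candidates[ord]) {
    if (any(used[g$rows])) next
    used[g$rows] <- TRUE
    groups[[length(groups) + 1]] <-
      list(pixels = cbind(d$u[g$rows], d$v[g$rows]),
           camera_ids = cam_of[g$rows], rows = g$rows)
  }
  groups
}

#' Triangulate associated view groups into 3D body positions
#'
#' @param groups Output of [associate_views()].
#' @param cameras Named list of [camera_model()]s.
#' @param cage Optional [cage_model()]; positions outside it (50 mm slack)
#'   are flagged `out_of_cage`.
#' @return Data.frame with x, y, z (mm), residual (px), n_views,
#'   low_confidence, out_of_cage — one row per group that triangulated.
#' @export
localize_bodies <- function(groups, cameras, cage = NULL) {
  rows <- lapply(groups, function(g) {
    tr <- tryCatch(triangulate(g$pixels, cameras[g$camera_ids]),
                   error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    data.frame(x = tr$point[1], y = tr$point[2], z = tr$point[3],
               residual = tr$residual, n_views = tr$n_views,
               low_confidence = tr$low_confidence)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      residual = numeric(0), n_views = integer(0),
                      low_confidence = logical(0))
  out$out_of_cage <- if (is.null(cage) || nrow(out) == 0) logical(nrow(out))
    else !in_cage(as.matrix(out[, c("x", "y", "z")]), cage, tol = 50)
  rownames(out) <- NULL
  out
}

#' Run the video pipeline over a detection stream
#'
#' Buckets body detections onto the tick grid, associates views and
#' triangulates, tick by tick.
#'
#' @param detections Detection data.frame (camera_id, t, class, x, y, w, h,
#'   conf); only class == "body" rows are used.
#' @param cameras Named list of [camera_model()]s.
#' @param cage Optional [cage_model()] for the out-of-cage flag.
#' @param tick_rate,sync_tol Passed to [bucket_ticks()].
#' @param max_residual Passed to [associate_views()].
#' @param merge_dist Per-tick deduplication radius in mm (default 100):
#'   when two triangulated points at one tick fall this close they are one
#'   animal seen through two partial camera subsets, and only the better
#'   supported point (more views, then lower residual) is kept.
#' @return Data.frame of video points: tick, t, x, y, z, residual, n_views,
#'   low_confidence, out_of_cage.
#' @export
video_points <- function(detections, cameras, cage = NULL, tick_rate = 7.4,
                         sync_tol = 0.5 / tick_rate, max_residual = 8,
                         merge_dist = 100) {
  bodies <- detections[detections$class == "body", , drop = FALSE]
  b <- bucket_ticks(bodies, tick_rate, sync_tol)
  out <- lapply(split(seq_len(nrow(b)), b$tick), function(ix) {
    g <- associate_views(b[ix, , drop = FALSE], cameras, max_residual)
    pts <- localize_bodies(g, cameras, cage)
    if (nrow(pts) == 0) return(NULL)
    pts <- dedup_points(pts, merge_dist)
    cbind(tick = b$tick[ix[1]], t = b$tick_t[ix[1]], pts)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(tick = integer(0), t = numeric(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), residual = numeric(0),
                      n_views = integer(0), low_confidence = logical(0),
                      out_of_cage = logical(0))
  rownames(out) <- NULL
  out
}

# closest point between two rays (least-squares midpoint); NULL when the
# rays are near parallel or the closest approach lies behind a camera
ray_midpoint <- function(r1, r2) {
  d1 <- r1$direction; d2 <- r2$direction
  b <- sum(d1 * d2)
  denom <- 1 - b^2
  if (denom < 1e-8) return(NULL)
  w <- r1$origin - r2$origin
  s <- (b * sum(d2 * w) - sum(d1 * w)) / denom
  t2 <- (sum(d2 * w) - b * sum(d1 * w)) / denom
  if (s < 0 || t2 < 0) return(NULL)
  (r1$origin + s * d1 + r2$origin + t2 * d2) / 2
}

ray_pair_residual <- function(point, d, i, j, cameras, cam_of) {
  e <- vapply(c(i, j), function(k)
    reproject_error(cameras[[cam_of[k]]], point, c(d$u[k], d$v[k])),
    numeric(1))
  sqrt(mean(e^2))
}

# keep the better-supported of any two same-tick points within merge_dist
dedup_points <- function(pts, merge_dist) {
  if (nrow(pts) < 2) return(pts)
  ord <- order(-pts$n_views, pts$residual)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) > 0) {
      d <- sqrt((pts$x[keep] - pts$x[i])^2 + (pts$y[keep] - pts$y[i])^2 +
                  (pts$z[keep] - pts$z[i])^2)
      if (any(d < merge_dist)) next
    }
    keep <- c(keep, i)
  }
  pts[sort(keep), , drop = FALSE]
}
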