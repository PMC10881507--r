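#' Video--lidar tracklet fusion
#'
#' Merges per-tick 3D video points (the primary modality) with lidar
#' cluster tracks (the fallback) into continuous anonymous tracklets.  At
#' every tick each live tracklet tries, in order: the nearest unclaimed
#' video point within the motion gate; else the nearest unclaimed lidar
#' centroid within the handoff gate of its last known position; else it
#' records a missing frame.  After `max_gap` seconds of missing frames the
#' tracklet closes.  Video points no tracklet claimed open new tracklets.
#' Sources are labelled per frame ("video", "lidar", "missing") so that
#' downstream stages can see which modality produced each coordinate.
#'
#' @name fusion_tracker
NULL

#' Fusion parameters
#'
#' @param gate Maximum per-tick displacement in mm (default 200, about
#'   1.5 m/s sustained — faster motion is a ballistic jump, which breaks
#'   the trajectory): a tracklet only claims a video point within
#'   `gate * elapsed_ticks` of its last position.
#' @param switch_gate Maximum video-to-lidar handoff distance in mm
#'   (default 300): when video is lost, the tracklet searches for a lidar
#'   centroid this close to the position just before the loss.
#' @param max_gap Seconds of consecutive missing frames before a tracklet
#'   closes (default 2).
#' @param contact_break Distance in mm (default 200, about one body length) below which two live
#'   tracklets are considered in physical contact and both are closed:
#'   association through contact is a coin flip, so the trajectory is
#'   broken and identity re-established from faces afterwards.  Set 0 to
#'   disable.
#' @return A list of class `fusion_params`.
#' @export
fusion_params <- function(gate = 200, switch_gate = 300, max_gap = 2,
                          contact_break = 200) {
  stopifnot(gate > 0, switch_gate > 0, max_gap > 0, contact_break >= 0)
  structure(list(gate = gate, switch_gate = switch_gate, max_gap = max_gap,
                 contact_break = contact_break),
            class = "fusion_params")
}

#' Fuse video points and lidar tracks into anonymous tracklets
#'
#' @param video Video point table from [video_points()] (tick, t, x, y, z;
#'   rows flagged `out_of_cage` are ignored).
#' @param lidar Lidar track table (`$tracks` of [track_stream()]): t,
#'   serial_id, cx, cy, cz.  May be `NULL` or empty for video-only runs.
#' @param ticks Integer vector of the complete tick grid to cover.
#' @param tick_rate Hz of the tick grid.
#' @param params A [fusion_params()].
#' @return A data.frame of class `fused_tracklets`: tick, t, tracklet_id,
#'   x, y, z (NA when missing), source.
#' @export
fuse_tracks <- function(video, lidar, ticks, tick_rate = 7.4,
                        params = fusion_params()) {
  ticks <- sort(unique(as.integer(ticks)))
  dt <- 1 / tick_rate
  if (!is.null(video) && nrow(video) > 0 && !is.null(video$out_of_cage))
    video <- video[!video$out_of_cage, , drop = FALSE]

  # lidar samples re-bucketed to the tick grid: per serial_id keep the
  # sample nearest each tick centre within half a tick
  lid_by_tick <- list()
  if (!is.null(lidar) && nrow(lidar) > 0) {
    lt <- lidar
    lt$tick <- as.integer(round(lt$t * tick_rate))
    keep <- abs(lt$t - lt$tick / tick_rate) <= 0.5 * dt + 1e-12
    lt <- lt[keep, , drop = FALSE]
    lid_by_tick <- split(lt, lt$tick)
  }
  vid_by_tick <- if (is.null(video) || nrow(video) == 0) list() else
    split(video, video$tick)

  live <- list()    # each: id, pos, last_tick (last non-missing)
  frames <- vector("list", length(ticks))
  next_id <- 1L

  for (k in seq_along(ticks)) {
    tk <- ticks[k]
    # close tracklets whose gap exceeded max_gap
    if (length(live) > 0) {
      gap <- vapply(live, function(tr) (tk - tr$last_tick) * dt, numeric(1))
      live <- live[gap <= params$max_gap + 1e-12]
    }
    vp <- vid_by_tick[[as.character(tk)]]
    vmat <- if (is.null(vp)) matrix(numeric(0), 0, 3) else
      as.matrix(vp[, c("x", "y", "z")])
    lp <- lid_by_tick[[as.character(tk)]]
    lmat <- if (is.null(lp)) matrix(numeric(0), 0, 3) else
      as.matrix(lp[, c("cx", "cy", "cz")])

    n_tr <- length(live)
    claimed_v <- rep(FALSE, nrow(vmat))
    claimed_l <- rep(FALSE, nrow(lmat))
    ext <- vector("list", n_tr)

    # stage 1: video, global min-cost within the displacement gate.
    # Association cost is measured from a constant-velocity prediction
    # (extrapolated at most 3 ticks) so that crossing animals keep their
    # own tracklets; the gate itself stays anchored at the last known
    # position.
    if (n_tr > 0 && nrow(vmat) > 0) {
      cost <- matrix(Inf, n_tr, nrow(vmat))
      for (i in seq_len(n_tr)) {
        el <- tk - live[[i]]$last_tick
        lim <- params$gate * max(1, el)
        pred <- live[[i]]$pos + live[[i]]$vel * min(el, 3)
        dv <- sqrt(colSums((t(vmat) - live[[i]]$pos)^2))
        dp <- sqrt(colSums((t(vmat) - pred)^2))
        ok <- dv <= lim
        cost[i, ok] <- dp[ok]
      }
      m <- min_cost_assignment(cost)
      for (i in seq_len(n_tr)) if (!is.na(m[i])) {
        ext[[i]] <- list(pos = vmat[m[i], ], source = "video")
        claimed_v[m[i]] <- TRUE
      }
    }
    # stage 2: lidar fallback for still-unmatched tracklets
    un <- which(vapply(ext, is.null, logical(1)))
    if (n_tr > 0 && length(un) > 0 && nrow(lmat) > 0) {
      cost <- matrix(Inf, length(un), nrow(lmat))
      for (a in seq_along(un)) {
        i <- un[a]
        el <- tk - live[[i]]$last_tick
        pred <- live[[i]]$pos + live[[i]]$vel * min(el, 3)
        dl <- sqrt(colSums((t(lmat) - live[[i]]$pos)^2))
        dp <- sqrt(colSums((t(lmat) - pred)^2))
        ok <- dl <= params$switch_gate & !claimed_l
        cost[a, ok] <- dp[ok]
      }
      m <- min_cost_assignment(cost)
      for (a in seq_along(un)) if (!is.na(m[a])) {
        ext[[un[a]]] <- list(pos = lmat[m[a], ], source = "lidar")
        claimed_l[m[a]] <- TRUE
      }
    }

    rows <- list()
    for (i in seq_len(n_tr)) {
      if (!is.null(ext[[i]])) {
        el <- max(1, tk - live[[i]]$last_tick)
        live[[i]]$vel <- (ext[[i]]$pos - live[[i]]$pos) / el
        live[[i]]$pos <- ext[[i]]$pos
        live[[i]]$last_tick <- tk
        rows[[length(rows) + 1]] <- data.frame(
          tick = tk, tracklet_id = live[[i]]$id,
          x = ext[[i]]$pos[1], y = ext[[i]]$pos[2], z = ext[[i]]$pos[3],
          source = ext[[i]]$source)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          tick = tk, tracklet_id = live[[i]]$id,
          x = NA_real_, y = NA_real_, z = NA_real_, source = "missing")
      }
    }
    # contact break: two live tracklets this close are one physical
    # contact event; close both so identity restarts cleanly afterwards
    if (params$contact_break > 0 && length(live) > 1) {
      drop_contact <- rep(FALSE, length(live))
      for (i in seq_len(length(live) - 1))
        for (j2 in seq(i + 1, length(live))) {
          # coasting tracklets count with their last known position: a
          # huddle absorbs several animals into one claimed point while
          # the others coast at the same spot
          if (sqrt(sum((live[[i]]$pos - live[[j2]]$pos)^2)) <
                params$contact_break) {
            drop_contact[i] <- TRUE; drop_contact[j2] <- TRUE
          }
        }
      live <- live[!drop_contact]
    }
    # unclaimed video points open new tracklets
    for (j in which(!claimed_v)) {
      live[[length(live) + 1]] <-
        list(id = next_id, pos = vmat[j, ], vel = c(0, 0, 0),
             last_tick = tk)
      rows[[length(rows) + 1]] <- data.frame(
        tick = tk, tracklet_id = next_id,
        x = vmat[j, 1], y = vmat[j, 2], z = vmat[j, 3], source = "video")
      next_id <- next_id + 1L
    }
    frames[[k]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  out <- do.call(rbind, frames[!vapply(frames, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(tick = integer(0), tracklet_id = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      source = character(0))
  out$t <- out$tick * dt
  out <- out[order(out$tracklet_id, out$tick),
             c("tick", "t", "tracklet_id", "x", "y", "z", "source")]
  # trim trailing missing frames of closed tracklets
  out <- do.call(rbind, lapply(split(out, out$tracklet_id), function(tr) {
    nz <- which(tr$source != "missing")
    if (length(nz) == 0) return(NULL)
    tr[seq_len(max(nz)), , drop = FALSE]
  }))
  rownames(out) <- NULL
  class(out) <- c("fused_tracklets", "data.frame")
  out
}

#' Replace out-of-cage coordinates with missing values
#'
#' Coordinates detected outside the cage volume are treated as missing;
#' the modality that produced them is preserved in a `source_raw` shadow
#' column for diagnostics.
#'
#' @param tracklets A [fuse_tracks()] table (or any tick/x/y/z/source
#'   table).
#' @param cage A [cage_model()].
#' @param tol Slack in mm on every cage face (default 20).
#' @return The table with offending rows set to missing.
#' @export
apply_cage_mask <- function(tracklets, cage, tol = 20) {
  out <- tracklets
  out$source_raw <- out$source
  has_pos <- !is.na(out$x)
  outside <- has_pos & !in_cage(cbind(out$x, out$y, out$z), cage, tol)
  out$x[outside] <- NA_real_
  out$y[outside] <- NA_real_
  out$z[outside] <- NA_real_
  out$source[outside] <- "missing"
  out
}

#' Summarise fused tracklets
#'
#' @param tracklets A [fuse_tracks()] table.
#' @param tick_rate Hz of the tick grid (used for durations).
#' @return List with `n_tracklets`, `mean_duration_s`, and
#'   `source_fraction` (named fractions of frames by modality).
#' @export
tracklet_stats <- function(tracklets, tick_rate = 7.4) {
  if (nrow(tracklets) == 0)
    return(list(n_tracklets = 0L, mean_duration_s = NaN,
                source_fraction = c(video = NaN, lidar = NaN, missing = NaN)))
  by_id <- split(tracklets$tick, tracklets$tracklet_id)
  dur <- vapply(by_id, function(tk) (diff(range(tk)) + 1) / tick_rate,
                numeric(1))
  src <- table(factor(tracklets$source,
                      levels = c("video", "lidar", "missing")))
  frac <- as.numeric(src) / sum(src)
  names(frac) <- names(src)
  list(n_tracklets = length(by_id),
       mean_duration_s = mean(dur),
       source_fraction = frac)
}
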