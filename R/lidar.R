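#' Lidar point-cloud pipeline
#'
#' Foreground extraction and cluster tracking for cage-frame lidar scans.
#' A scan is a data.frame (or matrix) with columns x, y, z in mm; streams
#' carry an additional t column (seconds).  The stages mirror the usual
#' range-sensor tracking recipe: voxel background subtraction learned from
#' animal-free calibration scans, Euclidean cluster extraction with a
#' linking tolerance and body-size gates, and greedy-optimal centroid
#' tracking that issues sequential serial IDs and opens a new ID whenever a
#' trajectory breaks.
#'
#' @name lidar_pipeline
NULL

as_cloud <- function(cloud) {
  if (is.data.frame(cloud)) cloud <- as.matrix(cloud[, c("x", "y", "z")])
  if (length(cloud) == 0) cloud <- matrix(numeric(0), 0, 3)
  cloud <- matrix(as.numeric(cloud), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  if (any(!is.finite(cloud))) stop("point cloud contains non-finite points")
  cloud
}

# numeric voxel key: packs the 3 voxel indices into one double (exact for
# |index| < 2^16, i.e. cages up to ~65 km at 1 mm voxels)
voxel_key <- function(points, voxel_size) {
  idx <- floor(points / voxel_size) + 65536
  (idx[, 1] * 131072 + idx[, 2]) * 131072 + idx[, 3]
}

#' Build a voxel background model from animal-free scans
#'
#' Marks every voxel touched by any calibration scan as background.  The
#' model is a pure function of its inputs: the same scans and voxel size
#' always give the same model.
#'
#' @param scans A list of point clouds (n x 3 matrices or data.frames with
#'   x, y, z in mm) recorded without animals present.
#' @param voxel_size Voxel edge length in mm (default 30).
#' @return An object of class `background_model`.
#' @export
build_background <- function(scans, voxel_size = 30) {
  if (is.data.frame(scans) || is.matrix(scans)) scans <- list(scans)
  if (length(scans) == 0) stop("need at least one animal-free scan")
  stopifnot(voxel_size > 0)
  keys <- unlist(lapply(scans, function(s) {
    s <- as_cloud(s)
    if (nrow(s) == 0) numeric(0) else unique(voxel_key(s, voxel_size))
  }))
  structure(list(voxel_size = voxel_size,
                 occupied = sort(unique(keys))),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %d occupied voxels @ %g mm\n",
              length(x$occupied), x$voxel_size))
  invisible(x)
}

#' Remove background points from a scan
#'
#' @param cloud An n x 3 point matrix or data.frame (mm).
#' @param bg A [build_background()] model in the same cage frame.
#' @return The foreground points (possibly zero rows).
#' @export
remove_background <- function(cloud, bg) {
  pts <- as_cloud(cloud)
  if (nrow(pts) == 0) return(pts)
  keep <- !(voxel_key(pts, bg$voxel_size) %in% bg$occupied)
  pts[keep, , drop = FALSE]
}

#' Cluster-extraction parameters
#'
#' @param tolerance Point-linking distance in mm: two points closer than
#'   this belong to the same cluster (default 50).
#' @param s1 Minimum accepted cluster extent in mm (default 100).
#' @param s2 Maximum accepted cluster extent in mm (default 500).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(tolerance = 50, s1 = 100, s2 = 500) {
  stopifnot(tolerance > 0, s1 > 0, s1 < s2)
  structure(list(tolerance = tolerance, s1 = s1, s2 = s2),
            class = "cluster_params")
}

#' Euclidean cluster extraction with body-size gates
#'
#' Groups foreground points into connected components under the pairwise
#' distance `tolerance` (single linkage through a uniform grid), then keeps
#' the components whose spatial extent — the largest axis-aligned span —
#' lies within `[s1, s2]`.  The centroid (arithmetic mean of member
#' points) is taken as the animal position.
#'
#' @param cloud Foreground points, n x 3 (mm).
#' @param params A [cluster_params()].
#' @return A data.frame with one row per accepted cluster: cluster (index),
#'   cx, cy, cz (centroid mm), extent (mm), n_points, and a `members` list
#'   column of point-row indices into `cloud`.
#' @export
extract_clusters <- function(cloud, params = cluster_params()) {
  pts <- as_cloud(cloud)
  empty <- data.frame(cluster = integer(0), cx = numeric(0), cy = numeric(0),
                      cz = numeric(0), extent = numeric(0),
                      n_points = integer(0))
  empty$members <- list()
  if (nrow(pts) == 0) return(empty)

  labels <- connected_components_tol(pts, params$tolerance)
  out <- list()
  for (comp in split(seq_len(nrow(pts)), labels)) {
    sub <- pts[comp, , drop = FALSE]
    extent <- max(apply(sub, 2, function(v) diff(range(v))))
    if (extent < params$s1 || extent > params$s2) next
    out[[length(out) + 1]] <- list(
      cx = mean(sub[, 1]), cy = mean(sub[, 2]), cz = mean(sub[, 3]),
      extent = extent, n_points = nrow(sub), members = comp)
  }
  if (length(out) == 0) return(empty)
  res <- data.frame(
    cluster = seq_along(out),
    cx = vapply(out, `[[`, numeric(1), "cx"),
    cy = vapply(out, `[[`, numeric(1), "cy"),
    cz = vapply(out, `[[`, numeric(1), "cz"),
    extent = vapply(out, `[[`, numeric(1), "extent"),
    n_points = vapply(out, `[[`, integer(1), "n_points"))
  res$members <- lapply(out, `[[`, "members")
  res
}

# Connected components of the graph linking points within `tolerance`.
# Equivalent to cutting a single-linkage dendrogram at the tolerance (the
# single-linkage merge height is the minimum inter-cluster distance), which
# the vectorised hclust handles quickly up to a few thousand points; larger
# clouds fall back to a grid-bucketed union-find.
connected_components_tol <- function(pts, tolerance) {
  n <- nrow(pts)
  if (n == 1) return(1L)
  if (n <= 600) {   # single-linkage on the full cloud is cheapest here
    hc <- stats::hclust(stats::dist(pts), method = "single")
    return(unname(stats::cutree(hc, h = tolerance)))
  }
  # coarse prepartition: points in grid cells more than one cell apart
  # (Chebyshev) are farther than the tolerance, so the exact
  # single-linkage pass only runs within each coarse group
  cell <- floor(pts / tolerance)
  key <- (cell[, 1] + 65536) * 131072 + (cell[, 2] + 65536)
  key <- key * 131072 + (cell[, 3] + 65536)
  ucells <- unique(cell)
  cgroup <- coarse_cell_groups(ucells)
  ukey <- (ucells[, 1] + 65536) * 131072 + (ucells[, 2] + 65536)
  ukey <- ukey * 131072 + (ucells[, 3] + 65536)
  pt_coarse <- cgroup[match(key, ukey)]

  labels <- integer(n)
  offset <- 0L
  for (g in unique(pt_coarse)) {
    ix <- which(pt_coarse == g)
    if (length(ix) == 1) {
      labels[ix] <- offset + 1L
      offset <- offset + 1L
    } else if (length(ix) <= 3000) {
      hc <- stats::hclust(stats::dist(pts[ix, , drop = FALSE]),
                          method = "single")
      sub <- unname(stats::cutree(hc, h = tolerance))
      labels[ix] <- offset + sub
      offset <- offset + max(sub)
    } else {
      sub <- grid_connected_components(pts[ix, , drop = FALSE], tolerance)
      labels[ix] <- offset + sub
      offset <- offset + max(sub)
    }
  }
  match(labels, unique(labels))
}

# union of occupied grid cells within Chebyshev distance 1, by matching
# each cell's 27 neighbour keys against the occupied-key set
coarse_cell_groups <- function(cells) {
  m <- nrow(cells)
  if (m == 1) return(1L)
  enc <- function(cc)
    ((cc[, 1] + 65536) * 131072 + (cc[, 2] + 65536)) * 131072 +
      (cc[, 3] + 65536)
  keys <- enc(cells)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    if (all(off == 0)) next
    nb <- match(enc(sweep(cells, 2, off, "+")), keys)
    for (i in which(!is.na(nb))) {
      ri <- find(i); rj <- find(nb[i])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

# Single-linkage connected components under a distance tolerance, using a
# uniform grid with cell edge = tolerance so only the 27 neighbouring cells
# need pairwise checks; union-find with path halving.
grid_connected_components <- function(pts, tolerance) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  cell <- floor(pts / tolerance)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  cell_of <- lapply(buckets, function(ix) cell[ix[1], ])
  tol2 <- tolerance^2
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (b in seq_along(buckets)) {
    ix <- buckets[[b]]
    # intra-cell links: all points in one cell of edge = tolerance are not
    # automatically within tolerance (cell diagonal > tolerance), so check
    if (length(ix) > 1) {
      d2 <- as.matrix(stats::dist(pts[ix, , drop = FALSE]))^2
      for (a in seq_along(ix))
        for (c in seq_len(a - 1L))
          if (d2[a, c] <= tol2) unite(ix[a], ix[c])
    }
    base <- cell_of[[b]]
    for (o in seq_len(nrow(offsets))) {
      off <- offsets[o, ]
      if (all(off == 0) ||
          off[1] < 0 || (off[1] == 0 && (off[2] < 0 || (off[2] == 0 && off[3] <= 0))))
        next  # visit each unordered cell pair once
      nb_key <- paste(base[1] + off[1], base[2] + off[2], base[3] + off[3])
      jx <- buckets[[nb_key]]
      if (is.null(jx)) next
      for (a in ix) for (c in jx) {
        if (sum((pts[a, ] - pts[c, ])^2) <= tol2) unite(a, c)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Track clusters across scans with sequential serial IDs
#'
#' Extends live tracks by a one-to-one assignment between track heads and
#' current cluster centroids that minimises the total matched distance,
#' with matches beyond `gate` forbidden.  Unmatched clusters open new
#' tracks carrying the next serial number — a trajectory that breaks is
#' never resumed under its old ID.  Tracks unseen for more than
#' `dropout` seconds are closed.
#'
#' @param state Tracker state from a previous call, or `NULL` to start.
#' @param clusters Cluster table from [extract_clusters()] (only cx, cy,
#'   cz are used), all at one timestamp.
#' @param t Scan timestamp (s).
#' @param gate Maximum matching distance in mm (default 300).
#' @param dropout Seconds without a match before a track closes (default 1).
#' @return Updated tracker state: a list with `tracks` (data.frame t,
#'   serial_id, cx, cy, cz), `live` bookkeeping and `next_id`.
#' @export
track_clusters <- function(state, clusters, t, gate = 300, dropout = 1) {
  if (is.null(state))
    state <- list(tracks = data.frame(t = numeric(0), serial_id = integer(0),
                                      cx = numeric(0), cy = numeric(0),
                                      cz = numeric(0)),
                  live = list(), next_id = 1L)
  cen <- if (nrow(clusters) == 0) matrix(numeric(0), 0, 3) else
    as.matrix(clusters[, c("cx", "cy", "cz")])

  # close stale tracks
  if (length(state$live) > 0) {
    stale <- vapply(state$live, function(tr) t - tr$last_t > dropout,
                    logical(1))
    state$live <- state$live[!stale]
  }

  n_tr <- length(state$live); n_cl <- nrow(cen)
  assign_tr <- rep(NA_integer_, n_cl)
  if (n_tr > 0 && n_cl > 0) {
    cost <- matrix(Inf, n_tr, n_cl)
    for (i in seq_len(n_tr))
      cost[i, ] <- sqrt(colSums((t(cen) - state$live[[i]]$pos)^2))
    cost[cost > gate] <- Inf
    m <- min_cost_assignment(cost)
    for (i in seq_len(n_tr))
      if (!is.na(m[i])) assign_tr[m[i]] <- i
  }

  new_rows <- vector("list", n_cl)
  for (j in seq_len(n_cl)) {
    if (!is.na(assign_tr[j])) {
      tr <- state$live[[assign_tr[j]]]
      tr$pos <- cen[j, ]; tr$last_t <- t
      state$live[[assign_tr[j]]] <- tr
      sid <- tr$serial_id
    } else {
      sid <- state$next_id
      state$next_id <- state$next_id + 1L
      state$live[[length(state$live) + 1]] <-
        list(serial_id = sid, pos = cen[j, ], last_t = t)
    }
    new_rows[[j]] <- data.frame(t = t, serial_id = sid, cx = cen[j, 1],
                                cy = cen[j, 2], cz = cen[j, 3])
  }
  if (n_cl > 0) {
    state$tracks <- rbind(state$tracks, do.call(rbind, new_rows))
    rownames(state$tracks) <- NULL
  }
  state
}

#' Run the cluster tracker over a scan stream
#'
#' @param clouds List of foreground clouds, one per scan.
#' @param times Numeric vector of scan timestamps, parallel to `clouds`.
#' @param params A [cluster_params()].
#' @param gate,dropout Passed to [track_clusters()].
#' @return The final tracker state; `$tracks` holds the full track table.
#' @export
track_stream <- function(clouds, times, params = cluster_params(),
                         gate = 300, dropout = 1) {
  stopifnot(length(clouds) == length(times))
  state <- NULL
  for (k in seq_along(clouds)) {
    cl <- extract_clusters(clouds[[k]], params)
    state <- track_clusters(state, cl, times[k], gate = gate,
                            dropout = dropout)
  }
  state
}

# Minimum-total-cost one-to-one assignment of rows to columns with Inf
# meaning forbidden.  Exhaustive over the smaller side when feasible
# (tracking a handful of animals), greedy otherwise; returns, per row, the
# assigned column or NA.
min_cost_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0) return(integer(0))
  if (n <= 9 && m <= 12) {
    # branch and bound over injective partial maps; skipping a row costs
    # SKIP >> any geometric distance, so matches are maximised first
    SKIP <- 1e9
    best <- rep(NA_integer_, n); best_cost <- Inf
    cols <- seq_len(m)
    rec <- function(i, used, cur, acc) {
      if (acc >= best_cost) return(invisible())
      if (i > n) {
        best <<- cur; best_cost <<- acc
        return(invisible())
      }
      feas <- cols[!used & is.finite(cost[i, ])]
      for (j in feas[order(cost[i, feas])]) {
        used[j] <- TRUE
        rec(i + 1, used, c(cur, j), acc + cost[i, j])
        used[j] <- FALSE
      }
      rec(i + 1, used, c(cur, NA_integer_), acc + SKIP)
    }
    rec(1L, rep(FALSE, m), integer(0), 0)
    return(best)
  }
  # greedy fallback: repeatedly take the globally cheapest feasible pair
  out <- rep(NA_integer_, n)
  cost <- cost  # local copy
  repeat {
    k <- which.min(cost)
    if (length(k) == 0 || !is.finite(cost[k])) break
    i <- (k - 1) %% n + 1; j <- (k - 1) %/% n + 1
    out[i] <- j
    cost[i, ] <- Inf; cost[, j] <- Inf
  }
  out
}
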