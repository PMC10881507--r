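#' Trajectory analytics
#'
#' Zone occupancy, place-preference grids and inter-individual distance
#' statistics over identified trajectories.  Zones are named axis-aligned
#' boxes in the cage frame; any point not in a named zone falls in the
#' implicit "other" complement.  All reported percentages are rounded
#' half-up to one decimal, matching ethology-table conventions.
#'
#' @name analytics
NULL

#' Define a zone layout
#'
#' @param zones A named list; each element is a list with `min` and `max`
#'   length-3 corners (mm).  Named zones must not overlap.
#' @param cage A [cage_model()] the zones must fit inside.
#' @return A list of class `zone_layout` (the "other" complement is
#'   implicit).
#' @export
zone_layout <- function(zones, cage = cage_model()) {
  for (nm in names(zones)) {
    z <- zones[[nm]]
    stopifnot(length(z$min) == 3, length(z$max) == 3, all(z$max > z$min))
    if (any(z$min < -1e-9) ||
        any(z$max > c(cage$width, cage$depth, cage$height) + 1e-9))
      stop(sprintf("zone '%s' extends outside the cage", nm))
  }
  nms <- names(zones)
  for (i in seq_along(zones)) for (j in seq_len(i - 1)) {
    a <- zones[[i]]; b <- zones[[j]]
    if (all(a$min < b$max - 1e-9) && all(b$min < a$max - 1e-9))
      stop(sprintf("zones '%s' and '%s' overlap", nms[i], nms[j]))
  }
  structure(list(zones = zones, cage = cage), class = "zone_layout")
}

#' Default five-zone layout of the family cage
#'
#' Four named zones — upper bed, middle floor, lower bed, lower floor —
#' plus the implicit "other" remainder.  The beds are back-half platforms;
#' the floors span the full footprint of their height band.
#'
#' @param cage A [cage_model()].
#' @return A [zone_layout()].
#' @export
default_zones <- function(cage = cage_model()) {
  W <- cage$width; D <- cage$depth; H <- cage$height
  zone_layout(list(
    lower_floor  = list(min = c(0, 0, 0),           max = c(W, D, 150)),
    lower_bed    = list(min = c(0, D / 2, 150),     max = c(W, D, 650)),
    middle_floor = list(min = c(0, 0, 650),         max = c(W, D, 1100)),
    upper_bed    = list(min = c(0, D / 2, 1100),    max = c(W, D, H))),
    cage)
}

#' Classify points into zones
#'
#' @param points n x 3 matrix (mm).
#' @param layout A [zone_layout()].
#' @return Character vector of zone names ("other" when in no named zone,
#'   NA for NA points).
#' @export
zone_of <- function(points, layout) {
  p <- to_points3(points)
  out <- rep("other", nrow(p))
  out[is.na(p[, 1])] <- NA_character_
  for (nm in names(layout$zones)) {
    z <- layout$zones[[nm]]
    hit <- !is.na(p[, 1]) &
      p[, 1] >= z$min[1] & p[, 1] < z$max[1] &
      p[, 2] >= z$min[2] & p[, 2] < z$max[2] &
      p[, 3] >= z$min[3] & p[, 3] < z$max[3]
    out[hit & out == "other"] <- nm
  }
  out
}

#' Zone occupancy of one trajectory
#'
#' Per-tick zone membership by point-in-box; ticks with a missing position
#' are excluded from the denominator.
#'
#' @param track Data.frame with x, y, z per tick (NA = missing).
#' @param layout A [zone_layout()].
#' @return Data.frame: zone, frames, percent (half-up, one decimal), plus
#'   attribute `valid_frames`.
#' @export
zone_occupancy <- function(track, layout) {
  zn <- zone_of(as.matrix(track[, c("x", "y", "z")]), layout)
  zn <- zn[!is.na(zn)]
  lev <- c(names(layout$zones), "other")
  counts <- table(factor(zn, levels = lev))
  out <- data.frame(zone = lev, frames = as.integer(counts))
  out$percent <- if (length(zn) > 0)
    percent_round(100 * out$frames / length(zn)) else NaN
  attr(out, "valid_frames") <- length(zn)
  out
}

#' Pairwise inter-individual distances per tick
#'
#' Euclidean 3D distance for every unordered pair on the common tick
#' grid; a tick yields a record only when both positions are non-missing
#' (which is why different pairs have different denominators).
#'
#' @param tracks Named list of per-individual trajectories (data.frames
#'   with tick, x, y, z on a common grid).
#' @return Data.frame: id_a, id_b, tick, distance.
#' @export
pairwise_distances <- function(tracks) {
  ids <- names(tracks)
  stopifnot(length(ids) >= 2)
  out <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    a <- tracks[[ids[j]]]; b <- tracks[[ids[i]]]
    m <- match(a$tick, b$tick)
    ok <- !is.na(m) & !is.na(a$x) & !is.na(b$x[m])
    if (!any(ok)) next
    out[[length(out) + 1]] <- data.frame(
      id_a = ids[j], id_b = ids[i], tick = a$tick[ok],
      distance = sqrt((a$x[ok] - b$x[m][ok])^2 +
                        (a$y[ok] - b$y[m][ok])^2 +
                        (a$z[ok] - b$z[m][ok])^2))
  }
  if (length(out) == 0)
    return(data.frame(id_a = character(0), id_b = character(0),
                      tick = integer(0), distance = numeric(0)))
  do.call(rbind, out)
}

#' Close/middle/far fractions of a pair's distance records
#'
#' @param distance Numeric vector of per-tick distances (mm) for one pair.
#' @param thresholds Length-2 (low, high) in mm, default 500 and 1000.
#' @return List with counts and half-up one-decimal percentages:
#'   `lt_low`, `mid`, `gt_high`, `n`.
#' @export
distance_fractions <- function(distance, thresholds = c(500, 1000)) {
  d <- distance[!is.na(distance)]
  if (length(d) == 0) stop("no valid distance records")
  n <- length(d)
  lo <- sum(d < thresholds[1]); hi <- sum(d > thresholds[2])
  list(n = n,
       n_lt_low = lo, n_mid = n - lo - hi, n_gt_high = hi,
       lt_low = percent_round(100 * lo / n),
       mid = percent_round(100 * (n - lo - hi) / n),
       gt_high = percent_round(100 * hi / n))
}

#' Place-preference occupancy grid
#'
#' Cubic-cell dwell-fraction histogram of a trajectory, with a display cap
#' flagging cells where the animal spent more than `cap` of the valid
#' time.
#'
#' @param track Data.frame with x, y, z (NA = missing).
#' @param cage A [cage_model()].
#' @param cell Cell edge in mm (default 100).
#' @param cap Saturation fraction (default 0.01, i.e. 1 percent of the
#'   record).
#' @return Data.frame: ix, iy, iz (cell indices), fraction, saturated.
#' @export
place_preference_grid <- function(track, cage = cage_model(), cell = 100,
                                  cap = 0.01) {
  stopifnot(cell > 0)
  p <- as.matrix(track[, c("x", "y", "z")])
  p <- p[!is.na(p[, 1]), , drop = FALSE]
  if (nrow(p) == 0)
    return(data.frame(ix = integer(0), iy = integer(0), iz = integer(0),
                      fraction = numeric(0), saturated = logical(0)))
  idx <- floor(p / cell)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  counts <- table(key)
  parts <- do.call(rbind, strsplit(names(counts), " "))
  out <- data.frame(ix = as.integer(parts[, 1]), iy = as.integer(parts[, 2]),
                    iz = as.integer(parts[, 3]),
                    fraction = as.numeric(counts) / nrow(p))
  out$saturated <- out$fraction > cap
  out[order(-out$fraction), ]
}

#' Compare system and observer occupancy summaries
#'
#' Pearson correlation over the paired per-zone, per-individual occupancy
#' percentages — the standard human-vs-system agreement check.
#'
#' @param system,human Numeric vectors of paired percentages (same zones
#'   and individuals, same order), or data.frames with a `percent` column.
#' @return List with `r`, `r_squared`, `n`, `p_value` and the paired table.
#' @export
compare_to_observer <- function(system, human) {
  s <- if (is.data.frame(system)) system$percent else as.numeric(system)
  h <- if (is.data.frame(human)) human$percent else as.numeric(human)
  stopifnot(length(s) == length(h))
  if (length(s) < 3) stop("need at least 3 paired values")
  ct <- stats::cor.test(s, h, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       n = length(s), p_value = ct$p.value,
       pairs = data.frame(system = s, human = h))
}
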