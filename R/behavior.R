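#' Grooming-bout detection
#'
#' A per-frame behavior detector (the same object detector that finds
#' bodies also fires on grooming postures) yields a 0/1 detection series
#' per camera.  To suppress frame-level noise the series is smoothed with
#' a Gaussian-weighted moving average over a 50 s window evaluated every
#' 5 s, the two top-camera series are averaged, and maximal runs above a
#' threshold become grooming bouts.  Bouts are attributed to the (at most
#' two) individuals nearest the grooming location, and detector-vs-human
#' agreement is scored on 30-second units.
#'
#' @name behavior
NULL

#' Smoothing parameters for behavior detection series
#'
#' @param window Moving-average window in seconds (default 50).
#' @param slide Evaluation step in seconds (default 5).
#' @param sigma Gaussian width in seconds; default `window / 6` puts
#'   essentially all kernel mass inside the window.
#' @param threshold Bout threshold on the averaged frequency (default 0.5).
#' @return A list of class `smooth_params`.
#' @export
smooth_params <- function(window = 50, slide = 5, sigma = window / 6,
                          threshold = 0.5) {
  stopifnot(window > slide, slide > 0, sigma > 0,
            threshold > 0, threshold < 1)
  structure(list(window = window, slide = slide, sigma = sigma,
                 threshold = threshold),
            class = "smooth_params")
}

#' Gaussian-weighted moving average of a detection series
#'
#' At each slide point the per-tick detection values inside the centred
#' window are averaged with Gaussian weights (normalised, so a constant
#' series is reproduced exactly).
#'
#' @param t Tick times, seconds, on a uniform grid.
#' @param value Detection value per tick (0/1 indicator or count).
#' @param p A [smooth_params()].
#' @return Data.frame with `t` (slide-grid times) and `value` (smoothed
#'   frequency).
#' @export
smooth_series <- function(t, value, p = smooth_params()) {
  stopifnot(length(t) == length(value), length(t) > 0)
  if (length(t) > 1) {
    dts <- diff(t)
    if (max(dts) - min(dts) > 1e-6)
      stop("detection series must be on a uniform tick grid")
  }
  grid <- seq(min(t), max(t), by = p$slide)
  half <- p$window / 2
  out <- vapply(grid, function(s) {
    sel <- abs(t - s) <= half + 1e-9
    if (!any(sel)) return(NA_real_)
    w <- exp(-((t[sel] - s)^2) / (2 * p$sigma^2))
    sum(w * value[sel]) / sum(w)
  }, numeric(1))
  data.frame(t = grid, value = out)
}

#' Average the smoothed series of two cameras
#'
#' @param left,right Data.frames from [smooth_series()] on the same slide
#'   grid.
#' @return Data.frame with the pointwise mean.
#' @export
combine_cameras <- function(left, right) {
  if (nrow(left) != nrow(right) || any(abs(left$t - right$t) > 1e-9))
    stop("camera series are on different slide grids")
  data.frame(t = left$t, value = (left$value + right$value) / 2)
}

#' Extract bouts from a smoothed probability series
#'
#' Maximal runs of slide points with value strictly above the threshold
#' become bouts; each slide point contributes a `slide`-second interval
#' centred on it, and runs separated by less than one slide step merge.
#'
#' @param series Data.frame (t, value) on the slide grid.
#' @param threshold Bout threshold.
#' @param slide Slide step in seconds; inferred from the grid if omitted.
#' @return Data.frame of bouts: start, end (seconds).
#' @export
extract_bouts <- function(series, threshold = 0.5, slide = NULL) {
  if (is.null(slide))
    slide <- if (nrow(series) > 1) series$t[2] - series$t[1] else 1
  above <- !is.na(series$value) & series$value > threshold
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  bouts <- data.frame(
    start = series$t[starts[runs]] - slide / 2,
    end = series$t[ends[runs]] + slide / 2)
  # merge bouts separated by less than one slide step
  if (nrow(bouts) > 1) {
    keep <- list(bouts[1, ])
    for (i in 2:nrow(bouts)) {
      last <- keep[[length(keep)]]
      if (bouts$start[i] - last$end < slide - 1e-9) {
        last$end <- bouts$end[i]
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1]] <- bouts[i, ]
    }
    bouts <- do.call(rbind, keep)
  }
  rownames(bouts) <- NULL
  bouts
}

#' Attribute a bout to the individuals nearest the grooming location
#'
#' The at most two individuals whose median distance to the grooming
#' location during the bout is smallest (and within `gate`) are named as
#' participants.
#'
#' @param bout A list or one-row data.frame with `start`, `end` (s).
#' @param identified A [link_identities()] table.
#' @param location Length-3 grooming location (mm).
#' @param gate Proximity gate in mm (default 300).
#' @return Character vector of 0--2 individual ids; zero-length (with a
#'   warning) when nobody is within the gate.
#' @export
attribute_bout <- function(bout, identified, location, gate = 300) {
  sel <- identified[!is.na(identified$individual_id) &
                      !is.na(identified$x) &
                      identified$t >= bout$start - 1e-9 &
                      identified$t <= bout$end + 1e-9, , drop = FALSE]
  if (nrow(sel) == 0) {
    warning("no identified individual present during bout")
    return(character(0))
  }
  d <- sqrt((sel$x - location[1])^2 + (sel$y - location[2])^2 +
              (sel$z - location[3])^2)
  med <- tapply(d, sel$individual_id, stats::median)
  med <- sort(med[med <= gate])
  if (length(med) == 0) {
    warning("no identified individual within gate during bout")
    return(character(0))
  }
  names(med)[seq_len(min(2, length(med)))]
}

#' Score machine bouts against reference bouts on fixed time units
#'
#' The horizon is partitioned into `unit`-second units; a unit is positive
#' for a source if any of its bouts overlaps the unit.  Recall is the
#' fraction of reference-positive units also machine-positive; precision
#' the fraction of machine-positive units also reference-positive.
#'
#' @param machine,truth Bout data.frames (start, end in seconds).
#' @param horizon Evaluation horizon in seconds.
#' @param unit Unit length in seconds (default 30).
#' @return List with `recall`, `precision` (percent; `NaN` when the
#'   denominator is zero), `n_truth_units`, `n_machine_units`,
#'   `n_overlap_units`, and the per-unit logical table.
#' @export
evaluate_units <- function(machine, truth, horizon, unit = 30) {
  starts <- seq(0, horizon - 1e-9, by = unit)
  unit_hit <- function(bouts, s, e)
    nrow(bouts) > 0 && any(bouts$start < e - 1e-9 & bouts$end > s + 1e-9)
  tab <- data.frame(
    unit_start = starts,
    machine = vapply(starts, function(s)
      unit_hit(machine, s, s + unit), logical(1)),
    truth = vapply(starts, function(s)
      unit_hit(truth, s, s + unit), logical(1)))
  n_t <- sum(tab$truth); n_m <- sum(tab$machine)
  n_o <- sum(tab$truth & tab$machine)
  list(recall = if (n_t > 0) 100 * n_o / n_t else NaN,
       precision = if (n_m > 0) 100 * n_o / n_m else NaN,
       n_truth_units = n_t, n_machine_units = n_m, n_overlap_units = n_o,
       units = tab)
}

#' Full grooming detection pass over two camera series
#'
#' Smooths each camera's per-tick grooming indicator, averages the two,
#' thresholds into bouts and (optionally) attributes each bout.
#'
#' @param t Tick times (uniform grid, seconds).
#' @param left,right Per-tick grooming-detection indicators of the two top
#'   cameras.
#' @param p A [smooth_params()].
#' @param identified Optional [link_identities()] table for attribution.
#' @param locate Optional function(bout) returning the grooming location
#'   (mm); defaults to the midpoint of the attributed participants and is
#'   only consulted when `identified` is given.
#' @return List with `series` (averaged smoothed series) and `bouts`
#'   (start, end, and participants when attributed).
#' @export
detect_grooming <- function(t, left, right, p = smooth_params(),
                            identified = NULL, locate = NULL) {
  s <- combine_cameras(smooth_series(t, left, p), smooth_series(t, right, p))
  bouts <- extract_bouts(s, p$threshold, p$slide)
  if (!is.null(identified) && nrow(bouts) > 0) {
    parts <- vector("list", nrow(bouts))
    for (i in seq_len(nrow(bouts))) {
      loc <- if (!is.null(locate)) locate(bouts[i, ]) else
        bout_location(bouts[i, ], identified)
      parts[[i]] <- if (is.null(loc)) character(0) else
        suppressWarnings(attribute_bout(bouts[i, ], identified, loc))
    }
    bouts$participants <- vapply(parts, paste, character(1), collapse = "+")
  }
  list(series = s, bouts = bouts)
}

# fallback grooming location: median position of the two closest-together
# identified individuals during the bout
bout_location <- function(bout, identified) {
  sel <- identified[!is.na(identified$individual_id) &
                      !is.na(identified$x) &
                      identified$t >= bout$start & identified$t <= bout$end, ,
                    drop = FALSE]
  if (nrow(sel) == 0) return(NULL)
  apply(sel[, c("x", "y", "z")], 2, stats::median)
}
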