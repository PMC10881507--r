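#' Identity assignment and recognition metrics
#'
#' Anonymous tracklets become individually identified trajectories through
#' intermittent face-recognition events: each event carries a timestamp, a
#' 3D position, a predicted individual and a confidence.  Events attach to
#' the nearest tracklet, tracklets take a confidence-weighted majority
#' vote, and per-tick conflicts between tracklets claiming the same
#' individual are resolved in favour of the stronger vote.  The module
#' also provides the one-vs-rest classification metrics used to evaluate
#' face classifiers and an ID-switch report against ground-truth labels.
#'
#' @name identity
NULL

#' Link face-recognition events to tracklets
#'
#' @param tracklets A [fuse_tracks()] table.
#' @param face_obs Data.frame of face events: t, x, y, z, predicted_id,
#'   confidence.  Events labelled "unknown" (the reject class of the face
#'   classifier) or below `min_confidence` are discarded before voting.
#' @param match_gate Maximum distance (mm) between an event and a tracklet
#'   position for attachment (default 300).
#' @param tick_rate Hz of the tick grid.
#' @param vote `"window"` (default): the vote is recomputed per tick over
#'   events within `window` seconds of the tick, falling back to the
#'   whole-tracklet vote for ticks with no nearby events — a long tracklet
#'   can recover its label as soon as a face is seen again after a huddle
#'   or crossing.  `"tracklet"`: one confidence-weighted majority vote for
#'   the whole tracklet.
#' @param window Vote window in seconds for `vote = "window"` (default 60).
#' @param min_confidence Confidence floor for events (default 0).
#' @return A data.frame of class `identified_trajectories`: tick, t,
#'   tracklet_id, individual_id (NA when unidentified), x, y, z, source.
#' @export
link_identities <- function(tracklets, face_obs, match_gate = 300,
                            tick_rate = 7.4, vote = c("window", "tracklet"),
                            window = 60, min_confidence = 0) {
  vote <- match.arg(vote)
  out <- tracklets
  out$individual_id <- NA_character_
  if (nrow(out) == 0 || is.null(face_obs) || nrow(face_obs) == 0) {
    class(out) <- c("identified_trajectories", "data.frame")
    return(out)
  }
  obs <- face_obs[!is.na(face_obs$predicted_id) &
                    face_obs$predicted_id != "unknown" &
                    face_obs$confidence >= min_confidence, , drop = FALSE]

  # attach each event to the nearest tracklet position at its tick
  pos <- out[!is.na(out$x), , drop = FALSE]
  if (nrow(obs) > 0 && nrow(pos) > 0) {
    obs$tick <- as.integer(round(obs$t * tick_rate))
    att_tracklet <- rep(NA_integer_, nrow(obs))
    pos_by_tick <- split(seq_len(nrow(pos)), pos$tick)
    for (e in seq_len(nrow(obs))) {
      ix <- pos_by_tick[[as.character(obs$tick[e])]]
      if (is.null(ix)) next
      d <- sqrt((pos$x[ix] - obs$x[e])^2 + (pos$y[ix] - obs$y[e])^2 +
                  (pos$z[ix] - obs$z[e])^2)
      j <- which.min(d)
      if (d[j] > match_gate) next
      att_tracklet[e] <- pos$tracklet_id[ix[j]]
      # ambiguous attachment: when a second tracklet is almost as close
      # (typically two animals in contact) the vote still counts, but
      # discounted by how cleanly the nearest wins
      if (length(d) > 1) {
        d2 <- min(d[-j])
        if (d2 <= match_gate)
          obs$confidence[e] <- obs$confidence[e] *
            (d2 - d[j]) / (d2 - d[j] + 100)
      }
    }
    obs$tracklet_id <- att_tracklet
    obs <- obs[!is.na(obs$tracklet_id), , drop = FALSE]
  } else obs <- obs[0, , drop = FALSE]

  weighted_winner <- function(ids, w) {
    if (length(ids) == 0) return(NA_character_)
    s <- tapply(w, ids, sum)
    top <- names(s)[s == max(s)]
    if (length(top) != 1) NA_character_ else top  # ties -> unidentified
  }

  if (nrow(obs) > 0) {
    votes_by_tr <- split(obs, obs$tracklet_id)
    tr_label <- vapply(votes_by_tr, function(o)
      weighted_winner(o$predicted_id, o$confidence), character(1))
    tr_weight <- vapply(votes_by_tr, function(o) {
      s <- tapply(o$confidence, o$predicted_id, sum)
      max(s)
    }, numeric(1))
    lab <- tr_label[as.character(out$tracklet_id)]
    out$individual_id <- unname(lab)
    if (vote == "window") {
      # per-frame vote over events within the window; frames with no
      # nearby events take the single nearest attached event in time, so
      # a tracklet that drifts between animals cannot poison its distant
      # frames through a global majority
      for (tid in names(votes_by_tr)) {
        o <- votes_by_tr[[tid]]
        rows <- which(out$tracklet_id == as.integer(tid))
        for (r in rows) {
          dt_obs <- abs(o$t - out$t[r])
          near <- dt_obs <= window / 2
          w <- if (any(near))
            weighted_winner(o$predicted_id[near], o$confidence[near])
          else o$predicted_id[which.min(dt_obs)]
          if (!is.na(w)) out$individual_id[r] <- w
        }
      }
    }
    # per-tick conflicts: the tracklet with the larger vote weight keeps
    # the individual, the other reverts to unidentified
    w_of <- function(tid) tr_weight[as.character(tid)]
    for (tk in unique(out$tick)) {
      rows <- which(out$tick == tk & !is.na(out$individual_id))
      if (length(rows) < 2) next
      for (id in unique(out$individual_id[rows])) {
        claim <- rows[out$individual_id[rows] == id]
        if (length(claim) < 2) next
        keep <- claim[which.max(vapply(out$tracklet_id[claim], w_of,
                                       numeric(1)))]
        out$individual_id[setdiff(claim, keep)] <- NA_character_
      }
    }
  }
  class(out) <- c("identified_trajectories", "data.frame")
  out
}

#' Extract one individual's trajectory on the full tick grid
#'
#' @param identified A [link_identities()] table.
#' @param individual_id Individual label.
#' @param ticks Tick grid to cover; missing ticks yield NA positions.
#' @return Data.frame tick, x, y, z (NA where the individual was not
#'   tracked).
#' @export
individual_track <- function(identified, individual_id, ticks) {
  sel <- identified[!is.na(identified$individual_id) &
                      identified$individual_id == individual_id &
                      !is.na(identified$x), , drop = FALSE]
  sel <- sel[!duplicated(sel$tick), ]
  m <- match(ticks, sel$tick)
  data.frame(tick = ticks, x = sel$x[m], y = sel$y[m], z = sel$z[m])
}

#' One-vs-rest classification metrics from confusion counts
#'
#' Computes, per class, specificity TN/(TN+FP), accuracy
#' (TP+TN)/(TP+FP+FN+TN), recall TP/(TP+FN), precision TP/(TP+FP) and the
#' F-measure 2PR/(P+R).  Metrics with a zero denominator are `NaN`.
#'
#' @param confusion Data.frame with columns class, tp, fp, fn, tn (one row
#'   per class, one-vs-rest counts over a fixed evaluation set).
#' @return Data.frame of per-class metrics in percent (not rounded; use
#'   [percent_round()] for one-decimal table reporting).
#' @export
classification_metrics <- function(confusion) {
  stopifnot(all(c("class", "tp", "fp", "fn", "tn") %in% names(confusion)))
  with(confusion, {
    safe <- function(num, den) ifelse(den > 0, num / den, NaN)
    recall <- safe(tp, tp + fn)
    precision <- safe(tp, tp + fp)
    data.frame(
      class = class,
      specificity = 100 * safe(tn, tn + fp),
      accuracy = 100 * safe(tp + tn, tp + fp + fn + tn),
      recall = 100 * recall,
      precision = 100 * precision,
      f_measure = 100 * ifelse(precision + recall > 0,
                               2 * precision * recall / (precision + recall),
                               NaN))
  })
}

#' F-measure from precision and recall in percent
#'
#' @param precision,recall Percentages.
#' @return The harmonic mean, percent.
#' @export
f_measure <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' Overall identification accuracy
#'
#' Total correct over total evaluated, in percent: the headline
#' "correct images / all images" number of a multi-class evaluation.
#'
#' @param correct Per-class counts of correctly classified items.
#' @param total Per-class totals.
#' @return Percent (not rounded).
#' @export
overall_accuracy <- function(correct, total) {
  stopifnot(length(correct) == length(total), all(total > 0),
            all(correct <= total))
  100 * sum(correct) / sum(total)
}

#' Round percentages half-up to one decimal
#'
#' Table-style reporting rounds 0.05 upward (base `round()` rounds to
#' even).
#'
#' @param x Percent values.
#' @param digits Decimal places (default 1).
#' @return Rounded values.
#' @export
percent_round <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Report identity-switch statistics against ground truth
#'
#' Compares estimated per-tick identities with ground-truth trajectories.
#' Each estimated position is matched to the nearest true individual
#' within `match_gate`; a tick of a true individual is "wrong" when the
#' estimate tracking it carries a different label.  Wrong runs shorter
#' than `min_duration` are ignored (brief flickers), matching the usual
#' scoring of sustained identity switches.
#'
#' @param identified A [link_identities()] table.
#' @param truth Data.frame of true trajectories: tick, individual_id, x,
#'   y, z.
#' @param tick_rate Hz.
#' @param min_duration Minimum wrong-run length in seconds to count
#'   (default 5).
#' @param match_gate Estimate-to-truth matching distance, mm (default 300).
#' @return List: `n_switches` (wrong runs >= min_duration),
#'   `wrong_id_fraction` (wrong time from counted runs, summed over
#'   individuals, over the record duration), `max_correct_streak_s`,
#'   `correct_tick_fraction` (correct labelled ticks / truth ticks).
#' @export
id_switch_report <- function(identified, truth, tick_rate = 7.4,
                             min_duration = 5, match_gate = 300) {
  est <- identified[!is.na(identified$x), , drop = FALSE]
  ticks <- sort(unique(truth$tick))
  if (length(ticks) == 0) stop("empty ground truth")
  dt <- 1 / tick_rate
  horizon <- (diff(range(ticks)) + 1) * dt
  inds <- sort(unique(truth$individual_id))

  est_by_tick <- split(est, est$tick)
  # status[tick, individual]: "correct", "wrong", or "untracked";
  # estimates and truths are paired one-to-one by minimum total distance
  # within the gate, the standard multi-object matching, so that one
  # estimate cannot stand in for two co-located animals
  status <- matrix("untracked", length(ticks), length(inds),
                   dimnames = list(NULL, inds))
  tr_by_tick <- split(truth, truth$tick)
  for (k in seq_along(ticks)) {
    tru <- tr_by_tick[[as.character(ticks[k])]]
    e <- est_by_tick[[as.character(ticks[k])]]
    if (is.null(e) || is.null(tru)) next
    tru <- tru[!is.na(tru$x), , drop = FALSE]
    if (nrow(tru) == 0) next
    cost <- matrix(Inf, nrow(tru), nrow(e))
    for (r in seq_len(nrow(tru))) {
      d <- sqrt((e$x - tru$x[r])^2 + (e$y - tru$y[r])^2 +
                  (e$z - tru$z[r])^2)
      cost[r, d <= match_gate] <- d[d <= match_gate]
    }
    m <- min_cost_assignment(cost)
    for (r in seq_len(nrow(tru))) {
      if (is.na(m[r])) next
      lab <- e$individual_id[m[r]]
      if (is.na(lab)) next
      status[k, tru$individual_id[r]] <-
        if (lab == tru$individual_id[r]) "correct" else "wrong"
    }
  }

  min_ticks <- ceiling(min_duration * tick_rate)
  n_switches <- 0L
  wrong_time <- 0
  max_correct <- 0
  for (ind in inds) {
    s <- status[, ind]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    for (q in seq_along(r$values)) {
      len_s <- r$lengths[q] * dt
      if (r$values[q] == "wrong" && r$lengths[q] >= min_ticks) {
        n_switches <- n_switches + 1L
        wrong_time <- wrong_time + len_s
      }
      if (r$values[q] == "correct") max_correct <- max(max_correct, len_s)
    }
  }
  labelled <- status != "untracked"
  list(n_switches = n_switches,
       wrong_id_fraction = wrong_time / horizon,
       max_correct_streak_s = max_correct,
       labelled_fraction = mean(labelled),
       correct_tick_fraction =
         if (any(labelled)) mean(status[labelled] == "correct") else NaN)
}
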