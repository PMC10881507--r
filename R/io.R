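#' Configuration, file formats and the end-to-end pipeline
#'
#' YAML configuration with schema validation, CSV round-trip of the
#' trajectory and detection tables, fixture bundles with checksummed
#' manifests, and [run_pipeline()] tying the stages together in order:
#' video triangulation, lidar cluster tracking, fusion, identity linking,
#' grooming detection, analytics.
#'
#' @name cli_io
NULL

config_schema <- list(
  cage = c("width", "depth", "height"),
  cameras = NULL,  # free-form named list, validated per camera
  fusion = c("gate", "switch_gate", "max_gap", "contact_break"),
  cluster = c("tolerance", "s1", "s2", "voxel_size", "gate", "dropout"),
  smooth = c("window", "slide", "sigma", "threshold"),
  zones = NULL,
  video = c("tick_rate", "sync_tol", "max_residual"),
  identity = c("match_gate", "vote", "window", "min_confidence"),
  simulator = c("horizon", "seed", "tick_rate"),
  seed = NA)

#' Default pipeline configuration
#'
#' @return Nested list of every tunable with its documented default.
#' @export
default_config <- function() {
  list(cage = list(width = 820, depth = 610, height = 1578),
       fusion = list(gate = 200, switch_gate = 300, max_gap = 2,
                     contact_break = 200),
       cluster = list(tolerance = 50, s1 = 100, s2 = 500, voxel_size = 30,
                      gate = 300, dropout = 1),
       smooth = list(window = 50, slide = 5, sigma = 50 / 6,
                     threshold = 0.5),
       video = list(tick_rate = 7.4, max_residual = 8),
       identity = list(match_gate = 300, vote = "window", window = 60,
                       min_confidence = 0),
       seed = 1)
}

#' Read and validate a pipeline configuration
#'
#' Unknown top-level sections or unknown keys inside a known section are
#' rejected by name; missing values fall back to [default_config()].
#'
#' @param path YAML file path, or a list to validate directly.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  base <- default_config()
  bad <- setdiff(names(cfg), names(config_schema))
  if (length(bad) > 0)
    stop(sprintf("unknown config section: '%s'", bad[1]))
  for (sec in names(cfg)) {
    allowed <- config_schema[[sec]]
    if (is.null(allowed) || all(is.na(allowed))) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad) > 0)
      stop(sprintf("unknown config key: '%s.%s'", sec, bad[1]))
  }
  for (sec in names(base))
    if (is.list(base[[sec]]))
      cfg[[sec]] <- utils::modifyList(base[[sec]], cfg[[sec]] %||% list())
    else if (is.null(cfg[[sec]])) cfg[[sec]] <- base[[sec]]
  cfg
}

#' Write a trajectory table to CSV
#'
#' Columns tick, t, id, x, y, z, source; missing positions are written as
#' empty fields.
#'
#' @param traj Data.frame with those columns (`tracklet_id` or
#'   `individual_id` is accepted for `id`).
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  id <- traj$id %||% traj$individual_id %||% traj$tracklet_id
  out <- data.frame(tick = traj$tick, t = traj$t, id = id,
                    x = traj$x, y = traj$y, z = traj$z,
                    source = traj$source %||% "video")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory table from CSV
#'
#' @param path File written by [write_trajectory()].
#' @return Data.frame tick, t, id, x, y, z, source; malformed rows raise
#'   an error naming the line.
#' @export
read_trajectory <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(tick = "integer", t = "numeric",
                                        id = "character", x = "numeric",
                                        y = "numeric", z = "numeric",
                                        source = "character"))
  need <- c("tick", "t", "id", "x", "y", "z", "source")
  if (!all(need %in% names(raw)))
    stop("trajectory file missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  bad <- which(is.na(raw$tick) | is.na(raw$t))
  if (length(bad) > 0)
    stop(sprintf("malformed trajectory row at line %d", bad[1] + 1L))
  raw
}

#' Write a point cloud as columnar CSV
#' @param cloud n x 3 matrix.
#' @param path File path.
#' @param t Optional scan timestamp column value.
#' @export
write_cloud_csv <- function(cloud, path, t = NULL) {
  df <- as.data.frame(as_cloud(cloud))
  if (!is.null(t)) df <- cbind(t = t, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a scene to a fixture bundle
#'
#' A directory holding the ground truth and every sensor stream as plain
#' CSV, the generating configuration as YAML, and a manifest with MD5
#' checksums of every file — enough to verify bit-identical regeneration.
#'
#' @param scene A [simulate_scene()] result.
#' @param dir Target directory (created).
#' @param name Fixture name recorded in the manifest.
#' @return The manifest, invisibly.
#' @export
make_fixture <- function(scene, dir, name = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  utils::write.csv(scene$truth, fp("truth.csv"), row.names = FALSE, na = "")
  utils::write.csv(scene$streams$detections, fp("detections.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$streams$face_events, fp("face_events.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$streams$grooming, fp("grooming.csv"),
                   row.names = FALSE)
  lid <- scene$streams$lidar
  cl <- do.call(rbind, lapply(seq_along(lid$clouds), function(i)
    cbind(t = lid$times[i], as.data.frame(lid$clouds[[i]]))))
  utils::write.csv(cl, fp("lidar.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(lid$background_scans[[1]]),
                   fp("lidar_background.csv"), row.names = FALSE)
  utils::write.csv(scene$script, fp("script.csv"), row.names = FALSE)
  yaml::write_yaml(list(seed = scene$seed, tick_rate = scene$tick_rate,
                        horizon = scene$horizon,
                        cage = list(width = scene$cage$width,
                                    depth = scene$cage$depth,
                                    height = scene$cage$height)),
                   fp("config.yaml"))
  files <- list.files(dir)
  manifest <- list(name = name, seed = scene$seed,
                   created = format(Sys.time(), tz = "UTC"),
                   files = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Run the full tracking pipeline on a scene's sensor streams
#'
#' Executes the stages in order — video triangulation, lidar background
#' removal / clustering / serial tracking, video-primary fusion, cage
#' masking, identity linking, grooming detection, analytics — using only
#' the sensor streams (never the hidden truth).
#'
#' @param scene A `scene` (or a list with the same `streams`, `cameras`,
#'   `cage`, `tick_rate` fields).
#' @param config Configuration list as from [read_config()] /
#'   [default_config()].
#' @return List of class `pipeline_result`: `video` (video points),
#'   `lidar_tracks`, `tracklets`, `identified`, `grooming` (series +
#'   bouts), `occupancy`, `distances`, `stats`, `manifest`.
#' @export
run_pipeline <- function(scene, config = default_config()) {
  config <- read_config(config)
  tick_rate <- config$video$tick_rate %||% scene$tick_rate
  cage <- scene$cage %||% do.call(cage_model, config$cage)
  cams <- scene$cameras
  st <- scene$streams
  if (is.null(st$detections) || nrow(st$detections) == 0)
    stop("pipeline stage 'video': no detections stream")

  vp <- video_points(st$detections, cams, cage, tick_rate = tick_rate,
                     max_residual = config$video$max_residual)

  lidar_tracks <- NULL
  if (!is.null(st$lidar) && length(st$lidar$clouds) > 0) {
    bg <- build_background(st$lidar$background_scans,
                           config$cluster$voxel_size)
    fg <- lapply(st$lidar$clouds, remove_background, bg = bg)
    lstate <- track_stream(fg, st$lidar$times,
                           cluster_params(config$cluster$tolerance,
                                          config$cluster$s1,
                                          config$cluster$s2),
                           gate = config$cluster$gate,
                           dropout = config$cluster$dropout)
    lidar_tracks <- lstate$tracks
  }

  horizon <- scene$horizon %||% ((max(vp$tick, 0) + 1) / tick_rate)
  ticks <- seq(0, floor(horizon * tick_rate) - 1)
  fused <- fuse_tracks(vp, lidar_tracks, ticks, tick_rate,
                       fusion_params(config$fusion$gate,
                                     config$fusion$switch_gate,
                                     config$fusion$max_gap,
                                     config$fusion$contact_break))
  fused <- apply_cage_mask(fused, cage)

  identified <- link_identities(
    fused, st$face_events, match_gate = config$identity$match_gate,
    tick_rate = tick_rate, vote = config$identity$vote,
    window = config$identity$window,
    min_confidence = config$identity$min_confidence)

  grooming <- NULL
  if (!is.null(st$grooming) && nrow(st$grooming) > 0) {
    sp <- smooth_params(config$smooth$window, config$smooth$slide,
                        config$smooth$sigma, config$smooth$threshold)
    grooming <- detect_grooming(st$grooming$t, st$grooming$left,
                                st$grooming$right, sp,
                                identified = identified)
  }

  layout <- default_zones(cage)
  ids <- sort(unique(stats::na.omit(identified$individual_id)))
  tracks <- lapply(ids, function(id)
    individual_track(identified, id, ticks))
  names(tracks) <- ids
  occupancy <- lapply(tracks, zone_occupancy, layout = layout)
  distances <- if (length(tracks) >= 2) pairwise_distances(tracks) else NULL

  structure(list(video = vp, lidar_tracks = lidar_tracks,
                 tracklets = fused, identified = identified,
                 grooming = grooming, occupancy = occupancy,
                 distances = distances,
                 stats = tracklet_stats(fused, tick_rate),
                 manifest = list(
                   seed = scene$seed %||% NA,
                   tick_rate = tick_rate,
                   n_detections = nrow(st$detections),
                   n_video_points = nrow(vp),
                   n_dropped_detections =
                     attr(vp, "n_dropped") %||% 0L,
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<pipeline_result> %d tracklets, mean %.1f s; sources v/l/m = %s\n",
              s$n_tracklets, s$mean_duration_s,
              paste(sprintf("%.2f", s$source_fraction), collapse = "/")))
  invisible(x)
}
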