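#' Cage model
#'
#' Axis-aligned model of the home cage.  The cage frame has its origin at
#' the front-lower-left corner: x runs along the width (0--`width`), y along
#' the depth (0--`depth`, front face at y = 0), z along the height
#' (0--`height`).  All coordinates are millimetres.  Four fiducial markers
#' sit on the corners of the front face (y = 0 plane) and anchor camera
#' calibration.
#'
#' @param width,depth,height Cage dimensions in mm.  Defaults match an
#'   820 x 610 x 1578 mm marmoset family cage.
#' @param fiducial_points Optional 4 x 3 matrix of marker positions (mm).
#'   Defaults to the four front-face corners.
#' @return An object of class `cage_model`.
#' @examples
#' cage <- cage_model()
#' cage$fiducial_points
#' @export
cage_model <- function(width = 820, depth = 610, height = 1578,
                       fiducial_points = NULL) {
  stopifnot(width > 0, depth > 0, height > 0)
  if (is.null(fiducial_points)) {
    fiducial_points <- rbind(
      c(0,     0, 0),
      c(width, 0, 0),
      c(width, 0, height),
      c(0,     0, height))
  }
  fiducial_points <- as.matrix(fiducial_points)
  stopifnot(nrow(fiducial_points) == 4, ncol(fiducial_points) == 3)
  if (any(abs(fiducial_points[, 2]) > 1e-9))
    stop("fiducial markers must lie on the front face (y = 0 plane)")
  structure(list(width = width, depth = depth, height = height,
                 fiducial_points = fiducial_points),
            class = "cage_model")
}

#' @export
print.cage_model <- function(x, ...) {
  cat(sprintf("<cage_model> %g x %g x %g mm (W x D x H), 4 front-face fiducials\n",
              x$width, x$depth, x$height))
  invisible(x)
}

#' Test whether points lie inside the cage volume
#'
#' @param points Numeric vector of length 3 or an n x 3 matrix (mm).
#' @param cage A [cage_model()].
#' @param tol Slack in mm applied to every face (default 0).
#' @return Logical vector, one element per point.
#' @export
in_cage <- function(points, cage, tol = 0) {
  p <- to_points3(points)
  p[, 1] >= -tol & p[, 1] <= cage$width + tol &
    p[, 2] >= -tol & p[, 2] <= cage$depth + tol &
    p[, 3] >= -tol & p[, 3] <= cage$height + tol
}

# coerce a length-3 vector or n x 3 matrix-like to an n x 3 matrix
to_points3 <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3)
    matrix(as.numeric(points), 1, 3)
  } else {
    p <- as.matrix(points)
    stopifnot(ncol(p) == 3)
    storage.mode(p) <- "double"
    p
  }
}

#' Pinhole camera model
#'
#' Intrinsics plus a rigid pose taking cage-frame coordinates (mm) into the
#' camera frame.  The camera frame is the usual computer-vision one: x
#' right, y down, z along the optical axis; a point `X` in the cage frame
#' maps to `R %*% X + t` in the camera frame and projects through the
#' intrinsics with no distortion model.
#'
#' @param camera_id Character label.
#' @param focal Length-2 numeric, (fx, fy) in px.
#' @param principal_point Length-2 numeric, (cx, cy) in px.
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 numeric, camera-frame translation (mm).
#' @param image_size Length-2 integer, (width, height) in px.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(camera_id, focal, principal_point, rotation,
                         translation, image_size = c(1920L, 1080L)) {
  focal <- as.numeric(focal); principal_point <- as.numeric(principal_point)
  stopifnot(length(focal) == 2, all(focal > 0),
            length(principal_point) == 2, length(translation) == 3,
            length(image_size) == 2)
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(crossprod(rotation), diag(3), tolerance = 1e-6)) ||
      det(rotation) < 0)
    stop("rotation must be orthonormal with determinant +1")
  K <- matrix(c(focal[1], 0, principal_point[1],
                0, focal[2], principal_point[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  structure(list(camera_id = as.character(camera_id), focal = focal,
                 principal_point = principal_point, rotation = rotation,
                 translation = as.numeric(translation),
                 image_size = as.numeric(image_size),
                 P = K %*% cbind(rotation, as.numeric(translation))),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  c0 <- camera_center(x)
  cat(sprintf("<camera_model> '%s' f = (%.1f, %.1f) px, centre at (%.0f, %.0f, %.0f) mm\n",
              x$camera_id, x$focal[1], x$focal[2], c0[1], c0[2], c0[3]))
  invisible(x)
}

#' Camera centre in the cage frame
#' @param camera A [camera_model()].
#' @return Length-3 numeric (mm).
#' @export
camera_center <- function(camera) {
  drop(-crossprod(camera$rotation, camera$translation))
}

#' Build a camera looking at a target point
#'
#' Convenience constructor: places the camera centre at `position` with the
#' optical axis through `target` and the image "up" direction as close to
#' +z (cage up) as the geometry allows.
#'
#' @param camera_id Label.
#' @param position,target Length-3 cage-frame points (mm).
#' @param focal,principal_point,image_size As in [camera_model()].
#' @return A `camera_model`.
#' @export
look_at_camera <- function(camera_id, position, target,
                           focal = c(1400, 1400),
                           principal_point = c(960, 540),
                           image_size = c(1920L, 1080L)) {
  position <- as.numeric(position); target <- as.numeric(target)
  fwd <- target - position
  nf <- sqrt(sum(fwd^2))
  if (nf < 1e-9) stop("camera position and target coincide")
  fwd <- fwd / nf
  up_world <- c(0, 0, 1)
  right <- vcross(fwd, up_world)
  nr <- sqrt(sum(right^2))
  if (nr < 1e-9) { # looking straight up/down: fall back to cage +y as up
    right <- vcross(fwd, c(0, 1, 0))
    nr <- sqrt(sum(right^2))
  }
  right <- right / nr
  down <- vcross(fwd, right)  # completes right-handed (x right, y down, z fwd)
  R <- rbind(right, down, fwd)
  dimnames(R) <- NULL
  camera_model(camera_id, focal, principal_point, R, -R %*% position,
               image_size)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project cage-frame points through a camera
#'
#' Perspective projection through the pinhole model, no distortion.
#'
#' @param camera A [camera_model()].
#' @param points Length-3 vector or n x 3 matrix of cage-frame points (mm).
#' @return An n x 2 matrix of pixel coordinates (u, v).  Signals an error
#'   if any point has non-positive depth in the camera frame.
#' @export
project <- function(camera, points) {
  p <- to_points3(points)
  pc <- p %*% t(camera$rotation) +
    matrix(camera$translation, nrow(p), 3, byrow = TRUE)
  if (any(pc[, 3] <= 0))
    stop("point behind camera: non-positive depth in camera frame")
  uv <- cbind(camera$principal_point[1] + camera$focal[1] * pc[, 1] / pc[, 3],
              camera$principal_point[2] + camera$focal[2] * pc[, 2] / pc[, 3])
  colnames(uv) <- c("u", "v")
  uv
}

#' Back-project a pixel to a viewing ray
#'
#' @param camera A [camera_model()].
#' @param pixel Length-2 numeric (u, v).
#' @return List with `origin` (camera centre, mm) and `direction` (unit
#'   vector in the cage frame).
#' @export
pixel_ray <- function(camera, pixel) {
  d_cam <- c((pixel[1] - camera$principal_point[1]) / camera$focal[1],
             (pixel[2] - camera$principal_point[2]) / camera$focal[2], 1)
  d <- drop(crossprod(camera$rotation, d_cam))
  list(origin = camera_center(camera), direction = d / sqrt(sum(d^2)))
}

# 3 x 4 projection matrix K [R | t] (cached at construction)
projection_matrix <- function(camera) camera$P

# reprojection pixel error without error signalling: Inf behind the camera
reproject_error <- function(camera, point, uv) {
  pc <- drop(camera$rotation %*% point) + camera$translation
  if (pc[3] <= 0) return(Inf)
  du <- camera$principal_point[1] + camera$focal[1] * pc[1] / pc[3] - uv[1]
  dv <- camera$principal_point[2] + camera$focal[2] * pc[2] / pc[3] - uv[2]
  sqrt(du^2 + dv^2)
}

#' Triangulate a 3D point from multi-view pixel observations
#'
#' Linear least-squares (direct linear transform) intersection of the
#' calibrated viewing rays, with optional rejection of a single outlier
#' view whose reprojection residual exceeds 3x the median residual of the
#' remaining views.
#'
#' @param pixels n x 2 matrix of pixel observations, one row per camera.
#' @param cameras List of [camera_model()]s, parallel to `pixels` rows.
#' @param reject_outliers If `TRUE` (default) and three or more views are
#'   available, drop at most one view by the 3x-median residual rule and
#'   re-triangulate.
#' @param min_ray_angle Rays spanning less than this angle (degrees) flag
#'   the result low-confidence (near-parallel geometry).
#' @return List with `point` (length-3, mm), `residual` (RMS reprojection
#'   error, px), `n_views` used, and `low_confidence` flag.
#' @export
triangulate <- function(pixels, cameras, reject_outliers = TRUE,
                        min_ray_angle = 2) {
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  if (length(cameras) < 2 || nrow(pixels) < 2)
    stop("insufficient views: triangulation needs >= 2 calibrated cameras")
  stopifnot(nrow(pixels) == length(cameras))

  sol <- dlt_solve(pixels, cameras)
  res_i <- reprojection_residuals(sol$point, pixels, cameras)

  # A corrupted view drags the joint solution, inflating every residual,
  # so the outlier test refits without each view in turn (leave-one-out)
  # and drops the view whose exclusion-residual exceeds 3x the median of
  # the remaining views' fit.  Only triggered when the joint fit is
  # suspicious, to keep the common clean case cheap.
  if (reject_outliers && length(cameras) >= 3 &&
      sqrt(mean(res_i^2)) > 3) {
    best <- NULL
    for (w in seq_along(cameras)) {
      sol_w <- dlt_solve(pixels[-w, , drop = FALSE], cameras[-w])
      res_keep <- reprojection_residuals(sol_w$point,
                                         pixels[-w, , drop = FALSE],
                                         cameras[-w])
      res_out <- reprojection_residuals(sol_w$point,
                                        pixels[w, , drop = FALSE],
                                        cameras[w])
      if (res_out > 3 * max(stats::median(res_keep), 1e-9) &&
          (is.null(best) || sqrt(mean(res_keep^2)) < best$rms)) {
        best <- list(w = w, sol = sol_w, res = res_keep,
                     rms = sqrt(mean(res_keep^2)))
      }
    }
    if (!is.null(best)) {
      pixels <- pixels[-best$w, , drop = FALSE]
      cameras <- cameras[-best$w]
      sol <- best$sol
      res_i <- best$res
    }
  }

  dirs <- t(vapply(seq_along(cameras), function(i)
    pixel_ray(cameras[[i]], pixels[i, ])$direction, numeric(3)))
  max_angle <- 0
  for (i in seq_len(nrow(dirs) - 1))
    for (j in seq(i + 1, nrow(dirs))) {
      ang <- acos(min(1, abs(sum(dirs[i, ] * dirs[j, ])))) * 180 / pi
      max_angle <- max(max_angle, ang)
    }

  list(point = sol$point,
       residual = sqrt(mean(res_i^2)),
       n_views = length(cameras),
       low_confidence = max_angle < min_ray_angle)
}

dlt_solve <- function(pixels, cameras) {
  A <- matrix(0, 2 * length(cameras), 4)
  for (i in seq_along(cameras)) {
    P <- projection_matrix(cameras[[i]])
    A[2 * i - 1, ] <- pixels[i, 1] * P[3, ] - P[1, ]
    A[2 * i, ]     <- pixels[i, 2] * P[3, ] - P[2, ]
  }
  # scale rows for conditioning, then take the right-singular vector of
  # the smallest singular value
  A <- A / pmax(sqrt(rowSums(A^2)), 1e-12)
  v <- svd(A, nu = 0)$v[, 4]
  if (abs(v[4]) < 1e-12) stop("triangulation degenerate: point at infinity")
  list(point = v[1:3] / v[4])
}

reprojection_residuals <- function(point, pixels, cameras) {
  vapply(seq_along(cameras), function(i)
    reproject_error(cameras[[i]], point, pixels[i, ]), numeric(1))
}

#' Calibrate a camera pose from the four cage-corner fiducials
#'
#' Estimates the rigid pose of a camera with known intrinsics from the
#' pixel positions of the four coplanar fiducial markers on the cage front
#' face.  An initial pose comes from the exact planar homography of the
#' four correspondences decomposed against the intrinsics; it is then
#' refined by least-squares minimisation of the summed squared reprojection
#' error.
#'
#' @param marker_pixels 4 x 2 matrix of observed marker pixels, rows
#'   matching the rows of `cage$fiducial_points`.
#' @param cage A [cage_model()].
#' @param intrinsics List with `focal`, `principal_point` and optionally
#'   `image_size` — the known intrinsics of the camera.
#' @param camera_id Label for the calibrated camera.
#' @return A list with `camera` (the calibrated [camera_model()]) and
#'   `residual` (RMS reprojection error of the four markers, px).
#' @export
calibrate_camera <- function(marker_pixels, cage, intrinsics,
                             camera_id = "cam") {
  px <- matrix(as.numeric(marker_pixels), ncol = 2)
  stopifnot(nrow(px) == 4)
  M <- cage$fiducial_points          # rows (x, 0, z)
  plane <- cbind(M[, 1], M[, 3])     # in-plane coordinates

  # collinearity check: rank of centred plane coordinates
  sv <- svd(scale(plane, scale = FALSE))$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("calibration failure: fiducial markers are collinear")

  H <- homography_dlt(plane, px)
  K <- matrix(c(intrinsics$focal[1], 0, intrinsics$principal_point[1],
                0, intrinsics$focal[2], intrinsics$principal_point[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  B <- solve(K, H)
  lam <- 1 / sqrt(sum(B[, 1]^2))
  # homography columns map plane coordinates (x, z, 1), so they carry the
  # world-x and world-z columns of R and the translation; pick the scale
  # sign putting the marker centroid at positive depth
  ctr <- colMeans(M)
  for (s in c(lam, -lam)) {
    r1 <- s * B[, 1]; r3 <- s * B[, 2]; t <- s * B[, 3]
    r2 <- vcross(r3, r1)               # world-y completes the frame
    Rm <- nearest_rotation(cbind(r1, r2, r3))
    pose <- list(rotation = Rm, translation = t)
    if ((Rm %*% ctr + t)[3] > 0) break
  }

  refined <- refine_pose(pose$rotation, pose$translation, M, px, K)
  cam <- camera_model(camera_id, intrinsics$focal, intrinsics$principal_point,
                      refined$rotation, refined$translation,
                      intrinsics$image_size %||% c(1920L, 1080L))
  res <- vapply(1:4, function(i)
    sqrt(sum((project(cam, M[i, ]) - px[i, ])^2)), numeric(1))
  list(camera = cam, residual = sqrt(mean(res^2)))
}

homography_dlt <- function(src, dst) {
  stopifnot(nrow(src) >= 4)
  A <- matrix(0, 2 * nrow(src), 9)
  for (i in seq_len(nrow(src))) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  e <- eigen(crossprod(A), symmetric = TRUE)
  if (sqrt(max(e$values[8], 0)) < 1e-10 * sqrt(e$values[1]))
    stop("calibration failure: degenerate fiducial configuration")
  matrix(e$vectors[, 9], 3, 3, byrow = TRUE)
}

nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

# axis-angle <-> rotation helpers for pose refinement
rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  Kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
}

rotation_log <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  th <- acos(min(1, max(-1, ct)))
  if (th < 1e-12) return(c(0, 0, 0))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  th * w / (2 * sin(th))
}

refine_pose <- function(R0, t0, world, pixels, K) {
  obj <- function(par) {
    R <- rodrigues(par[1:3]); t <- par[4:6]
    pc <- world %*% t(R) + matrix(t, nrow(world), 3, byrow = TRUE)
    if (any(pc[, 3] <= 0)) return(1e12)
    u <- K[1, 1] * pc[, 1] / pc[, 3] + K[1, 3]
    v <- K[2, 2] * pc[, 2] / pc[, 3] + K[2, 3]
    sum((u - pixels[, 1])^2 + (v - pixels[, 2])^2)
  }
  par0 <- c(rotation_log(R0), t0)
  fit <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(rotation = rodrigues(fit$par[1:3]), translation = fit$par[4:6])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Four-camera rig in front of the cage
#'
#' Builds the default acquisition geometry: two camera heights (900 and
#' 1900 mm) at a 1000 mm standoff in front of the cage, one camera left and
#' one right of centre at each height, all aimed at the cage centre.
#'
#' @param cage A [cage_model()].
#' @param standoff Distance from the cage front face (mm).
#' @param heights Two mounting heights (mm).
#' @param spread Horizontal offset of each camera from the cage centreline
#'   (mm).
#' @param focal,image_size Shared intrinsics.
#' @return A named list of four [camera_model()]s.
#' @export
default_rig <- function(cage = cage_model(), standoff = 1000,
                        heights = c(900, 1900), spread = 300,
                        focal = c(1400, 1400), image_size = c(1920L, 1080L)) {
  ctr <- c(cage$width / 2, cage$depth / 2, cage$height / 2)
  pp <- image_size / 2
  pos <- list(
    ll = c(cage$width / 2 - spread, -standoff, heights[1]),
    lr = c(cage$width / 2 + spread, -standoff, heights[1]),
    ul = c(cage$width / 2 - spread, -standoff, heights[2]),
    ur = c(cage$width / 2 + spread, -standoff, heights[2]))
  cams <- lapply(names(pos), function(nm)
    look_at_camera(nm, pos[[nm]], ctr, focal = focal,
                   principal_point = pp, image_size = image_size))
  names(cams) <- names(pos)
  cams
}
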