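#' Render a synthetic top-view bird image
#'
#' Draws the acquisition scene the vision pipeline expects: a near-black
#' reference floor rectangle centred in a lighter frame, with the bird as a
#' light elliptical blob whose axes come from the record's back length and
#' width (mm converted to px through the camera scale). Per-replicate
#' posture jitter perturbs the axes (clamped at +/-5%), rotates the body
#' and nudges its centre; mild additive pixel noise is applied everywhere.
#' The exact rasterized ellipse mask is returned as ground truth.
#'
#' Bird bodies are deliberately plain ellipses: downstream segmentation
#' must only rely on contrast with the black floor, not silhouette detail.
#'
#' @param record one bird-day row (needs `bird_id`, `day`,
#'   `back_length_mm`, `back_width_mm`).
#' @param replicate_index which replicate (1-based); folded into the RNG
#'   stream so replicates differ.
#' @param camera a [camera_geometry()].
#' @param seed integer seed; combined with bird id, day and replicate.
#' @param jitter_cv CV of the axis jitter (0 disables posture jitter and
#'   rotation and centres the bird exactly).
#' @param noise_sd additive Gaussian pixel noise SD on the 0..255 scale
#'   (0 disables).
#' @param floor_level,bird_level,background_level mean intensities
#'   (0..255) of floor, bird and out-of-floor frame.
#' @return list of class `bird_render`: `image` (height x width x 3 RGB
#'   array in \[0, 1\]), `mask` (logical ground-truth matrix),
#'   `pixel_count`, the true `floor_corners` (4 x 2, 0-based x,y), and the
#'   drawn ellipse geometry (`center`, `semi_axes_px`, `theta`).
#' @export
render_bird_image <- function(record, replicate_index = 1L,
                              camera = camera_geometry(), seed = 1L,
                              jitter_cv = 0.03, noise_sd = 4,
                              floor_level = 15, bird_level = 190,
                              background_level = 220) {
  stopifnot(all(c("back_length_mm", "back_width_mm") %in% names(record)))
  set.seed((abs(as.integer(seed)) + 1000003L * as.integer(replicate_index) +
              101L * as.integer(record$day[1]) +
              sum(utf8ToInt(as.character(record$bird_id[1])))) %% 2147483647L)

  H <- camera$image_height_px
  W <- camera$image_width_px
  mmpp <- camera$mm_per_px

  a <- (record$back_length_mm[1] / 2) / mmpp  # semi-major, px
  b <- (record$back_width_mm[1] / 2) / mmpp   # semi-minor, px
  theta <- 0
  cx <- (camera$floor_x0 + camera$floor_x1) / 2
  cy <- (camera$floor_y0 + camera$floor_y1) / 2
  if (jitter_cv > 0) {
    jab <- pmax(pmin(stats::rnorm(2, 0, jitter_cv), 0.05), -0.05)
    a <- a * (1 + jab[1])
    b <- b * (1 + jab[2])
    theta <- stats::runif(1, 0, pi)
    cx <- cx + stats::rnorm(1, 0, 0.02 * camera$floor_width_px)
    cy <- cy + stats::rnorm(1, 0, 0.02 * camera$floor_height_px)
  }

  # rotated-ellipse bounding half extents
  ext_x <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  ext_y <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  if (cx - ext_x < camera$floor_x0 || cx + ext_x > camera$floor_x1 ||
      cy - ext_y < camera$floor_y0 || cy + ext_y > camera$floor_y1)
    stop(sprintf("bird %s day %s: body ellipse exceeds floor bounds",
                 record$bird_id[1], record$day[1]), call. = FALSE)

  # pixel-centre coordinates, 0-based (x = col - 1, y = row - 1)
  xs <- matrix(rep(0:(W - 1), each = H), nrow = H)
  ys <- matrix(rep(0:(H - 1), times = W), nrow = H)
  dx <- xs - cx
  dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  mask <- (u / a)^2 + (v / b)^2 <= 1

  floor_px <- xs >= camera$floor_x0 & xs <= camera$floor_x1 &
    ys >= camera$floor_y0 & ys <= camera$floor_y1
  img <- matrix(background_level, H, W)
  img[floor_px] <- floor_level
  img[mask] <- bird_level
  if (noise_sd > 0) img <- img + stats::rnorm(H * W, 0, noise_sd)
  img <- pmin(pmax(img, 0), 255)

  rgb <- array(img / 255, dim = c(H, W, 3))
  corners <- cbind(
    x = c(camera$floor_x0, camera$floor_x1, camera$floor_x1, camera$floor_x0),
    y = c(camera$floor_y0, camera$floor_y0, camera$floor_y1, camera$floor_y1))
  structure(list(
    image = rgb, mask = mask, pixel_count = sum(mask),
    floor_corners = corners,
    center = c(x = cx, y = cy), semi_axes_px = c(a = a, b = b), theta = theta,
    bird_id = record$bird_id[1], day = record$day[1],
    replicate = as.integer(replicate_index), camera = camera
  ), class = "bird_render")
}

#' Render the replicate image set for one bird-day
#'
#' @inheritParams render_bird_image
#' @param n number of replicates (default: 5).
#' @param ... forwarded to [render_bird_image()].
#' @return list of `bird_render` objects, length `n`.
#' @export
render_replicates <- function(record, camera = camera_geometry(), n = 5L,
                              seed = 1L, ...) {
  lapply(seq_len(n), function(i)
    render_bird_image(record, replicate_index = i, camera = camera,
                      seed = seed, ...))
}

#' Write an image or mask as PNG
#'
#' Masks are written single-channel 0/255; RGB arrays as-is.
#'
#' @param x logical matrix (mask), numeric matrix (grayscale, 0..255 or
#'   0..1), or H x W x 3 array in \[0, 1\].
#' @param path output PNG path.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.numeric(x), nrow(x), ncol(x))
  if (is.matrix(x) && max(x) > 1) x <- x / 255
  png::writePNG(x, path)
  invisible(path)
}

#' Read a PNG/JPEG image as a 0..255 array
#'
#' @param path image path (.png, .jpg or .jpeg).
#' @return numeric matrix (grayscale) or array (colour), 0..255 scale.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("jpeg package required for JPEG input", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE))
  img * 255
}
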