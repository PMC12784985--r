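## Vision workflow: (i) ROI detection via the black reference floor,
## (ii) bird segmentation within the ROI, (iii) foreground pixel counting,
## (iv) QC overlay export; plus replicate averaging.
## Pixel coordinates are 0-based (x = column, y = row); masks are logical
## in memory and 0/255 single-channel PNG on disk.

as_gray <- function(image) {
  if (length(dim(image)) == 3)
    image <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  if (max(image) <= 1) image <- image * 255
  image
}

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 3x3 square structuring element
erode3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out & shift_mat(m, dr, dc, fill = FALSE)
  out
}

dilate3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out | shift_mat(m, dr, dc, fill = FALSE)
  out
}

# Otsu's threshold on 0..255 intensities (maximize between-class variance)
otsu_threshold <- function(values) {
  v <- pmin(pmax(round(values), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  denom[denom == 0] <- NA
  sigma_b <- (mu_t * omega - mu)^2 / denom
  which.max(sigma_b) - 1L # threshold: foreground strictly above
}

# minimum-area bounding rectangle of a point cloud (rotating calipers on
# the convex hull); points is a 2-column matrix (x, y)
min_area_rect <- function(points) {
  hull <- points[grDevices::chull(points[, 1], points[, 2]), , drop = FALSE]
  n <- nrow(hull)
  if (n == 1) return(list(corners = hull[rep(1, 4), ], width = 0, height = 0))
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% v
    w <- max(pu) - min(pu)
    h <- max(pv) - min(pv)
    if (is.null(best) || w * h < best$area) {
      c1 <- min(pu) * u + min(pv) * v
      corners <- rbind(c1, c1 + w * u, c1 + w * u + h * v, c1 + h * v)
      best <- list(area = w * h, corners = unname(corners),
                   width = max(w, h), height = min(w, h))
    }
  }
  best
}

#' Detect the black reference floor (ROI)
#'
#' Thresholds the frame at a fixed low intensity, keeps the largest dark
#' connected component and fits its minimum-area quadrilateral. The floor
#' must cover at least `min_frame_fraction` of the frame; an aspect ratio
#' deviating more than 25% from the physical floor's 600:400 raises a
#' warning flag (not an error).
#'
#' @param image RGB array or grayscale matrix (0..255 or 0..1).
#' @param floor_threshold intensity cut (0..255 scale) below which a pixel
#'   counts as floor-dark (default 60).
#' @param min_frame_fraction minimum dark coverage of the frame (default 0.2).
#' @param expected_aspect long/short side ratio of the physical floor
#'   (default 1.5) used for the QC check.
#' @return object of class `roi_quad`: `corners` (4 x 2, 0-based x,y),
#'   side lengths, `area`, and QC `flags`.
#' @export
detect_roi <- function(image, floor_threshold = 60, min_frame_fraction = 0.2,
                       expected_aspect = 1.5) {
  g <- as_gray(image)
  dark <- g < floor_threshold
  if (mean(dark) < min_frame_fraction)
    stop("floor not found: no dark region covering >= ",
         round(100 * min_frame_fraction), "% of frame", call. = FALSE)
  lab <- cc_label(dark)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  idx <- which(comp, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  rect <- min_area_rect(pts)
  flags <- character(0)
  aspect <- if (rect$height > 0) rect$width / rect$height else Inf
  if (!is.finite(aspect) || abs(aspect - expected_aspect) > 0.25 * expected_aspect)
    flags <- c(flags, "aspect_ratio")
  structure(list(corners = rect$corners, width = rect$width,
                 height = rect$height, area = rect$area, aspect = aspect,
                 flags = flags), class = "roi_quad")
}

# logical mask of pixels inside a convex quadrilateral (0-based coords)
roi_to_mask <- function(roi, nrow, ncol) {
  cr <- roi$corners
  # ensure counter-clockwise orientation
  area2 <- sum(cr[, 1] * cr[c(2:4, 1), 2] - cr[c(2:4, 1), 1] * cr[, 2])
  if (area2 < 0) cr <- cr[4:1, ]
  xs <- matrix(rep(0:(ncol - 1), each = nrow), nrow = nrow)
  ys <- matrix(rep(0:(nrow - 1), times = ncol), nrow = nrow)
  inside <- matrix(TRUE, nrow, ncol)
  for (i in 1:4) {
    j <- if (i == 4) 1L else i + 1L
    ex <- cr[j, 1] - cr[i, 1]
    ey <- cr[j, 2] - cr[i, 2]
    inside <- inside & (ex * (ys - cr[i, 2]) - ey * (xs - cr[i, 1]) >= -0.5)
  }
  inside
}

#' Segment the bird within the ROI
#'
#' Classifies foreground by Otsu's automatic threshold computed on the
#' intensities inside the ROI (the bird is lighter than the black floor),
#' applies 3x3 morphological opening then closing, keeps the largest
#' connected component and fills its holes.
#'
#' @param image RGB array or grayscale matrix.
#' @param roi a `roi_quad` from [detect_roi()].
#' @param min_area smallest acceptable component, px (default 50); below
#'   this the function errors with "no bird detected".
#' @param morphology apply the 3x3 opening/closing cleanup (default TRUE).
#' @param min_contrast minimum separation (0..255 intensity levels) between
#'   the mean intensities above and below the Otsu cut; below this the ROI
#'   is considered empty (pure floor noise has no bimodal structure) and
#'   "no bird detected" is raised (default 30).
#' @return object of class `segmentation_result`: `roi`, logical `mask`
#'   (nonzero only inside the ROI), `pixel_count`, the Otsu `threshold`,
#'   QC `flags` (`"border_contact"` when the component touches the ROI
#'   boundary), and `overlay_path` (NA until [export_overlay()]).
#' @export
segment_bird <- function(image, roi, min_area = 50, morphology = TRUE,
                         min_contrast = 30) {
  stopifnot(inherits(roi, "roi_quad"))
  g <- as_gray(image)
  inside <- roi_to_mask(roi, nrow(g), ncol(g))
  thr <- otsu_threshold(g[inside])
  vals <- g[inside]
  if (!any(vals > thr) ||
      mean(vals[vals > thr]) - mean(vals[vals <= thr]) < min_contrast)
    stop("no bird detected", call. = FALSE)
  fg <- inside & g > thr
  if (morphology) {
    fg <- dilate3(erode3(fg)) # opening
    fg <- erode3(dilate3(fg)) # closing
  }
  if (!any(fg)) stop("no bird detected", call. = FALSE)
  lab <- cc_label(fg)
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < min_area) stop("no bird detected", call. = FALSE)
  comp <- lab == which.max(sizes)
  comp <- cc_fill_holes(comp)
  comp <- comp & inside
  flags <- character(0)
  if (any(comp & !erode3(inside))) flags <- c(flags, "border_contact")
  structure(list(roi = roi, mask = comp, pixel_count = sum(comp),
                 threshold = thr, flags = flags, overlay_path = NA_character_),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Segmentation: %d foreground px (Otsu threshold %d)%s\n",
              x$pixel_count, x$threshold,
              if (length(x$flags)) paste0(" flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Average replicate pixel counts for one bird-day
#'
#' The per-bird-day measurement is the arithmetic mean of the replicate
#' image counts; the coefficient of variation across replicates is
#' recorded and flagged when it exceeds 10%.
#'
#' @param results list of `segmentation_result` objects (or a numeric
#'   vector of counts) from the same bird-day.
#' @param bird_id,day optional identifiers carried through.
#' @return object of class `replicate_set` with `counts`, `mean_count`,
#'   `cv` and `flags`.
#' @export
average_replicates <- function(results, bird_id = NA_character_, day = NA_integer_) {
  counts <- if (is.numeric(results)) results
            else vapply(results, function(r) as.numeric(r$pixel_count), 0)
  if (length(counts) < 1) stop("need at least one replicate", call. = FALSE)
  m <- mean(counts)
  cv <- if (length(counts) > 1) stats::sd(counts) / m else 0
  flags <- if (cv > 0.10) "high_replicate_cv" else character(0)
  structure(list(bird_id = bird_id, day = day, counts = counts,
                 mean_count = m, cv = cv, flags = flags),
            class = "replicate_set")
}

draw_segment_px <- function(layer, x0, y0, x1, y1) {
  n <- max(2, ceiling(max(abs(x1 - x0), abs(y1 - y0))) + 1)
  xs <- round(seq(x0, x1, length.out = n)) + 1
  ys <- round(seq(y0, y1, length.out = n)) + 1
  keep <- xs >= 1 & xs <= ncol(layer) & ys >= 1 & ys <= nrow(layer)
  layer[cbind(ys[keep], xs[keep])] <- TRUE
  layer
}

#' Export a quality-control overlay
#'
#' Writes a PNG of the input frame with the ROI outline burned in green
#' and the segmented mask contour in red. Flagged results additionally get
#' an orange banner strip across the top and a plain-text sidecar
#' `<name>.flags.txt` listing the flags. Naming is deterministic:
#' `<bird>_<day>_<rep>.overlay.png`.
#'
#' @param image the frame that was segmented.
#' @param result a `segmentation_result`.
#' @param dir output directory (must be writable).
#' @param bird_id,day,replicate identifiers used in the file name.
#' @return the overlay path (invisibly also stored in the result by the
#'   caller if desired).
#' @export
export_overlay <- function(image, result, dir, bird_id, day, replicate = 1L) {
  stopifnot(inherits(result, "segmentation_result"))
  if (!dir.exists(dir)) stop("unwritable path: ", dir, call. = FALSE)
  g <- as_gray(image) / 255
  H <- nrow(g); W <- ncol(g)
  rgb <- array(g, dim = c(H, W, 3))

  roi_line <- matrix(FALSE, H, W)
  cr <- result$roi$corners
  for (i in 1:4) {
    j <- if (i == 4) 1L else i + 1L
    roi_line <- draw_segment_px(roi_line, cr[i, 1], cr[i, 2], cr[j, 1], cr[j, 2])
  }
  contour <- result$mask & !erode3(result$mask)

  r <- rgb[, , 1]; gg <- rgb[, , 2]; b <- rgb[, , 3]
  r[roi_line] <- 0; gg[roi_line] <- 1; b[roi_line] <- 0
  r[contour] <- 1; gg[contour] <- 0; b[contour] <- 0
  path <- file.path(dir, sprintf("%s_%s_%s.overlay.png", bird_id, day, replicate))
  if (length(result$flags)) {
    rows <- 1:min(6, H)
    r[rows, ] <- 1; gg[rows, ] <- 0.6; b[rows, ] <- 0
    writeLines(result$flags, sub("\\.overlay\\.png$", ".flags.txt", path))
  }
  rgb[, , 1] <- r; rgb[, , 2] <- gg; rgb[, , 3] <- b
  png::writePNG(rgb, path)
  path
}

#' Run the full pipeline on a batch of image files
#'
#' Convenience wrapper for the CLI: detect ROI, segment, optionally export
#' overlays, and return one row per image. File names are expected to
#' encode identity as `<bird>_<day>_<replicate>.png`.
#'
#' @param paths character vector of image paths.
#' @param overlay_dir if non-NULL, overlays are written here.
#' @param ... forwarded to [detect_roi()] / [segment_bird()].
#' @return data frame `bird_id, day, replicate, pixel_count, flags`.
#' @export
segment_images <- function(paths, overlay_dir = NULL, ...) {
  rows <- lapply(paths, function(p) {
    parts <- strsplit(sub("\\.(png|jpe?g)$", "", basename(p)), "_")[[1]]
    img <- read_image(p)
    roi <- detect_roi(img)
    res <- segment_bird(img, roi)
    flags <- c(roi$flags, res$flags)
    if (!is.null(overlay_dir))
      export_overlay(img, res, overlay_dir, parts[1],
                     parts[2], if (length(parts) > 2) parts[3] else 1L)
    data.frame(bird_id = parts[1],
               day = as.integer(parts[2]),
               replicate = if (length(parts) > 2) as.integer(parts[3]) else 1L,
               pixel_count = res$pixel_count,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
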