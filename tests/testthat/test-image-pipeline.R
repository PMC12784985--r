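# helper: an adult-bird record whose ellipse is comfortably inside the floor
adult_record <- function() {
  data.frame(bird_id = "B001", day = 42,
             back_length_mm = 200, back_width_mm = 120)
}

test_that("noise-free rasterized ellipse matches the analytic area", {
  cam <- camera_geometry()  # mm_per_px = 2
  # axes 100 px x 60 px -> semi-axes 50 x 30 -> analytic area pi*50*30
  r <- render_bird_image(adult_record(), camera = cam, seed = 1,
                         jitter_cv = 0, noise_sd = 0)
  expect_lt(abs(r$pixel_count - pi * 50 * 30) / (pi * 50 * 30), 0.02)
  expect_identical(r$pixel_count, sum(r$mask))
})

test_that("blob size increases monotonically with growth", {
  cam <- camera_geometry()
  chick <- data.frame(bird_id = "B001", day = 1,
                      back_length_mm = 44, back_width_mm = 32)
  r1 <- render_bird_image(chick, camera = cam, seed = 2)
  r42 <- render_bird_image(adult_record(), camera = cam, seed = 2)
  expect_lt(r1$pixel_count, r42$pixel_count)
})

test_that("replicate jitter yields distinct masks with CV < 10%", {
  reps <- render_replicates(adult_record(), n = 5, seed = 11)
  counts <- vapply(reps, `[[`, 0, "pixel_count")
  expect_length(unique(counts), 5L)
  expect_lt(stats::sd(counts) / mean(counts), 0.10)
  masks <- lapply(reps, `[[`, "mask")
  expect_false(any(duplicated(lapply(masks, which))))
})

test_that("oversized birds and rendering determinism are handled", {
  big <- data.frame(bird_id = "B077", day = 42,
                    back_length_mm = 700, back_width_mm = 120)
  expect_error(render_bird_image(big, jitter_cv = 0, noise_sd = 0),
               "B077.*exceeds floor")
  a <- render_bird_image(adult_record(), seed = 9)
  b <- render_bird_image(adult_record(), seed = 9)
  expect_identical(a$image, b$image)
})

test_that("ROI detection recovers the floor quadrilateral within 2 px", {
  r <- render_bird_image(adult_record(), seed = 3)
  roi <- detect_roi(r$image)
  expect_length(roi$flags, 0)
  # match detected corners to ground truth by nearest distance
  truth <- r$floor_corners
  for (i in 1:4) {
    d <- sqrt(rowSums((roi$corners - matrix(truth[i, ], 4, 2, byrow = TRUE))^2))
    expect_lt(min(d), 2)
  }
})

test_that("a frame with no dark floor raises 'floor not found'", {
  white <- matrix(255, 120, 160)
  expect_error(detect_roi(white), "floor not found")
})

test_that("a rotated floor is recovered with area within 3%", {
  H <- 240; W <- 320
  img <- matrix(220, H, W)
  theta <- 10 * pi / 180
  xs <- matrix(rep(0:(W - 1), each = H), nrow = H) - (W - 1) / 2
  ys <- matrix(rep(0:(H - 1), times = W), nrow = H) - (H - 1) / 2
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  inside <- abs(u) <= 130 & abs(v) <= 260 / 3  # 260 x 173.3 px floor
  img[inside] <- 15
  roi <- detect_roi(img)
  expect_lt(abs(roi$area - sum(inside)) / sum(inside), 0.03)
  expect_equal(roi$aspect, 1.5, tolerance = 0.05)
})

test_that("segmentation reproduces the ground-truth count on clean frames", {
  r <- render_bird_image(adult_record(), seed = 5, jitter_cv = 0, noise_sd = 0)
  res <- segment_bird(r$image, detect_roi(r$image))
  expect_lt(abs(res$pixel_count - r$pixel_count) / r$pixel_count, 0.01)
  expect_identical(res$pixel_count, sum(res$mask))
  expect_length(res$flags, 0)
})

test_that("only the largest component is counted when an artifact is present", {
  r <- render_bird_image(adult_record(), seed = 6)
  img <- r$image
  # bright 10x10 artifact in a floor corner, well away from the bird
  img[31:40, 31:40, ] <- 0.8
  res <- segment_bird(img, detect_roi(img))
  expect_lt(abs(res$pixel_count - r$pixel_count) / r$pixel_count, 0.02)
})

test_that("an empty floor yields 'no bird detected'", {
  cam <- camera_geometry()
  r <- render_bird_image(adult_record(), camera = cam, seed = 7)
  img <- as.matrix((r$image[, , 1] + r$image[, , 2] + r$image[, , 3]) / 3 * 255)
  # paint the bird out with floor-level noise
  img[r$mask] <- pmax(rnorm(sum(r$mask), 15, 4), 0)
  expect_error(segment_bird(img, detect_roi(img)), "no bird detected")
})

test_that("replicate averaging follows the stated arithmetic", {
  rs <- average_replicates(rep(100, 5))
  expect_equal(rs$mean_count, 100)
  expect_equal(rs$cv, 0)
  expect_length(rs$flags, 0)
  expect_equal(average_replicates(c(90, 95, 100, 105, 110))$mean_count, 100)
  expect_equal(average_replicates(123)$mean_count, 123)
  expect_identical(average_replicates(c(10, 100, 1000))$flags, "high_replicate_cv")
  expect_error(average_replicates(numeric(0)), "at least one")
})

test_that("overlays are exported deterministically with flags annotated", {
  dir <- withr::local_tempdir()
  r <- render_bird_image(adult_record(), seed = 8)
  res <- segment_bird(r$image, detect_roi(r$image))
  p <- export_overlay(r$image, res, dir, "B001", 42, 1)
  expect_identical(basename(p), "B001_42_1.overlay.png")
  ov <- png::readPNG(p)
  expect_identical(dim(ov)[1:2], dim(r$mask))
  # flagged result: banner strip + sidecar text
  res$flags <- "border_contact"
  p2 <- export_overlay(r$image, res, dir, "B001", 42, 2)
  ov2 <- png::readPNG(p2)
  expect_true(all(ov2[1, , 1] == 1 & ov2[1, , 3] == 0))
  expect_identical(readLines(file.path(dir, "B001_42_2.flags.txt")),
                   "border_contact")
  expect_error(export_overlay(r$image, res, "/nonexistent/dir", "B001", 42, 3),
               "unwritable")
})

test_that("batch segmentation yields one row per input image", {
  dir <- withr::local_tempdir()
  odir <- withr::local_tempdir()
  paths <- character(3)
  for (i in 1:3) {
    r <- render_bird_image(adult_record(), replicate_index = i, seed = 21)
    paths[i] <- file.path(dir, sprintf("B001_42_%d.png", i))
    write_image_png(r$image, paths[i])
  }
  out <- segment_images(paths, overlay_dir = odir)
  expect_identical(nrow(out), 3L)
  expect_identical(out$replicate, 1:3)
  expect_true(all(out$pixel_count > 0))
  expect_length(list.files(odir, pattern = "overlay\\.png$"), 3L)
})

test_that("2x upscaling multiplies the count by 4 within 2%", {
  r <- render_bird_image(adult_record(), seed = 12)
  g <- (r$image[, , 1] + r$image[, , 2] + r$image[, , 3]) / 3 * 255
  base <- segment_bird(g, detect_roi(g))$pixel_count
  up <- kronecker(g, matrix(1, 2, 2))
  big <- segment_bird(up, detect_roi(up))$pixel_count
  expect_lt(abs(big - 4 * base) / (4 * base), 0.02)
})

test_that("translating the scene leaves the count nearly unchanged", {
  r <- render_bird_image(adult_record(), seed = 13)
  g <- (r$image[, , 1] + r$image[, , 2] + r$image[, , 3]) / 3 * 255
  base <- segment_bird(g, detect_roi(g))$pixel_count
  shifted <- cbind(g[, 9:ncol(g)], g[, 1:8])  # shift 8 px left
  mv <- segment_bird(shifted, detect_roi(shifted))$pixel_count
  expect_lt(abs(mv - base) / base, 0.01)
})

test_that("counts track ground truth across the growth range", {
  cfg <- cohort_config(n_birds = 4, seed = 31)
  coh <- generate_cohort(cfg)
  sel <- coh[coh$day %in% c(7, 21, 35, 42), ]
  errs <- vapply(seq_len(nrow(sel)), function(i) {
    r <- render_bird_image(sel[i, ], camera = cfg$camera, seed = 100 + i)
    res <- segment_bird(r$image, detect_roi(r$image))
    abs(res$pixel_count - r$pixel_count) / r$pixel_count
  }, 0)
  expect_lt(stats::median(errs), 0.03)
})
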