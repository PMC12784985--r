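#' Built-in log-pixel coefficient sets
#'
#' Default coefficient vectors of the log-linear image-based weight model
#' log LW = b0 + b1 Day + b2 log P + b3 (Day x log P), one row per sex
#' group. They drive the synthetic generator: pixel areas are produced by
#' inverting this relation, so a noise-free cohort refits exactly to these
#' coefficients. Logs are base 10.
#'
#' The back-transform is strictly increasing in P at fixed day only while
#' b2 + b3 * day > 0; this is asserted here for every built-in row across
#' days 1-42.
#'
#' @return data frame with columns `group`, `b0`, `b1`, `b2`, `b3`.
#' @export
default_pixel_coefficients <- function() {
  coefs <- data.frame(
    group = c("male", "female", "mixed"),
    b0 = c(-4.127, -4.380, -4.294),
    b1 = c(0.124, 0.127, 0.124),
    b2 = c(1.261, 1.318, 1.299),
    b3 = c(-0.020, -0.021, -0.021),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(coefs)))
    stopifnot(all(coefs$b2[i] + coefs$b3[i] * (1:42) > 0))
  coefs
}

#' Default per-sex Richards parameters for the synthetic cohort
#'
#' Asymptotic weights are sex-specific mature weights (males heavier); B, k
#' and m are chosen so trajectories run from ~30 g at day 1 to ~3400 g
#' (males) by day 42, the span typical of fast-growing broiler lines.
#'
#' @return named list with `male` and `female` [richards_params()].
#' @export
default_sex_params <- function() {
  list(
    male = richards_params(A = 6000.87, B = 200, k = 0.1327, m = 1),
    female = richards_params(A = 4788.52, B = 200, k = 0.1327, m = 1)
  )
}

#' Camera and reference-floor geometry
#'
#' Describes the image-acquisition setup: a rectangular black reference
#' floor of known physical size photographed from a fixed height, so that
#' the millimetre-per-pixel scale is constant across a cohort. The floor is
#' centred in the frame; `mm_per_px` is derived as
#' `floor_width_mm / floor_width_px`.
#'
#' @param floor_width_mm,floor_height_mm physical floor size (mm).
#' @param camera_height_m camera height above the floor (m); recorded for
#'   provenance, the scale is fully determined by the floor extent in
#'   pixels.
#' @param image_width_px,image_height_px rendered frame size.
#' @param floor_width_px width of the floor region in pixels (height is
#'   derived from the physical aspect ratio).
#' @return object of class `camera_geometry` with the floor rectangle in
#'   pixel coordinates (`floor_x0`, `floor_y0`, `floor_x1`, `floor_y1`,
#'   0-based, inclusive) and the derived `mm_per_px`.
#' @export
camera_geometry <- function(floor_width_mm = 600, floor_height_mm = 400,
                            camera_height_m = 1.0,
                            image_width_px = 320, image_height_px = 240,
                            floor_width_px = 300) {
  stopifnot(floor_width_mm > 0, floor_height_mm > 0, floor_width_px > 2)
  mm_per_px <- floor_width_mm / floor_width_px
  floor_height_px <- round(floor_height_mm / mm_per_px)
  if (floor_width_px > image_width_px || floor_height_px > image_height_px)
    stop("floor does not fit inside the image frame", call. = FALSE)
  x0 <- floor((image_width_px - floor_width_px) / 2)
  y0 <- floor((image_height_px - floor_height_px) / 2)
  structure(list(
    floor_width_mm = floor_width_mm, floor_height_mm = floor_height_mm,
    camera_height_m = camera_height_m,
    image_width_px = image_width_px, image_height_px = image_height_px,
    floor_width_px = floor_width_px, floor_height_px = floor_height_px,
    floor_x0 = x0, floor_y0 = y0,
    floor_x1 = x0 + floor_width_px - 1, floor_y1 = y0 + floor_height_px - 1,
    mm_per_px = mm_per_px
  ), class = "camera_geometry")
}

#' Synthetic-cohort configuration
#'
#' The stated measurement design: `n_birds` birds (half male), measured
#' daily for `n_days` days, with `replicate_images` top-view photographs
#' per bird-day. Weight trajectories follow the Richards curve with
#' bird-level log-normal perturbation of (A, k) and day-level
#' multiplicative log-normal noise; back length/width follow allometric
#' power laws L = alpha * LW^beta * (1 + eps); pixel areas invert the
#' log-linear day/log-pixel relation of [default_pixel_coefficients()].
#'
#' @param n_birds number of birds (default 100).
#' @param sex_ratio fraction of males (default 0.5). Sexes are interleaved
#'   deterministically along the bird index, so enlarging the cohort never
#'   reassigns an existing bird's sex.
#' @param n_days days of daily measurement (default 42).
#' @param replicate_images images per bird-day (default 5).
#' @param noise_cv_weight CV of the day-level multiplicative weight noise
#'   (default 0.03). Zero is allowed (noise-free mode); negative rejected.
#' @param morphometric_noise_cv CV of length/width noise (default 0.02).
#' @param pixel_noise_cv CV of multiplicative pixel-area noise (default 0.02).
#' @param bird_cv_A,bird_cv_k CVs of the bird-level log-normal random
#'   effects on the Richards A and k (defaults 0.08 and 0.03; flock-level
#'   heterogeneity of mature size and growth rate).
#' @param seed integer RNG seed; per-bird sub-seeds are derived from it so
#'   enlarging the cohort never reshuffles existing birds.
#' @param sex_params named list (`male`, `female`) of [richards_params()].
#' @param pixel_equation which coefficient row generates pixel areas:
#'   `"by_sex"` (default; each bird uses its own sex's row) or one of
#'   `"male"`, `"female"`, `"mixed"` to force a single equation.
#' @param log_base base of the generating logs, 10 (default) or exp(1).
#' @param alpha_length,beta_length,alpha_width,beta_width allometric
#'   coefficients mapping live weight (g) to back length/width (mm);
#'   defaults beta = 1/3 (linear dimension vs. mass) with alpha calibrated
#'   so mid-growth means sit near 143 mm x 104 mm.
#' @param camera a [camera_geometry()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_birds = 100, sex_ratio = 0.5, n_days = 42,
                          replicate_images = 5,
                          noise_cv_weight = 0.03,
                          morphometric_noise_cv = 0.02,
                          pixel_noise_cv = 0.02,
                          bird_cv_A = 0.08, bird_cv_k = 0.03,
                          seed = 1L,
                          sex_params = default_sex_params(),
                          pixel_equation = c("by_sex", "male", "female", "mixed"),
                          log_base = 10,
                          alpha_length = 14.0, beta_length = 1 / 3,
                          alpha_width = 10.3, beta_width = 1 / 3,
                          camera = camera_geometry()) {
  pixel_equation <- match.arg(pixel_equation)
  stopifnot(n_birds >= 1, n_days >= 1, replicate_images >= 1,
            sex_ratio >= 0, sex_ratio <= 1)
  for (cv in c(noise_cv_weight, morphometric_noise_cv, pixel_noise_cv,
               bird_cv_A, bird_cv_k))
    if (!is.numeric(cv) || cv < 0)
      stop("noise CVs must be non-negative", call. = FALSE)
  if (!all(c("male", "female") %in% names(sex_params)))
    stop("sex_params must contain male and female entries", call. = FALSE)
  coefs <- default_pixel_coefficients()
  used <- if (pixel_equation == "by_sex") c("male", "female") else pixel_equation
  for (g in used) {
    row <- coefs[coefs$group == g, ]
    den <- row$b2 + row$b3 * seq_len(n_days)
    if (any(den <= 0))
      stop(sprintf(
        "pixel-model denominator b2 + b3*day is non-positive for group %s within 1..%d",
        g, n_days), call. = FALSE)
  }
  structure(list(
    n_birds = as.integer(n_birds), sex_ratio = sex_ratio,
    n_days = as.integer(n_days), replicate_images = as.integer(replicate_images),
    noise_cv_weight = noise_cv_weight,
    morphometric_noise_cv = morphometric_noise_cv,
    pixel_noise_cv = pixel_noise_cv,
    bird_cv_A = bird_cv_A, bird_cv_k = bird_cv_k,
    seed = as.integer(seed), sex_params = sex_params,
    pixel_equation = pixel_equation, log_base = log_base,
    alpha_length = alpha_length, beta_length = beta_length,
    alpha_width = alpha_width, beta_width = beta_width,
    camera = camera
  ), class = "cohort_config")
}

# multiplicative log-normal factor with given CV (exact: sdlog from CV)
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sdlog))
}

bird_seed <- function(cohort_seed, bird_index) {
  (abs(cohort_seed) + 9973L * bird_index) %% 2147483647L
}

#' Generate a synthetic broiler cohort
#'
#' Emits one record per bird per day: live weight along a Richards
#' trajectory with bird- and day-level noise, allometric back length and
#' width, the ground-truth projected body area, and a pixel area obtained
#' by inverting log P = (log LW - b0 - b1 Day) / (b2 + b3 Day) with
#' multiplicative noise. Deterministic given the config (each bird draws
#' from its own sub-seeded stream).
#'
#' @param config a [cohort_config()].
#' @return data frame of class `bird_cohort` with columns `bird_id`, `sex`,
#'   `day`, `back_length_mm`, `back_width_mm`, `live_weight_g`,
#'   `pixel_area`, `true_area_mm2`; exactly `n_birds * n_days` rows.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  coefs <- default_pixel_coefficients()
  days <- seq_len(config$n_days)
  logb <- config$log_base

  # interleaved deterministic sex assignment: bird i is male iff the male
  # quota increases at i; stable under enlarging the cohort
  is_male <- ceiling(seq_len(config$n_birds) * config$sex_ratio) >
    ceiling((seq_len(config$n_birds) - 1) * config$sex_ratio)

  rows <- vector("list", config$n_birds)
  for (i in seq_len(config$n_birds)) {
    sex <- if (is_male[i]) "male" else "female"
    p <- config$sex_params[[sex]]
    set.seed(bird_seed(config$seed, i))
    A_i <- p$A * lognormal_factor(1, config$bird_cv_A)
    k_i <- p$k * lognormal_factor(1, config$bird_cv_k)
    params_i <- richards_params(A_i, p$B, k_i, p$m)
    lw_model <- richards_evaluate(params_i, days)
    lw <- lw_model * lognormal_factor(config$n_days, config$noise_cv_weight)
    len <- config$alpha_length * lw^config$beta_length *
      (1 + stats::rnorm(config$n_days, 0, config$morphometric_noise_cv))
    wid <- config$alpha_width * lw^config$beta_width *
      (1 + stats::rnorm(config$n_days, 0, config$morphometric_noise_cv))

    # pixel area reflects the bird's model-scale size: invert the log-pixel
    # relation at the noise-free trajectory weight, so day-level weight
    # noise becomes residual scatter with constant CV (RMSE grows with
    # age, MAPE stays flat)
    eq_group <- if (config$pixel_equation == "by_sex") sex else config$pixel_equation
    cr <- coefs[coefs$group == eq_group, ]
    log_p <- (log(lw_model, base = logb) - cr$b0 - cr$b1 * days) /
      (cr$b2 + cr$b3 * days)
    pixel <- logb^log_p * lognormal_factor(config$n_days, config$pixel_noise_cv)

    rows[[i]] <- data.frame(
      bird_id = sprintf("B%03d", i), sex = sex, day = days,
      back_length_mm = len, back_width_mm = wid, live_weight_g = lw,
      pixel_area = pixel,
      true_area_mm2 = pi / 4 * len * wid,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(nrow(out) == config$n_birds * config$n_days,
            all(out$live_weight_g > 0))
  class(out) <- c("bird_cohort", "data.frame")
  out
}

#' Write / read bird-day records as CSV
#'
#' The on-disk interchange format is a plain CSV with header
#' `bird_id,sex,day,back_length_mm,back_width_mm,live_weight_g,pixel_area`
#' (the synthetic-only `true_area_mm2` column is not part of the format and
#' is dropped on write).
#'
#' @param records a cohort data frame.
#' @param path CSV file path.
#' @return `read_bird_records()` returns the records data frame.
#' @export
write_bird_records <- function(records, path) {
  cols <- c("bird_id", "sex", "day", "back_length_mm", "back_width_mm",
            "live_weight_g", "pixel_area")
  stopifnot(all(cols %in% names(records)))
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bird_records
#' @export
read_bird_records <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "sex", "day", "live_weight_g")
  if (!all(need %in% names(out)))
    stop("records file lacks required columns", call. = FALSE)
  out
}
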