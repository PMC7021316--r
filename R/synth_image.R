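#' Parameters for a synthetic duplex ISH micrograph
#'
#' Describes one simulated brightfield field of view: a textured hematoxylin
#' counterstain with an elliptical epithelial region (the ROI) surrounded by
#' paler stroma, sparse anti-aliased circular chromogen dots of two colours
#' (blue target, fast-red housekeeping), optional tight clustering of target
#' dots (which merges under detection, emulating the undercount on strongly
#' expressing tissue), and an optional diffuse fast-red haze emulating
#' endogenous-phosphatase background.
#'
#' Densities are expressed as dots per 1000 ROI pixels and realized as
#' deterministic counts (`round(density * roi_area / 1000)`); housekeeping
#' dots are additionally scattered in the stroma at half density, since the
#' reference transcript is expressed tissue-wide while counting is
#' restricted to the epithelial ROI. `target_count`/`housekeeping_count`
#' override the density-derived in-ROI counts directly.
#'
#' @param height,width image size in pixels.
#' @param epithelial_fraction fraction of the frame covered by the
#'   epithelial ellipse, in (0, 1].
#' @param target_density,housekeeping_density dots per 1000 ROI pixels.
#' @param dot_radius_mean,dot_radius_sd dot radius distribution in pixels.
#' @param target_color,housekeeping_color,counterstain_color sRGB triples.
#' @param cluster_fraction fraction of target dots placed in tight clusters.
#' @param cluster_size dots per cluster.
#' @param red_background_level diffuse fast-red haze amplitude in \[0, 1\].
#' @param noise_sd per-pixel Gaussian sensor noise, 8-bit intensity units.
#' @param target_count,housekeeping_count optional explicit in-ROI counts.
#' @param seed integer; the same (params, seed) gives bit-identical output.
#' @return validated `image_params` list.
#' @export
image_params <- function(height = 512L, width = 512L,
                         epithelial_fraction = 0.45,
                         target_density = 0.4, housekeeping_density = 0.15,
                         dot_radius_mean = 3, dot_radius_sd = 0.5,
                         target_color = c(60, 90, 110),
                         housekeeping_color = c(240, 120, 140),
                         counterstain_color = c(160, 140, 190),
                         cluster_fraction = 0, cluster_size = 5L,
                         red_background_level = 0, noise_sd = 3,
                         target_count = NULL, housekeeping_count = NULL,
                         seed = NULL) {
  p <- list(height = as.integer(height), width = as.integer(width),
            epithelial_fraction = epithelial_fraction,
            target_density = target_density,
            housekeeping_density = housekeeping_density,
            dot_radius_mean = dot_radius_mean, dot_radius_sd = dot_radius_sd,
            target_color = as.numeric(target_color),
            housekeeping_color = as.numeric(housekeeping_color),
            counterstain_color = as.numeric(counterstain_color),
            cluster_fraction = cluster_fraction,
            cluster_size = as.integer(cluster_size),
            red_background_level = red_background_level, noise_sd = noise_sd,
            target_count = target_count,
            housekeeping_count = housekeeping_count, seed = seed)
  if (p$height < 8L || p$width < 8L)
    abort_config("image must be at least 8 x 8 pixels")
  if (p$epithelial_fraction <= 0 || p$epithelial_fraction > 1)
    abort_config("epithelial_fraction must be in (0, 1]")
  if (p$target_density < 0 || p$housekeeping_density < 0)
    abort_config("densities must be >= 0")
  if (p$dot_radius_mean <= 0 || p$dot_radius_sd < 0)
    abort_config("dot radii must be positive")
  for (col in list(p$target_color, p$housekeeping_color, p$counterstain_color))
    if (length(col) != 3L || any(col < 0) || any(col > 255))
      abort_config("colors must be sRGB triples in [0, 255]")
  if (p$cluster_fraction < 0 || p$cluster_fraction > 1)
    abort_config("cluster_fraction must be in [0, 1]")
  if (p$cluster_size < 2L) abort_config("cluster_size must be >= 2")
  if (p$red_background_level < 0 || p$red_background_level > 1)
    abort_config("red_background_level must be in [0, 1]")
  if (p$noise_sd < 0) abort_config("noise_sd must be >= 0")
  structure(p, class = "image_params")
}

#' Generate one synthetic duplex ISH micrograph with ground truth
#'
#' @param params an [image_params()].
#' @return list with `image` (an [as_rgb_image()]) and `truth`, a
#'   `ground_truth` list carrying `target_centers` / `housekeeping_centers`
#'   (matrices of (row, col)), `roi_mask`, the in-ROI counts and
#'   `true_ratio` (target / housekeeping; `NA` when the denominator is 0).
#' @examples
#' g <- generate_image(image_params(height = 96, width = 96, seed = 1))
#' g$truth$true_target_count
#' @export
generate_image <- function(params) {
  if (!inherits(params, "image_params")) params <- do.call(image_params, params)
  p <- params
  if (min(p$height, p$width) < 4 * p$dot_radius_mean)
    abort_data("image too small to hold a single dot at dot_radius_mean")
  with_seed(p$seed, {
    h <- p$height; w <- p$width
    roi <- ellipse_mask(h, w, p$epithelial_fraction)
    roi_area <- sum(roi)
    if (roi_area == 0L) abort_data("ROI has zero area")

    n_t <- if (!is.null(p$target_count)) as.integer(p$target_count)
           else as.integer(round(p$target_density * roi_area / 1000))
    n_h <- if (!is.null(p$housekeeping_count)) as.integer(p$housekeeping_count)
           else as.integer(round(p$housekeeping_density * roi_area / 1000))
    n_h_stroma <- as.integer(round(0.5 * n_h * (h * w - roi_area) /
                                     max(roi_area, 1L)))

    roi_idx <- which(roi)
    stroma_idx <- which(!roi)

    # target dots: singles plus tight clusters
    n_clustered <- as.integer(round(p$cluster_fraction * n_t))
    n_single <- n_t - n_clustered
    tc <- place_uniform(roi_idx, n_single, h)
    if (n_clustered > 0L) {
      n_clusters <- ceiling(n_clustered / p$cluster_size)
      sizes <- rep(p$cluster_size, n_clusters)
      sizes[n_clusters] <- n_clustered - p$cluster_size * (n_clusters - 1L)
      for (s in sizes) {
        ctr <- place_uniform(roi_idx, 1L, h)
        mem <- cbind(ctr[1L] + rnorm(s, sd = 0.9 * p$dot_radius_mean),
                     ctr[2L] + rnorm(s, sd = 0.9 * p$dot_radius_mean))
        mem[, 1L] <- pmin(pmax(mem[, 1L], 1), h)
        mem[, 2L] <- pmin(pmax(mem[, 2L], 1), w)
        tc <- rbind(tc, mem)
      }
    }
    hc <- rbind(place_uniform(roi_idx, n_h, h),
                place_uniform(stroma_idx, n_h_stroma, h))

    # counterstain background: epithelium denser than stroma, a soft
    # (blurred) tissue transition and a weak low-frequency mottle; both are
    # kept out of the spot-detection band (scale <= 3) on purpose, as real
    # counterstain texture at 400x is smooth relative to chromogen dots
    img <- array(0, dim = c(h, w, 3L))
    stroma_color <- 0.45 * p$counterstain_color + 0.55 * 255
    edge <- roi + 0
    if (min(h, w) >= 17L) edge <- b3_smooth(b3_smooth(edge, 1L), 2L)
    tex <- texture_field(h, w) * 6
    for (ch in 1:3) {
      plane <- edge * p$counterstain_color[ch] + (1 - edge) * stroma_color[ch]
      img[, , ch] <- plane + tex
    }

    if (p$red_background_level > 0) {
      haze <- p$red_background_level *
        (0.25 + 0.2 * (texture_field(h, w) + 1) / 2)
      for (ch in 1:3)
        img[, , ch] <- haze * p$housekeeping_color[ch] + (1 - haze) * img[, , ch]
    }

    img <- draw_dots(img, tc, p$target_color, p$dot_radius_mean, p$dot_radius_sd)
    img <- draw_dots(img, hc, p$housekeeping_color, p$dot_radius_mean,
                     p$dot_radius_sd)

    if (p$noise_sd > 0)
      img <- img + array(rnorm(length(img), sd = p$noise_sd), dim = dim(img))
    img <- round(pmin(pmax(img, 0), 255))

    in_roi <- function(centers) {
      if (nrow(centers) == 0L) return(0L)
      sum(mask_lookup(roi, centers[, 1L], centers[, 2L]))
    }
    tt <- in_roi(tc); th <- in_roi(hc)
    truth <- structure(list(
      target_centers = tc, housekeeping_centers = hc, roi_mask = roi,
      true_target_count = tt, true_housekeeping_count = th,
      true_ratio = if (th > 0L) tt / th else NA_real_), class = "ground_truth")
    list(image = as_rgb_image(img), truth = truth)
  })
}

# centered ellipse (aspect 1.25) whose area approximates fraction * h * w
ellipse_mask <- function(h, w, fraction) {
  a <- sqrt(fraction * h * w / (pi * 1.25))
  b <- 1.25 * a
  a <- min(a, 0.49 * h); b <- min(b, 0.49 * w)
  r <- (seq_len(h) - (h + 1) / 2) / a
  c <- (seq_len(w) - (w + 1) / 2) / b
  outer(r^2, c^2, `+`) <= 1
}

place_uniform <- function(pool_idx, n, h) {
  if (n <= 0L || length(pool_idx) == 0L)
    return(matrix(numeric(0), 0L, 2L))
  px <- pool_idx[sample.int(length(pool_idx), n, replace = TRUE)]
  cbind(((px - 1L) %% h) + 1L + runif(n, -0.49, 0.49),
        ((px - 1L) %/% h) + 1L + runif(n, -0.49, 0.49))
}

# smoothed white noise, normalized to sd 1; smoothing steps push the
# mottle below the dot-detection scales
texture_field <- function(h, w) {
  z <- matrix(rnorm(h * w), h, w)
  if (min(h, w) >= 33L) z <- b3_smooth(b3_smooth(z, 4L), 8L)
  else if (min(h, w) >= 9L) z <- b3_smooth(z, 2L)
  z / max(sd(z), 1e-12)
}

# anti-aliased discs with a soft (logistic ~ Gaussian) edge falloff,
# alpha-blended over the background
draw_dots <- function(img, centers, color, r_mean, r_sd) {
  if (nrow(centers) == 0L) return(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  radii <- pmax(1, rnorm(nrow(centers), r_mean, r_sd))
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1L]; c0 <- centers[i, 2L]; R <- radii[i]
    rr <- max(1L, floor(r0 - R - 2)):min(h, ceiling(r0 + R + 2))
    cc <- max(1L, floor(c0 - R - 2)):min(w, ceiling(c0 + R + 2))
    d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
    alpha <- 0.92 / (1 + exp((d - R) / 0.6))
    for (ch in 1:3)
      img[rr, cc, ch] <- alpha * color[ch] + (1 - alpha) * img[rr, cc, ch]
  }
  img
}
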