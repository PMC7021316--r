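#' Spot detection configuration
#'
#' Settings for the wavelet spot detector, mirroring the knobs of the
#' interactive detectors used on chromogenic ISH images. `mode = "dark"`
#' detects local minima (blue chromogen on a bright background), `"bright"`
#' detects maxima (fast red in the a* channel). Detection operates on the
#' a-trous detail planes listed in `scales` (scale 2 suits dot radii of
#' roughly 2-6 px); a pixel is significant when its detail coefficient
#' exceeds `sensitivity` times a robust noise scale (MAD-based) of that
#' plane, across all selected scales.
#'
#' @param mode `"dark"` or `"bright"`.
#' @param scales integer vector of wavelet scales (each >= 1).
#' @param sensitivity positive threshold multiplier k; larger is stricter.
#' @param min_area,max_area component area bounds in pixels.
#' @param roi_required if `TRUE`, an empty ROI is an error and spots whose
#'   centroid falls outside the ROI are discarded.
#' @return a `detection_config` list.
#' @export
detection_config <- function(mode = c("dark", "bright"), scales = 2L,
                             sensitivity = 3.0, min_area = 5L,
                             max_area = 2000L, roi_required = TRUE) {
  mode <- match.arg(mode)
  scales <- as.integer(scales)
  if (length(scales) == 0L || anyNA(scales) || any(scales < 1L))
    abort_config("scales must be a nonempty vector of integers >= 1")
  if (!is.numeric(sensitivity) || sensitivity <= 0)
    abort_config("sensitivity must be > 0")
  if (min_area <= 0 || min_area > max_area)
    abort_config("need 0 < min_area <= max_area")
  structure(list(mode = mode, scales = sort(unique(scales)),
                 sensitivity = sensitivity, min_area = as.integer(min_area),
                 max_area = as.integer(max_area),
                 roi_required = isTRUE(roi_required)),
            class = "detection_config")
}

#' Detect chromogen dots in a scalar image
#'
#' Applies the a-trous transform ([atrous_wavelet()]), thresholds the
#' selected detail planes at `sensitivity` times each plane's robust noise
#' scale (`mad/0.6745`), intersects significance across scales, labels
#' 8-connected components, filters them by area, and keeps components whose
#' centroid lies inside the ROI. Dark mode negates the image first so that
#' dark dots yield positive coefficients. Touching dots merge into a single
#' component; dense clusters are therefore counted as fewer spots than true
#' dots, reproducing the undercount seen on strongly expressing tissue.
#'
#' @param img numeric matrix (e.g. from [tritanope_dark_channel()] or
#'   [lab_a_channel()]).
#' @param roi logical matrix of the same shape, or `NULL` for the whole
#'   frame.
#' @param cfg a [detection_config()].
#' @param image_id optional identifier carried into the result.
#' @return a `spot_set`: data.frame with columns `row`, `col` (centroid,
#'   1-based pixel coordinates), `area`, `score` (peak summed detail
#'   coefficient), plus attributes `channel`/`image_id`/`config`.
#' @export
detect_spots <- function(img, roi = NULL, cfg = detection_config(),
                         image_id = NA_character_) {
  if (!is.matrix(img)) abort_data("detect_spots() needs a numeric matrix")
  if (!is.null(roi)) {
    if (!is.logical(roi)) roi <- roi > 0
    if (!identical(dim(roi), dim(img)))
      abort_data("ROI mask shape must equal image shape")
    if (cfg$roi_required && !any(roi))
      abort_data("ROI is empty: no region to count in (not zero spots)")
  }
  x <- if (cfg$mode == "dark") -img else img
  # one-sided detection: clip the working channel at the background median
  # so blobs of the *opposite* sign (the other chromogen: red dots in the
  # dark channel, blue dots in the a* channel) are flattened and cannot
  # throw positive wavelet rings that mimic spots
  bg <- stats::median(if (is.null(roi)) x else x[roi])
  w_raw <- atrous_wavelet(x, max(cfg$scales))
  w <- atrous_wavelet(pmax(x, bg), max(cfg$scales))
  sig <- NULL
  score_plane <- 0
  for (s in cfg$scales) {
    plane <- w$details[[s]]
    # noise scale from the unclipped plane: clipping flattens half the
    # field and would collapse the MAD estimate
    sigma <- stats::mad(as.vector(w_raw$details[[s]]))
    m <- plane > cfg$sensitivity * sigma
    sig <- if (is.null(sig)) m else (sig & m)
    score_plane <- score_plane + plane
  }
  x <- pmax(x, bg)
  # spot cores additionally sit strictly above background
  sig <- sig & (x > bg)
  # morphological closing (3x3): a blob much larger than the detection
  # scale yields a boundary ring of significant pixels; noise can break
  # the ring into arcs that would each count as a spot. Closing reconnects
  # them so one merged blob stays one component.
  sig <- erode3(dilate3(sig))
  spots <- empty_spots()
  if (any(sig)) {
    comp <- label_components(sig)
    keep <- lengths(comp) >= cfg$min_area & lengths(comp) <= cfg$max_area
    comp <- comp[keep]
    if (length(comp)) {
      h <- nrow(img)
      rows <- vapply(comp, function(i) mean(((i - 1L) %% h) + 1L), 0)
      cols <- vapply(comp, function(i) mean(((i - 1L) %/% h) + 1L), 0)
      spots <- data.frame(row = rows, col = cols,
                          area = lengths(comp),
                          score = vapply(comp, function(i) max(score_plane[i]), 0))
      if (!is.null(roi) && cfg$roi_required)
        spots <- spots[mask_lookup(roi, spots$row, spots$col), , drop = FALSE]
      rownames(spots) <- NULL
    }
  }
  structure(spots, class = c("spot_set", "data.frame"),
            channel = if (cfg$mode == "dark") "target" else "housekeeping",
            image_id = image_id, config = cfg)
}

#' @rdname detect_spots
#' @param spots a `spot_set`.
#' @return `count_in_roi()`: integer count of spots whose centroid lies
#'   inside the mask.
#' @export
count_in_roi <- function(spots, roi) {
  if (nrow(spots) == 0L) return(0L)
  stopifnot(is.matrix(roi))
  if (!is.logical(roi)) roi <- roi > 0
  sum(mask_lookup(roi, spots$row, spots$col))
}

#' @rdname detect_spots
#' @param file path for `write_spots_csv()`; the detection configuration is
#'   serialized into comment header lines for provenance.
#' @export
write_spots_csv <- function(spots, file) {
  cfg <- attr(spots, "config")
  hdr <- c(sprintf("# channel: %s", attr(spots, "channel")),
           sprintf("# image_id: %s", attr(spots, "image_id")),
           if (!is.null(cfg)) sprintf(
             "# mode=%s scales=%s sensitivity=%g min_area=%d max_area=%d",
             cfg$mode, paste(cfg$scales, collapse = ","), cfg$sensitivity,
             cfg$min_area, cfg$max_area))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(spots), con, row.names = FALSE)
  invisible(file)
}

empty_spots <- function() {
  data.frame(row = numeric(0), col = numeric(0), area = integer(0),
             score = numeric(0))
}

# centroid membership: nearest-pixel lookup, clamped to bounds
mask_lookup <- function(mask, row, col) {
  r <- pmin(pmax(round(row), 1L), nrow(mask))
  c <- pmin(pmax(round(col), 1L), ncol(mask))
  mask[cbind(r, c)]
}

shift_or <- function(m, combine = `|`) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    sh <- matrix(if (identical(combine, `|`)) FALSE else TRUE, h, w)
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    sh[rs, cs] <- m[rs - dr, cs - dc]
    out <- combine(out, sh)
  }
  out
}

dilate3 <- function(m) shift_or(m, `|`)
erode3 <- function(m) shift_or(m, `&`)

# 8-connected components of a logical matrix; returns a list of
# column-major pixel index vectors, one per component.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(list())
  id <- matrix(0L, h, w)
  id[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- d[1L]; dc <- d[2L]
    ri <- seq_len(h - dr)
    ci <- if (dc >= 0L) seq_len(w - dc) else seq.int(1L - dc, w)
    both <- mask[ri, ci, drop = FALSE] & mask[ri + dr, ci + dc, drop = FALSE]
    if (any(both)) {
      a <- id[ri, ci, drop = FALSE][both]
      b <- id[ri + dr, ci + dc, drop = FALSE][both]
      edges <- c(edges, rbind(a, b))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  unname(split(idx, memb))
}
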