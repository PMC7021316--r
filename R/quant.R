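#' Quality-control thresholds for per-image quantification
#'
#' The study excluded samples whose red (housekeeping) channel failed from
#' RNA degradation or showed strong diffuse fast-red background from
#' endogenous alkaline phosphatase, without stating numeric rules; these
#' thresholds make the exclusions operational. An image is flagged
#' `red_failure` when it yields fewer than `min_housekeeping` housekeeping
#' dots, and `red_high_background` when more than `background_fraction` of
#' ROI pixels exceed `a_threshold` on the CIELAB a* channel (diffuse redness
#' rather than discrete dots).
#'
#' @param min_housekeeping minimum housekeeping dots per image.
#' @param a_threshold a* level above which a pixel counts as red.
#' @param background_fraction ROI fraction of red pixels that trips the
#'   high-background flag.
#' @param min_valid_images minimum unflagged images for a sample to survive
#'   aggregation (3 of the nominal 5).
#' @return a `quant_config` list.
#' @export
quant_config <- function(min_housekeeping = 5L, a_threshold = 10,
                         background_fraction = 0.25, min_valid_images = 3L) {
  if (min_housekeeping < 0) abort_config("min_housekeeping must be >= 0")
  if (background_fraction <= 0 || background_fraction > 1)
    abort_config("background_fraction must be in (0, 1]")
  if (min_valid_images < 1L) abort_config("min_valid_images must be >= 1")
  structure(list(min_housekeeping = as.integer(min_housekeeping),
                 a_threshold = a_threshold,
                 background_fraction = background_fraction,
                 min_valid_images = as.integer(min_valid_images)),
            class = "quant_config")
}

#' Quantify one duplex ISH image
#'
#' Runs both chromogen channels of the automated pipeline on a single
#' micrograph: target dots are counted on the tritanope luminance channel
#' with dark-mode detection, housekeeping dots on the CIELAB a* channel of
#' the tritanope image with bright-mode detection, both restricted to the
#' epithelial ROI, and QC flags are set per [quant_config()].
#'
#' @param img an [as_rgb_image()] micrograph.
#' @param roi logical ROI mask of the same shape.
#' @param cfg_target dark-mode [detection_config()].
#' @param cfg_housekeeping bright-mode [detection_config()].
#' @param qc a [quant_config()].
#' @param image_id identifier carried into the result.
#' @return an `image_quant` list: `image_id`, `n_target`, `n_housekeeping`,
#'   `image_ratio` (`NA` when the housekeeping count is 0) and `qc_flags`
#'   (character vector, subset of `red_failure`, `red_high_background`,
#'   `empty_roi`).
#' @export
quantify_image <- function(img, roi,
                           cfg_target = detection_config("dark"),
                           cfg_housekeeping = detection_config("bright"),
                           qc = quant_config(), image_id = NA_character_) {
  img <- as_rgb_image(unclass(img))
  if (!is.matrix(roi)) abort_data("ROI must be a matrix")
  if (!is.logical(roi)) roi <- roi > 0
  if (!identical(dim(roi), dim(img)[1:2]))
    abort_data("image and ROI mask shapes differ")

  if (!any(roi))
    return(image_quant(image_id, 0L, 0L, qc_flags = "empty_roi"))

  trit <- simulate_tritanopia(img)
  dark <- tritanope_dark_channel(trit, simulate = FALSE)
  astar <- lab_a_channel(trit)

  n_t <- nrow(detect_spots(dark, roi, cfg_target, image_id))
  n_h <- nrow(detect_spots(astar, roi, cfg_housekeeping, image_id))

  flags <- character(0)
  if (n_h < qc$min_housekeeping) flags <- c(flags, "red_failure")
  if (mean(astar[roi] > qc$a_threshold) > qc$background_fraction)
    flags <- c(flags, "red_high_background")
  image_quant(image_id, n_t, n_h, qc_flags = flags)
}

#' @rdname quantify_image
#' @param n_target,n_housekeeping dot counts.
#' @param qc_flags character vector of QC flags.
#' @export
image_quant <- function(image_id = NA_character_, n_target, n_housekeeping,
                        qc_flags = character(0)) {
  n_target <- as.integer(n_target); n_housekeeping <- as.integer(n_housekeeping)
  if (n_target < 0L || n_housekeeping < 0L) abort_data("counts must be >= 0")
  structure(list(image_id = image_id, n_target = n_target,
                 n_housekeeping = n_housekeeping,
                 image_ratio = if (n_housekeeping > 0L)
                   n_target / n_housekeeping else NA_real_,
                 qc_flags = qc_flags),
            class = "image_quant")
}

#' Aggregate per-image quantifications into a sample-level ISH ratio
#'
#' The sample ratio is the arithmetic mean of per-image target/housekeeping
#' ratios over QC-passing images, following the study's averaging of five
#' representative fields per sample. The alternative pooled-count convention
#' (sum of targets over sum of housekeeping) is available via `method`.
#' Samples with fewer than `min_valid_images` usable images are excluded and
#' carry no ratio.
#'
#' @param quants list of [image_quant()] results for one sample.
#' @param metadata named list or one-row data.frame of sample metadata
#'   (e.g. `group`, `diagnosis`, `grade`, `lymphatic_invasion`).
#' @param sample_id sample identifier.
#' @param method `"mean_of_ratios"` (default) or `"pooled"`.
#' @param qc a [quant_config()]; only `min_valid_images` is used here.
#' @return a `sample_quant` list: `sample_id`, `ish_ratio` (`NA` when
#'   excluded), `n_images_used`, `excluded`, `reason`, `metadata`.
#' @export
aggregate_sample <- function(quants, metadata = list(),
                             sample_id = NA_character_,
                             method = c("mean_of_ratios", "pooled"),
                             qc = quant_config()) {
  method <- match.arg(method)
  if (length(quants) == 0L) abort_data("no image quantifications supplied")
  stopifnot(all(vapply(quants, inherits, TRUE, "image_quant")))
  flagged <- vapply(quants, function(q) length(q$qc_flags) > 0L, TRUE)
  ratio <- vapply(quants, function(q) q$image_ratio, 0)
  valid <- !flagged & is.finite(ratio)
  n_used <- sum(valid)
  excluded <- n_used < qc$min_valid_images
  ish <- if (excluded) NA_real_
         else if (method == "mean_of_ratios") mean(ratio[valid])
         else sum(vapply(quants[valid], `[[`, 0L, "n_target")) /
              sum(vapply(quants[valid], `[[`, 0L, "n_housekeeping"))
  reason <- if (!excluded) NA_character_ else {
    fl <- unlist(lapply(quants, `[[`, "qc_flags"))
    if (length(fl)) paste(sort(unique(fl)), collapse = "+")
    else "too_few_valid_images"
  }
  structure(list(sample_id = sample_id, ish_ratio = ish,
                 n_images_used = n_used, excluded = excluded,
                 reason = reason, metadata = as.list(metadata)),
            class = "sample_quant")
}

#' Assemble per-sample quantifications into a cohort table
#'
#' @param samples list of [aggregate_sample()] results.
#' @return list with `table` (data.frame, one row per non-excluded sample:
#'   `sample_id`, `ish_ratio`, `n_images_used` and metadata columns) and
#'   `exclusions` (data.frame `sample_id`, `reason`).
#' @export
build_cohort_table <- function(samples) {
  stopifnot(all(vapply(samples, inherits, TRUE, "sample_quant")))
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) abort_data("duplicate sample ids in cohort")
  meta_cols <- c("group", "diagnosis", "grade", "lymphatic_invasion")
  row_of <- function(s) {
    md <- s$metadata
    cbind(data.frame(sample_id = s$sample_id, ish_ratio = s$ish_ratio,
                     n_images_used = s$n_images_used),
          as.data.frame(lapply(setNames(meta_cols, meta_cols), function(k)
            if (!is.null(md[[k]])) as.character(md[[k]]) else NA_character_)))
  }
  excluded <- vapply(samples, `[[`, TRUE, "excluded")
  tab <- do.call(rbind, lapply(samples[!excluded], row_of))
  if (is.null(tab)) {
    tab <- data.frame(sample_id = character(0), ish_ratio = numeric(0),
                      n_images_used = integer(0), group = character(0),
                      diagnosis = character(0), grade = character(0),
                      lymphatic_invasion = character(0))
  }
  excl <- data.frame(sample_id = ids[excluded],
                     reason = vapply(samples[excluded], `[[`, "", "reason"))
  rownames(tab) <- NULL
  list(table = tab, exclusions = excl)
}
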