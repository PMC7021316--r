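#' Parameters for a synthetic ISH cohort
#'
#' Describes a cohort of samples grouped by immunohistochemistry (IHC)
#' score, with per-group target/housekeeping ratio distributions. The
#' default groups reproduce the published per-IHC-score ratio summaries for
#' the full canine mammary tissue cohort: 1+ (n = 20) 2.51 +/- 0.52, 2+
#' (n = 24) 3.00 +/- 0.50, 3+ (n = 18) 3.81 +/- 0.62.
#'
#' Each sample's true ratio is drawn from Normal(ratio_mean, ratio_sd)
#' truncated below at `ratio_floor` (default 0.1; the smallest ratio ever
#' observed in the study was 1.521, so the floor only guards against
#' degenerate draws). Within a sample, each image receives a housekeeping
#' count ~ Poisson(`housekeeping_per_image_mean`) and a target count ~
#' Poisson(ratio x housekeeping count), so per-image ratios are noisy around
#' the sample ratio; the study does not report within-sample dispersion.
#' A `failure_rate` fraction of samples emulate the red-channel failure
#' mode: housekeeping counts collapse (count mode) or the image receives a
#' maximal diffuse fast-red haze plus degraded housekeeping staining (image
#' mode), so downstream QC flags and excludes them.
#'
#' @param groups data.frame with columns `group`, `n_samples`, `ratio_mean`,
#'   `ratio_sd`.
#' @param images_per_sample images per sample (the study used 5
#'   representative fields).
#' @param housekeeping_per_image_mean mean housekeeping dots per image.
#' @param rendering_mode `"count"` emits dot-count pairs directly;
#'   `"image"` renders full micrographs via [generate_image()].
#' @param failure_rate fraction of samples given the red-channel failure.
#' @param ratio_floor truncation floor for sampled true ratios.
#' @param image an [image_params()] template used in image mode.
#' @param seed integer seed.
#' @return validated `cohort_params` list.
#' @export
cohort_params <- function(groups = default_cohort_groups(),
                          images_per_sample = 5L,
                          housekeeping_per_image_mean = 25,
                          rendering_mode = c("count", "image"),
                          failure_rate = 0, ratio_floor = 0.1,
                          image = image_params(height = 256L, width = 256L),
                          seed = NULL) {
  rendering_mode <- match.arg(rendering_mode)
  groups <- as.data.frame(groups)
  need <- c("group", "n_samples", "ratio_mean", "ratio_sd")
  if (nrow(groups) == 0L) abort_config("group list must not be empty")
  if (!all(need %in% names(groups)))
    abort_config(paste("groups needs columns:", paste(need, collapse = ", ")))
  if (any(groups$n_samples < 1L)) abort_config("n_samples must be >= 1")
  if (any(groups$ratio_mean <= 0)) abort_config("ratio_mean must be > 0")
  if (any(groups$ratio_sd < 0)) abort_config("ratio_sd must be >= 0")
  if (images_per_sample < 1L) abort_config("images_per_sample must be >= 1")
  if (failure_rate < 0 || failure_rate > 1)
    abort_config("failure_rate must be in [0, 1]")
  structure(list(groups = groups,
                 images_per_sample = as.integer(images_per_sample),
                 housekeeping_per_image_mean = housekeeping_per_image_mean,
                 rendering_mode = rendering_mode, failure_rate = failure_rate,
                 ratio_floor = ratio_floor, image = image, seed = seed),
            class = "cohort_params")
}

#' @rdname cohort_params
#' @export
default_cohort_groups <- function() {
  data.frame(group = c("1+", "2+", "3+"),
             n_samples = c(20L, 24L, 18L),
             ratio_mean = c(2.51, 3.00, 3.81),
             ratio_sd = c(0.52, 0.50, 0.62))
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param params a [cohort_params()].
#' @return list with:
#' \describe{
#'   \item{metadata}{data.frame: `sample_id`, `group`, `diagnosis`, `grade`,
#'     `lymphatic_invasion`, `n_images`, `failed`, `true_ratio`. Diagnosis,
#'     grade and invasion are drawn with the marginal frequencies of the
#'     published cohort (14/6/42 non-neoplastic/benign/malignant; grades
#'     23/9/10 among malignant; 6/42 invasion) for downstream contingency
#'     tests.}
#'   \item{samples}{named list; in count mode each element is a data.frame
#'     (`image`, `n_target`, `n_housekeeping`), in image mode a list of
#'     [generate_image()] results.}
#' }
#' @examples
#' co <- generate_cohort(cohort_params(seed = 1))
#' head(co$metadata)
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  p <- params
  with_seed(p$seed, {
    g <- p$groups
    n_total <- sum(g$n_samples)
    grp <- rep(g$group, g$n_samples)
    mu <- rep(g$ratio_mean, g$n_samples)
    sigma <- rep(g$ratio_sd, g$n_samples)
    true_ratio <- mapply(rtrunc_norm, mu, sigma,
                         MoreArgs = list(floor = p$ratio_floor))
    ids <- sprintf("S%03d", seq_len(n_total))
    diagnosis <- sample(c("non-neoplastic", "benign", "malignant"), n_total,
                        replace = TRUE, prob = c(14, 6, 42) / 62)
    grade <- ifelse(diagnosis == "malignant",
                    sample(c("1", "2", "3"), n_total, replace = TRUE,
                           prob = c(23, 9, 10) / 42), NA_character_)
    invasion <- ifelse(diagnosis == "malignant" & runif(n_total) < 6 / 42,
                       "present", "absent")
    failed <- runif(n_total) < p$failure_rate

    samples <- vector("list", n_total)
    names(samples) <- ids
    for (i in seq_len(n_total)) {
      hk_mean <- if (failed[i]) 1.5 else p$housekeeping_per_image_mean
      n_h <- rpois(p$images_per_sample, hk_mean)
      n_t <- rpois(p$images_per_sample, true_ratio[i] * n_h)
      if (p$rendering_mode == "count") {
        samples[[i]] <- data.frame(image = seq_len(p$images_per_sample),
                                   n_target = n_t, n_housekeeping = n_h)
      } else {
        imgs <- vector("list", p$images_per_sample)
        for (j in seq_len(p$images_per_sample)) {
          ip <- p$image
          ip$target_count <- n_t[j]
          ip$housekeeping_count <- n_h[j]
          if (failed[i]) ip$red_background_level <- 1
          ip$seed <- sample.int(.Machine$integer.max, 1L)
          imgs[[j]] <- generate_image(ip)
        }
        samples[[i]] <- imgs
      }
    }
    list(metadata = data.frame(sample_id = ids, group = grp,
                               diagnosis = diagnosis, grade = grade,
                               lymphatic_invasion = invasion,
                               n_images = p$images_per_sample,
                               failed = failed, true_ratio = true_ratio),
         samples = samples)
  })
}

# normal truncated below at `floor` by resampling
rtrunc_norm <- function(mean, sd, floor) {
  for (i in 1:1000) {
    x <- rnorm(1L, mean, sd)
    if (x >= floor) return(x)
  }
  floor
}
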