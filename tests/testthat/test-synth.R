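test_that("ground-truth ratio follows the placed counts", {
  g <- generate_image(image_params(height = 200, width = 200,
                                   target_count = 40, housekeeping_count = 10,
                                   seed = 2))
  expect_equal(g$truth$true_target_count, 40L)
  expect_equal(g$truth$true_housekeeping_count, 10L)
  expect_equal(g$truth$true_ratio, 4.0)
})

test_that("density-derived counts follow the ROI area", {
  probe <- generate_image(image_params(height = 200, width = 200,
                                       target_density = 0,
                                       housekeeping_density = 0, seed = 1))
  area <- sum(probe$truth$roi_mask)
  g <- generate_image(image_params(height = 200, width = 200,
                                   target_density = 40000 / area,
                                   housekeeping_density = 10000 / area,
                                   seed = 3))
  expect_equal(g$truth$true_target_count, 40L)
  expect_equal(g$truth$true_housekeeping_count, 10L)
})

test_that("zero densities give a blank counterstain with zero counts", {
  g <- generate_image(image_params(height = 96, width = 96, target_density = 0,
                                   housekeeping_density = 0, seed = 9))
  expect_equal(g$truth$true_target_count, 0L)
  expect_equal(g$truth$true_housekeeping_count, 0L)
  expect_equal(nrow(g$truth$target_centers), 0L)
  expect_true(is.na(g$truth$true_ratio))
})

test_that("generation is deterministic: same seed, identical buffers", {
  p <- image_params(height = 512, width = 512, target_count = 25,
                    housekeeping_count = 25, seed = 17)
  g1 <- generate_image(p)
  g2 <- generate_image(p)
  expect_identical(unclass(g1$image), unclass(g2$image))
  expect_identical(g1$truth$target_centers, g2$truth$target_centers)
  expect_identical(g1$truth$housekeeping_centers, g2$truth$housekeeping_centers)
})

test_that("ground-truth counts equal centers inside the ROI for random draws", {
  set.seed(31)
  for (rep in 1:8) {
    g <- generate_image(image_params(
      height = 128, width = 128,
      target_density = runif(1, 0, 1.5),
      housekeeping_density = runif(1, 0, 0.8),
      cluster_fraction = sample(c(0, 0.5, 1), 1),
      seed = sample.int(1e6, 1)))
    tr <- g$truth
    expect_equal(tr$true_target_count,
                 nrow(centers_in_roi(tr$target_centers, tr$roi_mask)))
    expect_equal(tr$true_housekeeping_count,
                 nrow(centers_in_roi(tr$housekeeping_centers, tr$roi_mask)))
    if (tr$true_housekeeping_count > 0)
      expect_equal(tr$true_ratio,
                   tr$true_target_count / tr$true_housekeeping_count)
  }
})

test_that("degenerate geometries fail explicitly", {
  expect_error(generate_image(image_params(height = 10, width = 10,
                                           dot_radius_mean = 4, seed = 1)),
               "too small")
  expect_error(generate_image(image_params(height = 8, width = 8,
                                           epithelial_fraction = 1e-4,
                                           dot_radius_mean = 1.5, seed = 1)),
               "zero area")
  expect_error(image_params(epithelial_fraction = 0), "epithelial_fraction")
  expect_error(image_params(cluster_fraction = 2), "cluster_fraction")
})

test_that("zero-variance cohorts reproduce configured ratios exactly", {
  g <- data.frame(group = c("lo", "hi"), n_samples = c(3L, 3L),
                  ratio_mean = c(2.51, 3.81), ratio_sd = c(0, 0))
  co <- generate_cohort(cohort_params(groups = g, seed = 5))
  expect_equal(co$metadata$true_ratio, rep(c(2.51, 3.81), each = 3))
})

test_that("cohort generation validates inputs and is deterministic", {
  expect_error(cohort_params(groups = data.frame()), "empty")
  expect_error(cohort_params(groups = data.frame(group = "a", n_samples = 1,
                                                 ratio_mean = -1, ratio_sd = 0)),
               "ratio_mean")
  co1 <- generate_cohort(cohort_params(seed = 99))
  co2 <- generate_cohort(cohort_params(seed = 99))
  expect_identical(co1$metadata, co2$metadata)
  expect_identical(co1$samples, co2$samples)
})

test_that("group means recover configured values within the CLT bound", {
  co <- generate_cohort(cohort_params(seed = 8))
  cfg <- default_cohort_groups()
  for (i in seq_len(nrow(cfg))) {
    x <- co$metadata$true_ratio[co$metadata$group == cfg$group[i]]
    expect_lt(abs(mean(x) - cfg$ratio_mean[i]),
              3 * cfg$ratio_sd[i] / sqrt(cfg$n_samples[i]))
  }
})

test_that("failure_rate 1 leads to downstream exclusion of every sample", {
  co <- generate_cohort(cohort_params(failure_rate = 1, seed = 13))
  expect_true(all(co$metadata$failed))
  for (id in names(co$samples)) {
    sq <- aggregate_sample(quants_from_counts(co$samples[[id]]),
                           sample_id = id)
    expect_true(sq$excluded)
    expect_true(is.na(sq$ish_ratio))
    expect_match(sq$reason, "red_failure")
  }
})

test_that("the generator recovers configured moments at large n", {
  # the 2% band needs n where 2% covers >= 4 SE of the sample SD
  # (1/sqrt(2n) <= 0.5%), hence n = 20000 per group rather than 500
  g <- default_cohort_groups()
  g$n_samples <- rep(20000L, 3)
  co <- generate_cohort(cohort_params(groups = g, images_per_sample = 1,
                                      seed = 1))
  cfg <- default_cohort_groups()
  for (i in 1:3) {
    x <- co$metadata$true_ratio[co$metadata$group == cfg$group[i]]
    expect_lt(abs(mean(x) - cfg$ratio_mean[i]) / cfg$ratio_mean[i], 0.02)
    expect_lt(abs(sd(x) - cfg$ratio_sd[i]) / cfg$ratio_sd[i], 0.02)
  }
})
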