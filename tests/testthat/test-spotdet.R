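# a small scalar fixture: flat background with Gaussian bumps of given
# amplitude at given centers
bump_image <- function(h, w, centers, amplitude = 1, sigma = 2, background = 0) {
  x <- matrix(background, h, w)
  for (i in seq_len(nrow(centers))) {
    rr <- seq_len(h); cc <- seq_len(w)
    x <- x + amplitude * outer(exp(-(rr - centers[i, 1])^2 / (2 * sigma^2)),
                               exp(-(cc - centers[i, 2])^2 / (2 * sigma^2)))
  }
  x
}

test_that("config validation rejects bad settings", {
  expect_error(detection_config(scales = integer(0)), "scales")
  expect_error(detection_config(sensitivity = 0), "sensitivity")
  expect_error(detection_config(min_area = 10, max_area = 5), "min_area")
})

test_that("a uniform image yields zero spots, an empty ROI errors", {
  img <- matrix(0.5, 64, 64)
  expect_equal(nrow(detect_spots(img, NULL, detection_config("bright"))), 0)
  expect_error(detect_spots(img, matrix(FALSE, 64, 64), detection_config()),
               "empty", ignore.case = TRUE)
})

test_that("well-separated dots are recovered with high recall and precision", {
  g <- generate_image(image_params(height = 320, width = 320,
                                   target_count = 30, housekeeping_count = 10,
                                   seed = 21))
  y <- tritanope_dark_channel(g$image)
  s <- detect_spots(y, g$truth$roi_mask, detection_config("dark"))
  truth <- centers_in_roi(g$truth$target_centers, g$truth$roi_mask)
  m <- match_spots(s, truth, radius = 3)
  expect_gte(m["tp"] / (m["tp"] + m["fn"]), 0.95)
  expect_gte(m["tp"] / (m["tp"] + m["fp"]), 0.95)
})

test_that("clustered dots are undercounted, never overcounted", {
  g <- generate_image(image_params(height = 192, width = 192,
                                   target_count = 25, housekeeping_count = 0,
                                   cluster_fraction = 1, cluster_size = 5,
                                   seed = 33))
  s <- detect_spots(tritanope_dark_channel(g$image), g$truth$roi_mask,
                    detection_config("dark"))
  expect_lte(nrow(s), g$truth$true_target_count)
})

test_that("undercount under clustering holds on average over seeded draws", {
  counts <- vapply(1:20, function(seed) {
    base <- image_params(height = 160, width = 160, target_count = 20,
                         housekeeping_count = 0, seed = seed)
    clustered <- image_params(height = 160, width = 160, target_count = 20,
                              housekeeping_count = 0, cluster_fraction = 1,
                              cluster_size = 5, seed = seed)
    c(nrow(detect_spots(tritanope_dark_channel(generate_image(base)$image),
                        NULL, detection_config("dark"))),
      nrow(detect_spots(tritanope_dark_channel(generate_image(clustered)$image),
                        NULL, detection_config("dark"))))
  }, c(0, 0))
  expect_lt(mean(counts[2, ]), mean(counts[1, ]))
})

test_that("count_in_roi counts centroid membership", {
  empty <- detect_spots(matrix(0.5, 32, 32), NULL, detection_config("bright"))
  expect_equal(count_in_roi(empty, matrix(TRUE, 32, 32)), 0L)

  centers <- rbind(c(16, 12), c(16, 52), c(48, 12), c(48, 52))
  x <- bump_image(64, 64, centers)
  s <- detect_spots(x, NULL, detection_config("bright"))
  expect_equal(nrow(s), 4L)
  expect_equal(count_in_roi(s, matrix(TRUE, 64, 64)), 4L)
  half <- matrix(FALSE, 64, 64); half[, 1:32] <- TRUE
  expect_equal(count_in_roi(s, half), 2L)
})

test_that("detection is equivariant under integer translation", {
  centers <- rbind(c(20, 20), c(30, 44), c(44, 28))
  x1 <- bump_image(80, 80, centers)
  x2 <- bump_image(80, 80, centers + matrix(rep(c(7, 5), each = 3), 3))
  s1 <- detect_spots(x1, NULL, detection_config("bright"))
  s2 <- detect_spots(x2, NULL, detection_config("bright"))
  expect_equal(nrow(s1), 3L)
  o1 <- order(s1$row, s1$col); o2 <- order(s2$row, s2$col)
  expect_equal(s2$row[o2] - s1$row[o1], rep(7, 3), tolerance = 0.05)
  expect_equal(s2$col[o2] - s1$col[o1], rep(5, 3), tolerance = 0.05)
})

test_that("spot count is monotone non-increasing in sensitivity", {
  g <- generate_image(image_params(height = 160, width = 160,
                                   target_count = 15, housekeeping_count = 0,
                                   seed = 5))
  y <- tritanope_dark_channel(g$image)
  counts <- vapply(c(1, 2, 3, 5, 8, 15, 40), function(k)
    nrow(detect_spots(y, g$truth$roi_mask,
                      detection_config("dark", sensitivity = k))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detected count equals the brute-force oracle on sparse bumps", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(1:10, 1)
    centers <- cbind(runif(n, 15, 85), runif(n, 15, 85))
    # enforce separation so the layout is unambiguous
    keep <- rep(TRUE, n)
    if (n > 1) for (i in 2:n) {
      d <- sqrt((centers[i, 1] - centers[1:(i - 1), 1])^2 +
                (centers[i, 2] - centers[1:(i - 1), 2])^2)
      if (min(d[keep[1:(i - 1)]]) < 14) keep[i] <- FALSE
    }
    centers <- centers[keep, , drop = FALSE]
    x <- bump_image(100, 100, centers, amplitude = 1, sigma = 2)
    oracle <- oracle_components(x > 0.5)   # threshold at half contrast
    s <- detect_spots(x, NULL, detection_config("bright"))
    expect_equal(nrow(s), oracle)
  }
})

test_that("spot CSV serialization records provenance", {
  x <- bump_image(48, 48, rbind(c(24, 24)))
  s <- detect_spots(x, NULL, detection_config("bright"), image_id = "img1")
  f <- tempfile(fileext = ".csv")
  write_spots_csv(s, f)
  lines <- readLines(f)
  expect_true(any(grepl("image_id: img1", lines)))
  expect_true(any(grepl("sensitivity", lines)))
  body <- read.csv(f, comment.char = "#")
  expect_equal(nrow(body), 1L)
})
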