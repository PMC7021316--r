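#' Undecimated B3-spline (a-trous) wavelet transform
#'
#' Multiscale decomposition standard in microscopy spot detection: at each
#' scale the image is smoothed with a separable B3-spline kernel
#' `(1,4,6,4,1)/16` whose taps are spaced `2^(j-1)` pixels apart ("holes"),
#' and the detail plane is the difference of consecutive smoothings. The sum
#' of all detail planes plus the final smooth plane reconstructs the input
#' exactly. Isolated bright spots of radius ~`2^j` pixels concentrate in the
#' detail plane of scale `j`.
#'
#' @param img numeric matrix.
#' @param n_scales number of detail planes (>= 1).
#' @return an object of class `atrous`: list with `details` (list of
#'   `n_scales` matrices) and `smooth` (residual plane). Boundaries are
#'   handled by whole-sample mirror reflection.
#' @examples
#' w <- atrous_wavelet(matrix(rnorm(64^2), 64), 3)
#' rec <- Reduce(`+`, w$details) + w$smooth
#' @export
atrous_wavelet <- function(img, n_scales) {
  if (!is.matrix(img) || !is.numeric(img))
    abort_data("atrous_wavelet() needs a numeric matrix")
  n_scales <- as.integer(n_scales)
  if (is.na(n_scales) || n_scales < 1L) abort_config("n_scales must be >= 1")
  support <- 4L * 2L^(n_scales - 1L) + 1L
  if (min(dim(img)) < support)
    abort_data(sprintf(
      "image (%d x %d) smaller than the B3 kernel support (%d) at scale %d",
      nrow(img), ncol(img), support, n_scales))
  details <- vector("list", n_scales)
  smooth <- img
  for (j in seq_len(n_scales)) {
    nxt <- b3_smooth(smooth, step = 2L^(j - 1L))
    details[[j]] <- smooth - nxt
    smooth <- nxt
  }
  structure(list(details = details, smooth = smooth, n_scales = n_scales),
            class = "atrous")
}

# separable B3 smoothing with hole spacing `step`, mirror boundary
b3_smooth <- function(x, step) {
  h <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2L, -1L, 0L, 1L, 2L) * step
  x <- conv_axis(x, h, off, axis = 1L)
  conv_axis(x, h, off, axis = 2L)
}

conv_axis <- function(x, h, off, axis) {
  n <- dim(x)[axis]
  out <- 0
  for (k in seq_along(h)) {
    idx <- mirror_index(seq_len(n) + off[k], n)
    out <- out + h[k] * (if (axis == 1L) x[idx, , drop = FALSE]
                         else x[, idx, drop = FALSE])
  }
  out
}

# whole-sample reflection: ..., 3, 2, 1, 2, 3, ..., n-1, n, n-1, ...
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * (n - 1L))
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}
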