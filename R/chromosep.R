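#' Chromogen separation by dichromat simulation and CIELAB projection
#'
#' The duplex assay deposits a dark blue chromogen on the target transcript
#' and fast red on the housekeeping transcript, both over a blue-purple
#' hematoxylin counterstain. Two pixel-wise colour transforms isolate the
#' channels: a tritanope (blue-yellow colour-vision deficiency) simulation
#' collapses the blue chromogen and counterstain onto distinguishable
#' luminance levels while leaving reds intact, and the CIELAB a* (red-green
#' opponent) channel of the tritanope image isolates the fast-red dots.
#'
#' `simulate_tritanopia()` linearizes sRGB (piecewise EOTF), maps to LMS cone
#' excitations, projects the S (short-wavelength) cone response onto a plane
#' through the origin spanned by the D65 white axis and the 485 nm tritan
#' confusion anchor, maps back and re-encodes to 8-bit sRGB. The projection
#' is linear, hence exactly idempotent up to 8-bit quantization, and
#' preserves the neutral axis.
#'
#' @param img an [as_rgb_image()] array (8-bit sRGB).
#' @param matrices transform constants from [tritanope_matrices()];
#'   replaceable so an alternative published dichromat formulation can be
#'   swapped in.
#' @return `simulate_tritanopia()`: an `rgb_image` of the same shape.
#' @seealso [tritanope_dark_channel()], [lab_a_channel()]
#' @export
simulate_tritanopia <- function(img, matrices = tritanope_matrices()) {
  if (!(is.array(img) && length(dim(img)) == 3L))
    abort_data("simulate_tritanopia() needs an h x w x 3 array")
  img <- as_rgb_image(unclass(img))
  d <- dim(img)
  lin <- srgb_decode(as.vector(img) / 255)
  dim(lin) <- c(d[1] * d[2], 3L)
  # pixels already on the confusion plane (within the worst-case 8-bit
  # quantization perturbation of the plane functional) pass through
  # unchanged; this makes the simulation exactly idempotent and exactly
  # gray-preserving despite quantization, which would otherwise be
  # amplified near the gamut floor by the sRGB toe
  cf <- matrices$rgb2lms[3L, ] -
    matrices$s_plane[1L] * matrices$rgb2lms[1L, ] -
    matrices$s_plane[2L] * matrices$rgb2lms[2L, ]
  tau <- (0.5 / 255) * 2.4 * sum(abs(cf))
  on_plane <- abs(lin %*% cf) <= tau
  lms <- lin %*% t(matrices$rgb2lms)
  lms[, 3L] <- matrices$s_plane[1L] * lms[, 1L] + matrices$s_plane[2L] * lms[, 2L]
  out <- lms %*% t(matrices$lms2rgb)
  # in-plane gamut mapping: desaturate out-of-gamut pixels toward the
  # equal-luminance gray (grays lie on the projection plane, and the plane
  # passes through the origin, so the blend stays on the plane; naive
  # channel clipping would leave the plane and break idempotence)
  bad <- out[, 1L] < 0 | out[, 1L] > 1 | out[, 2L] < 0 | out[, 2L] > 1 |
         out[, 3L] < 0 | out[, 3L] > 1
  if (any(bad)) {
    y <- pmin(pmax(out[bad, , drop = FALSE] %*% c(0.2126, 0.7152, 0.0722),
                   0), 1)
    dev <- out[bad, , drop = FALSE] - y[, c(1L, 1L, 1L)]
    t_hi <- (1 - y[, c(1L, 1L, 1L)]) / dev
    t_lo <- (0 - y[, c(1L, 1L, 1L)]) / dev
    tt <- ifelse(dev > 0, t_hi, ifelse(dev < 0, t_lo, Inf))
    t_px <- pmin(1, apply(tt, 1L, min))
    out[bad, ] <- y[, c(1L, 1L, 1L)] + t_px * dev
  }
  out <- quantize8(srgb_encode(pmin(pmax(out, 0), 1)))
  if (any(on_plane)) {
    src <- as.vector(img)
    dim(src) <- c(d[1] * d[2], 3L)
    out[on_plane, ] <- src[on_plane, ]
  }
  dim(out) <- d
  as_rgb_image(out)
}

#' @rdname simulate_tritanopia
#'
#' @details `tritanope_matrices()` returns the linear-sRGB-to-LMS matrix of
#' Vienot, Brettel & Mollon (1999), its inverse, and the coefficients
#' `(a, b)` of the tritan projection plane `S = a L + b M`. The plane is
#' derived at call time from the D65 white LMS vector and the LMS direction
#' of monochromatic 485 nm light (CIE 1931 coordinates), the tritan
#' confusion-line anchor of Brettel, Vienot & Mollon (1997).
#' @export
tritanope_matrices <- function() {
  rgb2lms <- matrix(c(17.8824, 43.5161, 4.11935,
                      3.45565, 27.1554, 3.86714,
                      0.0299566, 0.184309, 1.46709),
                    3L, 3L, byrow = TRUE)
  # XYZ -> linear sRGB (IEC 61966-2-1, D65)
  xyz2rgb <- matrix(c(3.2406, -1.5372, -0.4986,
                      -0.9689, 1.8758, 0.0415,
                      0.0557, -0.2040, 1.0570),
                    3L, 3L, byrow = TRUE)
  white <- as.vector(rgb2lms %*% c(1, 1, 1))
  anchor485 <- as.vector(rgb2lms %*% (xyz2rgb %*% c(0.05795, 0.1693, 0.6162)))
  s_plane <- solve(matrix(c(white[1:2], anchor485[1:2]), 2L, 2L, byrow = TRUE),
                   c(white[3L], anchor485[3L]))
  list(rgb2lms = rgb2lms, lms2rgb = solve(rgb2lms), s_plane = s_plane)
}

#' Scalar channels for spot detection
#'
#' `tritanope_dark_channel()` reduces a micrograph to the relative luminance
#' (linear-light Rec. 709 weights) of its tritanope-simulated rendering; the
#' blue target chromogen appears as local luminance minima, suited to
#' dark-mode [detect_spots()]. `lab_a_channel()` computes CIELAB a* (D65, 2
#' degree observer) of an sRGB image; fast-red housekeeping dots appear as
#' a* maxima, suited to bright mode. Both return a numeric matrix carrying a
#' `provenance` attribute.
#'
#' @param img an [as_rgb_image()] array.
#' @param simulate if `TRUE` (default) apply [simulate_tritanopia()] first;
#'   set `FALSE` when the input has already been filtered.
#' @return numeric matrix; luminance in `[0, 1]`, a* in CIELAB units
#'   (roughly -100..100, 0 on the neutral axis).
#' @export
tritanope_dark_channel <- function(img, simulate = TRUE) {
  if (simulate) img <- simulate_tritanopia(img)
  img <- as_rgb_image(unclass(img))
  lin <- srgb_decode(unclass(img) / 255)
  y <- 0.2126 * lin[, , 1L] + 0.7152 * lin[, , 2L] + 0.0722 * lin[, , 3L]
  structure(matrix(y, dim(img)[1L], dim(img)[2L]),
            provenance = "luminance_of_tritanope")
}

#' @rdname tritanope_dark_channel
#' @export
lab_a_channel <- function(img) {
  lab <- srgb_to_lab(img)
  a <- matrix(lab[, , 2L], dim(lab)[1L], dim(lab)[2L])
  structure(a, provenance = "lab_a_channel")
}

#' @rdname tritanope_dark_channel
#' @return `srgb_to_lab()`: array `h x w x 3` of L*, a*, b*.
#' @export
srgb_to_lab <- function(img) {
  img <- as_rgb_image(unclass(img))
  d <- dim(img)
  lin <- srgb_decode(as.vector(img) / 255)
  dim(lin) <- c(d[1] * d[2], 3L)
  # linear sRGB -> XYZ, D65
  rgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                      0.2126729, 0.7151522, 0.0721750,
                      0.0193339, 0.1191920, 0.9503041),
                    3L, 3L, byrow = TRUE)
  xyz <- lin %*% t(rgb2xyz)
  wp <- c(0.950456, 1, 1.088754)  # D65, 2 degree
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1L] / wp[1L]); fy <- f(xyz[, 2L] / wp[2L]); fz <- f(xyz[, 3L] / wp[3L])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  dim(lab) <- d
  lab
}

# piecewise sRGB EOTF and its inverse, on [0,1]
srgb_decode <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

srgb_encode <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}
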