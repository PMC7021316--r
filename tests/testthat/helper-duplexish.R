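# shared fixtures and independent oracles for the test suite

uniform_rgb <- function(value, h = 4L, w = 4L) {
  as_rgb_image(array(rep(value, each = h * w), dim = c(h, w, 3L)))
}

# greedy one-to-one matching of detections to true centers within `radius`;
# returns c(tp, fp, fn)
match_spots <- function(det, centers, radius) {
  if (nrow(det) == 0L) return(c(tp = 0, fp = 0, fn = nrow(centers)))
  if (nrow(centers) == 0L) return(c(tp = 0, fp = nrow(det), fn = 0))
  d <- sqrt(outer(det$row, centers[, 1L], "-")^2 +
            outer(det$col, centers[, 2L], "-")^2)
  tp <- 0L
  used <- rep(FALSE, ncol(d))
  for (i in order(apply(d, 1L, min))) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (is.finite(d[i, j]) && d[i, j] <= radius && !used[j]) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  c(tp = tp, fp = nrow(det) - tp, fn = ncol(d) - tp)
}

# centers whose nearest pixel lies inside the mask
centers_in_roi <- function(centers, mask) {
  if (nrow(centers) == 0L) return(centers)
  r <- pmin(pmax(round(centers[, 1L]), 1L), nrow(mask))
  c <- pmin(pmax(round(centers[, 2L]), 1L), ncol(mask))
  centers[mask[cbind(r, c)], , drop = FALSE]
}

# turn a count-mode cohort sample into image_quant objects with the
# standard red-failure rule applied
quants_from_counts <- function(df, min_housekeeping = 5L) {
  lapply(seq_len(nrow(df)), function(j) {
    flags <- if (df$n_housekeeping[j] < min_housekeeping) "red_failure"
             else character(0)
    image_quant(sprintf("img%02d", j), df$n_target[j], df$n_housekeeping[j],
                qc_flags = flags)
  })
}

# count-mode cohort -> per-sample ISH ratios via the quant layer
cohort_ratios <- function(co) {
  vapply(names(co$samples), function(id) {
    sq <- aggregate_sample(quants_from_counts(co$samples[[id]]),
                           sample_id = id)
    sq$ish_ratio
  }, 0)
}

# independent connected-component labeling (two-pass union-find), used by
# the brute-force detection oracle so it shares no code with the package
oracle_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (cc in seq_len(w)) for (rr in seq_len(h)) {
    if (!mask[rr, cc]) next
    nb <- integer(0)
    for (d in list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(-1L, 1L))) {
      r2 <- rr + d[1L]; c2 <- cc + d[2L]
      if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w && lab[r2, c2] > 0L)
        nb <- c(nb, lab[r2, c2])
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[rr, cc] <- nxt
    } else {
      roots <- unique(vapply(nb, find, 0L))
      lab[rr, cc] <- roots[1L]
      for (r in roots[-1L]) parent[r] <- roots[1L]
    }
  }
  roots <- unique(vapply(lab[lab > 0L], find, 0L))
  length(roots)
}
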