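#' Nonparametric cohort statistics for ISH ratios
#'
#' The statistics layer used on the quantified cohort: tie-corrected
#' Kruskal-Wallis for 3+ groups, Mann-Whitney U (exact by enumeration of the
#' null rank-sum distribution for small untied samples, otherwise normal
#' approximation with tie and continuity corrections) for 2 groups, pairwise
#' Mann-Whitney with Bonferroni correction as post-hoc, and exact Fisher /
#' Fisher-Freeman-Halton contingency tests by complete enumeration of the
#' margin-fixed table space with probability-ordering two-sided p values.
#' All tests are implemented from first principles so they can be checked
#' against independent oracles.
#'
#' @name cohort_stats
NULL

# common result container, printable via the htest method
stat_result <- function(method, statistic = NULL, parameter = NULL, p.value,
                        group_summaries = NULL, correction = NA_character_,
                        data.name = "cohort") {
  structure(list(method = method, statistic = statistic,
                 parameter = parameter, p.value = p.value,
                 group_summaries = group_summaries, correction = correction,
                 data.name = data.name),
            class = c("duplexish_stat", "htest"))
}

summarize_groups <- function(groups) {
  data.frame(group = names2(groups),
             n = vapply(groups, length, 0L),
             mean = vapply(groups, mean, 0),
             sd = vapply(groups, function(g)
               if (length(g) > 1L) sd(g) else NA_real_, 0))
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- rep("", length(x))
  ifelse(nm == "", paste0("g", seq_along(x)), nm)
}

#' Kruskal-Wallis rank sum test with tie correction
#'
#' Midrank-based H statistic with the standard tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; p value from the chi-square approximation
#' with k - 1 degrees of freedom. When every pooled observation is identical
#' the statistic is 0 and p = 1.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @return a `duplexish_stat` (printable as an `htest`) with fields
#'   `statistic` (H), `parameter` (df), `p.value` and per-group `n`, mean,
#'   SD in `group_summaries`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups, min_groups = 2L)
  x <- unlist(groups, use.names = FALSE)
  n <- vapply(groups, length, 0L)
  N <- length(x)
  if (N < 3L) abort_data("Kruskal-Wallis needs a total of at least 3 values")
  r <- rank(x)
  Ri <- vapply(split(r, rep(seq_along(groups), n)), sum, 0)
  H0 <- 12 / (N * (N + 1)) * sum(Ri^2 / n) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H0 / C
    p <- pchisq(H, df = length(groups) - 1L, lower.tail = FALSE)
  }
  stat_result("Kruskal-Wallis rank sum test (tie-corrected)",
              statistic = c(H = H), parameter = c(df = length(groups) - 1L),
              p.value = p, group_summaries = summarize_groups(groups))
}

#' Mann-Whitney U test
#'
#' Two-sided test of two independent samples. With `n1 + n2 <= 20` and no
#' ties, the exact p value is computed from the full null distribution of U
#' (counts of rank subsets, by dynamic programming over the Gaussian
#' binomial recurrence) as `2 * min(P(U <= u), P(U >= u))` capped at 1.
#' Otherwise a normal approximation with tie correction of the variance and
#' a 0.5 continuity correction is used.
#'
#' @param g1,g2 nonempty numeric vectors.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   distribution.
#' @return a `duplexish_stat` with `statistic` U (number of (g1, g2) pairs
#'   with g1 > g2, i.e. the rank-sum form for the first sample).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p.value  # exactly 0.1
#' @export
mann_whitney_u <- function(g1, g2, exact = NULL) {
  check_groups(list(g1, g2), min_groups = 2L)
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  pooled <- c(g1, g2)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (is.null(exact)) exact <- (N <= 20L) && !has_ties
  if (exact && has_ties)
    abort_config("exact Mann-Whitney distribution requires untied data")
  if (exact) {
    dist <- mwu_null_counts(n1, n2)           # counts of U = 0..n1*n2
    tot <- sum(dist)
    lo <- sum(dist[seq_len(U + 1)]) / tot      # P(U <= u)
    hi <- sum(dist[(U + 1):length(dist)]) / tot
    p <- min(1, 2 * min(lo, hi))
    method <- "Mann-Whitney U test (exact)"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(v)
      p <- min(1, 2 * pnorm(max(z, 0), lower.tail = FALSE))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  stat_result(method, statistic = c(U = U), p.value = p,
              group_summaries = summarize_groups(list(g1 = g1, g2 = g2)))
}

# number of size-n1 subsets of ranks 1..n1+n2 giving each U in 0..n1*n2;
# recurrence N(u; n1, n2) = N(u - n2; n1 - 1, n2) + N(u; n1, n2 - 1)
mwu_null_counts <- function(n1, n2) {
  dp <- matrix(0, nrow = n1 + 1L, ncol = n1 * n2 + 1L)
  dp[1L, 1L] <- 1
  for (i in seq_len(n1 + n2)) {
    for (j in rev(seq_len(min(i, n1)))) {
      # adding element with current rank i as a member of sample 1
      # contributes (i - j) "wins" over sample-2 elements so far
      shift <- i - j
      cols <- seq_len(n1 * n2 + 1L - shift)
      dp[j + 1L, cols + shift] <- dp[j + 1L, cols + shift] + dp[j, cols]
    }
  }
  dp[n1 + 1L, ]
}

#' Pairwise post-hoc comparisons with Bonferroni correction
#'
#' All pairwise [mann_whitney_u()] tests over >= 3 groups; corrected p is
#' `min(1, m * p_raw)` with m the number of pairs. Raw and corrected p are
#' both reported.
#'
#' @param groups named list of >= 3 numeric vectors.
#' @param correction only `"bonferroni"` is provided.
#' @return data.frame (class `duplexish_posthoc`) with columns `group1`,
#'   `group2`, `U`, `p_raw`, `p_adj`.
#' @export
posthoc_pairwise <- function(groups, correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  if (length(groups) < 3L)
    abort_config("post-hoc needs >= 3 groups; use mann_whitney_u() for 2")
  check_groups(groups, min_groups = 3L)
  nm <- names2(groups)
  pairs <- combn(length(groups), 2L)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    t <- mann_whitney_u(groups[[i]], groups[[j]])
    data.frame(group1 = nm[i], group2 = nm[j], U = unname(t$statistic),
               p_raw = t$p.value, p_adj = min(1, m * t$p.value))
  })
  structure(do.call(rbind, res), class = c("duplexish_posthoc", "data.frame"),
            correction = correction, method = "pairwise Mann-Whitney U")
}

#' Contingency tables and exact tests
#'
#' `contingency_table()` validates an r x c table of nonnegative integer
#' counts. `fisher_exact_2x2()` computes the two-sided exact p of a 2x2
#' table by the probability-ordering rule: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the observed table's probability (within relative tolerance
#' 1e-7). `fisher_freeman_halton()` generalizes this to r x c tables by
#' complete enumeration of the margin-fixed table space with multivariate
#' hypergeometric probabilities; on 2x2 input it reduces to the same value.
#'
#' @param counts matrix (>= 2 rows, >= 2 columns) of nonnegative integers.
#' @param row_labels,col_labels optional dimension labels.
#' @return `contingency_table()`: validated integer matrix of class
#'   `contingency_table`.
#' @examples
#' fisher_exact_2x2(contingency_table(rbind(c(14, 22), c(1, 5))))$p.value
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    abort_config("contingency table needs >= 2 rows and >= 2 columns")
  if (any(counts < 0) || any(counts != round(counts)))
    abort_config("contingency table counts must be nonnegative integers")
  if (sum(counts) < 1) abort_config("contingency table must hold >= 1 count")
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", "matrix"))
}

#' @rdname contingency_table
#' @param t a 2x2 [contingency_table()] (plain matrices are coerced).
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as_ct(t)
  if (nrow(t) != 2L || ncol(t) != 2L)
    abort_config("fisher_exact_2x2() needs a 2x2 table")
  if (any(rowSums(t) == 0L) || any(colSums(t) == 0L)) {
    warning("degenerate margin (zero row or column); p = 1 by convention")
    return(stat_result("Fisher's exact test (2x2)", p.value = 1))
  }
  r1 <- sum(t[1L, ]); r2 <- sum(t[2L, ]); c1 <- sum(t[, 1L])
  a <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a, r1, r2, c1)
  p_obs <- stats::dhyper(t[1L, 1L], r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  stat_result("Fisher's exact test (2x2, probability ordering)",
              statistic = c(odds_ratio = unname(
                (t[1, 1] * t[2, 2]) / max(t[1, 2] * t[2, 1], .Machine$double.eps))),
              p.value = min(1, p))
}

#' @rdname contingency_table
#' @param max_tables enumeration bound; beyond it the exact test aborts and
#'   recommends Monte Carlo mode.
#' @param monte_carlo sample the margin-fixed space instead of enumerating.
#' @param n_draws,seed Monte Carlo replicate count and seed.
#' @export
fisher_freeman_halton <- function(t, max_tables = 1e7, monte_carlo = FALSE,
                                  n_draws = 1e5, seed = NULL) {
  t <- as_ct(t)
  keep_r <- rowSums(t) > 0L; keep_c <- colSums(t) > 0L
  if (!all(keep_r) || !all(keep_c)) {
    t2 <- t[keep_r, keep_c, drop = FALSE]
    if (nrow(t2) < 2L || ncol(t2) < 2L) {
      warning("degenerate margins leave fewer than 2x2 informative cells; p = 1")
      return(stat_result("Fisher-Freeman-Halton exact test", p.value = 1))
    }
    t <- t2
  }
  rs <- rowSums(t); cs <- colSums(t); N <- sum(t)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  logp_of <- function(tab) log_const - sum(lgamma(tab + 1))
  logp_obs <- logp_of(t)
  tol <- log1p(1e-7)
  if (monte_carlo) {
    p <- with_seed(seed, {
      draws <- stats::r2dtable(n_draws, rs, cs)
      hits <- sum(vapply(draws, logp_of, 0) <= logp_obs + tol)
      (hits + 1) / (n_draws + 1)
    })
    return(stat_result(
      sprintf("Fisher-Freeman-Halton test (Monte Carlo, %d draws)",
              as.integer(n_draws)), p.value = min(1, p)))
  }
  acc <- new.env(parent = emptyenv())
  acc$p <- 0; acc$n_tables <- 0
  recurse <- function(row, col_left, partial_logp) {
    if (row == nrow(t)) {
      acc$n_tables <- acc$n_tables + 1
      if (acc$n_tables > max_tables)
        abort_config(paste("margin-fixed table space exceeds max_tables;",
                           "use monte_carlo = TRUE"))
      lp <- partial_logp - sum(lgamma(col_left + 1))
      if (lp <= logp_obs + tol) acc$p <- acc$p + exp(lp)
      return(invisible())
    }
    for (comp in compositions(rs[row], col_left)) {
      recurse(row + 1L, col_left - comp,
              partial_logp - sum(lgamma(comp + 1)))
    }
    invisible()
  }
  recurse(1L, cs, log_const)
  stat_result("Fisher-Freeman-Halton exact test (complete enumeration)",
              p.value = min(1, acc$p))
}

# all ways to split `total` into length(cap) nonnegative parts, part j <= cap[j]
compositions <- function(total, cap) {
  if (length(cap) == 1L) {
    if (total <= cap) return(list(total)) else return(list())
  }
  out <- list()
  for (first in max(0L, total - sum(cap[-1L])):min(cap[1L], total)) {
    for (rest in compositions(total - first, cap[-1L]))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

as_ct <- function(t) {
  if (!inherits(t, "contingency_table")) t <- contingency_table(t)
  t
}

check_groups <- function(groups, min_groups) {
  if (!is.list(groups) || length(groups) < min_groups)
    abort_data(sprintf("need a list of at least %d groups", min_groups))
  if (any(vapply(groups, length, 0L) == 0L))
    abort_data("every group must hold at least one observation")
  if (!all(vapply(groups, is.numeric, TRUE)))
    abort_data("groups must be numeric")
  invisible(TRUE)
}

#' Summarize an ISH-ratio cohort by a grouping factor
#'
#' Per-level n, mean and SD of the ratio column, with the appropriate test
#' attached: [kruskal_wallis()] for 3+ levels, [mann_whitney_u()] for 2, and
#' summaries only (with a warning) for a single level.
#'
#' @param tab cohort data.frame (e.g. from [build_cohort_table()]).
#' @param factor name of the grouping column.
#' @param value name of the numeric column (default `"ish_ratio"`).
#' @return a `duplexish_summary` list: `factor`, `summaries` data.frame and
#'   `test` (a `duplexish_stat` or `NULL`).
#' @export
summarize_cohort <- function(tab, factor, value = "ish_ratio") {
  tab <- as.data.frame(tab)
  for (col in c(factor, value))
    if (!col %in% names(tab))
      abort_config(sprintf("unknown column '%s'; available: %s", col,
                           paste(names(tab), collapse = ", ")))
  keep <- !is.na(tab[[factor]]) & is.finite(tab[[value]])
  groups <- split(tab[[value]][keep], as.character(tab[[factor]][keep]))
  if (length(groups) == 0L) abort_data("no usable rows for this factor")
  test <- if (length(groups) >= 3L) kruskal_wallis(groups)
          else if (length(groups) == 2L) mann_whitney_u(groups[[1]], groups[[2]])
          else { warning("factor has a single level; no test attached"); NULL }
  structure(list(factor = factor, summaries = summarize_groups(groups),
                 test = test),
            class = "duplexish_summary")
}

#' @export
print.duplexish_summary <- function(x, ...) {
  cat(sprintf("ISH ratio by '%s'\n", x$factor))
  print(x$summaries, row.names = FALSE)
  if (!is.null(x$test))
    cat(sprintf("%s: p = %.4g\n", x$test$method, x$test$p.value))
  invisible(x)
}
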