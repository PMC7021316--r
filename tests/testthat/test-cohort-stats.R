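test_that("Kruskal-Wallis handles ties, identical data and the rank-formula case", {
  r <- kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)

  r2 <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(unname(r2$statistic), 7.2)   # 12/(N(N+1)) sum Ri^2/ni - 3(N+1)
  expect_equal(unname(r2$parameter), 2)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "observation")
})

test_that("Kruskal-Wallis agrees with the reference implementation on tied data", {
  set.seed(6)
  for (rep in 1:5) {
    groups <- lapply(1:3, function(i) sample(1:6, sample(4:9, 1), TRUE))
    ours <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(groups)
    expect_equal(unname(ours$statistic), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(3)
  groups <- lapply(1:3, function(i) rnorm(7, i))
  a <- kruskal_wallis(groups)
  b <- kruskal_wallis(lapply(groups, function(g) exp(2 * g) - 1))
  expect_equal(unname(a$statistic), unname(b$statistic))
})

test_that("exact Mann-Whitney matches full enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 0.1)              # 2 / choose(6, 3)

  # enumeration oracle: all labelings of the pooled sample
  enum_p <- function(g1, g2) {
    n1 <- length(g1); pooled <- c(g1, g2); N <- length(pooled)
    u_of <- function(idx) sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
    u_obs <- u_of(seq_len(n1))
    us <- apply(combn(N, n1), 2, u_of)
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  }
  set.seed(9)
  for (rep in 1:5) {
    g1 <- sample(seq(1, 100, by = 1), sample(3:5, 1))
    g2 <- sample(seq(0.5, 99.5, by = 1), sample(3:5, 1))
    expect_equal(mann_whitney_u(g1, g2)$p.value, enum_p(g1, g2),
                 tolerance = 1e-12)
  }
})

test_that("tied and identical samples give p = 1; approximation matches wilcox.test", {
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$p.value, 1, tolerance = 1e-6)
  set.seed(12)
  g1 <- sample(1:8, 15, TRUE); g2 <- sample(2:9, 14, TRUE)
  ours <- mann_whitney_u(g1, g2)
  ref <- suppressWarnings(stats::wilcox.test(g1, g2, correct = TRUE))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
})

test_that("post-hoc produces all pairs with capped Bonferroni correction", {
  set.seed(5)
  groups <- list(a = rnorm(8, 0), b = rnorm(8, 1), c = rnorm(8, 3))
  ph <- posthoc_pairwise(groups)
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p_adj, pmin(1, 3 * ph$p_raw))
  expect_true(all(ph$p_adj >= ph$p_raw))

  same <- posthoc_pairwise(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_true(all(same$p_adj == 1))
  expect_error(posthoc_pairwise(list(1:3, 4:6)), "3 groups")
})

test_that("2x2 Fisher reproduces known exact values", {
  expect_equal(round(fisher_exact_2x2(rbind(c(14, 22), c(1, 5)))$p.value, 3),
               0.395)
  expect_equal(fisher_exact_2x2(rbind(c(1, 1), c(1, 1)))$p.value, 1)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))$p.value, 2 / 252,
               tolerance = 1e-12)
  expect_warning(p0 <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4)))$p.value,
                 "degenerate")
  expect_equal(p0, 1)
})

test_that("2x2 Fisher agrees with the reference implementation on random tables", {
  set.seed(18)
  for (rep in 1:20) {
    t <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_exact_2x2(t)$p.value,
                 stats::fisher.test(t)$p.value, tolerance = 1e-7)
  }
})

test_that("Freeman-Halton reproduces the published r x 2 values", {
  expect_equal(round(fisher_freeman_halton(rbind(c(3, 11), c(2, 4), c(15, 27)))$p.value, 3),
               0.697)
  expect_equal(round(fisher_freeman_halton(rbind(c(8, 15), c(5, 4), c(2, 8)))$p.value, 3),
               0.317)
})

test_that("Freeman-Halton equals the 2x2 test and the reference r x c test", {
  set.seed(27)
  for (rep in 1:25) {
    t <- matrix(rpois(4, 5), 2, 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_freeman_halton(t)$p.value,
                 fisher_exact_2x2(t)$p.value, tolerance = 1e-10)
  }
  for (rep in 1:5) {
    t <- matrix(rpois(9, 4), 3, 3)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_freeman_halton(t)$p.value,
                 stats::fisher.test(t)$p.value, tolerance = 1e-6)
  }
})

test_that("exact p matches the Monte-Carlo margin-fixed sampler", {
  t <- rbind(c(3, 11), c(2, 4), c(15, 27))
  exact <- fisher_freeman_halton(t)$p.value
  mc <- fisher_freeman_halton(t, monte_carlo = TRUE, n_draws = 1e4,
                              seed = 7)$p.value
  se <- sqrt(exact * (1 - exact) / 1e4)
  expect_lt(abs(mc - exact), 3 * se)
})

test_that("table validation and the enumeration bound are enforced", {
  expect_error(contingency_table(matrix(1, 1, 2)), ">= 2")
  expect_error(contingency_table(matrix(-1, 2, 2)), "nonnegative")
  expect_error(fisher_freeman_halton(matrix(40, 4, 4), max_tables = 100),
               "monte_carlo")
})

test_that("p values live in (0, 1] and corrections never decrease them", {
  set.seed(44)
  for (rep in 1:10) {
    groups <- lapply(1:3, function(i) rnorm(6, sample(0:2, 1)))
    p <- kruskal_wallis(groups)$p.value
    expect_gt(p, 0); expect_lte(p, 1)
    ph <- posthoc_pairwise(groups)
    expect_true(all(ph$p_adj >= ph$p_raw & ph$p_adj <= 1))
  }
})

test_that("cohort summaries pick the right test and check pooled-mean identity", {
  tab <- data.frame(ish_ratio = c(1, 2, 3, 4, 5, 6),
                    lvl2 = rep(c("a", "b"), each = 3),
                    lvl3 = rep(c("x", "y", "z"), each = 2))
  s2 <- summarize_cohort(tab, "lvl2")
  expect_match(s2$test$method, "Mann-Whitney")
  s3 <- summarize_cohort(tab, "lvl3")
  expect_match(s3$test$method, "Kruskal-Wallis")
  expect_error(summarize_cohort(tab, "nope"), "available")

  same <- data.frame(ish_ratio = rep(2, 6), f = rep(c("a", "b"), 3))
  ss <- summarize_cohort(same, "f")
  expect_equal(ss$test$p.value, 1, tolerance = 1e-6)
  expect_equal(ss$summaries$mean, c(2, 2))

  # n-weighted mean of group means equals the pooled mean exactly
  set.seed(2)
  x <- rnorm(30); f <- sample(letters[1:3], 30, TRUE)
  sm <- summarize_cohort(data.frame(ish_ratio = x, f = f), "f")$summaries
  expect_equal(sum(sm$n * sm$mean) / sum(sm$n), mean(x), tolerance = 1e-12)
})

test_that("zero-variance three-group cohort separates fully", {
  tab <- data.frame(ish_ratio = rep(c(1, 2, 3), each = 4),
                    f = rep(c("a", "b", "c"), each = 4))
  s <- summarize_cohort(tab, "f")
  expect_equal(s$summaries$sd, rep(0, 3))
  # fully separated ranks: H = 12/(N(N+1)) sum Ri^2/ni - 3(N+1) on midranks
  expect_equal(unname(s$test$statistic),
               unname(kruskal_wallis(list(rep(1, 4), rep(2, 4), rep(3, 4)))$statistic))
  expect_lt(s$test$p.value, 0.01)
})
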