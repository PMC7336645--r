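test_that("pooled t test matches the reference implementation", {
  expect_identical(t_test_two_tailed(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_identical(t_test_two_tailed(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4)
  mine <- t_test_two_tailed(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(t_test_two_tailed(1, c(1, 2)), "n >= 2")
  for (seed in 1:5) {
    set.seed(seed)
    x <- stats::rnorm(8); y <- stats::rnorm(13, 0.7)
    m <- t_test_two_tailed(x, y)
    r <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(m$statistic, unname(r$statistic), tolerance = 1e-12)
    expect_equal(m$p_value, r$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance t inputs follow the stated conventions", {
  same <- t_test_two_tailed(c(2, 2, 2), c(2, 2))
  expect_identical(same$p_value, 1)
  diffm <- t_test_two_tailed(c(2, 2, 2), c(3, 3))
  expect_identical(diffm$p_value, 0)
  expect_match(diffm$note, "unequal means")
})

test_that("one-way ANOVA matches the direct sum-of-squares oracle", {
  g_same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_identical(anova_oneway(g_same)$statistic, 0)
  # k = 2: F equals the square of the pooled t statistic
  set.seed(3)
  a <- stats::rnorm(9); b <- stats::rnorm(11, 0.4)
  expect_equal(anova_oneway(list(a, b))$statistic,
               t_test_two_tailed(a, b)$statistic^2, tolerance = 1e-12)
  # independent sum-of-squares computation
  for (seed in 1:5) {
    set.seed(100 + seed)
    g <- list(stats::rnorm(7), stats::rnorm(9, 1), stats::rnorm(8, 0.3))
    mine <- anova_oneway(g)
    y <- unlist(g); f <- rep(seq_along(g), lengths(g))
    grand <- mean(y)
    ssb <- sum(lengths(g) * (vapply(g, mean, 1) - grand)^2)
    ssw <- sum((y - ave(y, f))^2)
    fstat <- (ssb / 2) / (ssw / (length(y) - 3))
    expect_equal(mine$statistic, fstat, tolerance = 1e-10)
    expect_equal(mine$p_value, stats::pf(fstat, 2, length(y) - 3,
                                         lower.tail = FALSE), tolerance = 1e-10)
  }
  expect_error(anova_oneway(list(c(1, 2))), ">= 2 groups")
})

test_that("KS statistic equals the brute-force ECDF scan and the reference", {
  expect_identical(suppressWarnings(ks_two_sample(c(1, 2), c(1, 2)))$statistic, 0)
  expect_identical(suppressWarnings(ks_two_sample(c(1, 2), c(3, 4)))$statistic, 1)
  for (seed in 1:20) {
    set.seed(200 + seed)
    a <- stats::rnorm(14); b <- stats::rnorm(17, 0.5)
    mine <- ks_two_sample(a, b)
    # brute force: scan |ECDF difference| over all pooled points
    pooled <- sort(c(a, b))
    D <- max(vapply(pooled, function(x) abs(mean(a <= x) - mean(b <= x)), 1))
    expect_equal(mine$statistic, D, tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    # corrected asymptotic p tracks the exact p: tightly where decisions
    # are made, coarsely deep inside the acceptance region
    tol <- if (ref$p.value < 0.5) 0.02 else 0.05
    expect_lt(abs(mine$p_value - ref$p.value), tol)
  }
})

test_that("log-rank matches a hand-worked table and survdiff", {
  # toy 3-per-arm table: A = (2+, 3c, 6c), B = (4+, 5+, 7c); worked by hand:
  # t=2: risk 3A+3B, event in A -> E_A = 3/6, V = (3/6)(3/6)(6-1)/(6-1) = 1/4
  # t=4: risk 1A+3B, event in B -> E_A = 1/4, V = (1/4)(3/4)(4-1)/(4-1) = 3/16
  # t=5: risk 1A+2B, event in B -> E_A = 1/3, V = (1/3)(2/3)(3-1)/(3-1) = 2/9
  # O_A = 1, E_A = 13/12, sum V = 95/144 -> chi2 = (1/12)^2 / (95/144) = 1/95
  toy <- data.frame(time = c(2, 3, 6, 4, 5, 7),
                    event = c(1, 0, 0, 1, 1, 0),
                    group = rep(c("A", "B"), each = 3))
  mine <- log_rank(toy)
  expect_equal(mine$statistic, 1 / 95, tolerance = 1e-12)
  ref <- survival::survdiff(survival::Surv(time, event) ~ group, toy)
  expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)

  dup <- data.frame(time = rep(c(1, 2, 3), 2), event = rep(c(1, 1, 0), 2),
                    group = rep(c("A", "B"), each = 3))
  expect_identical(log_rank(dup)$statistic, 0)
  expect_identical(log_rank(dup)$p_value, 1)

  cens <- data.frame(time = 1:4, event = 0, group = c("A", "A", "B", "B"))
  expect_error(log_rank(cens), "no events")

  for (seed in 1:20) {
    sv <- simulate_survival(c(a = 0.04, b = 0.1), 15, follow_up = 50,
                            seed = 300 + seed)
    mine <- log_rank(sv)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group, sv)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-8)
    expect_equal(mine$p_value, stats::pchisq(ref$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("tests are invariant to group order and p values stay in [0, 1]", {
  set.seed(9)
  a <- stats::rnorm(12); b <- stats::rnorm(10, 1)
  expect_equal(abs(t_test_two_tailed(a, b)$statistic),
               abs(t_test_two_tailed(b, a)$statistic))
  expect_identical(ks_two_sample(a, b)$statistic, ks_two_sample(b, a)$statistic)
  sv <- simulate_survival(c(x = 0.05, y = 0.12), 12, 60, seed = 4)
  sv2 <- sv; sv2$group <- ifelse(sv$group == "x", "y", "x")
  expect_equal(log_rank(sv)$statistic, log_rank(sv2)$statistic, tolerance = 1e-12)
  for (seed in 1:10) {
    set.seed(400 + seed)
    x <- stats::rexp(11); y <- stats::rexp(13)
    for (p in c(t_test_two_tailed(x, y)$p_value,
                anova_oneway(list(x, y))$p_value,
                ks_two_sample(x, y)$p_value))
      expect_true(p >= 0 && p <= 1)
  }
})

test_that("group summaries emit both SD and SEM", {
  s <- group_summary(c(1, 2, 3, 10, 20, 30), rep(c("u", "t"), each = 3))
  expect_identical(s$n, c(3L, 3L))
  u <- s[s$group == "u", ]
  expect_equal(u$mean, 2)
  expect_equal(u$sd, 1)
  expect_equal(u$sem, 1 / sqrt(3))
})
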