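test_that("spearman matches the midrank Pearson definition and sign conventions", {
  d <- tibble::tibble(x = c(1, 2, 2, 3, 5, 8, 2, 9, 4, 4, 7),
                      y = c(1, 3, 2, 4, 2, 9, 1, 8, 5, 5, 6))
  got <- spearman_test(d, x, y)
  # independent midrank oracle: Pearson product-moment on average ranks
  rx <- rank(d$x); ry <- rank(d$y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, oracle, tolerance = 1e-12)

  up <- tibble::tibble(x = seq(0.25, 5, 0.25), y = seq(0.25, 5, 0.25)^3)
  expect_equal(spearman_test(up, x, y)$rho, 1)
  down <- tibble::tibble(x = seq(0.25, 5, 0.25), y = -seq(0.25, 5, 0.25))
  expect_equal(spearman_test(down, x, y)$rho, -1)

  const <- tibble::tibble(x = rep(1, 10), y = rnorm(10))
  expect_true(is.na(spearman_test(const, x, y)$rho))
})

test_that("small-sample spearman p comes from exact permutation enumeration", {
  set.seed(2)
  d <- tibble::tibble(x = c(0.3, 1.2, 2.5, 0.9, 3.3, 1.8),
                      y = c(0.1, 1.0, 2.0, 1.5, 2.8, 0.7))
  got <- spearman_test(d, x, y)
  expect_equal(got$method, "exact permutation")
  # oracle: enumerate all 6! rank permutations directly
  perms <- expand.grid(rep(list(1:6), 6))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  rx <- rank(d$x)
  rho_obs <- cor(rx, rank(d$y))
  null_rho <- apply(perms, 1, function(r) cor(rx, as.numeric(r)))
  expect_equal(got$p_value, mean(abs(null_rho) >= abs(rho_obs) - 1e-12),
               tolerance = 1e-12)
})

test_that("chi-square equals the direct O/E formula and is label-invariant", {
  even <- matrix(c(25, 25, 25, 25), 2)
  got0 <- chisq_assoc(table = even)
  expect_equal(got0$statistic, 0)
  expect_equal(got0$p_value, 1)

  tab <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  got <- chisq_assoc(table = tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - expected)^2 / expected), tolerance = 1e-12)
  expect_equal(chisq_assoc(table = tab[2:1, ])$statistic, got$statistic)

  expect_error(chisq_assoc(table = matrix(c(5, 0, 7, 0), 2)), "degenerate")
  expect_gte(chisq_assoc(table = matrix(c(2, 3, 4, 1), 2))$low_expected_cells, 1)
})

test_that("BH adjustment equals the brute-force step-up on the worked example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH matches the step-up oracle on 1000 random p-vectors", {
  set.seed(13)
  worst <- 0
  for (i in 1:1000) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    worst <- max(worst, max(abs(bh_adjust(p) - brute_force_bh(p))))
  }
  expect_lt(worst, 1e-12)
})

test_that("group differences are detected with high power at a 2 SD shift", {
  set.seed(4)
  d <- tibble::tibble(
    value = c(rnorm(50), rnorm(50) + 2),
    group = rep(c("a", "b"), each = 50)
  )
  expect_lt(group_difference(d, value, group, "anova")$p_value, 1e-6)
  expect_lt(group_difference(d, value, group, "median_test")$p_value, 1e-4)
  one <- tibble::tibble(value = rnorm(10), group = "a")
  expect_error(group_difference(one, value, group), "at least 2 groups")
})

test_that("anova/median-test statistics are invariant to row permutation", {
  set.seed(9)
  d <- tibble::tibble(value = rnorm(60), group = rep(c("a", "b", "c"), 20))
  shuf <- d[sample(nrow(d)), ]
  for (m in c("anova", "median_test")) {
    expect_equal(group_difference(d, value, group, m)$statistic,
                 group_difference(shuf, value, group, m)$statistic)
  }
})

test_that("linear fit is exact on noiseless data and flags collinear columns", {
  d <- tibble::tibble(x = seq(-2, 2, length.out = 30), y = 2 * seq(-2, 2, length.out = 30))
  fit <- fit_linear(d, y ~ x)
  # summary.lm warns about the (intentionally) perfect fit
  expect_equal(suppressWarnings(tidy(fit))$estimate[2], 2, tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(fit))$adjusted_r2, 1, tolerance = 1e-10)

  d$z <- d$x * 3  # exactly collinear
  expect_warning(fit2 <- fit_linear(d, y ~ x + z), "collinear")
  expect_equal(suppressWarnings(tidy(fit2))$estimate[2], 2, tolerance = 1e-10)
})

test_that("linear fit recovers planted methylation and dose coefficients", {
  set.seed(31)
  n <- 800
  d <- tibble::tibble(
    methylation = rbeta(n, 2, 2),
    cna = sample(-1:1, n, TRUE),
    cohort = sample(c("A", "B"), n, TRUE)
  )
  d$expr <- -0.6 * d$methylation + 0.1 * d$cna + 0.05 * (d$cohort == "B") + rnorm(n, 0, 0.3)
  fit <- tidy(fit_linear(d, expr ~ methylation + cna + cohort))
  meth <- fit[fit$term == "methylation", ]
  cna <- fit[fit$term == "cna", ]
  expect_lt(abs(meth$estimate - (-0.6)) / meth$std_error, 3)
  expect_lt(abs(cna$estimate - 0.1) / cna$std_error, 3)
  expect_lt(meth$estimate, 0)  # canonical inverse methylation-expression pattern
})

test_that("logistic fit recovers a planted log-odds and flips with labels", {
  set.seed(17)
  n <- 800
  x <- rnorm(n)
  pr <- plogis(-0.2 + 1.0 * x)
  y <- runif(n) < pr
  d <- tibble::tibble(x = x, y = y)
  fit <- tidy(fit_logistic(d, y ~ x))
  b <- fit[fit$term == "x", ]
  expect_lt(abs(b$estimate - 1.0) / b$std_error, 3)

  d$ny <- !d$y
  flip <- tidy(fit_logistic(d, ny ~ x))
  expect_equal(flip$estimate, -fit$estimate, tolerance = 1e-6)

  d$sep <- d$x > 0
  w <- capture_warnings(fit_logistic(d, sep ~ x))  # glm also warns on convergence
  expect_true(any(grepl("separation", w)))
  expect_error(fit_logistic(tibble::tibble(x = rnorm(20), y = TRUE), y ~ x),
               "single class")
})

test_that("log-rank matches the hand-tabulated 6-subject oracle", {
  d <- tibble::tibble(
    time = c(1, 3, 4, 5, 8, 9),
    event = c(1, 1, 0, 1, 1, 0),
    group = c("a", "b", "a", "b", "a", "b")
  )
  fit <- km_logrank(d, time, event, group)
  expect_equal(fit$chi_square, hand_logrank(d$time, d$event, d$group),
               tolerance = 1e-10)
  expect_equal(fit$p_value, pchisq(fit$chi_square, 1, lower.tail = FALSE))

  # identical groups: duplicated data split evenly -> statistic 0
  dup <- tibble::tibble(time = rep(c(2, 4, 6), 2), event = rep(c(1, 1, 0), 2),
                        group = rep(c("a", "b"), each = 3))
  expect_equal(km_logrank(dup, time, event, group)$chi_square, 0, tolerance = 1e-12)

  none <- tibble::tibble(time = 1:6, event = 0, group = rep(c("a", "b"), 3))
  expect_error(km_logrank(none, time, event, group), "no events")
})

test_that("log-rank statistic grows with the planted hazard ratio", {
  set.seed(77)
  stat_at_hr <- vapply(c(1, 2, 4), function(hr) {
    mean(replicate(20, {
      t1 <- rexp(60, 0.05); t2 <- rexp(60, 0.05 * hr)
      d <- tibble::tibble(time = c(t1, t2), event = 1,
                          group = rep(c("a", "b"), each = 60))
      km_logrank(d, time, event, group)$chi_square
    }))
  }, numeric(1))
  expect_true(all(diff(stat_at_hr) > 0))
})

test_that("association blocks report per-test denominators and block FDR", {
  set.seed(6)
  n <- 120
  d <- tibble::tibble(
    marker = rep(c(TRUE, FALSE), each = n / 2),
    linked = rep(c("yes", "no"), each = n / 2),          # perfectly associated
    noise_cat = sample(c("u", "v"), n, TRUE),
    noise_num = rnorm(n)
  )
  d$noise_cat[1:4] <- NA
  blk <- association_block(d, "marker", c("linked", "noise_cat", "noise_num"))
  expect_equal(nrow(blk), 3)
  expect_lt(blk$fdr[blk$variable == "linked"], 0.001)
  expect_equal(blk$n_used[blk$variable == "noise_cat"], n - 4)
  expect_equal(blk$fdr, bh_adjust(blk$p_value))
})
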