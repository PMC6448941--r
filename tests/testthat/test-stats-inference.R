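test_that("Brunner-Munzel relative effect matches enumeration oracles", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  bm <- brunner_munzel(x, y)
  expect_equal(bm$p_hat, bf_relative_effect(x, y))
  # frozen hand enumeration: 13 strict wins + 2 ties out of 16 pairs
  expect_equal(bm$p_hat, 0.875)
  expect_equal(bm$statistic, 3, tolerance = 1e-12)
  expect_equal(bm$df, 6, tolerance = 1e-12)
  expect_equal(bm$p.value, 2 * pt(-3, 6), tolerance = 1e-12)
  # random small samples against the brute-force oracle
  set.seed(42)
  for (i in 1:25) {
    a <- sample(1:6, sample(3:8, 1), replace = TRUE)
    b <- sample(1:6, sample(3:8, 1), replace = TRUE)
    r <- tryCatch(brunner_munzel(a, b), error = function(e) NULL)
    if (!is.null(r)) expect_equal(r$p_hat, bf_relative_effect(a, b))
  }
})

test_that("Brunner-Munzel symmetry and degenerate-data contracts", {
  s <- c(2, 5, 5, 7, 9)
  expect_equal(brunner_munzel(s, s)$p_hat, 0.5)
  expect_equal(brunner_munzel(1:5, 6:12)$p_hat, 1)
  # complementarity is exact
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(12, 0.5)
    expect_equal(brunner_munzel(a, b)$p_hat + brunner_munzel(b, a)$p_hat,
                 1, tolerance = 1e-14)
  }
  expect_error(brunner_munzel(rep(3, 5), rep(3, 7)), "degenerate")
  expect_error(brunner_munzel(1, 1:5), "n >= 2")
})

test_that("Fisher's exact test matches enumeration and the study contrast", {
  # hypoglycaemia contrast: 19/21 RYGB vs 0/17 obese
  expect_lt(fisher_exact(rbind(c(19, 2), c(0, 17)))$p.value, 0.001)
  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5)))$p.value, 1)
  tab <- rbind(c(3, 1), c(1, 3))
  expect_equal(fisher_exact(tab)$p.value, bf_fisher_p(tab), tolerance = 1e-9)
  expect_equal(fisher_exact(tab)$p.value, 34 / 70, tolerance = 1e-9)
  # transposition invariance
  set.seed(3)
  for (i in 1:10) {
    t2 <- matrix(rpois(4, 6), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(fisher_exact(t2)$p.value, fisher_exact(t(t2))$p.value,
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact(rbind(c(0, 0), c(3, 4))), "degenerate")
  expect_error(fisher_exact(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("paired rank test: exact small-sample behaviour", {
  before <- c(5, 7, 3, 8, 2, 6, 9, 4, 5, 7, 3, 8, 6, 2)
  expect_error(paired_rank_test(before, before), "degenerate")
  # uniform +1 shift over 14 pairs attains the minimal exact two-sided p
  res <- paired_rank_test(before, before + 1)
  expect_equal(res$p.value, 2 / 2^14, tolerance = 1e-12)
  expect_equal(res$n, 14L)
  # interface on a 14-pair fixture with a mixed-direction change
  set.seed(9)
  after <- before + rnorm(14, 0.3)
  r2 <- paired_rank_test(before, after)
  expect_true(r2$p.value >= 0 && r2$p.value <= 1)
  expect_error(paired_rank_test(1:3, 1:4), "equal length")
})

test_that("Spearman: rank-correlation oracle, CI and invariance", {
  expect_equal(spearman_ci(1:10, (1:10)^3)$rho, 1)
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  expect_equal(spearman_ci(x, rev(sort(x)))$rho,
               cor(rank(x), rank(rev(sort(x)))))
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.85, 4, 5, 6)
  # rank-then-correlate oracle
  expect_equal(spearman_ci(x, y)$rho, cor(rank(x), rank(y)))
  # invariant under strictly monotone transforms of either variable
  expect_equal(spearman_ci(exp(x), y)$rho, spearman_ci(x, y)$rho)
  expect_equal(spearman_ci(x, qlogis(y / 10))$rho, spearman_ci(x, y)$rho)
  # CI uses the 1.06/(n-3) Fisher-z variance
  sc <- spearman_ci(x, y)
  z <- atanh(sc$rho); se <- sqrt(1.06 / (10 - 3))
  expect_equal(sc$conf.int, tanh(z + c(-1, 1) * qnorm(0.975) * se))
  expect_error(spearman_ci(rep(1, 5), 1:5), "constant")
  expect_error(spearman_ci(1:3, 3:1), "n >= 4")
})

test_that("protected LSD: omnibus gate, closed-form F, two-group identity", {
  set.seed(21)
  same <- lapply(1:3, function(i) rnorm(20))
  names(same) <- c("a", "b", "c")
  r_null <- anova_lsd(list(a = same$a, b = same$a + 1e-9, c = same$a))
  expect_false(r_null$evaluated)
  expect_true(all(is.na(r_null$pairwise$p.value)))

  g <- list(a = rnorm(20, 0), b = rnorm(20, 0), c = rnorm(20, 5))
  r <- anova_lsd(g)
  # closed-form F from sums of squares
  y <- unlist(g); gm <- mean(y)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  expect_equal(r$F, (ssb / 2) / (ssw / 57), tolerance = 1e-9)
  expect_true(r$evaluated)
  pw <- r$pairwise
  expect_gt(pw$p.value[pw$group1 == "a" & pw$group2 == "b"], 0.05)
  expect_lt(max(pw$p.value[pw$group2 == "c"]), 1e-6)

  # two groups: LSD p equals the pooled-variance t-test
  r2 <- anova_lsd(g[c("a", "c")])
  tt <- t.test(g$a, g$c, var.equal = TRUE)
  expect_equal(r2$pairwise$p.value, tt$p.value, tolerance = 1e-12)
  expect_error(anova_lsd(list(a = 1:3, b = numeric(0))), "degenerate")
})

test_that("hyperbolic fit: exact recovery, degenerate slope, lm equivalence", {
  x <- seq(0.1, 1, length.out = 20)
  fit <- hyperbolic_fit(x, 252.3 + 146.5 / x)
  expect_equal(unname(coef(fit)["intercept"]), 252.3, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["slope"]), 146.5, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-18)
  expect_equal(predict(fit, 0.5), 252.3 + 146.5 / 0.5, tolerance = 1e-9)

  cst <- hyperbolic_fit(x, rep(7, 20))
  expect_equal(unname(coef(cst)), c(7, 0), tolerance = 1e-12)

  set.seed(5)
  y <- 200 + 100 / x + rnorm(20, 0, 10)
  fit2 <- hyperbolic_fit(x, y)
  oracle <- lm(y ~ I(1 / x))
  expect_equal(unname(coef(fit2)), unname(coef(oracle)), tolerance = 1e-12)
  expect_equal(residuals(fit2), unname(residuals(oracle)), tolerance = 1e-12)
  expect_error(hyperbolic_fit(c(0, x[-1]), y), "domain")
})

test_that("change-score comparison applies rank inference per group pair", {
  set.seed(13)
  same <- list(a = rnorm(14), b = rnorm(14))
  r0 <- change_score_compare(same)
  expect_equal(nrow(r0), 1L)
  # RYGB deltas shifted upward vs obese deltas near zero: the obese-first
  # orientation makes the relative effect P(obese < RYGB) > 0.5
  obese <- rnorm(9, 0.05, 0.1)
  rygb <- rnorm(14, 0.35, 0.1)
  r <- change_score_compare(list(obese = obese, RYGB = rygb))
  expect_gt(r$p_hat, 0.5)
  expect_lt(r$p.value, 0.05)
  expect_error(change_score_compare(list(a = rnorm(5))), ">= 2 groups")
})
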