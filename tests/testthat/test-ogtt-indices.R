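test_that("trapezoid AUC matches closed forms and the fine-grid oracle", {
  const5 <- og_curve(rep(5, 7))
  expect_equal(auc_trapezoid(const5, 0, 180), 900)
  lin <- og_curve(seq(4, 8, length.out = 7))
  expect_equal(auc_trapezoid(lin, 0, 180), 1080)
  # quadratic sampled on the grid vs fine-grid integral of the interpolant
  quad <- og_curve(4 + 0.002 * ogtt_grid() + 1e-4 * ogtt_grid()^2)
  expect_equal(auc_trapezoid(quad, 0, 180),
               bf_auc(ogtt_grid(), quad$values, 0, 180), tolerance = 1e-9)
  # additivity over adjacent windows
  curve <- og_curve(c(4.1, 9.9, 5.0, 2.4, 2.9, 3.4, 3.9))
  expect_equal(auc_trapezoid(curve, 0, 60) + auc_trapezoid(curve, 60, 180),
               auc_trapezoid(curve, 0, 180), tolerance = 1e-12)
  # contract violations
  expect_error(auc_trapezoid(curve, 60, 60), "t_start")
  expect_error(auc_trapezoid(curve, 0, 200), "insufficient")
  holey <- og_curve(c(4, NA, 6, 5, 5, 4, 4))
  expect_error(auc_trapezoid(holey, 0, 180), "missing values inside")
})

test_that("secretion ratio is the quotient of windowed AUCs", {
  ins <- og_curve(rep(300, 7), "insulin")
  glu <- og_curve(rep(5, 7))
  for (w in c("early", "late", "total"))
    expect_equal(secretion_ratio(ins, glu, w), 60)
  ins2 <- og_curve(c(47, 900, 400, 100, 90, 80, 70), "insulin")
  glu2 <- og_curve(c(4.1, 9.9, 5.0, 2.4, 2.9, 3.4, 3.9))
  expect_equal(secretion_ratio(ins2, glu2, "early"),
               auc_trapezoid(ins2, 0, 60) / auc_trapezoid(glu2, 0, 60))
  dbl <- og_curve(ins2$values * 2, "insulin")
  expect_equal(secretion_ratio(dbl, glu2, "total"),
               2 * secretion_ratio(ins2, glu2, "total"))
})

test_that("glucose summary separates fasting from the post-load nadir", {
  rising <- og_curve(c(4, 5, 6, 7, 8, 9, 10))
  s <- glucose_summary(rising)
  expect_equal(s$nadir, 5)   # t = 30, never the fasting sample
  expect_equal(s$max, 10)
  expect_equal(s$fasting, 4)
  rygb <- og_curve(c(4.15, 9.95, 4.8, 2.36, 2.9, 3.4, 3.9))
  expect_equal(glucose_summary(rygb)$nadir, 2.36)
  expect_true(classify_hypoglycaemia(rygb)$flag)
  const <- og_curve(rep(5, 7))
  s2 <- glucose_summary(const)
  expect_true(all(unlist(s2) == 5))
  # unweighted sample mean by default, time-weighted on request
  expect_equal(glucose_summary(rising)$mean, mean(rising$values))
  expect_equal(glucose_summary(rising, time_weighted = TRUE)$mean,
               auc_trapezoid(rising, 0, 180) / 180)
})

test_that("shape index: zero on lines, affine-invariant, matches the loop oracle", {
  affine <- og_curve(4 + 0.01 * ogtt_grid())
  expect_equal(whosh_g(affine), 0)
  curve <- og_curve(c(4.1, 9.9, 5.0, 2.4, 2.9, 3.4, 3.9))
  expect_equal(whosh_g(curve), bf_whosh(curve$values), tolerance = 1e-12)
  # adding a linear trend changes nothing
  trended <- og_curve(curve$values + 0.01 * ogtt_grid() + 1)
  expect_equal(whosh_g(trended), whosh_g(curve), tolerance = 1e-12)
  # positive scaling scales the (pre-normalisation) index linearly
  expect_equal(whosh_g(og_curve(curve$values * 3)), 3 * whosh_g(curve),
               tolerance = 1e-12)
  expect_error(whosh_g(sampled_curve("glucose", c(0, 30), c(4, 5))),
               ">= 3 samples")
})

test_that("QUICKI evaluates the reciprocal log-sum with unit conversions", {
  expect_equal(quicki(4.15, 47), 0.3613, tolerance = 1e-4)
  # within the reported RYGB population band
  expect_gt(quicki(4.15, 47), 0.37 - 0.03)
  expect_lt(quicki(4.15, 47), 0.37 + 0.03)
  # monotone decreasing in fasting insulin
  expect_gt(quicki(4.15, 47), quicki(4.15, 60))
  # constructed log-sum of 2 -> 0.5: I0 with log10(I0_uU) = 2 - log10(G0_mgdl)
  g0 <- 5
  i0_uu <- 10^(2 - log10(g0 * 18.016))
  expect_equal(quicki(g0, i0_uu * 6.0), 0.5, tolerance = 1e-12)
  expect_error(quicki(-1, 50), "positive")
})

test_that("OGIS lands in the physiological range and responds correctly", {
  # normal-weight-like inputs: value should bracket the published
  # population scale (roughly 400-650 ml/min/m^2)
  val <- ogis_120(4.16, 6.0, 5.2, 51, 350, bmi = 25.1)
  expect_gt(val, 400); expect_lt(val, 650)
  # more insulin for the same glucose = less sensitive
  expect_lt(ogis_120(4.16, 6.0, 5.2, 510, 3500, bmi = 25.1), val)
  # higher 120-min glucose at fixed insulin = less sensitive
  expect_lt(ogis_120(4.16, 6.0, 7.8, 51, 350, bmi = 25.1), val)
  expect_error(ogis_120(4.16, NA, 5.2, 51, 350, bmi = 25.1), "insufficient")
  expect_error(ogis_120(4.16, 6.0, 5.2, 51, 350), "insufficient")
})

test_that("GDM classification applies the inclusive OR rule", {
  mk <- function(g0, g60, g120)
    og_curve(c(g0, 6, g60, 6, g120, 5, 4.5))
  neg <- classify_gdm(mk(4.0, 8.0, 7.0))
  expect_false(neg$flag)
  pos_f <- classify_gdm(mk(5.2, 8.0, 7.0))
  expect_true(pos_f$flag)
  expect_true(pos_f$components[["fasting"]])
  expect_false(any(pos_f$components[c("t60", "t120")]))
  # boundary values are inclusive
  expect_true(classify_gdm(mk(5.1, 8.0, 7.0))$flag)
  expect_true(classify_gdm(mk(4.0, 10.0, 7.0))$components[["t60"]])
  expect_true(classify_gdm(mk(4.0, 8.0, 8.5))$components[["t120"]])
  expect_false(classify_gdm(mk(5.0999, 9.999, 8.4999))$flag)
  holey <- og_curve(c(4, 6, NA, 6, 7, 5, 4.5))
  expect_error(classify_gdm(holey), "insufficient")
})

test_that("hypoglycaemia flag is strict and ignores the fasting sample", {
  mk <- function(nadir) og_curve(c(4.1, 9.9, 5.0, nadir, 3.0, 3.4, 3.9))
  expect_true(classify_hypoglycaemia(mk(2.36))$flag)
  expect_false(classify_hypoglycaemia(mk(2.78))$flag)  # strict <
  expect_false(classify_hypoglycaemia(og_curve(c(4.7, 6.4, 8.7, 7.5, 6.4,
                                                 5.5, 4.67)))$flag)
  # a low fasting value alone never triggers the flag
  low_fast <- og_curve(c(2.5, 6, 7, 6, 5, 4.5, 4))
  expect_false(classify_hypoglycaemia(low_fast)$flag)
  expect_equal(classify_hypoglycaemia(low_fast)$nadir, 4)
})

test_that("classifications depend only on their stated samples", {
  # permuting values at unrelated timepoints never changes the GDM flag
  base <- c(4.0, 6.5, 9.0, 6.0, 7.0, 5.0, 4.5)
  flag0 <- classify_gdm(og_curve(base))$flag
  for (perm in list(c(1, 2, 3, 6, 5, 4, 7), c(1, 7, 3, 4, 5, 2, 6))) {
    shuffled <- base
    shuffled[c(2, 4, 6, 7)] <- base[perm[c(2, 4, 6, 7)]]
    expect_identical(classify_gdm(og_curve(shuffled))$flag, flag0)
  }
})
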