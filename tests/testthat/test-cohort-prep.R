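match_cohort <- function(t_bmi, c_bmi, c_groups = NULL) {
  n_t <- length(t_bmi); n_c <- length(c_bmi)
  if (is.null(c_groups)) c_groups <- rep("obese_control", n_c)
  subjects <- data.frame(
    id = sprintf("S%02d", seq_len(n_t + n_c)),
    group = c(rep("RYGB", n_t), c_groups),
    bmi_v1 = c(t_bmi, c_bmi), stringsAsFactors = FALSE)
  ogtt <- data.frame(id = subjects$id[1], visit = "V1", analyte = "glucose",
                     time_min = 0, value = 4.5, stringsAsFactors = FALSE)
  gp_cohort(subjects, ogtt)
}

test_that("identical covariates match everyone with zero imbalance", {
  co <- match_cohort(rep(30, 5), rep(30, 5))
  m <- suppressWarnings(propensity_match(co))
  expect_equal(nrow(m$pairs), 5L)
  expect_length(m$unmatched, 0)
  expect_equal(unname(m$smd_after), 0)
})

test_that("the caliper excludes treated subjects far outside the control range", {
  set.seed(2)
  co <- match_cohort(c(rnorm(10, 31, 1), 60), rnorm(12, 31.5, 1))
  m <- propensity_match(co)
  # the BMI-60 outlier finds no in-caliper control
  out_id <- co$subjects$id[co$subjects$bmi_v1 == 60]
  expect_true(out_id %in% m$unmatched)
  # every retained pair respects the caliper and controls are disjoint
  expect_true(all(m$pairs$distance <= m$caliper))
  expect_false(anyDuplicated(m$pairs$control_id) > 0)
})

test_that("greedy pairing matches the exhaustive minimal-greedy oracle", {
  t_bmi <- c(28, 31, 34, 37, 40)
  c_bmi <- c(27.5, 30, 33, 39, 41)
  co <- match_cohort(t_bmi, c_bmi)
  m <- propensity_match(co)
  # oracle: replay greedy nearest-neighbour in descending treated
  # propensity directly on the returned propensity scores
  ps <- m$propensity
  t_ids <- co$subjects$id[co$subjects$group == "RYGB"]
  c_ids <- setdiff(co$subjects$id, t_ids)
  t_ids <- t_ids[order(-ps[t_ids], t_ids)]
  avail <- c_ids; oracle <- list()
  for (ti in t_ids) {
    d <- abs(ps[avail] - ps[ti])
    j <- avail[order(d, avail)][1]
    if (abs(ps[j] - ps[ti]) <= m$caliper) {
      oracle[[ti]] <- j
      avail <- setdiff(avail, j)
    }
  }
  expect_equal(m$pairs$control_id[match(names(oracle), m$pairs$treated_id)],
               unname(unlist(oracle)))
})

test_that("matching reduces covariate imbalance on simulated cohorts", {
  for (seed in 1:3) {
    sim <- simulate_cohort(n = c(15, 12, 12), seed = seed, p_v2 = 0)
    m <- propensity_match(sim$cohort)
    expect_true(nrow(m$pairs) >= 1)
    expect_lte(abs(m$smd_after[["bmi_v1"]]), abs(m$smd_before[["bmi_v1"]]))
    expect_true(all(m$pairs$distance <= m$caliper))
  }
})

test_that("missingness report applies the strict 50% ceiling per experiment", {
  co <- tiny_cohort()
  # subject A glucose: mask 3 of 7 (42.9%) -> eligible
  sel_a <- co$ogtt$id == "A" & co$ogtt$analyte == "glucose" &
    co$ogtt$time_min %in% c(30, 90, 150)
  co$ogtt$value[sel_a] <- NA
  # subject B glucose: mask 4 of 7 (57.1%) -> excluded
  sel_b <- co$ogtt$id == "B" & co$ogtt$analyte == "glucose" &
    co$ogtt$time_min %in% c(0, 60, 120, 180)
  co$ogtt$value[sel_b] <- NA
  rep_ <- missingness_report(co)
  a <- rep_[rep_$id == "A" & rep_$analyte == "glucose" & rep_$test == "ogtt", ]
  b <- rep_[rep_$id == "B" & rep_$analyte == "glucose" & rep_$test == "ogtt", ]
  cc <- rep_[rep_$id == "C" & rep_$analyte == "glucose" & rep_$test == "ogtt", ]
  expect_true(a$eligible);  expect_equal(a$frac_missing, 3 / 7)
  expect_false(b$eligible); expect_equal(b$frac_missing, 4 / 7)
  expect_true(cc$eligible); expect_equal(cc$frac_missing, 0)
  # exactly at the ceiling (50%) is excluded, below is eligible
  expect_false(0.5 < gp_config()$impute$max_missing)
})

test_that("imputation is a seeded no-op on complete data and deterministic", {
  sim <- simulate_cohort(n = c(4, 3, 3), seed = 8, p_v2 = 0)
  co <- sim$cohort
  out <- mice_impute(co, seed = 99)
  expect_identical(out$cohort$ogtt, co$ogtt)
  expect_identical(out$cohort$ivgtt, co$ivgtt)
  expect_equal(nrow(out$log), 0L)

  masked <- inject_missingness(co, rate = 0.08, seed = 4)$cohort
  r1 <- mice_impute(masked, seed = 123)
  r2 <- mice_impute(masked, seed = 123)
  expect_identical(r1$cohort$ogtt, r2$cohort$ogtt)
  r3 <- mice_impute(masked, seed = 124)
  expect_false(identical(r1$cohort$ogtt$value, r3$cohort$ogtt$value))
})

test_that("imputed cells track the truth; observed cells never change", {
  sim <- simulate_cohort(n = c(20, 20, 20), seed = 31, p_v2 = 0)
  co <- sim$cohort
  co$ivgtt <- NULL
  inj <- inject_missingness(co, rate = 0.10, seed = 6)
  imp <- mice_impute(inj$cohort, seed = 7)
  # observed cells are bit-identical
  obs <- !is.na(inj$cohort$ogtt$value)
  expect_identical(imp$cohort$ogtt$value[obs], inj$cohort$ogtt$value[obs])
  # recover the glucose cells and compare with the pre-masking truth
  mk <- inj$mask[inj$mask$analyte == "glucose", ]
  key <- paste(imp$cohort$ogtt$id, imp$cohort$ogtt$visit,
               imp$cohort$ogtt$analyte, imp$cohort$ogtt$time_min)
  got <- imp$cohort$ogtt$value[match(paste(mk$id, mk$visit, mk$analyte,
                                           mk$time_min), key)]
  filled <- !is.na(got)
  expect_gt(mean(filled), 0.8)  # only >=50%-missing curves stay unfilled
  rel_err <- abs(got[filled] - mk$true_value[filled]) / mk$true_value[filled]
  # imputation error is small on the concentration scale ...
  expect_lt(mean(rel_err), 0.10)
  # ... and downstream mean glucose is essentially unbiased (< 2%)
  idx_true <- compute_indices(co)
  idx_imp <- compute_indices(imp$cohort)
  mg <- merge(idx_true[c("id", "visit", "glucose_mean")],
              idx_imp[c("id", "visit", "glucose_mean")], by = c("id", "visit"))
  bias <- abs(mean(mg$glucose_mean.y / mg$glucose_mean.x - 1))
  expect_lt(bias, 0.02)
})

test_that("full-visit dropout flows into the exclusion path", {
  sim <- simulate_cohort(n = c(4, 3, 3), seed = 12, p_v2 = 0)
  inj <- inject_missingness(sim$cohort, dropout_n = 2, seed = 5)
  rep_ <- missingness_report(inj$cohort)
  dropped <- unique(inj$mask$id)
  expect_length(dropped, 2)
  expect_true(all(!rep_$eligible[rep_$id %in% dropped & rep_$test == "ogtt"]))
  imp <- mice_impute(inj$cohort, seed = 1)
  # dropped experiments are not imputed
  expect_false(any(imp$log$id %in% dropped & imp$log$test == "ogtt"))
})
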