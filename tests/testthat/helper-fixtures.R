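# shared fixtures and independent oracles, built in code at test time

og_curve <- function(values, analyte = "glucose") {
  sampled_curve(analyte, ogtt_grid(), values, grid = ogtt_grid())
}

# a well-formed three-subject cohort with OGTT and IVGTT data
tiny_cohort <- function() {
  subjects <- data.frame(
    id = c("A", "B", "C"),
    group = c("RYGB", "obese_control", "normal_weight_control"),
    age_years = c(31, 33, 29), parity = c(1, 2, 0),
    bmi_pre_surgery = c(46, NA, NA),
    bmi_pregestational = c(28, 38, 22),
    bmi_v1 = c(31, 41, 25), weight_gain_kg = c(9, 8, 10),
    years_since_surgery = c(3.3, NA, NA),
    birthweight_percentile = c(30, 70, 45),
    multiple_pregnancy = c(FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  long <- function(id, analyte, times, values)
    data.frame(id = id, visit = "V1", analyte = analyte, time_min = times,
               value = values, stringsAsFactors = FALSE)
  ogtt <- rbind(
    long("A", "glucose", ogtt_grid(), c(4.1, 9.9, 5.0, 2.4, 2.9, 3.4, 3.9)),
    long("A", "insulin", ogtt_grid(), c(47, 900, 400, 100, 90, 80, 70)),
    long("B", "glucose", ogtt_grid(), c(4.8, 6.4, 8.7, 7.5, 6.4, 5.5, 4.7)),
    long("B", "insulin", ogtt_grid(), c(132, 600, 1200, 1000, 800, 500, 300)),
    long("C", "glucose", ogtt_grid(), c(4.2, 5.4, 7.0, 6.0, 5.2, 4.5, 3.9)),
    long("C", "insulin", ogtt_grid(), c(51, 300, 600, 450, 300, 150, 90)))
  ivgtt <- rbind(
    long("A", "glucose", ivgtt_grid(),
         c(4.1, 13.5, 13.1, 12.7, 12.4, 11.7, 11.1, 9.8, 8.7, 6.9, 5.9, 5.2, 4.8)),
    long("A", "insulin", ivgtt_grid(),
         c(47, 800, 700, 620, 560, 460, 390, 250, 160, 1100, 600, 300, 160)))
  gp_cohort(subjects, ogtt, ivgtt)
}

# brute-force relative effect: P(X < Y) + 0.5 P(X = Y) by enumeration
bf_relative_effect <- function(x, y) {
  s <- outer(x, y, function(a, b) (a < b) + 0.5 * (a == b))
  mean(s)
}

# brute-force two-sided Fisher p for a 2x2 table: enumerate all tables
# with the observed margins, sum hypergeometric probabilities <= observed
bf_fisher_p <- function(tab) {
  r <- rowSums(tab); c1 <- colSums(tab)[1]
  a_range <- max(0, c1 - r[2]):min(r[1], c1)
  probs <- stats::dhyper(a_range, r[1], r[2], c1)
  p_obs <- stats::dhyper(tab[1, 1], r[1], r[2], c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# fine-grid numeric integral of the piecewise-linear interpolant
bf_auc <- function(times, values, t0, t1, dt = 0.01) {
  tt <- seq(t0, t1, by = dt)
  vv <- stats::approx(times, values, xout = tt)$y
  sum((vv[-1] + vv[-length(vv)]) / 2) * dt
}

# explicit second-difference loop for the glucose shape index
bf_whosh <- function(values, h = 30, norm = 2.24e-3) {
  acc <- 0
  for (i in 2:(length(values) - 1))
    acc <- acc + abs(values[i - 1] - 2 * values[i] + values[i + 1])
  (acc / (length(values) - 2)) / h^2 / norm
}
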