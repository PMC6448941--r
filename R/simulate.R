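#' Group templates for the synthetic cohort generator
#'
#' Each template encodes one study arm's latent physiology: OGTT glucose
#' knot levels (fasting, post-load peak, post-load nadir, 180-min recovery,
#' all mmol/l, as lognormal medians with between-subject log-SDs), knot
#' times, insulin/C-peptide fasting and peak levels, IVGTT parameters
#' (bolus glucose rise, glucose disappearance rate KG, target acute insulin
#' response, exogenous insulin bump), covariate distributions, the
#' neonatal-outcome copula loadings, and postpartum (V2) multipliers.
#'
#' Defaults emulate the three arms of a pregnancy-after-gastric-bypass
#' cohort: RYGB subjects show an early (30 min) exaggerated glucose peak
#' followed by a sub-fasting nadir (median 2.36 mmol/l at 90 min), obese
#' controls a slow high excursion with a late, near-fasting minimum, and
#' normal-weight controls an intermediate curve. Fasting glucose medians
#' 4.15 / 4.78 / 4.16 mmol/l, peaks 9.95 / 8.71 / 7.01 mmol/l, fasting
#' insulin 47 / 132 / 51 pmol/l, and group BMI distributions follow the
#' published arm summaries; between-subject spreads are calibrated so
#' simulated cohort SDs approximate the printed ones (approximate by
#' design).
#'
#' @return Named list of three templates (`RYGB`, `obese_control`,
#'   `normal_weight_control`).
#' @export
default_templates <- function() {
  base <- function(label, fasting, fasting_sd, peak, peak_sd, peak_t,
                   nadir, nadir_sd, nadir_t, recovery,
                   ifast, ifast_sd, ipeak, ipeak_sd,
                   cfast, cpeak, glucagon_rise,
                   sec_nadir_rho, kg, kg_sd, airg, airg_sd,
                   bmi_pg, bmi_pg_sd, bmi_v1, bmi_v1_sd,
                   p_multiple, outcome_m, rho_nadir,
                   v2_fasting_mult, v2_kg_mult) {
    list(label = label,
         fasting = fasting, fasting_sd = fasting_sd,
         peak = peak, peak_sd = peak_sd, peak_t = peak_t,
         nadir = nadir, nadir_sd = nadir_sd, nadir_t = nadir_t,
         recovery = recovery,
         ifast = ifast, ifast_sd = ifast_sd,
         ipeak = ipeak, ipeak_sd = ipeak_sd,
         cfast = cfast, cpeak = cpeak,
         sec_nadir_rho = sec_nadir_rho,
         glucagon_base = 100, glucagon_rise = glucagon_rise,
         ivgtt_dg = 9.5, kg = kg, kg_sd = kg_sd,
         airg = airg, airg_sd = airg_sd, exo_insulin = 1200,
         age = 31.5, age_sd = 6, parity_max = 3,
         bmi_pg = bmi_pg, bmi_pg_sd = bmi_pg_sd,
         bmi_v1 = bmi_v1, bmi_v1_sd = bmi_v1_sd,
         weight_gain = 9.0, weight_gain_sd = 5.0,
         p_multiple = p_multiple,
         outcome_m = outcome_m, rho_nadir = rho_nadir, b_bmi = 0.2,
         v2 = list(fasting_mult = v2_fasting_mult, kg_mult = v2_kg_mult,
                   airg_mult = 0.95))
  }
  list(
    RYGB = c(base("RYGB",
                  fasting = 4.15, fasting_sd = 0.07,
                  peak = 9.95, peak_sd = 0.22, peak_t = 30,
                  nadir = 2.36, nadir_sd = 0.26, nadir_t = 90,
                  recovery = 4.4,
                  ifast = 47, ifast_sd = 0.35, ipeak = 1150, ipeak_sd = 0.45,
                  cfast = 0.58, cpeak = 5.89, glucagon_rise = 0.8,
                  sec_nadir_rho = -0.5, kg = 0.016, kg_sd = 0.25, airg = 520, airg_sd = 0.35,
                  bmi_pg = 28.6, bmi_pg_sd = 5.0, bmi_v1 = 32.0,
                  bmi_v1_sd = 5.2, p_multiple = 0.2,
                  outcome_m = -0.257, rho_nadir = 0.90,
                  v2_fasting_mult = 1.08, v2_kg_mult = 1.9),
             list(bmi_pre_surgery = 46.8, bmi_pre_surgery_sd = 7.6,
                  years_since_surgery = 3.3, years_since_surgery_sd = 0.5)),
    obese_control = base("obese_control",
                         fasting = 4.78, fasting_sd = 0.11,
                         peak = 8.71, peak_sd = 0.20, peak_t = 60,
                         nadir = 4.67, nadir_sd = 0.12, nadir_t = 180,
                         recovery = NA,
                         ifast = 132, ifast_sd = 0.30, ipeak = 1226,
                         ipeak_sd = 0.50, cfast = 1.13, cpeak = 4.97,
                         glucagon_rise = 0.05,
                         sec_nadir_rho = 0, kg = 0.008, kg_sd = 0.25, airg = 800, airg_sd = 0.40,
                         bmi_pg = 38.0, bmi_pg_sd = 2.9, bmi_v1 = 41.1,
                         bmi_v1_sd = 4.3, p_multiple = 0.16,
                         outcome_m = 0.626, rho_nadir = 0.30,
                         v2_fasting_mult = 1.05, v2_kg_mult = 1.15),
    normal_weight_control = base("normal_weight_control",
                                 fasting = 4.16, fasting_sd = 0.08,
                                 peak = 7.01, peak_sd = 0.17, peak_t = 60,
                                 nadir = 3.83, nadir_sd = 0.17, nadir_t = 180,
                                 recovery = NA,
                                 ifast = 51, ifast_sd = 0.35, ipeak = 603,
                                 ipeak_sd = 0.30, cfast = 0.63, cpeak = 3.41,
                                 glucagon_rise = 0.05,
                                 sec_nadir_rho = 0, kg = 0.024, kg_sd = 0.25, airg = 570,
                                 airg_sd = 0.35,
                                 bmi_pg = 21.7, bmi_pg_sd = 2.1, bmi_v1 = 25.1,
                                 bmi_v1_sd = 2.5, p_multiple = 0.05,
                                 outcome_m = -0.286, rho_nadir = 0.30,
                                 v2_fasting_mult = 1.05, v2_kg_mult = 1.4)
  )
}

#' Assay noise model
#'
#' Multiplicative lognormal per-sample noise at the assay coefficients of
#' variation: glucose 1.3% (hexokinase method), insulin 5.5% (midpoint of
#' the 4-7% chemiluminescence range), C-peptide 3.5% (of 3-4%), glucagon
#' 5%. `noise_model(0)` switches noise off entirely.
#'
#' @param scale multiplier on all CVs (1 = assay defaults, 0 = noiseless).
#' @return Named list of CVs per analyte.
#' @export
noise_model <- function(scale = 1) {
  lapply(list(glucose = 0.013, insulin = 0.055, c_peptide = 0.035,
              glucagon = 0.05), function(cv) cv * scale)
}

# piecewise log-linear curve through knots, evaluated on a grid
loglin_curve <- function(knot_t, knot_v, grid) {
  keep <- !is.na(knot_v)
  exp(stats::approx(knot_t[keep], log(knot_v[keep]), xout = grid,
                    rule = 2)$y)
}

rlnorm_med <- function(z, median, sdlog) median * exp(sdlog * z)

apply_noise <- function(values, cv) {
  if (cv <= 0) return(values)
  sdlog <- sqrt(log(1 + cv^2))
  values * stats::rlnorm(length(values), -sdlog^2 / 2, sdlog)
}

# latent OGTT curves for one subject given drawn knot levels
latent_ogtt <- function(tpl, fast, peak, nadir) {
  grid <- ogtt_grid()
  if (tpl$nadir_t >= 180) {
    kt <- c(0, tpl$peak_t, 180); kv <- c(fast, peak, nadir)
  } else {
    kt <- c(0, tpl$peak_t, tpl$nadir_t, 180)
    kv <- c(fast, peak, nadir, tpl$recovery * nadir / tpl$nadir)
  }
  glu <- loglin_curve(kt, kv, grid)
  # excitation anchored at 0 for t = 0 so insulin/C-peptide start at fasting
  excit <- pmax(glu - fast, 0) / max(peak - fast, 1e-9)
  excit[1] <- 0
  list(glucose = glu, excitation = excit)
}

#' Simulate one subject
#'
#' Draws one subject from a group template: latent noiseless OGTT and
#' IVGTT curves on the exact protocol grids (piecewise log-linear glucose
#' knots; insulin and C-peptide proportional to the glucose excursion with
#' group-specific gain; IVGTT with exponential glucose decay at the
#' subject's KG and a first-phase insulin peak hitting the subject's AIRg),
#' observed curves = latent x lognormal assay noise, plus the covariate row
#' and the ground-truth index panel computed from the latent curves.
#'
#' @param id subject id string.
#' @param template one element of [default_templates()].
#' @param noise a [noise_model()].
#' @param visit `"V1"` or `"V2"` (postpartum applies the template's V2
#'   multipliers).
#' @param seed optional integer; if given, seeds the RNG first.
#' @param config [gp_config()] used for the ground-truth panel.
#' @return List: `subject` (one-row data.frame), `ogtt`, `ivgtt` (long
#'   data.frames of observed values), `latent` (same shape, noiseless),
#'   `z_nadir` (the latent normal score behind the nadir, used by the
#'   outcome copula).
#' @export
simulate_subject <- function(id, template, noise = noise_model(),
                             visit = "V1", seed = NULL,
                             config = gp_config()) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- template
  if (tpl$fasting <= 0 || tpl$peak <= 0 ||
      (!is.na(tpl$nadir) && tpl$nadir <= 0))
    stop("config error: template implies non-positive concentrations",
         call. = FALSE)
  if (visit == "V2") {
    tpl$fasting <- tpl$fasting * tpl$v2$fasting_mult
    tpl$kg <- tpl$kg * tpl$v2$kg_mult
    tpl$airg <- tpl$airg * tpl$v2$airg_mult
  }
  z_f <- stats::rnorm(1); z_p <- stats::rnorm(1); z_n <- stats::rnorm(1)
  fast <- rlnorm_med(z_f, tpl$fasting, tpl$fasting_sd)
  peak <- rlnorm_med(z_p, tpl$peak, tpl$peak_sd)
  nadir <- rlnorm_med(z_n, tpl$nadir, tpl$nadir_sd)
  peak <- max(peak, 1.05 * max(fast, nadir))  # keep the excursion a peak

  og <- latent_ogtt(tpl, fast, peak, nadir)
  grid <- ogtt_grid()
  ifast <- rlnorm_med(stats::rnorm(1), tpl$ifast, tpl$ifast_sd)
  # insulin response coupled to nadir depth: stronger post-load secretion
  # drives deeper hypoglycaemia (negative loading in the RYGB template)
  rho_s <- tpl$sec_nadir_rho
  z_ip <- rho_s * z_n + sqrt(1 - rho_s^2) * stats::rnorm(1)
  ipeak <- max(rlnorm_med(z_ip, tpl$ipeak, tpl$ipeak_sd), 1.2 * ifast)
  ins <- ifast + (ipeak - ifast) * og$excitation
  cfast <- tpl$cfast * exp(0.2 * stats::rnorm(1))
  cpk <- max(tpl$cpeak * exp(0.2 * stats::rnorm(1)), 1.2 * cfast)
  cpep <- cfast + (cpk - cfast) * og$excitation
  gluca <- tpl$glucagon_base *
    (1 + tpl$glucagon_rise * exp(-((grid - 30) / 40)^2)) *
    seq(1, 0.88, length.out = length(grid))

  # IVGTT latent curves
  ig <- ivgtt_grid()
  kg <- rlnorm_med(stats::rnorm(1), tpl$kg, tpl$kg_sd)
  dg <- tpl$ivgtt_dg * exp(0.15 * stats::rnorm(1))
  ivg <- ifelse(ig < 3, fast,
                fast + dg * exp(-kg * (ig - 3)) *
                  ifelse(ig > 20, exp(-0.5 * kg * (ig - 20)), 1))
  airg_t <- rlnorm_med(stats::rnorm(1), tpl$airg, tpl$airg_sd)
  tau <- 6
  shape <- exp(-(c(3, 4, 5, 6, 8, 10) - 3) / tau)
  A <- airg_t / mean(shape)
  endog <- ifelse(ig < 3, 0, A * exp(-(ig - 3) / tau))
  exo_profile <- stats::approx(c(0, 15, 20, 30, 40, 50, 60),
                               c(0, 0, 0.1, 1, 0.45, 0.2, 0.1),
                               xout = ig)$y
  exo <- tpl$exo_insulin * exp(0.15 * stats::rnorm(1)) * exo_profile
  ivi <- ifast + endog + exo
  ivc <- cfast * (pmax(ifast + endog, 1e-6) / ifast)^0.6

  # covariates
  bmi_v1 <- max(rlnorm_med(stats::rnorm(1), tpl$bmi_v1,
                           tpl$bmi_v1_sd / tpl$bmi_v1), 16)
  bmi_pg <- max(rlnorm_med(stats::rnorm(1), tpl$bmi_pg,
                           tpl$bmi_pg_sd / tpl$bmi_pg), 15)
  subject <- data.frame(
    id = id, group = tpl$label,
    age_years = round(stats::rnorm(1, tpl$age, tpl$age_sd), 1),
    parity = sample.int(tpl$parity_max + 1L, 1) - 1L,
    bmi_pre_surgery = if (!is.null(tpl$bmi_pre_surgery))
      max(stats::rnorm(1, tpl$bmi_pre_surgery, tpl$bmi_pre_surgery_sd), 30)
      else NA_real_,
    bmi_pregestational = bmi_pg,
    bmi_v1 = bmi_v1,
    weight_gain_kg = stats::rnorm(1, tpl$weight_gain, tpl$weight_gain_sd),
    years_since_surgery = if (!is.null(tpl$years_since_surgery))
      rlnorm_med(stats::rnorm(1), tpl$years_since_surgery,
                 tpl$years_since_surgery_sd) else NA_real_,
    birthweight_percentile = NA_real_,  # filled by the cohort-level copula
    multiple_pregnancy = stats::runif(1) < tpl$p_multiple,
    stringsAsFactors = FALSE)

  long <- function(analyte, times, values)
    data.frame(id = id, visit = visit, analyte = analyte, time_min = times,
               value = values, stringsAsFactors = FALSE)
  latent_ogtt_df <- rbind(long("glucose", grid, og$glucose),
                          long("insulin", grid, ins),
                          long("c_peptide", grid, cpep),
                          long("glucagon", grid, gluca))
  latent_ivgtt_df <- rbind(long("glucose", ig, ivg),
                           long("insulin", ig, ivi),
                           long("c_peptide", ig, ivc))
  obs_ogtt <- latent_ogtt_df
  obs_ivgtt <- latent_ivgtt_df
  for (an in unique(obs_ogtt$analyte)) {
    sel <- obs_ogtt$analyte == an
    obs_ogtt$value[sel] <- apply_noise(obs_ogtt$value[sel], noise[[an]])
  }
  for (an in unique(obs_ivgtt$analyte)) {
    sel <- obs_ivgtt$analyte == an
    obs_ivgtt$value[sel] <- apply_noise(obs_ivgtt$value[sel], noise[[an]])
  }
  list(subject = subject, ogtt = obs_ogtt, ivgtt = obs_ivgtt,
       latent = list(ogtt = latent_ogtt_df, ivgtt = latent_ivgtt_df),
       z_nadir = z_n)
}

#' Simulate a three-group cohort with ground truth
#'
#' Independent subjects per group (default arm sizes 25/19/19), a fraction
#' of whom also receive a postpartum (V2) test pair; neonatal birthweight
#' percentiles are generated by a Gaussian copula so that within each group
#' the percentile is rank-correlated with the subject's latent glucose
#' nadir (target Spearman ~0.89 in the RYGB arm) and mildly with BMI.
#' Returns both the observed cohort and the latent (noiseless) cohort plus
#' the ground-truth index table computed from the latent curves.
#'
#' @param n integer vector of arm sizes, in the order of `templates`.
#' @param templates [default_templates()] or overrides.
#' @param noise [noise_model()].
#' @param seed integer seed; the entire cohort is reproducible from it.
#' @param p_v2 fraction of subjects re-examined postpartum.
#' @param config [gp_config()].
#' @return List of class `"gp_simulation"`: `cohort` ([gp_cohort()]),
#'   `latent_cohort`, `truth` (index table from latent curves), `seed`.
#' @examples
#' sim <- simulate_cohort(n = c(5, 4, 4), seed = 1)
#' sim$cohort
#' @export
simulate_cohort <- function(n = c(25, 19, 19), templates = default_templates(),
                            noise = noise_model(), seed = 1L, p_v2 = 0.75,
                            config = gp_config()) {
  stopifnot(length(n) == length(templates), all(n >= 1))
  set.seed(seed)
  subs <- list(); og <- list(); iv <- list(); log_og <- list();
  liv <- list(); zn <- numeric(0); zb <- numeric(0)
  k <- 0L
  for (gi in seq_along(templates)) {
    tpl <- templates[[gi]]
    for (s in seq_len(n[gi])) {
      k <- k + 1L
      id <- sprintf("S%03d", k)
      one <- simulate_subject(id, tpl, noise, visit = "V1", config = config)
      if (stats::runif(1) < p_v2) {
        two <- simulate_subject(id, tpl, noise, visit = "V2", config = config)
        two$subject <- NULL
        one$ogtt <- rbind(one$ogtt, two$ogtt)
        one$ivgtt <- rbind(one$ivgtt, two$ivgtt)
        one$latent$ogtt <- rbind(one$latent$ogtt, two$latent$ogtt)
        one$latent$ivgtt <- rbind(one$latent$ivgtt, two$latent$ivgtt)
      }
      # copula scores: nadir RE and the subject's BMI score
      zn[k] <- one$z_nadir
      zb[k] <- (one$subject$bmi_v1 - tpl$bmi_v1) / tpl$bmi_v1_sd
      rho <- tpl$rho_nadir; b <- tpl$b_bmi
      w <- tpl$outcome_m + rho * zn[k] + b * zb[k] +
        sqrt(max(1 - rho^2 - b^2, 0)) * stats::rnorm(1)
      one$subject$birthweight_percentile <- 100 * stats::pnorm(w)
      subs[[k]] <- one$subject
      og[[k]] <- one$ogtt; iv[[k]] <- one$ivgtt
      log_og[[k]] <- one$latent$ogtt; liv[[k]] <- one$latent$ivgtt
    }
  }
  subjects <- do.call(rbind, subs)
  cohort <- gp_cohort(subjects, do.call(rbind, og), do.call(rbind, iv))
  latent <- gp_cohort(subjects, do.call(rbind, log_og), do.call(rbind, liv))
  truth <- compute_indices(latent, config = config)
  structure(list(cohort = cohort, latent_cohort = latent, truth = truth,
                 seed = seed),
            class = "gp_simulation")
}

#' @export
print.gp_simulation <- function(x, ...) {
  cat("<gp_simulation, seed ", x$seed, ">\n", sep = "")
  print(x$cohort)
  invisible(x)
}

#' Mask cells or whole experiments to emulate missing examinations
#'
#' Either MCAR masking of individual samples at a given rate, or full-visit
#' dropout of whole experiments for `k` subjects (emulating skipped OGTT /
#' IVGTT appointments). Masked cells have their `value` set to `NA`; the
#' pre-masking values are returned for imputation scoring.
#'
#' @param cohort a [gp_cohort()].
#' @param rate MCAR masking probability per cell, in `[0, 1)`.
#' @param dropout_n number of subjects whose entire OGTT (per
#'   `dropout_test`) is masked.
#' @param dropout_test `"ogtt"` or `"ivgtt"`.
#' @param seed integer seed.
#' @return List: `cohort` (masked), `mask` (data.frame of masked cells with
#'   the true values).
#' @export
inject_missingness <- function(cohort, rate = 0, dropout_n = 0,
                               dropout_test = "ogtt", seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  set.seed(seed)
  mask <- list()
  for (test in c("ogtt", "ivgtt")) {
    df <- cohort[[test]]
    if (is.null(df) || !nrow(df)) next
    hit <- stats::runif(nrow(df)) < rate & !is.na(df$value)
    if (dropout_n > 0 && test == dropout_test) {
      ids <- sample(unique(df$id), min(dropout_n, length(unique(df$id))))
      hit <- hit | (df$id %in% ids & !is.na(df$value))
    }
    if (any(hit)) {
      mask[[test]] <- data.frame(test = test, df[hit, c("id", "visit",
                                                        "analyte", "time_min")],
                                 true_value = df$value[hit])
      df$value[hit] <- NA_real_
      cohort[[test]] <- df
    }
  }
  list(cohort = cohort,
       mask = if (length(mask)) do.call(rbind, mask) else NULL)
}
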