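#' Compute the derived index panel for every subject-visit
#'
#' Walks the cohort and computes, per subject-visit: OGTT glucose summary
#' (fasting/max/mean/nadir), hypoglycaemia and GDM flags, the glucose shape
#' index, QUICKI, 2-h OGIS, the three AUC-ratio secretion indices, and the
#' IVGTT panel (AIRg, CSI, disposition index). An index whose required
#' samples are missing is reported as `NA` rather than aborting the row.
#'
#' @param cohort a [gp_cohort()].
#' @param config [gp_config()].
#' @param imputation_log optional log from [mice_impute()]; when given, the
#'   per-row provenance flags `ogtt_imputed` / `ivgtt_imputed` mark panels
#'   that consumed imputed inputs.
#' @return data.frame, one row per subject-visit (the index table).
#' @export
compute_indices <- function(cohort, config = gp_config(),
                            imputation_log = NULL) {
  subj <- cohort$subjects
  occ <- unique(rbind(cohort$ogtt[c("id", "visit")],
                      if (!is.null(cohort$ivgtt))
                        cohort$ivgtt[c("id", "visit")]))
  occ <- occ[order(occ$id, occ$visit), ]
  try_na <- function(expr) tryCatch(expr, error = function(e) NA)
  rows <- lapply(seq_len(nrow(occ)), function(i) {
    id <- occ$id[i]; vis <- occ$visit[i]
    srow <- subj[subj$id == id, ]
    glu <- cohort_curve(cohort, id, vis, "glucose", "ogtt")
    ins <- cohort_curve(cohort, id, vis, "insulin", "ogtt")
    gs <- if (!is.null(glu)) try_na(glucose_summary(glu)) else NA
    has_gs <- is.list(gs)
    q <- o <- NA_real_
    if (has_gs && !is.null(ins)) {
      i0 <- curve_at(ins, 0)
      if (!is.na(gs$fasting) && !is.na(i0))
        q <- try_na(quicki(gs$fasting, i0, config))
      o <- try_na(ogis_120(gs$fasting, curve_at(glu, 90), curve_at(glu, 120),
                           i0, curve_at(ins, 90),
                           bmi = if (nrow(srow)) srow$bmi_v1 else NA,
                           config = config))
    }
    sec <- function(w) {
      if (is.null(ins) || is.null(glu)) return(NA_real_)
      try_na(secretion_ratio(ins, glu, w))
    }
    ivg <- cohort_curve(cohort, id, vis, "glucose", "ivgtt")
    ivi <- cohort_curve(cohort, id, vis, "insulin", "ivgtt")
    a <- cs <- NA_real_
    if (!is.null(ivi)) a <- try_na(suppressWarnings(airg(ivi, config)))
    if (!is.null(ivg) && !is.null(ivi)) {
      rec <- ivgtt_record(id, vis, list(glucose = ivg, insulin = ivi))
      cs <- try_na(csi(rec, config))
    }
    data.frame(
      id = id, visit = vis,
      group = if (nrow(srow)) srow$group else NA_character_,
      glucose_fasting = if (has_gs) gs$fasting else NA_real_,
      glucose_max = if (has_gs) gs$max else NA_real_,
      glucose_mean = if (has_gs) gs$mean else NA_real_,
      glucose_nadir = if (has_gs) gs$nadir else NA_real_,
      hypoglycaemia = if (has_gs)
        gs$nadir < config$hypoglycaemia$threshold else NA,
      gdm = if (!is.null(glu)) try_na(classify_gdm(glu, config)$flag) else NA,
      whosh_g = if (!is.null(glu)) try_na(whosh_g(glu, config)) else NA_real_,
      quicki = q, ogis = o,
      secretion_early = sec("early"), secretion_late = sec("late"),
      secretion_total = sec("total"),
      airg = a, csi = cs,
      di = if (is.na(a) || is.na(cs)) NA_real_ else disposition_index(cs, a),
      ogtt_imputed = has_imputed(imputation_log, id, vis, "ogtt"),
      ivgtt_imputed = has_imputed(imputation_log, id, vis, "ivgtt"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

has_imputed <- function(log, id, vis, test) {
  if (is.null(log) || !nrow(log)) return(FALSE)
  any(log$id == id & log$visit == vis & log$test == test)
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
}
mean_sd <- function(x) sprintf("%.3g ± %.3g", mean(x, na.rm = TRUE),
                               stats::sd(x, na.rm = TRUE))

# variables reported per table, with the summary style used for each
baseline_variables <- function() {
  c(quicki = "mean_sd", ogis = "mean_sd",
    secretion_early = "med_iqr", secretion_late = "med_iqr",
    secretion_total = "med_iqr",
    glucose_fasting = "mean_sd", glucose_max = "mean_sd",
    glucose_mean = "mean_sd", glucose_nadir = "mean_sd",
    whosh_g = "mean_sd", airg = "med_iqr", csi = "med_iqr", di = "med_iqr")
}

#' Baseline (three-group) comparison report
#'
#' Per-group summaries (mean +/- SD or median (IQR), following each
#' variable's conventional presentation) of every index-panel variable at
#' the pregnancy visit, with pairwise rank-based (Brunner-Munzel) tests of
#' each control group against the RYGB arm; `flag` marks p <= alpha.
#'
#' @param cohort a [gp_cohort()] (or a [simulate_cohort()] result).
#' @param config [gp_config()].
#' @param indices optionally a precomputed [compute_indices()] table.
#' @param visit visit to report (default `"V1"`).
#' @return data.frame of class `"gp_report"`, one row per (variable,
#'   comparison).
#' @export
run_baseline_comparison <- function(cohort, config = gp_config(),
                                    indices = NULL, visit = "V1") {
  if (inherits(cohort, "gp_simulation")) cohort <- cohort$cohort
  if (is.null(indices)) indices <- compute_indices(cohort, config)
  idx <- indices[indices$visit == visit, ]
  if (!all(gp_groups() %in% idx$group))
    stop("config error: all three groups must be present", call. = FALSE)
  vars <- baseline_variables()
  out <- list()
  for (v in names(vars)) {
    x <- split(idx[[v]], idx$group)
    ref <- x[["RYGB"]]
    for (g in setdiff(gp_groups(), "RYGB")) {
      bm <- tryCatch(brunner_munzel(ref, x[[g]]),
                     error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        variable = v,
        rygb = if (vars[[v]] == "mean_sd") mean_sd(ref) else med_iqr(ref),
        comparator = g,
        comparator_summary = if (vars[[v]] == "mean_sd") mean_sd(x[[g]])
                             else med_iqr(x[[g]]),
        p_hat = if (is.null(bm)) NA_real_ else bm$p_hat,
        p.value = if (is.null(bm)) NA_real_ else bm$p.value,
        flag = if (is.null(bm)) FALSE else bm$p.value <= config$alpha,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("gp_report", "data.frame"))
}

#' BMI-matched pairs comparison report
#'
#' Runs [propensity_match()] (default covariate: BMI at the first visit),
#' then compares RYGB vs the matched control set on the index-panel
#' variables by Brunner-Munzel tests with median (IQR) summaries. With
#' zero matched pairs an empty report (0 rows) is returned.
#'
#' @inheritParams run_baseline_comparison
#' @return `"gp_report"` data.frame plus attributes `match` (the
#'   [propensity_match()] object).
#' @export
run_matched_comparison <- function(cohort, config = gp_config(),
                                   indices = NULL, visit = "V1") {
  if (inherits(cohort, "gp_simulation")) cohort <- cohort$cohort
  if (is.null(indices)) indices <- compute_indices(cohort, config)
  m <- propensity_match(cohort, config)
  idx <- indices[indices$visit == visit, ]
  out <- list()
  if (nrow(m$pairs)) {
    treated <- idx[match(m$pairs$treated_id, idx$id), ]
    control <- idx[match(m$pairs$control_id, idx$id), ]
    for (v in names(baseline_variables())) {
      bm <- tryCatch(brunner_munzel(treated[[v]], control[[v]]),
                     error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        variable = v, rygb = med_iqr(treated[[v]]),
        matched_control = med_iqr(control[[v]]),
        p_hat = if (is.null(bm)) NA_real_ else bm$p_hat,
        p.value = if (is.null(bm)) NA_real_ else bm$p.value,
        flag = if (is.null(bm)) FALSE else bm$p.value <= config$alpha,
        stringsAsFactors = FALSE)
    }
  }
  rep_ <- if (length(out)) do.call(rbind, out) else
    data.frame(variable = character(0), rygb = character(0),
               matched_control = character(0), p_hat = numeric(0),
               p.value = numeric(0), flag = logical(0))
  structure(rep_, class = c("gp_report", "data.frame"), match = m)
}

#' Pregnancy vs postpartum (paired) comparison report
#'
#' Paired rank tests per variable on the RYGB subjects with both visits,
#' reporting the per-variable number of usable pairs, as visit-comparison
#' tables do.
#'
#' @inheritParams run_baseline_comparison
#' @param group which arm to follow longitudinally (default `"RYGB"`).
#' @return `"gp_report"` data.frame: `variable`, `n_pairs`, `v1`, `v2`
#'   (median (IQR)), `p.value`.
#' @export
run_visit_comparison <- function(cohort, config = gp_config(),
                                 indices = NULL, group = "RYGB") {
  if (inherits(cohort, "gp_simulation")) cohort <- cohort$cohort
  if (is.null(indices)) indices <- compute_indices(cohort, config)
  idx <- indices[indices$group == group, ]
  v1 <- idx[idx$visit == "V1", ]; v2 <- idx[idx$visit == "V2", ]
  both <- intersect(v1$id, v2$id)
  out <- list()
  for (v in names(baseline_variables())) {
    a <- v1[[v]][match(both, v1$id)]
    b <- v2[[v]][match(both, v2$id)]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) next
    pt <- tryCatch(paired_rank_test(a[ok], b[ok]), error = function(e) NULL)
    out[[length(out) + 1L]] <- data.frame(
      variable = v, n_pairs = sum(ok), v1 = med_iqr(a[ok]),
      v2 = med_iqr(b[ok]),
      p.value = if (is.null(pt)) NA_real_ else pt$p.value,
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("gp_report", "data.frame"))
}

#' Neonatal-outcome association report
#'
#' Spearman correlations (with Fisher-z CIs) of the birthweight percentile
#' against pre-gestational BMI, BMI at the first visit, mean OGTT glucose
#' and the glucose nadir -- across the whole cohort and within the RYGB
#' arm -- plus the within-RYGB correlations of the percentile with early
#' and total insulin secretion. Multiple pregnancies are excluded (the
#' percentile standard assumes singletons); subjects without a percentile
#' are dropped and counted.
#'
#' @inheritParams run_baseline_comparison
#' @param exclude_multiple drop multiple pregnancies (default TRUE).
#' @return `"gp_report"` data.frame: `scope`, `variable`, `rho`, `ci_low`,
#'   `ci_high`, `p.value`, `n`; attribute `n_excluded`.
#' @export
run_association_analysis <- function(cohort, config = gp_config(),
                                     indices = NULL,
                                     exclude_multiple = TRUE) {
  if (inherits(cohort, "gp_simulation")) cohort <- cohort$cohort
  if (is.null(indices)) indices <- compute_indices(cohort, config)
  subj <- cohort$subjects
  n0 <- nrow(subj)
  if (exclude_multiple && "multiple_pregnancy" %in% names(subj))
    subj <- subj[!isTRUE_v(subj$multiple_pregnancy), ]
  subj <- subj[!is.na(subj$birthweight_percentile), ]
  idx <- indices[indices$visit == "V1", ]
  d <- merge(subj, idx, by = "id", suffixes = c("", ".idx"))
  pairs <- list(
    c("all", "bmi_pregestational"), c("all", "bmi_v1"),
    c("all", "glucose_mean"), c("all", "glucose_nadir"),
    c("RYGB", "glucose_nadir"), c("RYGB", "secretion_early"),
    c("RYGB", "secretion_total"))
  out <- list()
  for (p in pairs) {
    dd <- if (p[1] == "all") d else d[d$group == "RYGB", ]
    sc <- tryCatch(spearman_ci(dd[[p[2]]], dd$birthweight_percentile),
                   error = function(e) NULL)
    out[[length(out) + 1L]] <- data.frame(
      scope = p[1], variable = p[2],
      rho = if (is.null(sc)) NA_real_ else sc$rho,
      ci_low = if (is.null(sc)) NA_real_ else sc$conf.int[1],
      ci_high = if (is.null(sc)) NA_real_ else sc$conf.int[2],
      p.value = if (is.null(sc)) NA_real_ else sc$p.value,
      n = if (is.null(sc)) 0L else sc$n, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("gp_report", "data.frame"),
            n_excluded = n0 - nrow(subj))
}

isTRUE_v <- function(x) !is.na(x) & x

#' @export
print.gp_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
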