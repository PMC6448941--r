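#' Insulinogenic (AUC-ratio) secretion indices
#'
#' Post-hepatic insulin secretion expressed as the ratio of the insulin AUC
#' to the glucose AUC over a window of the OGTT: early (0-60 min), late
#' (60-180 min) or total (0-180 min). Units pmol/mmol.
#'
#' @param insulin,glucose [sampled_curve()]s on the OGTT grid.
#' @param window `"early"`, `"late"` or `"total"`.
#' @return Ratio in pmol/mmol, strictly positive.
#' @examples
#' ins <- sampled_curve("insulin", ogtt_grid(), rep(300, 7))
#' glu <- sampled_curve("glucose", ogtt_grid(), rep(5, 7))
#' secretion_ratio(ins, glu, "early")  # 60
#' @export
secretion_ratio <- function(insulin, glucose,
                            window = c("early", "late", "total")) {
  window <- match.arg(window)
  w <- switch(window, early = c(0, 60), late = c(60, 180), total = c(0, 180))
  auc_trapezoid(insulin, w[1], w[2]) / auc_trapezoid(glucose, w[1], w[2])
}

#' Glucose curve summary: fasting, maximum, mean, nadir
#'
#' Fasting is the t = 0 sample; maximum and mean are over all non-missing
#' samples 0-180 min (mean = unweighted mean of the sampled values, the
#' 7-point grid convention; set `time_weighted = TRUE` for the AUC/duration
#' alternative); the nadir is the minimum over post-load samples (t > 0)
#' only -- the fasting value never counts as a nadir.
#'
#' @param curve glucose [sampled_curve()].
#' @param time_weighted use AUC(0-180)/180 as the mean instead of the
#'   unweighted sample mean.
#' @return List with `fasting`, `max`, `mean`, `nadir` (mmol/l).
#' @export
glucose_summary <- function(curve, time_weighted = FALSE) {
  stopifnot(inherits(curve, "sampled_curve"))
  if (all(is.na(curve$values)))
    stop("insufficient data: all-missing glucose curve", call. = FALSE)
  fasting <- curve_at(curve, 0)
  post <- curve$values[curve$times > 0]
  if (all(is.na(post)))
    stop("insufficient data: no post-load glucose samples", call. = FALSE)
  m <- if (time_weighted) {
    auc_trapezoid(curve, min(curve$times), max(curve$times)) /
      diff(range(curve$times))
  } else mean(curve$values, na.rm = TRUE)
  list(fasting = fasting,
       max = max(curve$values, na.rm = TRUE),
       mean = m,
       nadir = min(post, na.rm = TRUE))
}

#' Glucose shape (variability) index from second differences
#'
#' The discrete second-order derivative of the 3 h OGTT glucose curve,
#' aggregated as the mean absolute central second difference divided by
#' the squared sampling interval (30 min)^2, then normalised by a fixed
#' population-mean reference level (default 2.24e-3 mmol/l min^-2) so a
#' typical curve scores near 1. Zero exactly when the curve is affine in
#' time; adding any linear trend leaves it unchanged.
#'
#' @param curve glucose [sampled_curve()] on an equally spaced grid.
#' @param config [gp_config()]; `config$whosh$norm` is the normalisation
#'   constant.
#' @return Dimensionless, >= 0.
#' @export
whosh_g <- function(curve, config = gp_config()) {
  stopifnot(inherits(curve, "sampled_curve"))
  ok <- !is.na(curve$values)
  t <- curve$times[ok]; v <- curve$values[ok]
  if (length(v) < 3)
    stop("insufficient data: shape index needs >= 3 samples", call. = FALSE)
  dt <- diff(t)
  if (length(unique(dt)) != 1L)
    stop("insufficient data: shape index needs equally spaced samples",
         call. = FALSE)
  h <- dt[1]
  n <- length(v)
  d2 <- v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]
  mean(abs(d2)) / h^2 / config$whosh$norm
}

#' Quantitative insulin sensitivity check index (QUICKI)
#'
#' Fasting (hepatic) insulin sensitivity:
#' `1 / (log10 I0 + log10 G0)` with insulin in uU/ml and glucose in mg/dl.
#' Inputs are taken in the study units (pmol/l, mmol/l) and converted with
#' the configured constants.
#'
#' @param fasting_glucose mmol/l.
#' @param fasting_insulin pmol/l.
#' @param config [gp_config()] (unit-conversion constants).
#' @return Dimensionless; typically 0.25-0.5.
#' @examples
#' quicki(4.15, 47)  # ~0.361
#' @export
quicki <- function(fasting_glucose, fasting_insulin, config = gp_config()) {
  if (any(fasting_glucose <= 0) || any(fasting_insulin <= 0))
    stop("fasting concentrations must be positive", call. = FALSE)
  g_mgdl <- fasting_glucose * config$units$glucose_mgdl_per_mmol
  i_uu <- fasting_insulin / config$units$insulin_pmol_per_uu
  s <- log10(i_uu) + log10(g_mgdl)
  if (any(s <= 0))
    stop("domain error: log10(I0) + log10(G0) must be positive",
         call. = FALSE)
  1 / s
}

# DuBois body surface area (m^2) from weight (kg) and height (m)
bsa_dubois <- function(weight_kg, height_m) {
  0.007184 * weight_kg^0.425 * (height_m * 100)^0.725
}

#' Oral glucose insulin sensitivity index (2-h OGIS)
#'
#' Formula-based glucose-clearance estimate from the first 120 min of the
#' OGTT, using glucose at 0, 90 and 120 min and insulin at 0 and 90 min,
#' scaled to body surface area. Glucose is converted to mg/dl and insulin
#' to uU/ml internally; the result is in ml min^-1 m^-2.
#'
#' @param g0,g90,g120 glucose mmol/l at 0, 90, 120 min.
#' @param i0,i90 insulin pmol/l at 0 and 90 min.
#' @param weight_kg,height_m anthropometrics for body surface area; when
#'   `weight_kg` is missing it is derived from `bmi` and the configured
#'   default height.
#' @param bmi BMI kg/m^2, used only as a fallback for weight.
#' @param config [gp_config()]; `config$ogis` holds the formula constants
#'   and the oral dose (75 g).
#' @return OGIS in ml min^-1 m^-2, positive.
#' @export
ogis_120 <- function(g0, g90, g120, i0, i90, weight_kg = NA, height_m = NA,
                     bmi = NA, config = gp_config()) {
  p <- config$ogis
  if (any(vapply(p[c("p1", "p2", "p3", "p4", "p5", "p6")], is.null,
                 logical(1))))
    stop("OGIS constants unset in config", call. = FALSE)
  if (anyNA(c(g0, g90, g120, i0, i90)))
    stop("insufficient data: OGIS needs glucose at 0/90/120 and insulin at 0/90",
         call. = FALSE)
  if (is.na(height_m)) height_m <- p$default_height_m
  if (is.na(weight_kg)) {
    if (is.na(bmi))
      stop("insufficient data: OGIS needs weight or BMI for body surface area",
           call. = FALSE)
    weight_kg <- bmi * height_m^2
  }
  bsa <- bsa_dubois(weight_kg, height_m)
  k <- gp_config()$units$glucose_mgdl_per_mmol
  G0 <- g0 * k; G90 <- g90 * k; G120 <- g120 * k
  I0 <- i0 / gp_config()$units$insulin_pmol_per_uu
  I90 <- i90 / gp_config()$units$insulin_pmol_per_uu
  D0 <- p$dose_g / bsa
  x1 <- p$p4 * ((p$p1 * D0 - p$V * (G120 - G90) / 30) / G90 + p$p3 / G0) /
    (I90 - I0 + p$p2)
  0.5 * (x1 + sqrt(x1^2 + 4 * p$p5 * p$p6 * (G120 - p$Gcl) * x1))
}

#' Gestational diabetes screening classification
#'
#' OR-combination of the three inclusive OGTT thresholds: fasting >= 5.1,
#' 60 min >= 10, 120 min >= 8.5 mmol/l. Returns which components fired.
#'
#' @param curve glucose [sampled_curve()] with samples at 0, 60, 120 min.
#' @param config [gp_config()] (thresholds under `config$gdm`).
#' @return List: `flag` (logical) and `components` (named logical vector
#'   `fasting`, `t60`, `t120`).
#' @export
classify_gdm <- function(curve, config = gp_config()) {
  g <- c(fasting = curve_at(curve, 0), t60 = curve_at(curve, 60),
         t120 = curve_at(curve, 120))
  if (anyNA(g))
    stop("insufficient data: GDM classification needs samples at 0, 60, 120",
         call. = FALSE)
  th <- config$gdm
  comp <- c(fasting = g[["fasting"]] >= th$fasting,
            t60 = g[["t60"]] >= th$t60,
            t120 = g[["t120"]] >= th$t120)
  list(flag = any(comp), components = comp)
}

#' Post-load hypoglycaemia classification
#'
#' Flags a strict nadir below the threshold (default 2.78 mmol/l) among
#' post-load samples (t > 0); the fasting value is never considered.
#'
#' @param curve glucose [sampled_curve()].
#' @param config [gp_config()] (`config$hypoglycaemia$threshold`).
#' @return List: `flag` (logical), `nadir` (mmol/l).
#' @export
classify_hypoglycaemia <- function(curve, config = gp_config()) {
  s <- glucose_summary(curve)
  list(flag = s$nadir < config$hypoglycaemia$threshold, nadir = s$nadir)
}
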