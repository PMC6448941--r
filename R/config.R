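#' Analysis configuration defaults
#'
#' Central store of every fixed constant the index and classification
#' functions use: unit conversions, diagnostic thresholds, the glucose
#' shape-index normalisation, and the OGIS / CSI formula constants.
#' All downstream functions take a `config` argument defaulting to
#' `gp_config()`, so a study can override any constant in one place.
#'
#' @param ... named overrides of the defaults (nested lists are replaced
#'   wholesale, not merged element-wise).
#'
#' @details
#' Units follow clinical convention for this test battery: glucose mmol/l,
#' insulin pmol/l, C-peptide nmol/l. Conversions used internally:
#' glucose mmol/l * 18.016 = mg/dl; insulin pmol/l / 6.0 = uU/ml
#' (the 6.0 pmol per uU convention; some labs use 6.945 -- hence a config
#' constant, not a literal).
#'
#' Components:
#' \describe{
#'   \item{gdm}{OGTT screening thresholds, mmol/l, inclusive (>=):
#'     fasting 5.1, 60 min 10, 120 min 8.5, OR-combined.}
#'   \item{hypoglycaemia}{post-load threshold 2.78 mmol/l, strict (<),
#'     evaluated on samples at t > 0 only.}
#'   \item{whosh}{normalisation constant for the glucose shape index,
#'     2.24e-3 mmol/l min^-2 (a population-mean reference level so the
#'     index is reported on a dimensionless scale near 1).}
#'   \item{ogis}{2-h OGIS formula constants (glucose in mg/dl, insulin
#'     in uU/ml, dose in g per m^2 body surface): p1..p6, distribution
#'     volume V (ml/m^2), glucose clamp reference Gcl (mg/dl), and the
#'     default height (m) used to derive body surface area from BMI when
#'     height/weight are not recorded.}
#'   \item{csi}{IVGTT calculated-sensitivity-index constants: the fitting
#'     window (min) for the glucose disappearance rate KG, the insulin
#'     exposure window (min), and the scale factor `k` placing the result
#'     on the x1e-4 min^-1 (pmol/l)^-1 scale. `k = NULL` disables CSI
#'     (the function refuses to run rather than default silently).}
#'   \item{ivgtt_windows}{AIRg sampling window (3-10 min) and the start of
#'     the exogenous insulin infusion (20 min); AIRg must precede it.}
#'   \item{match}{propensity matching: covariates, caliper in SDs of the
#'     propensity score, caliper scale ("response" or "logit").}
#'   \item{impute}{chained-equation imputation: m completed datasets,
#'     burn-in cycles, missingness ceiling (fraction, exclusive).}
#'   \item{alpha}{two-sided significance level for protected tests and
#'     report flags.}
#' }
#'
#' @return A list of class `"gp_config"`.
#' @examples
#' cfg <- gp_config()
#' cfg$gdm$fasting
#' gp_config(hypoglycaemia = list(threshold = 3.34))$hypoglycaemia$threshold
#' @export
gp_config <- function(...) {
  cfg <- list(
    units = list(
      glucose_mgdl_per_mmol = 18.016,
      insulin_pmol_per_uu   = 6.0
    ),
    gdm = list(fasting = 5.1, t60 = 10.0, t120 = 8.5),
    hypoglycaemia = list(threshold = 2.78),
    whosh = list(norm = 2.24e-3),
    ogis = list(
      p1 = 289, p2 = 270, p3 = 14000, p4 = 440, p5 = 637e-6, p6 = 117,
      V = 1e4, Gcl = 90, dose_g = 75, default_height_m = 1.66
    ),
    csi = list(
      kg_window = c(10, 50),
      exposure_window = c(0, 60),
      k = 1.0
    ),
    ivgtt_windows = list(airg = c(3, 10), insulin_infusion_start = 20),
    match = list(covariates = "bmi_v1", caliper_sd = 0.25,
                 caliper_scale = "response", replace = FALSE),
    impute = list(m = 50, burnin = 10, max_missing = 0.5),
    alpha = 0.05
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "gp_config")
}

#' @export
print.gp_config <- function(x, ...) {
  cat("<glucopreg analysis configuration>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
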