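#' Acute insulin response to glucose (AIRg)
#'
#' Mean incremental insulin concentration 3-10 min after the intravenous
#' glucose bolus: mean of I(t) - I(0) over the samples at 3, 4, 5, 6, 8 and
#' 10 min. The window ends well before the 20-25 min exogenous insulin
#' infusion, so the response is purely endogenous first-phase secretion.
#' AIRg is invariant to vertical shifts of the whole curve. A negative
#' value (insulin falling below fasting after the bolus) is pathological
#' and passed through with a warning.
#'
#' @param insulin [sampled_curve()] on the IVGTT grid.
#' @param config [gp_config()]; `config$ivgtt_windows$airg` is the window.
#' @return AIRg in pmol/l.
#' @examples
#' ins <- sampled_curve("insulin", ivgtt_grid(),
#'   c(50, 400, 500, 550, 450, 350, 300, 200, 150, 600, 400, 150, 80))
#' airg(ins)
#' @export
airg <- function(insulin, config = gp_config()) {
  stopifnot(inherits(insulin, "sampled_curve"))
  w <- config$ivgtt_windows$airg
  i0 <- curve_at(insulin, 0)
  if (is.na(i0))
    stop("insufficient data: fasting insulin sample missing", call. = FALSE)
  keep <- insulin$times >= w[1] & insulin$times <= w[2]
  vals <- insulin$values[keep]
  if (!length(vals) || anyNA(vals))
    stop("insufficient data: AIRg window samples missing (impute first)",
         call. = FALSE)
  out <- mean(vals - i0)
  if (out < 0)
    warning("negative AIRg: insulin fell below fasting after the bolus")
  out
}

#' IVGTT calculated sensitivity index (CSI)
#'
#' Empirical whole-body insulin sensitivity from the insulin-modified
#' IVGTT, on the x1e-4 min^-1 (pmol/l)^-1 scale used for reporting:
#' \deqn{CSI = k \cdot 10^4 \cdot K_G / \bar{\Delta I}}
#' where \eqn{K_G} (min^-1) is the glucose disappearance rate -- the
#' negative least-squares slope of log glucose over the configured fitting
#' window (default 10-50 min) -- and \eqn{\bar{\Delta I}} (pmol/l) is the
#' time-averaged incremental insulin exposure over the configured window
#' (default 0-60 min, which deliberately includes the 20-25 min exogenous
#' infusion: the index measures glucose disposal per unit of circulating
#' insulin, whatever its source). `k` scales the index (default 1) and must
#' be set in the config; the function refuses to run with it unset.
#'
#' @param record an [ivgtt_record()] with glucose and insulin curves.
#' @param config [gp_config()]; constants under `config$csi`.
#' @return CSI on the x1e-4 min^-1 (pmol/l)^-1 scale; higher = more
#'   insulin-sensitive.
#' @export
csi <- function(record, config = gp_config()) {
  stopifnot(inherits(record, "ivgtt_record"))
  cc <- config$csi
  # exact indexing: `$` partial matching must not resurrect removed constants
  cc <- list(k = cc[["k"]], kg_window = cc[["kg_window"]],
             exposure_window = cc[["exposure_window"]])
  if (is.null(cc$k) || is.null(cc$kg_window) || is.null(cc$exposure_window))
    stop("CSI constants unset in config (csi$k, csi$kg_window, csi$exposure_window)",
         call. = FALSE)
  glu <- record$curves$glucose
  ins <- record$curves$insulin
  if (is.null(glu) || is.null(ins))
    stop("insufficient data: CSI needs glucose and insulin curves",
         call. = FALSE)
  keep <- glu$times >= cc$kg_window[1] & glu$times <= cc$kg_window[2]
  t <- glu$times[keep]; g <- glu$values[keep]
  if (sum(!is.na(g)) < 3)
    stop("insufficient data: < 3 glucose samples in the KG fitting window",
         call. = FALSE)
  kg <- -unname(stats::coef(stats::lm(log(g) ~ t))[2])
  if (!is.finite(kg) || kg <= 0)
    stop("degenerate data: non-positive glucose disappearance rate",
         call. = FALSE)
  i0 <- curve_at(ins, 0)
  if (is.na(i0))
    stop("insufficient data: fasting insulin sample missing", call. = FALSE)
  w <- cc$exposure_window
  exposure <- auc_trapezoid(ins, w[1], w[2]) / (w[2] - w[1]) - i0
  if (exposure <= 0)
    stop("degenerate data: non-positive incremental insulin exposure",
         call. = FALSE)
  cc$k * 1e4 * kg / exposure
}

#' Disposition index
#'
#' Beta-cell function as the product of insulin sensitivity and insulin
#' secretion: `DI = CSI x AIRg`, with CSI on the x1e-4 min^-1 (pmol/l)^-1
#' scale and AIRg in pmol/l, so DI is reported on the x1e-4 scale.
#' Bilinear in its arguments; zero iff either factor is zero; a negative
#' AIRg propagates its sign.
#'
#' @param csi_value CSI on the x1e-4 scale.
#' @param airg_value AIRg in pmol/l.
#' @return DI on the x1e-4 scale.
#' @examples
#' disposition_index(0.404, 521)  # ~210
#' @export
disposition_index <- function(csi_value, airg_value) {
  csi_value * airg_value
}
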