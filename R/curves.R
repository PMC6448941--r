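#' Timed concentration curves on a test protocol grid
#'
#' A `sampled_curve` is one analyte's concentration series for one test
#' occasion: times in minutes since the glucose dose and concentrations in
#' the analyte's clinical unit (glucose mmol/l, insulin pmol/l, C-peptide
#' nmol/l, glucagon assay units). Missing samples are `NA` values; an
#' explicit zero concentration is an integrity error, not a value.
#'
#' @param analyte one of `"glucose"`, `"insulin"`, `"c_peptide"`,
#'   `"glucagon"`.
#' @param times numeric minutes, strictly increasing, >= 0.
#' @param values numeric concentrations, positive where present, `NA` for
#'   missing samples.
#' @param grid optional protocol grid the times must belong to (e.g.
#'   [ogtt_grid()]); `NULL` skips the grid check.
#' @return An object of class `"sampled_curve"`.
#' @seealso [ogtt_grid()], [ivgtt_grid()], [auc_trapezoid()]
#' @examples
#' sampled_curve("glucose", ogtt_grid(), c(4.1, 9.9, 5.0, 2.4, 3.0, 3.4, 3.9))
#' @export
sampled_curve <- function(analyte, times, values, grid = NULL) {
  analyte <- match.arg(analyte, gp_analytes())
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) == 0L)
    stop("a sampled_curve needs at least one timepoint", call. = FALSE)
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  present <- !is.na(values)
  if (any(values[present] <= 0))
    stop("concentrations must be positive; explicit 0 is an integrity error",
         call. = FALSE)
  if (!is.null(grid) && !all(times %in% grid))
    stop("off protocol grid: time(s) ",
         paste(setdiff(times, grid), collapse = ", "),
         " not in {", paste(grid, collapse = ","), "}", call. = FALSE)
  structure(list(analyte = analyte, times = times, values = values),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("<sampled_curve: %s, %d timepoints (%d missing)>\n",
              x$analyte, length(x$times), sum(is.na(x$values))))
  print(stats::setNames(x$values, paste0("t", x$times)))
  invisible(x)
}

#' Recognised analytes
#' @return Character vector of analyte names.
#' @export
gp_analytes <- function() c("glucose", "insulin", "c_peptide", "glucagon")

#' OGTT and IVGTT protocol sampling grids
#'
#' The extended 3 h 75 g OGTT samples every 30 min; the 1 h insulin-modified
#' IVGTT samples densely after the glucose bolus (insulin infused 20-25 min).
#' @return Integer minutes since the glucose dose.
#' @export
ogtt_grid <- function() c(0, 30, 60, 90, 120, 150, 180)

#' @rdname ogtt_grid
#' @export
ivgtt_grid <- function() c(0, 3, 4, 5, 6, 8, 10, 15, 20, 30, 40, 50, 60)

# value at an exact grid time, NA if missing or absent
curve_at <- function(curve, t) {
  i <- match(t, curve$times)
  if (is.na(i)) NA_real_ else curve$values[i]
}

# restrict to the [t0, t1] window, keeping NA samples
curve_window <- function(curve, t0, t1) {
  keep <- curve$times >= t0 & curve$times <= t1
  list(times = curve$times[keep], values = curve$values[keep])
}

#' Trapezoidal area under a sampled curve
#'
#' Area under the piecewise-linear interpolant of the samples between
#' `t_start` and `t_end` (both must be sampled times). The trapezoid rule on
#' the protocol grid is the AUC convention used by the insulinogenic
#' (AUC-ratio) secretion indices.
#'
#' @param curve a [sampled_curve()].
#' @param t_start,t_end window bounds in minutes, `t_start < t_end`, both on
#'   the curve's sampled grid.
#' @return Area in concentration x min; non-negative, additive over
#'   adjacent windows.
#' @examples
#' g <- sampled_curve("glucose", ogtt_grid(), rep(5, 7))
#' auc_trapezoid(g, 0, 180)  # 900
#' @export
auc_trapezoid <- function(curve, t_start, t_end) {
  stopifnot(inherits(curve, "sampled_curve"))
  if (!(t_start < t_end))
    stop("t_start must be < t_end", call. = FALSE)
  if (!(t_start %in% curve$times) || !(t_end %in% curve$times))
    stop("insufficient data: window [", t_start, ",", t_end,
         "] not covered by sampled times", call. = FALSE)
  w <- curve_window(curve, t_start, t_end)
  if (anyNA(w$values))
    stop("insufficient data: missing values inside AUC window (impute first)",
         call. = FALSE)
  sum(diff(w$times) * (utils::head(w$values, -1) + utils::tail(w$values, -1)) / 2)
}
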