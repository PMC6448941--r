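#' Test records: one OGTT or IVGTT occasion for one subject
#'
#' An `ogtt_record` bundles the available analyte curves for one extended
#' 3 h 75 g OGTT (grid 0/30/.../180 min); the glucose curve is required.
#' An `ivgtt_record` holds the insulin-modified IVGTT (glucose bolus
#' 300 mg/kg at t = 0, insulin 0.05 U/kg infused 20-25 min) on its dense
#' 0-60 min grid, with the dosing fields needed by dose-dependent indices.
#'
#' @param id subject identifier.
#' @param visit `"V1"` (pregnancy, 24-28 weeks) or `"V2"` (3-6 months
#'   postpartum).
#' @param curves named list of [sampled_curve()]s, names from
#'   [gp_analytes()].
#' @param glucose_dose_mg_kg,insulin_dose_u_kg,weight_kg IVGTT dosing.
#' @return An object of class `"ogtt_record"` / `"ivgtt_record"`.
#' @export
ogtt_record <- function(id, visit, curves) {
  visit <- match.arg(visit, gp_visits())
  curves <- check_record_curves(curves, ogtt_grid())
  if (!"glucose" %in% names(curves))
    stop("OGTT record for ", id, " lacks a glucose curve", call. = FALSE)
  structure(list(id = as.character(id), visit = visit, curves = curves,
                 grid = ogtt_grid()),
            class = c("ogtt_record", "gp_record"))
}

#' @rdname ogtt_record
#' @export
ivgtt_record <- function(id, visit, curves, glucose_dose_mg_kg = 300,
                         insulin_dose_u_kg = 0.05, weight_kg = NA_real_) {
  visit <- match.arg(visit, gp_visits())
  curves <- check_record_curves(curves, ivgtt_grid())
  if (glucose_dose_mg_kg <= 0 || insulin_dose_u_kg <= 0)
    stop("IVGTT dose fields must be positive", call. = FALSE)
  structure(list(id = as.character(id), visit = visit, curves = curves,
                 grid = ivgtt_grid(),
                 glucose_dose_mg_kg = glucose_dose_mg_kg,
                 insulin_dose_u_kg = insulin_dose_u_kg,
                 weight_kg = weight_kg),
            class = c("ivgtt_record", "gp_record"))
}

check_record_curves <- function(curves, grid) {
  if (!length(curves)) stop("record needs at least one curve", call. = FALSE)
  if (is.null(names(curves)) || any(!names(curves) %in% gp_analytes()))
    stop("curves must be a named list keyed by analyte", call. = FALSE)
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    stopifnot(inherits(cv, "sampled_curve"))
    if (cv$analyte != nm)
      stop("curve stored under '", nm, "' is labelled '", cv$analyte, "'",
           call. = FALSE)
    if (!all(cv$times %in% grid))
      stop("off protocol grid: ", nm, " sampled at ",
           paste(setdiff(cv$times, grid), collapse = ","), call. = FALSE)
  }
  curves
}

#' @export
print.gp_record <- function(x, ...) {
  cat(sprintf("<%s: subject %s, visit %s, analytes: %s>\n",
              class(x)[1], x$id, x$visit,
              paste(names(x$curves), collapse = ", ")))
  invisible(x)
}

#' Study visits
#' @return Character vector `c("V1", "V2")`.
#' @export
gp_visits <- function() c("V1", "V2")

#' Study groups
#' @return Character vector of the three cohort arms.
#' @export
gp_groups <- function() c("RYGB", "obese_control", "normal_weight_control")

#' Assemble a cohort object
#'
#' A `gp_cohort` is the unit the statistical comparisons operate on:
#' a subject covariate table plus the long-format OGTT and IVGTT
#' measurement tables (one row per subject, visit, analyte, time).
#'
#' @param subjects data.frame with columns `id`, `group`, and the covariate
#'   columns listed under [read_cohort()].
#' @param ogtt,ivgtt long data.frames with columns `id`, `visit`,
#'   `analyte`, `time_min`, `value` (`NA` value = missing sample). `ivgtt`
#'   may additionally carry `weight_kg` rows metadata via the subjects
#'   table.
#' @return An object of class `"gp_cohort"`.
#' @export
gp_cohort <- function(subjects, ogtt, ivgtt = NULL) {
  stopifnot(is.data.frame(subjects), is.data.frame(ogtt))
  need <- c("id", "group")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("subjects table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!subjects$group %in% gp_groups()))
    stop("unknown group label(s): ",
         paste(setdiff(subjects$group, gp_groups()), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(subjects$id))
    stop("duplicate subject id(s) in subjects table", call. = FALSE)
  ogtt <- validate_long(ogtt, ogtt_grid(), "ogtt")
  if (!is.null(ivgtt) && nrow(ivgtt))
    ivgtt <- validate_long(ivgtt, ivgtt_grid(), "ivgtt")
  structure(list(subjects = subjects, ogtt = ogtt, ivgtt = ivgtt),
            class = "gp_cohort")
}

#' @export
print.gp_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("<gp_cohort: ", nrow(x$subjects), " subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "); ",
      nrow(x$ogtt), " OGTT rows",
      if (!is.null(x$ivgtt)) paste0(", ", nrow(x$ivgtt), " IVGTT rows"),
      ">\n", sep = "")
  invisible(x)
}

# long-table validation shared by gp_cohort() and read_cohort()
validate_long <- function(df, grid, what) {
  need <- c("id", "visit", "analyte", "time_min", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: ", what, " table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$id <- as.character(df$id)
  bad_an <- !df$analyte %in% gp_analytes()
  if (any(bad_an))
    stop("format error: unknown analyte(s) in ", what, ": ",
         paste(unique(df$analyte[bad_an]), collapse = ", "), call. = FALSE)
  bad_v <- !df$visit %in% gp_visits()
  if (any(bad_v))
    stop("format error: unknown visit label(s) in ", what, call. = FALSE)
  off <- !df$time_min %in% grid
  if (any(off))
    stop("off protocol grid: ", what, " row(s) at t = ",
         paste(unique(df$time_min[off]), collapse = ", "), " min",
         call. = FALSE)
  key <- paste(df$id, df$visit, df$analyte, df$time_min)
  if (anyDuplicated(key))
    stop("integrity error: duplicate (id, visit, analyte, time) in ", what,
         ": ", key[anyDuplicated(key)], call. = FALSE)
  if (any(!is.na(df$value) & df$value <= 0))
    stop("integrity error: non-positive concentration in ", what,
         " (missing must be empty/NA, not 0)", call. = FALSE)
  df[order(df$id, df$visit, df$analyte, df$time_min), need]
}

#' Extract one analyte curve from a cohort's long table
#'
#' Missing grid times are filled with `NA` so the curve always lives on the
#' full protocol grid (the missingness mask is `is.na(values)`).
#'
#' @param cohort a [gp_cohort()].
#' @param id,visit,analyte record coordinates.
#' @param test `"ogtt"` or `"ivgtt"`.
#' @return A [sampled_curve()], or `NULL` if the subject-visit has no rows
#'   for that analyte.
#' @export
cohort_curve <- function(cohort, id, visit, analyte, test = "ogtt") {
  df <- if (test == "ogtt") cohort$ogtt else cohort$ivgtt
  grid <- if (test == "ogtt") ogtt_grid() else ivgtt_grid()
  if (is.null(df)) return(NULL)
  rows <- df[df$id == id & df$visit == visit & df$analyte == analyte, ]
  if (!nrow(rows)) return(NULL)
  vals <- rows$value[match(grid, rows$time_min)]
  if (all(is.na(vals))) return(NULL)
  sampled_curve(analyte, grid, vals, grid = grid)
}
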