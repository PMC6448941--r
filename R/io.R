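#' Read a cohort from tidy CSV files
#'
#' Expects the documented long layout: `subjects.csv` with one row per
#' subject (columns `id`, `group`, `visit` optional, `age_years`, `parity`,
#' `bmi_pre_surgery`, `bmi_pregestational`, `bmi_v1`, `weight_gain_kg`,
#' `years_since_surgery`, `birthweight_percentile`, `multiple_pregnancy`),
#' and `ogtt.csv` / `ivgtt.csv` with one row per (id, visit, analyte,
#' time_min, value). Empty `value` fields are missing samples; explicit
#' zeros, duplicate keys, unknown analytes, and off-grid times are rejected
#' with row-level messages.
#'
#' @param subjects_path,ogtt_path,ivgtt_path CSV paths; `ivgtt_path` may be
#'   `NULL` when no IVGTT was performed.
#' @return A [gp_cohort()].
#' @seealso [write_cohort()], [write_index_table()]
#' @export
read_cohort <- function(subjects_path, ogtt_path, ivgtt_path = NULL) {
  subjects <- utils::read.csv(subjects_path, stringsAsFactors = FALSE)
  subjects$id <- as.character(subjects$id)
  if ("multiple_pregnancy" %in% names(subjects))
    subjects$multiple_pregnancy <- as.logical(subjects$multiple_pregnancy)
  ogtt <- read_long_csv(ogtt_path)
  ivgtt <- if (!is.null(ivgtt_path)) read_long_csv(ivgtt_path)
  gp_cohort(subjects, ogtt, ivgtt)
}

read_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "numeric"))
  df$id <- as.character(df$id)
  df
}

#' Write a cohort back to tidy CSVs
#'
#' Inverse of [read_cohort()]: `read_cohort()` on the written files
#' reproduces the cohort exactly (missing samples round-trip as empty
#' fields).
#'
#' @param cohort a [gp_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             ogtt = file.path(dir, "ogtt.csv"))
  utils::write.csv(cohort$subjects, paths[["subjects"]], row.names = FALSE,
                   na = "")
  utils::write.csv(cohort$ogtt, paths[["ogtt"]], row.names = FALSE, na = "")
  if (!is.null(cohort$ivgtt)) {
    paths <- c(paths, ivgtt = file.path(dir, "ivgtt.csv"))
    utils::write.csv(cohort$ivgtt, paths[["ivgtt"]], row.names = FALSE,
                     na = "")
  }
  invisible(paths)
}

#' Write / read the derived-index table
#'
#' One row per subject-visit with every index-panel column
#' (see [compute_indices()]). The written file round-trips losslessly
#' through [read_index_table()].
#'
#' @param indices data.frame from [compute_indices()].
#' @param path output CSV path.
#' @return `write_index_table()`: the path, invisibly.
#'   `read_index_table()`: the data.frame.
#' @export
write_index_table <- function(indices, path) {
  stopifnot(is.data.frame(indices))
  utils::write.csv(indices, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_index_table
#' @export
read_index_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df)) df$id <- as.character(df$id)
  for (nm in intersect(c("hypoglycaemia", "gdm"), names(df)))
    df[[nm]] <- as.logical(df[[nm]])
  df
}
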