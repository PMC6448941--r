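#' Propensity-score caliper matching
#'
#' 1:1 nearest-neighbour matching of treated (RYGB) to control subjects on
#' the propensity score from a logistic regression of treatment on the
#' configured covariates (default: BMI at the first visit). Greedy order is
#' descending treated propensity (hardest-to-match first), tie-broken by
#' subject id for determinism; matching is without replacement, and a pair
#' is kept only when the absolute propensity distance is within the
#' caliper, default 0.25 SD of the propensity score on the response scale.
#' Treated subjects with no in-caliper control remain unmatched.
#'
#' If the logistic fit separates (a covariate perfectly splits the arms),
#' the function falls back to matching on standardised covariate distance
#' with a warning.
#'
#' @param cohort a [gp_cohort()]; `group == "RYGB"` is the treated arm,
#'   everything else control.
#' @param config [gp_config()]; options under `config$match`.
#' @return List of class `"gp_match"`: `pairs` (data.frame `treated_id`,
#'   `control_id`, `distance`), `unmatched` (treated ids), `caliper`,
#'   `smd_before`, `smd_after` (standardised mean differences of each
#'   covariate), `propensity` (per-subject scores).
#' @export
propensity_match <- function(cohort, config = gp_config()) {
  cfg <- config$match
  subj <- cohort$subjects
  covs <- cfg$covariates
  miss <- setdiff(covs, names(subj))
  if (length(miss))
    stop("matching covariate(s) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- stats::complete.cases(subj[covs])
  subj <- subj[keep, ]
  treated <- subj$group == "RYGB"
  if (!any(treated) || !all(c(TRUE, FALSE) %in% treated))
    stop("need at least one treated and one control subject", call. = FALSE)

  fml <- stats::as.formula(paste("treated ~", paste(covs, collapse = " + ")))
  dat <- cbind(treated = treated, subj[covs])
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = dat))
  ps <- stats::fitted(fit)
  separated <- !fit$converged || any(ps > 1 - 1e-8) || any(ps < 1e-8)
  if (separated) {
    warning("separation in the propensity model; matching on standardised covariate distance")
    z <- scale(as.matrix(subj[covs]))
    ps <- as.numeric(z %*% rep(1 / sqrt(ncol(z)), ncol(z)))
    ps <- stats::pnorm(ps)  # keep on (0,1) so the caliper rule is unchanged
  }
  score <- if (identical(cfg$caliper_scale, "logit")) stats::qlogis(ps) else ps
  caliper <- cfg$caliper_sd * stats::sd(score)

  t_idx <- which(treated)
  t_idx <- t_idx[order(-score[t_idx], subj$id[t_idx])]
  avail <- which(!treated)
  pairs <- list()
  unmatched <- character(0)
  for (i in t_idx) {
    if (!length(avail)) { unmatched <- c(unmatched, subj$id[i]); next }
    d <- abs(score[avail] - score[i])
    j <- avail[order(d, subj$id[avail])][1]
    dj <- abs(score[j] - score[i])
    if (dj <= caliper) {
      pairs[[length(pairs) + 1L]] <-
        data.frame(treated_id = subj$id[i], control_id = subj$id[j],
                   distance = dj)
      if (!isTRUE(cfg$replace)) avail <- setdiff(avail, j)
    } else {
      unmatched <- c(unmatched, subj$id[i])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated_id = character(0), control_id = character(0),
               distance = numeric(0))

  smd <- function(ids_t, ids_c) {
    vapply(covs, function(v) {
      xt <- subj[[v]][subj$id %in% ids_t]
      xc <- subj[[v]][subj$id %in% ids_c]
      sp <- sqrt((stats::var(xt) + stats::var(xc)) / 2)
      if (!is.finite(sp) || sp == 0) return(0)
      (mean(xt) - mean(xc)) / sp
    }, numeric(1))
  }
  structure(list(
    pairs = pairs, unmatched = unmatched, caliper = caliper,
    smd_before = smd(subj$id[treated], subj$id[!treated]),
    smd_after = if (nrow(pairs)) smd(pairs$treated_id, pairs$control_id)
                else stats::setNames(rep(NA_real_, length(covs)), covs),
    propensity = stats::setNames(ps, subj$id)
  ), class = "gp_match")
}

#' @export
print.gp_match <- function(x, ...) {
  cat(sprintf("<gp_match: %d pairs, %d unmatched treated, caliper %.4f>\n",
              nrow(x$pairs), length(x$unmatched), x$caliper))
  cat("  SMD before:", round(x$smd_before, 3),
      " after:", round(x$smd_after, 3), "\n")
  invisible(x)
}
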