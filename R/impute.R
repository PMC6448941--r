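#' Per-experiment missingness report
#'
#' One experiment is one analyte curve within one test occasion (subject,
#' visit, OGTT or IVGTT, analyte), measured against the full protocol grid.
#' Experiments missing at least half of their grid samples are flagged
#' ineligible: they are excluded from analysis rather than imputed.
#'
#' @param cohort a [gp_cohort()].
#' @param config [gp_config()]; `config$impute$max_missing` is the
#'   (exclusive) ceiling, default 0.5.
#' @return data.frame: `id`, `visit`, `test`, `analyte`, `n_grid`,
#'   `n_missing`, `frac_missing`, `eligible`.
#' @export
missingness_report <- function(cohort, config = gp_config()) {
  ceiling_frac <- config$impute$max_missing
  one_test <- function(df, test, grid) {
    if (is.null(df) || !nrow(df)) return(NULL)
    key <- unique(df[c("id", "visit", "analyte")])
    out <- lapply(seq_len(nrow(key)), function(i) {
      rows <- df[df$id == key$id[i] & df$visit == key$visit[i] &
                   df$analyte == key$analyte[i], ]
      n_obs <- sum(!is.na(rows$value))
      data.frame(id = key$id[i], visit = key$visit[i], test = test,
                 analyte = key$analyte[i], n_grid = length(grid),
                 n_missing = length(grid) - n_obs)
    })
    do.call(rbind, out)
  }
  rep_ <- rbind(one_test(cohort$ogtt, "ogtt", ogtt_grid()),
                one_test(cohort$ivgtt, "ivgtt", ivgtt_grid()))
  rep_$frac_missing <- rep_$n_missing / rep_$n_grid
  rep_$eligible <- rep_$frac_missing < ceiling_frac
  rownames(rep_) <- NULL
  rep_
}

#' Chained-equation imputation of sparse test timepoints
#'
#' Multivariate imputation by chained equations over the timepoint columns
#' of each (test, visit, analyte) experiment matrix: missing cells are
#' initialised at column means, then cycled through per-column linear
#' regressions on the other timepoints with normal-noise draws (10 burn-in
#' cycles); `m` completed datasets (default 50) are averaged cellwise.
#' Observed cells are never altered, ineligible experiments (>= 50%
#' missing, see [missingness_report()]) are left untouched, and the whole
#' procedure is deterministic given `seed`.
#'
#' Concentrations are imputed on the log scale so draws stay positive.
#'
#' @param cohort a [gp_cohort()].
#' @param config [gp_config()] (`config$impute`: `m`, `burnin`,
#'   `max_missing`).
#' @param seed integer RNG seed; recorded in the log.
#' @return List of class `"gp_imputed"`: `cohort` (completed), `log`
#'   (data.frame `id`, `visit`, `test`, `analyte`, `time_min`,
#'   `imputed_value`, `m`, `seed`), `report` (the missingness report).
#' @export
mice_impute <- function(cohort, config = gp_config(), seed = 1L) {
  cfg <- config$impute
  report <- missingness_report(cohort, config)
  set.seed(seed)
  logs <- list()
  for (test in c("ogtt", "ivgtt")) {
    df <- cohort[[test]]
    if (is.null(df) || !nrow(df)) next
    grid <- if (test == "ogtt") ogtt_grid() else ivgtt_grid()
    for (vis in unique(df$visit)) {
      for (an in unique(df$analyte[df$visit == vis])) {
        el <- report[report$test == test & report$visit == vis &
                       report$analyte == an & report$eligible, "id"]
        sub <- df[df$visit == vis & df$analyte == an & df$id %in% el, ]
        if (!nrow(sub)) next
        ids <- unique(sub$id)
        X <- matrix(NA_real_, length(ids), length(grid),
                    dimnames = list(ids, grid))
        X[cbind(match(sub$id, ids), match(sub$time_min, grid))] <- sub$value
        if (!anyNA(X)) next
        if (any(colSums(!is.na(X)) == 0))
          stop("cannot impute: timepoint with no observed values (",
               test, " ", an, " ", vis, ")", call. = FALSE)
        filled <- chain_impute(log(X), m = cfg$m, burnin = cfg$burnin)
        Xc <- exp(filled)
        Xc[!is.na(X)] <- X[!is.na(X)]
        # write back into the long table
        nas <- which(is.na(X), arr.ind = TRUE)
        for (r in seq_len(nrow(nas))) {
          id_r <- ids[nas[r, 1]]; t_r <- grid[nas[r, 2]]
          val <- Xc[nas[r, 1], nas[r, 2]]
          sel <- df$id == id_r & df$visit == vis & df$analyte == an &
            df$time_min == t_r
          if (any(sel)) df$value[sel] <- val else {
            df <- rbind(df, data.frame(id = id_r, visit = vis, analyte = an,
                                       time_min = t_r, value = val))
          }
          logs[[length(logs) + 1L]] <-
            data.frame(id = id_r, visit = vis, test = test, analyte = an,
                       time_min = t_r, imputed_value = val,
                       m = cfg$m, seed = seed)
        }
      }
    }
    cohort[[test]] <- df[order(df$id, df$visit, df$analyte, df$time_min), ]
  }
  log_df <- if (length(logs)) do.call(rbind, logs) else
    data.frame(id = character(0), visit = character(0), test = character(0),
               analyte = character(0), time_min = numeric(0),
               imputed_value = numeric(0), m = integer(0), seed = integer(0))
  structure(list(cohort = cohort, log = log_df, report = report),
            class = "gp_imputed")
}

# chained-equation core on one numeric matrix (NAs = cells to impute);
# returns the cellwise mean over m completed matrices
chain_impute <- function(X, m = 50, burnin = 10) {
  nas <- is.na(X)
  acc <- matrix(0, nrow(X), ncol(X))
  for (imp in seq_len(m)) {
    Z <- X
    for (j in seq_len(ncol(Z)))
      Z[nas[, j], j] <- mean(Z[, j], na.rm = TRUE)
    for (cyc in seq_len(burnin)) {
      for (j in which(colSums(nas) > 0)) {
        obs <- !nas[, j]
        others <- Z[, -j, drop = FALSE]
        if (sum(obs) >= ncol(Z) + 2) {
          fit <- stats::lm.fit(cbind(1, others[obs, , drop = FALSE]),
                               X[obs, j])
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          sigma <- stats::sd(fit$residuals)
          pred <- cbind(1, others[!obs, , drop = FALSE]) %*% beta
        } else if (sum(obs) >= 3) {
          rm_ <- rowMeans(others)
          fit <- stats::lm(X[obs, j] ~ rm_[obs])
          sigma <- stats::sd(stats::residuals(fit))
          pred <- stats::coef(fit)[1] + stats::coef(fit)[2] * rm_[!obs]
        } else {
          sigma <- stats::sd(X[obs, j])
          if (!is.finite(sigma)) sigma <- 0
          pred <- rep(mean(X[obs, j]), sum(!obs))
        }
        if (!is.finite(sigma)) sigma <- 0
        Z[!obs, j] <- pred + stats::rnorm(sum(!obs), 0, sigma)
      }
    }
    acc <- acc + Z
  }
  acc / m
}
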