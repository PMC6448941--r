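#' Brunner-Munzel rank test for two independent samples
#'
#' Nonparametric two-sample inference on the relative effect
#' p = P(X < Y) + 0.5 P(X = Y): the probability that a random observation
#' from `y` exceeds one from `x`. Valid under unequal variances and ties
#' (mid-ranks), with a t reference distribution and Satterthwaite-type
#' degrees of freedom -- the standard small-sample form. p = 0.5 means
#' stochastic equality.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param alpha level for the relative-effect confidence interval.
#' @return An object of class `"gp_rank_test"`: list with `p_hat`
#'   (relative effect), `statistic`, `df`, `p.value` (two-sided),
#'   `conf.int`, `n`.
#' @examples
#' brunner_munzel(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
brunner_munzel <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  N <- n1 + n2
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (v1 == 0 && v2 == 0) {
    if (p_hat == 0.5)
      stop("degenerate data: zero rank variance in both samples",
           call. = FALSE)
    # complete separation: the relative effect is 0 or 1 and the
    # studentised statistic degenerates; report the boundary directly
    return(structure(list(p_hat = p_hat, statistic = sign(p_hat - 0.5) * Inf,
                          df = NA_real_, p.value = 0,
                          conf.int = c(p_hat, p_hat), n = c(n1, n2),
                          method = "Brunner-Munzel rank test (separated samples)"),
                     class = "gp_rank_test"))
  }
  se <- sqrt(v1 / (n1 * n2^2) + v2 / (n2 * n1^2))
  stat <- (p_hat - 0.5) / se
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  ci <- p_hat + c(-1, 1) * stats::qt(1 - alpha / 2, df) * se
  structure(list(p_hat = p_hat, statistic = stat, df = df, p.value = p,
                 conf.int = pmin(pmax(ci, 0), 1), n = c(n1, n2),
                 method = "Brunner-Munzel rank test"),
            class = "gp_rank_test")
}

#' @export
print.gp_rank_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  relative effect p-hat = %.4f [%.4f, %.4f]\n",
              x$p_hat, x$conf.int[1], x$conf.int[2]))
  if (!is.null(x$statistic))
    cat(sprintf("  statistic = %.4f, df = %.2f, p = %.4g\n",
                x$statistic, x$df, x$p.value))
  else
    cat(sprintf("  statistic (V) = %g, p = %.4g\n", x$V, x$p.value))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value (summation of tables at least as
#' extreme in probability, the conventional definition). Thin wrapper
#' around [stats::fisher.test()] with the integrity checks this pipeline
#' needs.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative passed to [stats::fisher.test()].
#' @return List with `p.value`, `odds.ratio`, `table`.
#' @export
fisher_exact <- function(table, alternative = "two.sided") {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop("fisher_exact expects a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate data: empty margin", call. = FALSE)
  ft <- stats::fisher.test(table, alternative = alternative)
  list(p.value = ft$p.value, odds.ratio = unname(ft$estimate), table = table)
}

#' Paired rank (Wilcoxon signed-rank) test
#'
#' Within-subject comparison of a variable measured at two visits, by the
#' exact signed-rank distribution where sample size allows (zeros dropped,
#' mid-ranks for ties with the normal approximation).
#'
#' @param before,after paired numeric vectors; pairs with any missing value
#'   are dropped.
#' @return `"gp_rank_test"` object with `V` (signed-rank statistic),
#'   `p.value`, `n` (pairs used).
#' @export
paired_rank_test <- function(before, after) {
  if (length(before) != length(after))
    stop("paired samples must have equal length", call. = FALSE)
  ok <- !is.na(before) & !is.na(after)
  before <- before[ok]; after <- after[ok]
  d <- after - before
  d <- d[d != 0]  # zeros carry no sign information
  if (!length(d))
    stop("degenerate data: no non-zero paired differences", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  n <- length(d)
  if (n <= 14) {
    # exact sign-flip enumeration (valid under ties via mid-ranks)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% r)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Vs <= V + eps), mean(Vs >= V - eps)))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE))
    p <- wt$p.value
  }
  structure(list(V = V, p.value = p,
                 p_hat = NA_real_, statistic = NULL,
                 n = sum(ok), method = "Paired rank (Wilcoxon signed-rank) test"),
            class = "gp_rank_test")
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Mid-rank Spearman rho, p-value from the t approximation, and a 95% CI
#' from the Fisher z transform with the rank-correlation variance
#' 1.06/(n - 3).
#'
#' @param x,y numeric vectors; pairs with missing values dropped.
#' @param alpha CI level complement.
#' @return List with `rho`, `conf.int`, `p.value`, `n`.
#' @examples
#' spearman_ci(1:10, (1:10)^3)  # rho = 1
#' @export
spearman_ci <- function(x, y, alpha = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("Spearman CI needs n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  se <- sqrt(1.06 / (n - 3))
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  ci <- tanh(z + c(-1, 1) * stats::qnorm(1 - alpha / 2) * se)
  list(rho = rho, conf.int = ci, p.value = ct$p.value, n = n)
}

#' One-way ANOVA with Fisher's protected LSD
#'
#' Omnibus one-way ANOVA across >= 3 groups; pairwise least-significant-
#' difference t tests (pooled error variance, df = N - k) are evaluated
#' only when the omnibus p-value is at or below `alpha` -- the "protected"
#' rule. With the omnibus not significant the pairwise slots are returned
#' as `NA` and flagged `evaluated = FALSE`.
#'
#' @param groups named list of numeric vectors (>= 2 per group).
#' @param alpha protection level (default 0.05).
#' @return List: `F`, `df`, `p.omnibus`, `pairwise` (data.frame with
#'   `group1`, `group2`, `diff`, `p.value`), `evaluated`.
#' @export
anova_lsd <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("degenerate data: every group needs >= 2 observations",
         call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  p_omni <- tab[["Pr(>F)"]][1]
  mse <- tab[["Mean Sq"]][2]
  df_err <- tab[["Df"]][2]
  means <- vapply(groups, mean, numeric(1))
  cmb <- utils::combn(names(groups), 2)
  pw <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                   diff = means[cmb[1, ]] - means[cmb[2, ]],
                   p.value = NA_real_, row.names = NULL)
  evaluated <- p_omni <= alpha
  if (evaluated) {
    for (i in seq_len(nrow(pw))) {
      n1 <- sizes[[pw$group1[i]]]; n2 <- sizes[[pw$group2[i]]]
      tstat <- pw$diff[i] / sqrt(mse * (1 / n1 + 1 / n2))
      pw$p.value[i] <- 2 * stats::pt(-abs(tstat), df_err)
    }
  }
  list(F = tab[["F value"]][1], df = c(tab[["Df"]][1], df_err),
       p.omnibus = p_omni, pairwise = pw, evaluated = evaluated)
}

#' Between-group comparison of paired change scores
#'
#' Computes per-group pregnancy-to-postpartum deltas elsewhere; here each
#' element of `deltas` is one group's vector of change scores, and every
#' pair of groups is compared by [brunner_munzel()] with no multiplicity
#' adjustment (the study design is explorative).
#'
#' @param deltas named list (>= 2 groups) of numeric change-score vectors.
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `p_hat`, `p.value`, `n1`, `n2`.
#' @export
change_score_compare <- function(deltas) {
  stopifnot(is.list(deltas))
  if (length(deltas) < 2)
    stop("change-score comparison needs >= 2 groups", call. = FALSE)
  if (is.null(names(deltas))) names(deltas) <- seq_along(deltas)
  cmb <- utils::combn(names(deltas), 2)
  out <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    bm <- brunner_munzel(deltas[[a]], deltas[[b]])
    data.frame(group1 = a, group2 = b, p_hat = bm$p_hat,
               p.value = bm$p.value, n1 = bm$n[1], n2 = bm$n[2])
  })
  do.call(rbind, out)
}
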