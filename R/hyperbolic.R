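#' Hyperbolic sensitivity-secretion regression
#'
#' Fits the hyperbolic relation between insulin secretion and insulin
#' sensitivity, `y = a + b / x`, by ordinary least squares on the
#' transformed predictor 1/x. In normal glucose tolerance, secretion (AIRg)
#' compensates falling sensitivity (CSI) roughly along such a hyperbola;
#' the fitted curve is the reference against which beta-cell compensation
#' is judged.
#'
#' @param x insulin-sensitivity values (e.g. CSI), all > 0.
#' @param y insulin-secretion values (e.g. AIRg, pmol/l), same length.
#' @return An object of class `"hyperbolic_fit"` with `coef` methods etc.;
#'   coefficients are named `intercept` (a) and `slope` (b, the coefficient
#'   of 1/x); `rss` is the residual sum of squares.
#' @examples
#' x <- seq(0.1, 1, length.out = 20)
#' fit <- hyperbolic_fit(x, 252.3 + 146.5 / x)
#' coef(fit)
#' predict(fit, newdata = c(0.25, 0.5))
#' @export
hyperbolic_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("hyperbolic fit needs n >= 3", call. = FALSE)
  if (any(x <= 0))
    stop("domain error: sensitivity values must be positive", call. = FALSE)
  inv <- 1 / x
  fit <- stats::lm(y ~ inv)
  cf <- stats::setNames(unname(stats::coef(fit)), c("intercept", "slope"))
  structure(list(coefficients = cf, lm = fit, x = x, y = y,
                 rss = sum(stats::residuals(fit)^2), n = length(x)),
            class = "hyperbolic_fit")
}

#' @export
coef.hyperbolic_fit <- function(object, ...) object$coefficients

#' @export
print.hyperbolic_fit <- function(x, digits = 4, ...) {
  cat("Hyperbolic regression  y = a + b/x\n")
  cat(sprintf("  a (intercept) = %.*f\n  b (slope)     = %.*f\n",
              digits, x$coefficients["intercept"],
              digits, x$coefficients["slope"]))
  cat(sprintf("  n = %d, RSS = %.*g\n", x$n, digits, x$rss))
  invisible(x)
}

#' @export
predict.hyperbolic_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  x <- if (is.list(newdata)) newdata$x else newdata
  if (any(x <= 0)) stop("domain error: x must be positive", call. = FALSE)
  unname(object$coefficients["intercept"] + object$coefficients["slope"] / x)
}

#' @export
residuals.hyperbolic_fit <- function(object, ...) {
  unname(stats::residuals(object$lm))
}

#' @export
fitted.hyperbolic_fit <- function(object, ...) {
  unname(stats::fitted(object$lm))
}

#' @export
summary.hyperbolic_fit <- function(object, ...) {
  s <- summary(object$lm)
  rownames(s$coefficients) <- c("intercept", "slope (1/x)")
  s
}

#' @export
plot.hyperbolic_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "insulin sensitivity",
                 ylab = "insulin secretion", ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}
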