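#' Phylogenetic generalized least-squares regression
#'
#' Fits the allometric regression `y = intercept + slope * x` by
#' generalized least squares with a phylogenetic error covariance,
#' \eqn{\hat\beta = (X' C^{-1} X)^{-1} X' C^{-1} y}. With `C` proportional
#' to the identity (a star phylogeny) the fit reduces to ordinary least
#' squares. Inputs are typically log10 brain volume (`x`) and log10 region
#' volume (`y`), one value per species, ordered as the rows of `C`.
#'
#' An optional Pagel's lambda transform of the off-diagonal covariance is
#' available for sensitivity analyses; the default `lambda = 1` is the
#' plain Brownian-motion pGLS used throughout the package.
#'
#' @param x,y Numeric vectors (length n >= 3) sharing the tip order of `C`.
#' @param C Positive-definite covariance matrix from [bm_covariance()] (or
#'   any user-supplied phylogenetic covariance). If `NULL`, the identity is
#'   used and the fit is OLS.
#' @param lambda Off-diagonal multiplier in `[0, 1]`; 1 = Brownian motion.
#' @return An object of class `pgls_fit`: a list with `slope`, `intercept`,
#'   `residuals` (tip-ordered, named if `C` has dimnames), `sigma2`
#'   (residual variance, `r' C^{-1} r / (n - 2)`), `vcov` (2x2 coefficient
#'   covariance), `C`, `n`, `x`, `y`, `loglik`.
#' @examples
#' x <- 1:5
#' fit <- pgls_fit(x, 2 * x + 1, C = diag(5))
#' coef(fit)
#' @export
pgls_fit <- function(x, y, C = NULL, lambda = 1) {
  n <- length(x)
  if (length(y) != n) stop_input("`x` and `y` must have equal length")
  if (n < 3) stop_input("need at least 3 species to fit a pGLS",
                        class = "rubrovol_insufficient_data")
  if (is.null(C)) C <- diag(n)
  if (!is.matrix(C) || nrow(C) != n || ncol(C) != n) {
    stop_input("`C` must be an n x n matrix matching x and y")
  }
  if (lambda < 0 || lambda > 1) stop_input("`lambda` must be in [0, 1]")
  if (lambda != 1) {
    Cd <- diag(C)
    C <- lambda * C
    diag(C) <- Cd
  }
  L <- tryCatch(chol(C), error = function(e) {
    stop_input("covariance matrix is not positive definite",
               class = "rubrovol_decomposition_error")
  })
  # whiten: solve L' z = v  =>  z = L^{-T} v, so z' z = v' C^{-1} v
  wh <- function(v) backsolve(L, v, transpose = TRUE)
  X <- cbind(`(Intercept)` = 1, x = x)
  Xw <- wh(X)
  colnames(Xw) <- colnames(X)
  yw <- wh(y)
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  r <- as.numeric(y - X %*% beta)
  names(r) <- rownames(C)
  rw <- wh(r)
  rss <- sum(rw^2)
  sigma2 <- rss / (n - 2)
  loglik <- -0.5 * (n * log(2 * pi) + n * log(rss / n) +
                      2 * sum(log(diag(L))) + n)
  structure(
    list(
      slope = unname(beta["x", 1]), intercept = unname(beta["(Intercept)", 1]),
      coefficients = c(intercept = unname(beta[1, 1]),
                       slope = unname(beta[2, 1])),
      residuals = r, sigma2 = sigma2, vcov = sigma2 * solve(XtX),
      C = C, n = n, x = x, y = y, rss_weighted = rss, loglik = loglik,
      lambda = lambda
    ),
    class = "pgls_fit"
  )
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$loglik, df = 3, class = "logLik")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("pGLS fit (n =", x$n, ")\n")
  cat(sprintf("  slope     %.4f\n  intercept %.4f\n  sigma^2   %.4g\n",
              x$slope, x$intercept, x$sigma2))
  invisible(x)
}

#' Tidy a pGLS fit
#'
#' @param x A `pgls_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value` (t-tests on n - 2 df).
#' @export
tidy.pgls_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  stat <- unname(x$coefficients / se)
  tibble::tibble(
    term = c("(Intercept)", "slope"),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = stat,
    p.value = 2 * pt(abs(stat), df = x$n - 2, lower.tail = FALSE)
  )
}

#' Glance at a pGLS fit
#'
#' @inheritParams tidy.pgls_fit
#' @return One-row tibble: `sigma2`, `logLik`, `nobs`, `lambda`.
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(sigma2 = x$sigma2, logLik = x$loglik, nobs = x$n,
                 lambda = x$lambda)
}

#' Per-species phylogenetic prediction intervals and deviation flags
#'
#' Phylogenetic prediction intervals around the fitted allometry. Each
#' species' interval is centred on its leave-one-out prediction: the
#' regression line plus the residual expected from the species' covariance
#' with all other species (the phylogenetic best linear unbiased
#' prediction). The prediction variance is the corresponding conditional
#' variance `sigma2 * (C_ii - c_i' C_-i^-1 c_i)` plus the propagated
#' uncertainty of the coefficient estimates, and the interval uses
#' Student-t quantiles on n - 2 df. A species whose observed value falls
#' outside its interval deviates from what the allometry and the
#' phylogeny jointly predict from every other species, and is flagged.
#' With a star phylogeny (diagonal `C`) the conditional prediction
#' reduces to the regression line with the familiar marginal interval.
#'
#' @param fit A `pgls_fit` object.
#' @param level Coverage probability in (0, 1); default 0.95.
#' @return Tibble with one row per species: `species`, `x`, `y`, `fitted`
#'   (line value), `predicted` (leave-one-out phylogenetic prediction),
#'   `lwr`, `upr`, `outside` (logical flag).
#' @export
prediction_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop_input("`level` must be a probability in (0, 1)")
  }
  n <- fit$n
  X <- cbind(1, fit$x)
  fitted <- as.numeric(X %*% fit$coefficients)
  r <- unname(fit$residuals)
  predicted <- numeric(n)
  pred_var <- numeric(n)
  for (i in seq_len(n)) {
    ci <- fit$C[-i, i]
    w <- solve(fit$C[-i, -i], ci) # kriging weights
    predicted[i] <- fitted[i] + sum(w * r[-i])
    # conditional variance + coefficient uncertainty at the adjusted design
    d <- X[i, ] - drop(crossprod(w, X[-i, , drop = FALSE]))
    pred_var[i] <- fit$sigma2 * (fit$C[i, i] - sum(w * ci)) +
      drop(d %*% fit$vcov %*% d)
  }
  tq <- qt(1 - (1 - level) / 2, df = n - 2)
  half <- tq * sqrt(pmax(pred_var, 0))
  species <- names(fit$residuals) %||% as.character(seq_len(n))
  tibble::tibble(
    species = species, x = fit$x, y = fit$y, fitted = fitted,
    predicted = predicted,
    lwr = predicted - half, upr = predicted + half,
    outside = fit$y < predicted - half | fit$y > predicted + half
  )
}

#' Augment data with pGLS fit quantities
#'
#' @param x A `pgls_fit` object.
#' @param level Coverage for the prediction intervals.
#' @param ... Unused.
#' @return The [prediction_intervals()] tibble plus a `.resid` column.
#' @export
augment.pgls_fit <- function(x, level = 0.95, ...) {
  out <- prediction_intervals(x, level = level)
  out$.resid <- unname(x$residuals)
  out
}

#' Plot a pGLS allometry with prediction intervals
#'
#' @param object A `pgls_fit` object.
#' @param level Interval coverage (default 0.95).
#' @param ... Unused.
#' @return A ggplot: observations, fitted line, interval ribbon; species
#'   outside their interval are highlighted.
#' @export
autoplot.pgls_fit <- function(object, level = 0.95, ...) {
  d <- augment(object, level = level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y, colour = .data$outside)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"),
                                 name = "outside PI") +
    ggplot2::labs(x = "log10 brain volume", y = "log10 region volume") +
    ggplot2::theme_minimal()
}
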