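#' Phylogenetic ANCOVA grade-shift test
#'
#' Tests whether designated groups of species share the allometric
#' intercept (grade), slope, or both, by comparing nested GLS regressions
#' under a phylogenetic error covariance. Both models are fitted in the
#' whitened (C^-1/2) metric; the F statistic is
#' \deqn{F = \frac{(RSS_0 - RSS_1)/\Delta p}{RSS_1/(n - p_1)}}
#' with the standard nested-model degrees of freedom (`df1` = number of
#' added parameters, `df2` = n minus parameters of the richer model). With
#' `C` the identity this is exactly ordinary ANCOVA. Group factors use
#' treatment contrasts with the largest group as baseline; F is invariant
#' to that choice.
#'
#' @param x,y Numeric predictor/response vectors sharing the tip order of
#'   `C` (typically log10 volumes).
#' @param C Positive-definite phylogenetic covariance (`NULL` = identity).
#' @param groups Factor or character vector assigning each species to a
#'   group; at least 2 groups, covering every tip.
#' @param test Which parameters may differ between groups under the
#'   alternative: `"intercept"` (grade shift, default), `"slope"`, or
#'   `"both"`.
#' @return A one-row tibble of class `rn_ancova`: `test`, `statistic` (F),
#'   `df1`, `df2`, `p_value`, `rss_null`, `rss_alt`, `n`, `n_groups`.
#' @examples
#' x <- rep(1:4, 2); g <- rep(c("a", "b"), each = 4)
#' y <- x + ifelse(g == "b", 1, 0)
#' grade_test(x, y, groups = g)
#' @export
grade_test <- function(x, y, C = NULL, groups,
                       test = c("intercept", "slope", "both")) {
  test <- match.arg(test)
  n <- length(x)
  if (length(y) != n || length(groups) != n) {
    stop_input("`x`, `y` and `groups` must have equal length")
  }
  if (anyNA(groups)) stop_input("`groups` must cover all tips")
  tab <- table(groups)
  if (length(tab) < 2) stop_input("need at least 2 groups")
  if (test %in% c("slope", "both") && any(tab < 2)) {
    stop_input("every group needs >= 2 tips for a slope test",
               class = "rubrovol_insufficient_data")
  }
  g <- factor(groups)
  g <- stats::relevel(g, ref = names(which.max(tab)))
  if (is.null(C)) C <- diag(n)
  L <- tryCatch(chol(C), error = function(e) {
    stop_input("covariance matrix is not positive definite",
               class = "rubrovol_decomposition_error")
  })
  wh <- function(m) backsolve(L, m, transpose = TRUE)
  X0 <- cbind(1, x)
  X1 <- switch(test,
    intercept = stats::model.matrix(~ g + x),
    slope     = stats::model.matrix(~ x + g:x),
    both      = stats::model.matrix(~ g * x)
  )
  rss <- function(X) {
    fitw <- stats::lm.fit(wh(X), wh(y))
    sum(fitw$residuals^2)
  }
  rss0 <- rss(X0)
  rss1 <- rss(X1)
  p1 <- ncol(X1)
  df1 <- p1 - ncol(X0)
  df2 <- n - p1
  if (df2 < 1) stop_input("too few species for the requested test",
                          class = "rubrovol_insufficient_data")
  num <- max(0, rss0 - rss1) / df1
  # a perfect fit under both models carries no evidence: F = 0
  Fstat <- if (num <= 1e-12 * max(rss0, 1)) 0 else num / (rss1 / df2)
  out <- tibble::tibble(
    test = test, statistic = Fstat, df1 = df1, df2 = df2,
    p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
    rss_null = rss0, rss_alt = rss1, n = n, n_groups = length(tab)
  )
  class(out) <- c("rn_ancova", class(out))
  out
}
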