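#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom stats pf pt qt optimize cor.test shapiro.test wilcox.test
#'   t.test kmeans sd var setNames rnorm pchisq
#' @importFrom utils head
NULL

# Run code with a temporary RNG state seeded at `seed`; the caller's
# .Random.seed is restored afterwards so simulations never perturb the
# global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_input <- function(..., class = "rubrovol_input_error") {
  abort(paste0(...), class = class)
}

check_number <- function(x, name, positive = FALSE, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(name, " must be a single finite number")
  }
  if (positive && x <= 0) stop_input(name, " must be > 0")
  if (!is.null(min) && x < min) stop_input(name, " must be >= ", min)
  invisible(x)
}

# standard error of the mean
sem <- function(x) sd(x) / sqrt(length(x))
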