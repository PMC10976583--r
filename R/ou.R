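# Multi-regime Ornstein-Uhlenbeck modelling of comparative traits:
# dX = alpha (theta - X) dt + sigma dB, with the optimum theta allowed to
# shift on designated edges of the tree. All regimes share alpha and
# sigma^2; the root state sits at the ancestral optimum (stationary
# convention). Likelihood is the exact multivariate Gaussian implied by
# the process on an ultrametric tree.

# Precompute the tree quantities every OU evaluation needs.
ou_ctx <- function(tree) {
  validate_phylo(tree, ultrametric = TRUE)
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree) # from root, all nodes
  tip_depth <- depths[seq_len(n)]
  Tmax <- max(tip_depth)
  Cbm <- ape::vcv.phylo(tree)                # shared times t_ij
  Dmat <- outer(tip_depth, tip_depth, "+") - 2 * Cbm # tip-tip distances
  edge <- tree$edge
  parent_edge <- integer(max(edge))          # edge index above each node
  parent_edge[edge[, 2]] <- seq_len(nrow(edge))
  root <- setdiff(edge[, 1], edge[, 2])
  paths <- vector("list", n)                 # root-to-tip edge sequences
  for (i in seq_len(n)) {
    p <- integer(0)
    node <- i
    while (node != root) {
      e <- parent_edge[node]
      p <- c(e, p)
      node <- edge[e, 1]
    }
    paths[[i]] <- p
  }
  # edge segment times from the root: [start, end]
  e_start <- depths[edge[, 1]]
  e_end <- depths[edge[, 2]]
  list(tree = tree, n = n, Tmax = Tmax, Cbm = Cbm, Dmat = Dmat,
       edge = edge, paths = paths, e_start = e_start, e_end = e_end,
       tip_depth = tip_depth, root = root)
}

# (1 - exp(-2 a t)) / (2 a), continuous at a = 0 where it equals t
ou_decay <- function(t, alpha) {
  if (alpha <= 0) return(t)
  -expm1(-2 * alpha * t) / (2 * alpha)
}

ou_cov_from_ctx <- function(ctx, alpha, sigma2) {
  V <- sigma2 * ou_decay(ctx$Cbm, alpha) * exp(-alpha * ctx$Dmat)
  dimnames(V) <- dimnames(ctx$Cbm)
  V
}

#' Ornstein-Uhlenbeck covariance matrix on an ultrametric tree
#'
#' For tips i, j with shared time \eqn{t_{ij}} (root-to-MRCA) and tree
#' distance \eqn{d_{ij}}, the covariance is
#' \eqn{\sigma^2/(2\alpha)\,(1 - e^{-2\alpha t_{ij}})\,e^{-\alpha d_{ij}}},
#' computed in a form continuous at \eqn{\alpha = 0}, where it equals the
#' Brownian-motion covariance \eqn{\sigma^2 t_{ij}}.
#'
#' @param tree An ultrametric `phylo` object (non-ultrametric trees are
#'   rejected; a documented limitation of the stationary OU form used).
#' @param alpha Selection strength (1/time), >= 0.
#' @param sigma2 Diffusion variance (trait^2/time), > 0.
#' @return Covariance matrix in tip order, with tip-label dimnames.
#' @export
ou_covariance <- function(tree, alpha, sigma2 = 1) {
  check_number(alpha, "alpha", min = 0)
  check_number(sigma2, "sigma2", positive = TRUE)
  ou_cov_from_ctx(ou_ctx(tree), alpha, sigma2)
}

# Regime design matrix W(alpha): E[y] = W %*% theta, theta = (base,
# shift_1, ..., shift_K). Each tip's expectation is the optima along its
# root-to-tip path weighted by exp(-alpha * (time remaining)) increments;
# the root contributes exp(-alpha * T) to the base regime (root state at
# the ancestral optimum).
ou_design <- function(ctx, alpha, shift_edges) {
  K <- length(shift_edges)
  W <- matrix(0, ctx$n, K + 1)
  for (i in seq_len(ctx$n)) {
    Ti <- ctx$tip_depth[i]
    W[i, 1] <- exp(-alpha * Ti)
    regime <- 1L # column index, 1 = base
    for (e in ctx$paths[[i]]) {
      hit <- match(e, shift_edges)
      if (!is.na(hit)) regime <- hit + 1L
      wseg <- exp(-alpha * (Ti - ctx$e_end[e])) -
        exp(-alpha * (Ti - ctx$e_start[e]))
      W[i, regime] <- W[i, regime] + wseg
    }
  }
  W
}

# Which tips are painted with each shift regime (nearest-shift-wins).
regime_membership <- function(ctx, shift_edges) {
  K <- length(shift_edges)
  reg <- rep(1L, ctx$n)
  for (i in seq_len(ctx$n)) {
    for (e in ctx$paths[[i]]) {
      hit <- match(e, shift_edges)
      if (!is.na(hit)) reg[i] <- hit + 1L
    }
  }
  reg
}

# Human-readable clade label for the child clade of an edge.
edge_clade_label <- function(ctx, e) {
  tips <- which(vapply(ctx$paths, function(p) e %in% p, logical(1)))
  labs <- ctx$tree$tip.label[tips]
  if (length(labs) == 1) labs else {
    paste0("mrca(", labs[1], ",", labs[length(labs)], ")")
  }
}

#' Multi-regime OU log-likelihood
#'
#' Exact multivariate-Gaussian log-density of tip values under a
#' multi-regime OU process: regime optima shift on `shift_edges`, the mean
#' of each tip weights the optima along its root-to-tip path by the OU
#' decay factors, and the covariance is [ou_covariance()].
#'
#' @param y Tip-ordered numeric vector of trait values.
#' @param tree Ultrametric `phylo`.
#' @param alpha,sigma2 OU parameters (alpha >= 0, sigma2 > 0).
#' @param theta Optima vector, base regime first then one per shift edge.
#' @param shift_edges Integer vector of edge indices (rows of `tree$edge`)
#'   carrying shifts; empty for a single-regime model.
#' @return Log-likelihood (scalar).
#' @export
ou_loglik <- function(y, tree, alpha, sigma2, theta,
                      shift_edges = integer(0)) {
  ctx <- ou_ctx(tree)
  if (length(y) != ctx$n) stop_input("`y` must have one value per tip")
  if (length(theta) != length(shift_edges) + 1) {
    stop_input("`theta` must have one optimum per regime (base first)")
  }
  if (length(shift_edges) && any(shift_edges < 1 |
                                 shift_edges > nrow(ctx$edge))) {
    stop_input("`shift_edges` must index rows of tree$edge")
  }
  V <- ou_cov_from_ctx(ctx, alpha, sigma2)
  L <- tryCatch(chol(V), error = function(e) {
    stop_input("OU covariance is numerically singular",
               class = "rubrovol_decomposition_error")
  })
  mu <- as.numeric(ou_design(ctx, alpha, shift_edges) %*% theta)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (ctx$n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# Profile fit of a fixed shift configuration: theta and sigma^2 are
# profiled analytically at each alpha, alpha optimised on a coarse grid
# followed by a local search.
ou_profile_fit <- function(ctx, y, shift_edges) {
  n <- ctx$n
  eval_alpha <- function(alpha) {
    V0 <- ou_decay(ctx$Cbm, alpha) * exp(-alpha * ctx$Dmat)
    L <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(L)) return(list(loglik = -Inf))
    wh <- function(v) backsolve(L, v, transpose = TRUE)
    W <- ou_design(ctx, alpha, shift_edges)
    Ww <- wh(W)
    yw <- wh(y)
    qrW <- qr(Ww)
    theta <- qr.coef(qrW, yw)
    theta[is.na(theta)] <- theta[1] # unidentifiable regimes -> base optimum
    r <- y - as.numeric(W %*% theta)
    rss <- sum(wh(r)^2)
    sigma2 <- max(rss / n, 1e-12)
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) +
                    2 * sum(log(diag(L))) + rss / sigma2)
    list(loglik = ll, alpha = alpha, sigma2 = sigma2, theta = theta)
  }
  grid <- c(0, 10^seq(log10(0.01 / ctx$Tmax), log10(50 / ctx$Tmax),
                      length.out = 12))
  fits <- lapply(grid, eval_alpha)
  lls <- vapply(fits, function(f) f$loglik, 0)
  best_i <- which.max(lls)
  lo <- grid[max(1, best_i - 1)]
  hi <- grid[min(length(grid), best_i + 1)]
  if (hi > lo) {
    opt <- optimize(function(a) eval_alpha(a)$loglik, c(lo, hi),
                    maximum = TRUE, tol = 1e-6 / ctx$Tmax)
    cand <- eval_alpha(opt$maximum)
    if (cand$loglik > lls[best_i]) return(cand)
  }
  fits[[best_i]]
}

ou_criterion <- function(loglik, K, n, n_edges, criterion) {
  p <- K + 3 # K+1 optima, alpha, sigma^2
  switch(criterion,
    BIC = -2 * loglik + p * log(n),
    AICc = -2 * loglik + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1),
    pBIC = -2 * loglik + p * log(n) + 2 * lchoose(n_edges, K)
  )
}

new_ou_shift_fit <- function(ctx, y, shift_edges, prof, criterion, score) {
  K <- length(shift_edges)
  shifts <- tibble::tibble(
    edge = shift_edges,
    clade = vapply(shift_edges, function(e) edge_clade_label(ctx, e), ""),
    n_tips = vapply(shift_edges, function(e) {
      sum(vapply(ctx$paths, function(p) e %in% p, logical(1)))
    }, 0L),
    theta = if (K) unname(prof$theta[-1]) else numeric(0),
    delta_theta = if (K) unname(prof$theta[-1] - prof$theta[1]) else numeric(0)
  )
  structure(
    list(tree = ctx$tree, y = y, shift_edges = shift_edges,
         shifts = shifts, theta_base = unname(prof$theta[1]),
         alpha = prof$alpha, sigma2 = prof$sigma2, loglik = prof$loglik,
         criterion = criterion, score = score, n = ctx$n,
         n_edges = nrow(ctx$edge)),
    class = "ou_shift_fit"
  )
}

#' Detect optimum shifts on a phylogeny
#'
#' Searches for edges of the tree on which the OU optimum of a trait
#' (typically an allometric residual) shifted, with no a priori hypothesis
#' about where. The search is exhaustive over single edges and extends
#' greedily (forward selection) for additional shifts, each candidate
#' configuration fitted by profile maximum likelihood and scored by the
#' chosen information criterion. The default `pBIC` adds a
#' placement-multiplicity term `2 log C(E, K)` (E edges, K shifts) to BIC,
#' penalising the size of the model-search space in the spirit of
#' phylogenetically corrected BIC. Ties are broken toward fewer shifts,
#' then toward the edge closer to the root.
#'
#' @param y Tip-ordered trait vector (named vectors are checked against
#'   the tree's tip labels).
#' @param tree Ultrametric `phylo` with at least 6 tips.
#' @param max_shifts Maximum number of shifts to consider (< number of
#'   tips; default 3).
#' @param criterion `"pBIC"` (default), `"BIC"` or `"AICc"`.
#' @param seed Accepted for interface stability; the search itself is
#'   deterministic.
#' @return An `ou_shift_fit`: selected shift edges with clade labels and
#'   optima, base optimum, `alpha`, `sigma2`, log-likelihood and criterion
#'   score. Never scores worse than the zero-shift model.
#' @examples
#' tr <- rn_chronogram()
#' y <- simulate_bm(tr, sigma2 = 0.01, seed = 1)
#' detect_shifts(y, tr)
#' @export
detect_shifts <- function(y, tree, max_shifts = 3,
                          criterion = c("pBIC", "BIC", "AICc"),
                          seed = NULL) {
  criterion <- match.arg(criterion)
  ctx <- ou_ctx(tree)
  if (ctx$n < 6) stop_input("need at least 6 tips to search for shifts",
                            class = "rubrovol_insufficient_data")
  if (max_shifts >= ctx$n) {
    stop_input("`max_shifts` must be smaller than the number of tips")
  }
  if (!is.null(names(y))) {
    if (!setequal(names(y), tree$tip.label)) {
      stop_input("names of `y` do not match the tree's tips")
    }
    y <- y[tree$tip.label]
  }
  if (length(y) != ctx$n) stop_input("`y` must have one value per tip")

  n_edges <- nrow(ctx$edge)
  score_of <- function(prof, K) ou_criterion(prof$loglik, K, ctx$n,
                                             n_edges, criterion)
  prof0 <- ou_profile_fit(ctx, y, integer(0))
  best <- list(edges = integer(0), prof = prof0, score = score_of(prof0, 0))

  current <- best
  K <- 0L
  while (K < max_shifts) {
    cand_edges <- setdiff(seq_len(n_edges), current$edges)
    cand_best <- NULL
    for (e in cand_edges) {
      edges_e <- c(current$edges, e)
      prof_e <- ou_profile_fit(ctx, y, edges_e)
      sc <- score_of(prof_e, K + 1L)
      better <- is.null(cand_best) && is.finite(sc) ||
        (!is.null(cand_best) &&
           (sc < cand_best$score - 1e-8 ||
              (abs(sc - cand_best$score) <= 1e-8 &&
                 ctx$e_start[e] < ctx$e_start[cand_best$new_edge])))
      if (better) {
        cand_best <- list(edges = edges_e, prof = prof_e, score = sc,
                          new_edge = e)
      }
    }
    if (is.null(cand_best)) break
    current <- cand_best
    K <- K + 1L
    # accept only strict improvement over the incumbent (ties -> fewer)
    if (cand_best$score < best$score - 1e-8) best <- cand_best
  }
  new_ou_shift_fit(ctx, y, best$edges, best$prof, criterion, best$score)
}

#' @export
print.ou_shift_fit <- function(x, ...) {
  cat("Multi-regime OU fit (", x$criterion, " = ", format(x$score),
      ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("  alpha %.4g  sigma^2 %.4g  base optimum %.4g\n",
              x$alpha, x$sigma2, x$theta_base))
  if (nrow(x$shifts) == 0) {
    cat("  no shifts selected\n")
  } else {
    print(x$shifts)
  }
  invisible(x)
}

#' @describeIn detect_shifts Tidy the selected shifts (one row per shift
#'   edge, with `support` merged in when present).
#' @param x An `ou_shift_fit`.
#' @param ... Unused.
#' @export
tidy.ou_shift_fit <- function(x, ...) x$shifts

#' @describeIn detect_shifts One-row model summary.
#' @export
glance.ou_shift_fit <- function(x, ...) {
  tibble::tibble(n_shifts = nrow(x$shifts), alpha = x$alpha,
                 sigma2 = x$sigma2, logLik = x$loglik,
                 criterion = x$criterion, score = x$score, nobs = x$n)
}

#' Parametric bootstrap support for detected shifts
#'
#' Simulates replicate trait vectors from the fitted multi-regime OU model
#' (its estimated mean structure and covariance), reruns the shift search
#' on each, and reports for every edge the percentage of replicates in
#' which that edge was selected. Reproducible given `seed`.
#'
#' @param fit An `ou_shift_fit` from [detect_shifts()].
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed (required for reproducibility).
#' @param max_shifts,criterion Search settings for the replicate runs;
#'   default to the fitted object's settings.
#' @return Tibble with one row per edge ever selected (plus all fitted
#'   shift edges): `edge`, `clade`, `support` (percent of replicates),
#'   `in_fit` (logical).
#' @export
bootstrap_support <- function(fit, n_boot = 100, seed = 1,
                              max_shifts = NULL, criterion = NULL) {
  stopifnot(inherits(fit, "ou_shift_fit"))
  if (n_boot < 1) stop_input("`n_boot` must be >= 1")
  criterion <- criterion %||% fit$criterion
  max_shifts <- max_shifts %||% max(3, length(fit$shift_edges))
  ctx <- ou_ctx(fit$tree)
  W <- ou_design(ctx, fit$alpha, fit$shift_edges)
  theta <- c(fit$theta_base, fit$shifts$theta)
  mu <- as.numeric(W %*% theta)
  V <- ou_cov_from_ctx(ctx, fit$alpha, fit$sigma2)
  Lt <- t(chol(V))
  counts <- numeric(nrow(ctx$edge))
  Z <- with_seed(seed, matrix(rnorm(ctx$n * n_boot), ctx$n, n_boot))
  for (b in seq_len(n_boot)) {
    yb <- mu + as.numeric(Lt %*% Z[, b])
    fb <- detect_shifts(yb, fit$tree, max_shifts = max_shifts,
                        criterion = criterion)
    counts[fb$shift_edges] <- counts[fb$shift_edges] + 1
  }
  support <- counts / n_boot * 100
  edges <- sort(union(which(counts > 0), fit$shift_edges))
  tibble::tibble(
    edge = edges,
    clade = vapply(edges, function(e) edge_clade_label(ctx, e), ""),
    support = support[edges],
    in_fit = edges %in% fit$shift_edges
  )
}

#' Signal-to-noise effect size of detected shifts
#'
#' Scales each estimated optimum shift by the stationary standard
#' deviation of the OU process, \eqn{\sqrt{\sigma^2/(2\alpha)}}, and by
#' the regime design factor \eqn{\sqrt{n_r (n - n_r)/n}} (the balance of
#' tips inside vs outside the shifted regime). Values much greater than 1
#' indicate a shift large relative to the stationary trait fluctuation,
#' i.e. high power. This is the documented surrogate statistic for the
#' signal-to-noise effect size \eqn{\sqrt{\eta_\phi}}; the output labels
#' it as such.
#'
#' @param fit An `ou_shift_fit` with at least one shift.
#' @return Tibble with one row per shift: `clade`, `delta_theta`, `snr`;
#'   attribute `overall` holds the maximum. Zero when `alpha = 0`
#'   (infinite stationary variance).
#' @export
snr_effect_size <- function(fit) {
  stopifnot(inherits(fit, "ou_shift_fit"))
  if (nrow(fit$shifts) == 0) {
    stop_input("effect size is undefined for a single-regime fit",
               class = "rubrovol_undefined_effect")
  }
  stat_sd <- if (fit$alpha > 0) sqrt(fit$sigma2 / (2 * fit$alpha)) else Inf
  design <- sqrt(fit$shifts$n_tips * (fit$n - fit$shifts$n_tips) / fit$n)
  snr <- abs(fit$shifts$delta_theta) / stat_sd * design
  out <- tibble::tibble(clade = fit$shifts$clade,
                        delta_theta = fit$shifts$delta_theta,
                        snr = snr, statistic = "fallback |dtheta|/sd_stat")
  attr(out, "overall") <- max(snr)
  out
}
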