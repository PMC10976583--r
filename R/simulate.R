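# Trait and data simulators. All simulation is exact multivariate
# Gaussian sampling from the model's mean and covariance (no path
# discretization), so simulated data match the likelihoods tested
# elsewhere in the package exactly, and all generators are reproducible
# given a seed.

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Draws one tip vector from `N(root_state, sigma2 * C)` with `C` the
#' Brownian covariance of the tree.
#'
#' @param tree A `phylo`.
#' @param sigma2 Diffusion variance per unit branch length (> 0; `0` is
#'   allowed and returns the root state everywhere).
#' @param root_state Trait value at the root (default 0).
#' @param seed Integer seed (required for reproducibility).
#' @return Named numeric vector of tip values (tip order of the tree).
#' @examples
#' simulate_bm(rn_chronogram(), sigma2 = 0.01, seed = 7)
#' @export
simulate_bm <- function(tree, sigma2, root_state = 0, seed = 1) {
  check_number(sigma2, "sigma2", min = 0)
  validate_phylo(tree)
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    return(setNames(rep(root_state, n), tree$tip.label))
  }
  C <- bm_covariance(tree)
  z <- with_seed(seed, rnorm(n))
  y <- root_state + as.numeric(t(chol(sigma2 * C)) %*% z)
  setNames(y, tree$tip.label)
}

#' Simulate multi-regime Ornstein-Uhlenbeck trait evolution on a tree
#'
#' Draws one tip vector from the exact Gaussian distribution of the
#' multi-regime OU process: mean from the regime painting (see
#' [ou_loglik()]) and covariance from [ou_covariance()]. As `alpha` tends
#' to 0 with no shifts the distribution approaches [simulate_bm()]'s.
#'
#' @param tree Ultrametric `phylo`.
#' @param alpha,sigma2 OU parameters.
#' @param theta Optima: base regime first, then one per shift edge.
#' @param shift_edges Edge indices carrying optimum shifts (may be empty).
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_ou <- function(tree, alpha, sigma2, theta = 0,
                        shift_edges = integer(0), seed = 1) {
  check_number(alpha, "alpha", min = 0)
  check_number(sigma2, "sigma2", positive = TRUE)
  ctx <- ou_ctx(tree)
  if (length(theta) != length(shift_edges) + 1) {
    stop_input("`theta` must have one optimum per regime (base first)")
  }
  if (length(shift_edges) && any(shift_edges < 1 |
                                 shift_edges > nrow(ctx$edge))) {
    stop_input("`shift_edges` must index rows of tree$edge")
  }
  mu <- as.numeric(ou_design(ctx, alpha, shift_edges) %*% theta)
  V <- ou_cov_from_ctx(ctx, alpha, sigma2)
  z <- with_seed(seed, rnorm(ctx$n))
  setNames(mu + as.numeric(t(chol(V)) %*% z), tree$tip.label)
}

#' Simulate a random ultrametric (Yule) tree
#'
#' Pure-birth tree with `n` tips, rescaled to the requested depth.
#'
#' @param n Number of tips (>= 2).
#' @param seed Integer seed.
#' @param depth Root-to-tip depth of the returned tree (default 1).
#' @return An ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n, seed = 1, depth = 1) {
  if (n < 2) stop_input("`n` must be >= 2")
  check_number(depth, "depth", positive = TRUE)
  tree <- with_seed(seed, ape::rphylo(n, birth = 1, death = 0))
  tree$edge.length <- tree$edge.length * (depth / max(tip_depths(tree)))
  tree
}

#' Simulate a grade-shifted allometric species table
#'
#' Generates a drop-in replacement for the packaged trait table: brain
#' volumes evolve by Brownian motion on the tree (on the log10 scale),
#' and each region volume follows a power-law allometry
#' `log10(region) = intercept(group) + slope * log10(brain) + noise`,
#' where the noise is itself Brownian on the tree (phylogenetically
#' structured residuals) and the intercept may shift for tips descending
#' from designated edges -- a grade shift. Bilateral volumes are split
#' into left/right halves with small log-normal asymmetry jitter.
#'
#' Defaults emulate the study conditions: ~20 species, RNp scaling
#' proportionally (one grade) and RNm carrying a strong downward grade
#' shift on the clade of humans plus non-human apes.
#'
#' @param tree Tree over the species (default: the surrogate chronogram).
#' @param slope Common allometric slope (default 0.95).
#' @param intercept_rnp,intercept_rnm Base intercepts on the log10 mm^3
#'   scale (defaults -2.6 and -2.9, giving relative volumes of the order
#'   of 0.01-0.1% of brain volume).
#' @param shift_edges Edge indices whose descendant tips get a shifted
#'   RNm intercept (default: none).
#' @param shift_delta Added to the RNm intercept inside shifted clades
#'   (default -1.5, i.e. a ~30-fold reduction).
#' @param sigma2_bv BM variance of log10 brain volume per unit time
#'   (default 0.01).
#' @param sigma2_resid BM variance of the allometric residual per unit
#'   time (default 2.5e-4, residual SD ~0.14 at the surrogate tree depth).
#' @param asymmetry_sd SD of the log10 left/right jitter (default 0.02).
#' @param root_log10_bv Root state of log10 brain volume in mm^3
#'   (default 4.3, ~20 cm^3).
#' @param seed Integer seed.
#' @return A trait table tibble with the standard columns (`species`,
#'   `group`, `bv_cm3`, `rnp_r`, `rnp_l`, `rnm_r`, `rnm_l`, `n`).
#' @export
make_allometric_table <- function(tree = rn_chronogram(),
                                  slope = 0.95,
                                  intercept_rnp = -2.6,
                                  intercept_rnm = -2.9,
                                  shift_edges = integer(0),
                                  shift_delta = -1.5,
                                  sigma2_bv = 0.01,
                                  sigma2_resid = 2.5e-4,
                                  asymmetry_sd = 0.02,
                                  root_log10_bv = 4.3,
                                  seed = 1) {
  validate_phylo(tree)
  n <- length(tree$tip.label)
  groups <- rn_species_groups()
  group <- groups$group[match(tree$tip.label, groups$species)]
  group[is.na(group)] <- "prosimians" # arbitrary valid label for non-study tips
  seeds <- with_seed(seed, sample.int(2^31 - 1, 4))
  log_bv <- simulate_bm(tree, sigma2_bv, root_state = root_log10_bv,
                        seed = seeds[1])
  resid_rnp <- simulate_bm(tree, sigma2_resid, seed = seeds[2])
  resid_rnm <- simulate_bm(tree, sigma2_resid, seed = seeds[3])
  shift_ind <- rep(0, n)
  if (length(shift_edges)) {
    ctx <- ou_ctx(tree)
    hit <- vapply(ctx$paths, function(p) any(shift_edges %in% p), logical(1))
    shift_ind[hit] <- 1
  }
  log_rnp <- intercept_rnp + slope * log_bv + resid_rnp
  log_rnm <- intercept_rnm + shift_delta * shift_ind + slope * log_bv +
    resid_rnm
  jit <- with_seed(seeds[4], matrix(rnorm(2 * n, sd = asymmetry_sd), n, 2))
  tibble::tibble(
    species = tree$tip.label,
    group = group,
    bv_cm3 = 10^log_bv / 1000,
    rnp_r = 10^(log_rnp + jit[, 1]) / 2,
    rnp_l = 10^(log_rnp - jit[, 1]) / 2,
    rnm_r = 10^(log_rnm + jit[, 2]) / 2,
    rnm_l = 10^(log_rnm - jit[, 2]) / 2,
    n = 1L
  )
}

#' Serial-section area profile of an ellipsoid
#'
#' Analytic cross-sectional areas of an axis-aligned ellipsoid sliced
#' perpendicular to its first semi-axis, for testing and demonstrating
#' the Cavalieri estimator against a solid of known volume.
#'
#' @param semi_axes Numeric length-3 vector of semi-axes (mm).
#' @param spacing Section spacing (mm).
#' @param offset Position of the first section relative to the ellipsoid
#'   centre, in `[0, spacing)`; default `spacing / 2` (a systematic
#'   uniform start).
#' @return Tibble with `position` (mm, from centre) and `area` (mm^2).
#' @export
ellipsoid_sections <- function(semi_axes, spacing, offset = spacing / 2) {
  stopifnot(length(semi_axes) == 3)
  a <- semi_axes[1]
  pos <- seq(-a + offset, a, by = spacing)
  area <- pi * semi_axes[2] * semi_axes[3] * pmax(0, 1 - (pos / a)^2)
  tibble::tibble(position = pos, area = area)
}
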