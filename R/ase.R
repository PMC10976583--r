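# Ancestral state estimation under Brownian motion. The ML/GLS point
# estimates solve a weighted-Laplacian system: each internal node's value
# is the inverse-branch-length weighted mean of its neighbours' values,
# which minimises the sum over edges of (change)^2 / length.

ase_solve <- function(tree, y, lengths) {
  n <- length(tree$tip.label)
  n_node <- tree$Nnode
  edge <- tree$edge
  w <- 1 / lengths
  A <- matrix(0, n_node, n_node)
  b <- numeric(n_node)
  idx <- function(node) node - n # internal node -> unknown index
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    ip <- idx(p)
    A[ip, ip] <- A[ip, ip] + w[e]
    if (ch <= n) {
      b[ip] <- b[ip] + w[e] * y[ch]
    } else {
      ic <- idx(ch)
      A[ip, ic] <- A[ip, ic] - w[e]
      A[ic, ic] <- A[ic, ic] + w[e]
      A[ic, ip] <- A[ic, ip] - w[e]
    }
  }
  as.numeric(solve(A, b))
}

# MRCA-pair label for an internal node, so reports are readable without
# node numbering conventions.
node_labels <- function(tree) {
  n <- length(tree$tip.label)
  vapply(seq_len(tree$Nnode) + n, function(nd) {
    tips <- tree$tip.label[unlist(ape::prop.part(tree)[nd - n])]
    paste0("mrca(", tips[1], ",", tips[length(tips)], ")")
  }, "")
}

prep_ase_input <- function(y, tree) {
  validate_phylo(tree)
  n <- length(tree$tip.label)
  if (!is.null(names(y))) {
    if (!setequal(names(y), tree$tip.label)) {
      stop_input("names of `y` do not match the tree's tips")
    }
    y <- y[tree$tip.label]
  }
  if (length(y) != n) stop_input("`y` must have one value per tip")
  lengths <- tree$edge.length
  if (any(lengths == 0)) {
    eps <- 1e-8 * max(tip_depths(tree))
    warn(paste0("zero-length branch(es); applying pseudo-length ", eps))
    lengths[lengths == 0] <- eps
  }
  list(y = y, lengths = lengths)
}

new_rn_ase <- function(tree, estimates, rates, method, converged = TRUE,
                       iterations = NA_integer_) {
  structure(
    list(
      estimates = tibble::tibble(
        node = seq_len(tree$Nnode) + length(tree$tip.label),
        label = node_labels(tree),
        estimate = estimates
      ),
      rates = tibble::tibble(edge = seq_len(nrow(tree$edge)), rate = rates),
      method = method, tree = tree, converged = converged,
      iterations = iterations
    ),
    class = "rn_ase"
  )
}

#' Ancestral state estimation under single-rate Brownian motion
#'
#' Maximum-likelihood (GLS) point estimates of trait values at the
#' internal nodes of a tree under Brownian motion. Estimates are the
#' solution of the inverse-branch-length weighted-mean system, so they
#' always lie within the range of the tip values. Nodal point estimates
#' carry high inherent uncertainty and should be read as a visualization
#' of trends through time, not as measurements; reports carry that
#' disclaimer.
#'
#' @param y Tip values (named vectors are matched to tip labels).
#' @param tree A `phylo` with positive branch lengths; zero-length
#'   branches get a pseudo-length of `1e-8 *` tree depth, with a warning.
#' @return An `rn_ase` object: tibble of per-node estimates (nodes
#'   labelled by MRCA tip pairs), per-edge rate scalars (all 1 under
#'   single-rate BM), and a method tag.
#' @examples
#' tr <- read_newick("(A:1,B:3);")
#' ase_bm(c(A = 0, B = 4), tr)
#' @export
ase_bm <- function(y, tree) {
  inp <- prep_ase_input(y, tree)
  est <- ase_solve(tree, inp$y, inp$lengths)
  new_rn_ase(tree, est, rates = rep(1, nrow(tree$edge)), method = "BM")
}

#' Ancestral state estimation under multiple-variance Brownian motion
#'
#' Relaxes the single-rate assumption by giving every branch its own rate
#' scalar, so clades evolving faster contribute less precision to nearby
#' nodal estimates. The estimates and rates are obtained by alternating
#' (i) BM ancestral estimation on rate-scaled branch lengths and (ii)
#' updating each branch's rate scalar from the squared change along it per
#' unit original length (its squared independent contrast), normalised to
#' mean 1, with damping and a small floor for numerical stability, until
#' the nodal estimates move less than `tol` or `max_iter` is reached.
#' With all rate scalars equal to 1 the procedure is exactly [ase_bm()].
#'
#' @inheritParams ase_bm
#' @param max_iter Maximum iterations (default 100).
#' @param tol Convergence tolerance on the max change in nodal estimates
#'   (default 1e-6).
#' @return An `rn_ase` with method `"mvBM"`, per-branch rate scalars
#'   (mean 1), and a `converged` flag (`FALSE` if `max_iter` was hit).
#' @export
ase_mvbm <- function(y, tree, max_iter = 100, tol = 1e-6) {
  inp <- prep_ase_input(y, tree)
  lengths <- inp$lengths
  n <- length(tree$tip.label)
  rates <- rep(1, nrow(tree$edge))
  est <- ase_solve(tree, inp$y, lengths)
  node_val <- function(est) c(inp$y, est) # value at any node id
  converged <- FALSE
  it <- 0L
  floor_rate <- 1e-6
  for (it in seq_len(max_iter)) {
    vals <- node_val(est)
    contrast2 <- (vals[tree$edge[, 2]] - vals[tree$edge[, 1]])^2 / lengths
    if (mean(contrast2) < .Machine$double.eps * max(1, mean(inp$y)^2)) {
      rates <- rep(1, length(rates)) # constant trait: homogeneous rates
      converged <- TRUE
      break
    }
    prop <- pmax(contrast2 / mean(contrast2), floor_rate)
    new_rates <- sqrt(rates * prop) # damped (geometric) update
    new_rates <- new_rates / mean(new_rates)
    new_est <- ase_solve(tree, inp$y, lengths * new_rates)
    delta <- max(abs(new_est - est))
    rates <- new_rates
    est <- new_est
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  new_rn_ase(tree, est, rates, method = "mvBM", converged = converged,
             iterations = it)
}

#' @export
print.rn_ase <- function(x, ...) {
  cat("Ancestral state estimates (", x$method, ")\n", sep = "")
  if (!x$converged) cat("  WARNING: did not converge\n")
  print(x$estimates)
  cat("Note: nodal point estimates carry high uncertainty;",
      "use for visualizing trends through time only.\n")
  invisible(x)
}

#' @describeIn ase_bm Per-node estimates as a tibble.
#' @param x An `rn_ase` object.
#' @param ... Unused.
#' @export
tidy.rn_ase <- function(x, ...) x$estimates

#' @describeIn ase_bm One-row summary (method, convergence, rate spread).
#' @export
glance.rn_ase <- function(x, ...) {
  tibble::tibble(method = x$method, converged = x$converged,
                 iterations = x$iterations,
                 rate_min = min(x$rates$rate), rate_max = max(x$rates$rate))
}
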