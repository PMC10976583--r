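# Independent oracles used across the test files. These deliberately use
# direct, brute-force arithmetic (explicit matrix inversion, enumeration)
# rather than the package's own code paths.

# GLS estimates by explicit inversion: (X' C^-1 X)^-1 X' C^-1 y
brute_gls <- function(x, y, C) {
  X <- cbind(1, x)
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       rss = drop(t(r) %*% Ci %*% r))
}

# Nested-regression F by brute force in the C^-1 metric
brute_ancova_F <- function(x, y, C, g, test = "intercept") {
  Ci <- solve(C)
  rss <- function(X) {
    b <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
    r <- y - X %*% b
    drop(t(r) %*% Ci %*% r)
  }
  X0 <- cbind(1, x)
  gf <- factor(g)
  X1 <- switch(test,
    intercept = cbind(stats::model.matrix(~gf), x),
    both = stats::model.matrix(~ gf * x)
  )
  r0 <- rss(X0); r1 <- rss(X1)
  df1 <- ncol(X1) - 2
  df2 <- length(y) - ncol(X1)
  ((r0 - r1) / df1) / (r1 / df2)
}

# dense multivariate normal log-density via explicit inverse/determinant
dense_mvn_loglik <- function(y, mu, V) {
  n <- length(y)
  -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
            drop(t(y - mu) %*% solve(V) %*% (y - mu)))
}

# all 2-partitions of n points: minimum achievable total WCSS
brute_kmeans2_wcss <- function(m) {
  n <- nrow(m)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    w <- 0
    for (side in list(grp, !grp)) {
      pts <- m[side, , drop = FALSE]
      cen <- colMeans(pts)
      w <- w + sum(sweep(pts, 2, cen)^2)
    }
    best <- min(best, w)
  }
  best
}

same_partition <- function(a, b) {
  identical(a == a[1], b == b[1])
}

# hominoid species of the study set
hominoid_species <- function() {
  g <- rn_species_groups()
  g$species[g$group %in% c("humans", "non-human apes")]
}

# edge index whose descendant clade is exactly `tips`
find_clade_edge <- function(tree, tips) {
  n <- length(tree$tip.label)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    clade <- if (child <= n) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    if (setequal(clade, tips)) return(e)
  }
  NA_integer_
}

# parent/child edges of an edge (for near-miss credit in recovery tests)
adjacent_edges <- function(tree, e) {
  pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
  which(tree$edge[, 2] == pa | tree$edge[, 1] == ch)
}
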