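#' Morphospace features from a volume summary
#'
#' Builds the two-dimensional feature space used to compare the balance of
#' the RN subdivisions across species: `x` is the relative difference
#' between RNp and RNm as a percentage of brain volume (absolute by
#' default, so direction lives on the other axis), and `y` is
#' `log10(RNm/RNp)` -- positive when RNm is the larger subdivision, zero
#' when the two are equally large, and `10^|y|` gives the fold difference.
#'
#' @param species_summary Output of [rn_species_summary()] (a raw trait
#'   table is accepted and summarized first).
#' @param signed_x If `TRUE`, `x` keeps the sign of RNp - RNm instead of
#'   the absolute value.
#' @return Tibble: `species`, `group`, `x`, `y`.
#' @export
rn_features <- function(species_summary, signed_x = FALSE) {
  if (!"rn_total" %in% names(species_summary)) {
    species_summary <- rn_species_summary(species_summary)
  }
  bad <- species_summary$rnm <= 0 | species_summary$rnp <= 0
  if (any(bad)) {
    stop_input("log ratio undefined (zero RNm or RNp) for species: ",
               paste(species_summary$species[bad], collapse = ", "))
  }
  tibble::tibble(
    species = species_summary$species,
    group = species_summary$group,
    x = if (signed_x) species_summary$rel_diff else
      species_summary$abs_rel_diff,
    y = species_summary$log10_ratio
  )
}

#' Two-cluster k-means on morphospace features
#'
#' Runs k-means with k = 2 on the feature columns, taking the best of
#' `n_init` random restarts; deterministic given `seed`. Features are not
#' standardized by default (the morphospace axes are compared on their raw
#' scales); set `standardize = TRUE` to z-score them first. Cluster labels
#' are arbitrary -- compare memberships as partitions, not label values.
#'
#' @param features Tibble from [rn_features()], or any data frame with
#'   numeric columns `x` and `y` (and optionally `species`).
#' @param seed Integer seed.
#' @param n_init Number of random restarts (default 50).
#' @param standardize Z-score the features first? Default `FALSE`.
#' @return An `rn_clusters` object: tibble of assignments (`species`,
#'   `cluster`), plus `centroids` and total within-cluster sum of squares
#'   `wcss` as fields.
#' @export
kmeans2 <- function(features, seed = 1, n_init = 50, standardize = FALSE) {
  m <- as.matrix(features[, c("x", "y")])
  if (nrow(m) < 2) stop_input("need at least 2 points for k = 2")
  if (standardize) m <- scale(m)
  if (nrow(m) == 2) {
    # k = n: each point is its own cluster (kmeans refuses this case)
    km <- list(cluster = 1:2, centers = m, tot.withinss = 0)
  } else {
    km <- with_seed(seed, kmeans(m, centers = 2, nstart = n_init))
  }
  structure(
    list(
      assignments = tibble::tibble(
        species = features[["species"]] %||% as.character(seq_len(nrow(m))),
        cluster = unname(km$cluster)
      ),
      centroids = km$centers,
      wcss = km$tot.withinss,
      seed = seed, n_init = n_init, standardize = standardize,
      features = features
    ),
    class = "rn_clusters"
  )
}

#' @export
print.rn_clusters <- function(x, ...) {
  cat("k-means (k = 2), WCSS =", format(x$wcss), "\n")
  print(x$assignments)
  invisible(x)
}

#' @describeIn kmeans2 Assignments as a tibble.
#' @param x An `rn_clusters` object.
#' @param ... Unused.
#' @export
tidy.rn_clusters <- function(x, ...) x$assignments

#' @describeIn kmeans2 One-row summary with the WCSS.
#' @export
glance.rn_clusters <- function(x, ...) {
  tibble::tibble(k = 2, wcss = x$wcss, n = nrow(x$assignments),
                 n_init = x$n_init)
}

#' @describeIn kmeans2 Plot the clustered morphospace, with centroids.
#' @param object An `rn_clusters` object.
#' @export
autoplot.rn_clusters <- function(object, ...) {
  d <- dplyr::bind_cols(object$features,
                        cluster = factor(object$assignments$cluster))
  cen <- tibble::as_tibble(object$centroids)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 2) +
    ggplot2::geom_point(data = cen, shape = 4, size = 4, stroke = 1.2) +
    ggplot2::labs(x = "|RNp - RNm| (% of brain volume)",
                  y = "log10(RNm / RNp)") +
    ggplot2::theme_minimal()
}

#' Pearson correlation with a two-sided test
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be
#'   constant (the correlation is undefined).
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_input("`x` and `y` must match in length")
  if (length(x) < 3) stop_input("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_input("correlation undefined for a constant vector",
               class = "rubrovol_undefined_correlation")
  }
  ct <- cor.test(x, y)
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
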