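#' Cavalieri volume estimate from serial-section areas
#'
#' Estimates the volume of a delineated structure from areas measured on a
#' systematic subsample of serial sections: the sum of delineated areas
#' times the spacing between measured sections, scaled back to fresh-tissue
#' scale by the shrinkage factor.
#'
#' @param areas Numeric vector of delineated areas (mm^2), one per measured
#'   section, in section order. Areas must be >= 0.
#' @param spacing Distance between measured sections (mm), > 0. Typically
#'   an integer multiple of the physical section thickness.
#' @param shrinkage Dimensionless shrinkage factor, the ratio of fresh to
#'   processed volume (>= 1 for shrinking tissue; see [shrinkage_factor()]).
#' @return Volume in mm^3 at fresh-tissue scale.
#' @examples
#' cavalieri_volume(2, spacing = 0.3) # single section
#' @export
cavalieri_volume <- function(areas, spacing, shrinkage = 1) {
  if (length(areas) < 1L) stop_input("`areas` must be non-empty")
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop_input("`areas` must be finite and >= 0")
  }
  check_number(spacing, "spacing", positive = TRUE)
  check_number(shrinkage, "shrinkage", positive = TRUE)
  sum(areas) * spacing * shrinkage
}

#' Fresh brain volume from fresh weight
#'
#' Converts a fresh brain weight to a fresh brain volume using a tissue
#' density constant. The default density of 1.032 g/cm^3 reproduces the
#' packaged human brain-volume figures from the specimen weights.
#'
#' @param weight_g Fresh weight in grams (> 0). Vectorized.
#' @param density Tissue density in g/cm^3 (> 0); default 1.032.
#' @return Volume in cm^3.
#' @examples
#' fresh_brain_volume(1032) # 1000 cm^3
#' @export
fresh_brain_volume <- function(weight_g, density = 1.032) {
  if (any(!is.finite(weight_g)) || any(weight_g <= 0)) {
    stop_input("`weight_g` must be finite and > 0")
  }
  check_number(density, "density", positive = TRUE)
  weight_g / density
}

#' Shrinkage factor from fresh and processed volumes
#'
#' The shrinkage factor is the ratio between the estimated fresh volume and
#' the volume after histological processing; multiplying a processed-tissue
#' Cavalieri estimate by it restores fresh-tissue scale.
#'
#' @param fresh Fresh volume (> 0).
#' @param processed Volume after histological processing (> 0).
#' @return Dimensionless ratio fresh / processed.
#' @export
shrinkage_factor <- function(fresh, processed) {
  check_number(fresh, "fresh", positive = TRUE)
  check_number(processed, "processed", positive = TRUE)
  fresh / processed
}

trait_cols <- c("species", "group", "bv_cm3", "rnp_r", "rnp_l",
                "rnm_r", "rnm_l", "n")

validate_trait_table <- function(traits) {
  missing_cols <- setdiff(trait_cols, names(traits))
  if (length(missing_cols)) {
    stop_input("trait table is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(traits$species)) {
    stop_input("species names must be unique")
  }
  vol_cols <- c("bv_cm3", "rnp_r", "rnp_l", "rnm_r", "rnm_l")
  for (cl in vol_cols) {
    bad <- !is.finite(traits[[cl]]) | traits[[cl]] <= 0
    if (any(bad)) {
      stop_input("non-positive or missing volume in column '", cl,
                 "' for species: ",
                 paste(traits$species[bad], collapse = ", "))
    }
  }
  groups <- c("humans", "non-human apes", "old world monkeys",
              "new world monkeys", "prosimians")
  bad <- !(traits$group %in% groups)
  if (any(bad)) {
    stop_input("unknown group label(s): ",
               paste(unique(traits$group[bad]), collapse = ", "),
               "; expected one of: ", paste(groups, collapse = ", "))
  }
  invisible(traits)
}

#' Per-species volume summary
#'
#' Computes, for each species in a trait table, the bilateral RNp, RNm and
#' total red-nucleus volumes, their relative volumes as percentages of
#' whole-brain volume, the RNm/RNp ratio and its log10, and the relative
#' difference between the two subdivisions (both signed and absolute).
#' All values are kept at full precision; round only for display.
#'
#' @param traits A trait table with columns `species`, `group`, `bv_cm3`
#'   (fresh brain volume in cm^3), `rnp_r`, `rnp_l`, `rnm_r`, `rnm_l`
#'   (subdivision volumes in mm^3) and `n` (specimen count), as returned by
#'   [load_rn_fixture()] or [make_allometric_table()].
#' @return A tibble with one row per species: bilateral volumes (`rnp`,
#'   `rnm`, `rn_total`, mm^3), brain volume in mm^3 (`bv_mm3`), relative
#'   volumes in percent (`rel_rn`, `rel_rnp`, `rel_rnm`), `ratio_rnm_rnp`,
#'   `log10_ratio`, and relative differences in percent of brain volume
#'   (`rel_diff` signed as RNp - RNm; `abs_rel_diff`).
#' @examples
#' rn_species_summary(load_rn_fixture("table3"))
#' @export
rn_species_summary <- function(traits) {
  validate_trait_table(traits)
  tibble::as_tibble(traits) |>
    dplyr::mutate(
      bv_mm3 = .data$bv_cm3 * 1000,
      rnp = .data$rnp_r + .data$rnp_l,
      rnm = .data$rnm_r + .data$rnm_l,
      rn_total = .data$rnp + .data$rnm,
      rel_rn = .data$rn_total / .data$bv_mm3 * 100,
      rel_rnp = .data$rnp / .data$bv_mm3 * 100,
      rel_rnm = .data$rnm / .data$bv_mm3 * 100,
      ratio_rnm_rnp = .data$rnm / .data$rnp,
      log10_ratio = log10(.data$ratio_rnm_rnp),
      rel_diff = (.data$rnp - .data$rnm) / .data$bv_mm3 * 100,
      abs_rel_diff = abs(.data$rel_diff)
    ) |>
    dplyr::select(dplyr::all_of(c(
      "species", "group", "n", "bv_mm3", "rnp", "rnm", "rn_total",
      "rel_rn", "rel_rnp", "rel_rnm", "ratio_rnm_rnp", "log10_ratio",
      "rel_diff", "abs_rel_diff"
    )))
}

#' Group-level volume summary
#'
#' Aggregates a per-species summary to the five primate groups. Relative
#' volumes are averaged across species within a group (mean and SEM of the
#' per-species percentages). Fold ratios between the subdivisions are, by
#' default, computed from the group-mean bilateral volumes (the convention
#' that matches the published between-group fold differences); the
#' alternative -- averaging per-species ratios -- is available via
#' `ratio_method`. The group-level relative difference uses group-mean
#' volumes under the default convention and the mean of per-species
#' differences otherwise.
#'
#' @param species_summary Output of [rn_species_summary()] (a raw trait
#'   table is also accepted and summarized first).
#' @param ratio_method `"group_mean"` (default) or `"species_mean"`.
#' @return A tibble with one row per group: species count, mean bilateral
#'   volumes, mean and SEM of relative volumes (percent), `ratio_rnm_rnp`,
#'   `fold_difference` (how many times the larger subdivision exceeds the
#'   smaller, `10^|log10 ratio|`), and `rel_diff` (percent of brain volume).
#' @export
rn_group_summary <- function(species_summary,
                             ratio_method = c("group_mean", "species_mean")) {
  ratio_method <- match.arg(ratio_method)
  if (!"rn_total" %in% names(species_summary)) {
    species_summary <- rn_species_summary(species_summary)
  }
  out <- species_summary |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      mean_bv_mm3 = mean(.data$bv_mm3),
      mean_rnp = mean(.data$rnp),
      mean_rnm = mean(.data$rnm),
      mean_rn_total = mean(.data$rn_total),
      sem_rn_total = sem(.data$rn_total),
      mean_rel_rn = mean(.data$rel_rn),
      sem_rel_rn = sem(.data$rel_rn),
      mean_rel_rnp = mean(.data$rel_rnp),
      sem_rel_rnp = sem(.data$rel_rnp),
      mean_rel_rnm = mean(.data$rel_rnm),
      sem_rel_rnm = sem(.data$rel_rnm),
      ratio_species_mean = mean(.data$ratio_rnm_rnp),
      rel_diff_species_mean = mean(.data$rel_diff),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio_rnm_rnp = if (ratio_method == "group_mean") {
        .data$mean_rnm / .data$mean_rnp
      } else {
        .data$ratio_species_mean
      },
      rel_diff = if (ratio_method == "group_mean") {
        (.data$mean_rnp - .data$mean_rnm) / .data$mean_bv_mm3 * 100
      } else {
        .data$rel_diff_species_mean
      },
      fold_difference = 10^abs(log10(.data$ratio_rnm_rnp))
    ) |>
    dplyr::select(-dplyr::all_of(c("ratio_species_mean",
                                   "rel_diff_species_mean")))
  out
}

#' Paired asymmetry test with a normality gate
#'
#' Tests whether paired left/right measurements differ, choosing the test
#' by a normality check on the paired differences: if normality is not
#' rejected at the 0.05 level a paired t-test is used, otherwise a Wilcoxon
#' signed-rank test. The normality gate is the Anderson-Darling test where
#' defined (n >= 8) and the Shapiro-Wilk test for shorter samples (3-7
#' pairs), since the Anderson-Darling statistic's null distribution is not
#' tabulated below n = 8.
#'
#' If every difference is exactly zero the signed-rank statistic is
#' undefined; the function then reports no asymmetry with p = 1 and warns.
#'
#' @param left,right Paired numeric vectors of equal length >= 3.
#' @return A one-row tibble: `test` (`"paired t"`, `"wilcoxon signed rank"`
#'   or `"none"`), `statistic`, `p_value`, `n`, and `normality_p` (gate
#'   p-value, `NA` for the degenerate all-ties case).
#' @examples
#' asymmetry_test(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.4))
#' @export
asymmetry_test <- function(left, right) {
  if (length(left) != length(right)) {
    stop_input("`left` and `right` must have equal length")
  }
  n <- length(left)
  if (n < 3) stop_input("need at least 3 pairs")
  d <- left - right
  if (all(d == 0)) {
    warn("all paired differences are zero; no asymmetry (p = 1 by convention)")
    return(tibble::tibble(test = "none", statistic = NA_real_,
                          p_value = 1, n = n, normality_p = NA_real_))
  }
  normality_p <- if (n >= 8) {
    nortest::ad.test(d)$p.value
  } else {
    shapiro.test(d)$p.value
  }
  if (normality_p >= 0.05) {
    tt <- t.test(left, right, paired = TRUE)
    tibble::tibble(test = "paired t", statistic = unname(tt$statistic),
                   p_value = tt$p.value, n = n, normality_p = normality_p)
  } else {
    wt <- suppressWarnings(wilcox.test(left, right, paired = TRUE))
    tibble::tibble(test = "wilcoxon signed rank",
                   statistic = unname(wt$statistic),
                   p_value = wt$p.value, n = n, normality_p = normality_p)
  }
}
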