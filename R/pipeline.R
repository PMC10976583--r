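#' Run the full comparative red-nucleus analysis
#'
#' Orchestrates the whole pipeline on a species trait table and a tree:
#' per-species and per-group volume summaries, within-group left/right
#' asymmetry tests, and -- for each requested response column, analyzed
#' independently (left and right sides separately, with no multiplicity
#' correction, which the report states) -- a pGLS allometry of log10
#' region volume on log10 brain volume with prediction intervals,
#' multi-regime OU shift detection on the allometric residuals with
#' parametric bootstrap support and signal-to-noise effect size, a
#' phylogenetic ANCOVA testing the grade structure implied by the shift
#' search, and ancestral state estimation (mvBM) of the residuals. A
#' k-means (k = 2) clustering of the ratio/difference morphospace
#' completes the bundle. Deterministic given `seed`.
#'
#' @param traits Trait table (default: the packaged species table).
#' @param tree Tree over the species (default: the surrogate chronogram).
#' @param responses Response columns to analyze; any of `"rnm_l"`,
#'   `"rnm_r"`, `"rnp_l"`, `"rnp_r"`, or the bilateral `"rnm"`, `"rnp"`.
#' @param residual_type Residuals fed to shift detection and ASE:
#'   `"log_relative"` (default; log10 of region/brain volume, i.e. the
#'   deviation from proportional scaling) or `"pgls"` (residuals of the
#'   fitted one-grade pGLS). The default is the relative-volume form
#'   because a one-grade pGLS fitted to data containing a clade-wide
#'   grade shift partially absorbs the shift into its slope estimate
#'   (the shifted clade holds the extreme predictor values), flattening
#'   the very residual signal the shift search needs; see the package
#'   vignette.
#' @param n_boot Bootstrap replicates per response (default 100; set to 0
#'   to skip the bootstrap).
#' @param max_shifts Maximum shifts searched per response (default 2).
#' @param support_threshold Percent bootstrap support above which a shift
#'   is reported as supported (default 65).
#' @param seed Integer seed driving every stochastic stage.
#' @return An `rn_analysis` list: `species_summary`, `group_summary`,
#'   `asymmetry`, `allometry` (per-response tibble of fits, shifts,
#'   support, effect sizes, ANCOVA results, ASE objects), `clusters`,
#'   and `meta` (inputs, seeds, package version).
#' @examples
#' \donttest{
#' res <- run_rn_analysis(n_boot = 0, responses = "rnm_l")
#' res$group_summary
#' }
#' @export
run_rn_analysis <- function(traits = load_rn_fixture("table3"),
                            tree = rn_chronogram(),
                            responses = c("rnm_l", "rnm_r",
                                          "rnp_l", "rnp_r"),
                            residual_type = c("log_relative", "pgls"),
                            n_boot = 100,
                            max_shifts = 2,
                            support_threshold = 65,
                            seed = 1) {
  residual_type <- match.arg(residual_type)
  validate_trait_table(traits)
  validate_phylo(tree, ultrametric = TRUE)
  if (!setequal(traits$species, tree$tip.label)) {
    stop_input("trait table species and tree tips must match")
  }
  species_summary <- rn_species_summary(traits)
  group_summary <- rn_group_summary(species_summary)

  # within-group left vs right comparisons across species (groups with
  # >= 3 species), for each subdivision and the total
  sides <- tibble::tribble(
    ~measure, ~left, ~right,
    "rnp", "rnp_l", "rnp_r",
    "rnm", "rnm_l", "rnm_r"
  )
  asymmetry <- traits |>
    dplyr::group_by(.data$group) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::group_modify(function(d, key) {
      purrr::pmap_dfr(sides, function(measure, left, right) {
        dplyr::bind_cols(measure = measure,
                         asymmetry_test(d[[left]], d[[right]]))
      })
    }) |>
    dplyr::ungroup()

  # per-response phylogenetic analyses, tip-ordered on the tree
  ord <- tree$tip.label
  tr_ord <- traits[match(ord, traits$species), ]
  C <- bm_covariance(tree)
  x <- log10(tr_ord$bv_cm3 * 1000)
  resp_col <- function(r) {
    switch(r,
      rnm = tr_ord$rnm_l + tr_ord$rnm_r,
      rnp = tr_ord$rnp_l + tr_ord$rnp_r,
      tr_ord[[r]]
    )
  }
  hominoid <- ifelse(tr_ord$group %in% c("humans", "non-human apes"),
                     "hominoid", "other")
  three_grade <- ifelse(tr_ord$group %in% c("humans", "non-human apes"),
                        tr_ord$group, "other")
  seeds <- with_seed(seed, sample.int(2^31 - 1, length(responses)))

  allometry <- purrr::map2(responses, seeds, function(r, s) {
    y <- setNames(log10(resp_col(r)), ord)
    fit <- pgls_fit(x, y, C)
    resid <- switch(residual_type,
      pgls = residuals(fit),
      log_relative = y - x
    )
    shifts <- detect_shifts(resid, tree, max_shifts = max_shifts)
    support <- if (n_boot > 0) {
      bootstrap_support(shifts, n_boot = n_boot, seed = s)
    } else {
      tibble::tibble(edge = integer(), clade = character(),
                     support = numeric(), in_fit = logical())
    }
    shift_tab <- tidy(shifts)
    if (nrow(shift_tab)) {
      shift_tab <- dplyr::left_join(shift_tab,
                                    support[c("edge", "support")],
                                    by = "edge") |>
        dplyr::mutate(supported = !is.na(.data$support) &
                        .data$support >= support_threshold)
    }
    snr <- if (nrow(shift_tab)) snr_effect_size(shifts) else NULL
    list(
      response = r,
      pgls = fit,
      intervals = prediction_intervals(fit),
      residuals = resid,
      shift_fit = shifts,
      shifts = shift_tab,
      support = support,
      effect_size = snr,
      ancova_hominoid = grade_test(x, y, C, hominoid, test = "intercept"),
      ancova_three_grade = grade_test(x, y, C, three_grade,
                                      test = "intercept"),
      ase = ase_mvbm(resid, tree)
    )
  })
  names(allometry) <- responses

  clusters <- kmeans2(rn_features(species_summary), seed = seed)

  structure(
    list(
      species_summary = species_summary,
      group_summary = group_summary,
      asymmetry = asymmetry,
      allometry = allometry,
      clusters = clusters,
      meta = list(
        n_species = nrow(traits), responses = responses,
        residual_type = residual_type, seed = seed, n_boot = n_boot,
        support_threshold = support_threshold,
        tree_depth = max(tip_depths(tree)),
        version = as.character(utils::packageVersion("rubrovol")),
        note = paste("responses analyzed independently;",
                     "no multiplicity correction applied")
      )
    ),
    class = "rn_analysis"
  )
}

#' @export
print.rn_analysis <- function(x, ...) {
  cat("Comparative red-nucleus analysis (", x$meta$n_species,
      " species, seed ", x$meta$seed, ")\n\n", sep = "")
  cat("Group summary (relative volumes, % of brain volume):\n")
  print(dplyr::select(x$group_summary, dplyr::all_of(c(
    "group", "n_species", "mean_rel_rn", "mean_rel_rnp", "mean_rel_rnm",
    "ratio_rnm_rnp", "fold_difference"
  ))))
  for (r in names(x$allometry)) {
    a <- x$allometry[[r]]
    cat("\nResponse ", r, ": slope ", sprintf("%.3f", a$pgls$slope),
        ", ", nrow(tidy(a$shift_fit)), " shift(s)", sep = "")
    if (nrow(a$shifts)) {
      cat(" on ", paste(a$shifts$clade, collapse = "; "), sep = "")
      if ("support" %in% names(a$shifts) && any(!is.na(a$shifts$support))) {
        cat(" [support ",
            paste0(format(a$shifts$support), "%", collapse = ", "), "]",
            sep = "")
      }
    }
    cat("\n")
  }
  cat("\n", x$meta$note, "\n", sep = "")
  cat("ASE nodal estimates are for visualizing trends only",
      "(high uncertainty).\n")
  invisible(x)
}
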