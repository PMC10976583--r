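#' Parse a Newick string into a phylogenetic tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is
#' an `ape` `phylo` object, the container used throughout the package.
#' Branch lengths are required; tip labels must be unique and non-empty.
#'
#' @param text A single Newick string (terminated by `;`).
#' @return A `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop_input("`text` must be a single non-empty Newick string")
  }
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_input("malformed Newick: unmatched ')' at character ", i,
                   class = "rubrovol_parse_error")
      }
    }
  }
  if (depth != 0L) {
    stop_input("malformed Newick: ", depth, " unclosed '(' at character ",
               length(chars), class = "rubrovol_parse_error")
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop_input("malformed Newick: missing terminating ';' at character ",
               length(chars), class = "rubrovol_parse_error")
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL
  )
  if (is.null(tree)) {
    stop_input("malformed Newick string (unparseable)",
               class = "rubrovol_parse_error")
  }
  validate_phylo(tree)
  tree
}

#' Write a tree as a Newick string
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths (default 10, so
#'   parse/write round-trips preserve lengths to 10 significant digits).
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  validate_phylo(tree)
  ape::write.tree(tree, digits = digits)
}

#' Validate a phylogenetic tree
#'
#' Checks the invariants the package relies on: a single root, non-negative
#' branch lengths, unique non-empty tip labels, and (optionally)
#' ultrametricity within a relative tolerance.
#'
#' @param tree A `phylo` object.
#' @param ultrametric If `TRUE`, additionally require all root-to-tip path
#'   lengths to agree within `rel_tol`.
#' @param rel_tol Relative tolerance for the ultrametricity check.
#' @return The tree, invisibly; errors on violation.
#' @export
validate_phylo <- function(tree, ultrametric = FALSE, rel_tol = 1e-8) {
  if (!inherits(tree, "phylo")) stop_input("`tree` must be a `phylo` object")
  if (is.null(tree$edge.length)) {
    stop_input("tree must carry branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    stop_input("branch lengths must be >= 0")
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop_input("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop_input("tip labels must be non-empty")
  # exactly one root: one node that never appears as a child
  parents <- unique(tree$edge[, 1])
  children <- tree$edge[, 2]
  roots <- setdiff(parents, children)
  if (length(roots) != 1L) stop_input("tree must have exactly one root")
  if (ultrametric) {
    d <- tip_depths(tree)
    if (diff(range(d)) > rel_tol * max(d)) {
      stop_input("tree is not ultrametric within relative tolerance ", rel_tol)
    }
  }
  invisible(tree)
}

#' Root-to-tip path lengths
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector of root-to-tip distances, one per tip.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Test ultrametricity within a relative tolerance
#'
#' @inheritParams validate_phylo
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, rel_tol = 1e-8) {
  d <- tip_depths(tree)
  diff(range(d)) <= rel_tol * max(d)
}

#' Brownian-motion covariance matrix of a tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j;
#' the diagonal holds root-to-tip depths. This is the error covariance
#' (up to the rate \eqn{\sigma^2}) assumed by pGLS under Brownian motion.
#' Polytomies are treated as hard: tips joined at a polytomy share the
#' path length to the polytomy node.
#'
#' @param tree A `phylo` object.
#' @param tip_order Optional character vector giving the tip order of the
#'   returned matrix; defaults to `tree$tip.label`. All entries must be
#'   tips of the tree.
#' @return A symmetric positive semi-definite matrix with dimnames set to
#'   the tip order.
#' @export
bm_covariance <- function(tree, tip_order = NULL) {
  validate_phylo(tree)
  C <- ape::vcv.phylo(tree)
  ord <- tip_order %||% tree$tip.label
  missing <- setdiff(ord, rownames(C))
  if (length(missing)) {
    stop_input("unknown tip label(s): ", paste(missing, collapse = ", "),
               class = "rubrovol_lookup_error")
  }
  C[ord, ord, drop = FALSE]
}

#' Sanitize species names into tip labels
#'
#' Tip labels use underscores in place of spaces (standard Newick
#' convention); this helper applies that rule.
#'
#' @param x Character vector of species names.
#' @return Character vector of tip labels.
#' @export
species_label <- function(x) gsub(" ", "_", trimws(x))

# ---- surrogate chronogram for the 20 study species ------------------------

#' The twenty study species and their primate groups
#'
#' Species names are spelled exactly as in the packaged trait table (so they
#' match both the fixture and the surrogate chronogram tips). Groups follow
#' the five-group scheme: humans, non-human apes, old world monkeys
#' (Cercopithecidae), new world monkeys (Platyrrhini), and prosimians.
#'
#' @return A tibble with columns `species` (tip label) and `group`.
#' @export
rn_species_groups <- function() {
  tibble::tibble(
    species = c(
      "Homo_sapiens",
      "Gorilla_gorilla", "Hylobates_lar", "Pan_paniscus", "Pan_troglodytes",
      "Pongo_pygmaeus",
      "Lophocebus_albigena", "Cercopithecus_Spec", "Macaca_fascicularis",
      "Macaca_mulatta",
      "Aotus_trivirgatus", "Callithrix_jacchus", "Saimiri_scuireus",
      "Daubentonia_madagescariensis", "Galago_senegalensis", "Indri_indri",
      "Lemur_catta", "Lepilemur_ruficaudatus", "Nycticebus_coucang",
      "Tarsius_bancanus"
    ),
    group = c(
      "humans",
      rep("non-human apes", 5),
      rep("old world monkeys", 4),
      rep("new world monkeys", 3),
      rep("prosimians", 7)
    )
  )
}

#' Divergence dates used by the surrogate chronogram
#'
#' Node ages in millions of years for the internal nodes of the surrogate
#' chronogram. Values are round consensus estimates from the primate
#' phylogenetics literature; they are deliberately configurable because
#' the analyses shipped here are designed to be invariant to (or robust
#' against) the exact chronogram, which differs between dated-tree sources.
#'
#' @return Named numeric vector of node ages (Ma).
#' @export
rn_node_ages <- function() {
  c(
    primates       = 74, # prosimian group vs simians
    prosimians     = 70, # tarsier vs strepsirrhines
    strepsirrhini  = 62, # lorisiforms vs lemuriforms
    lorisiformes   = 40, # Nycticebus vs Galago
    lemuriformes   = 55, # Daubentonia vs other lemurs
    lepilemuroidea = 38, # Lepilemur vs (Lemur, Indri)
    lemur_indri    = 30,
    simiiformes    = 43, # platyrrhines vs catarrhines
    platyrrhini    = 20, # Aotus vs cebids
    cebidae        = 16, # Saimiri vs Callithrix
    catarrhini     = 31, # cercopithecids vs hominoids
    cercopithecidae = 14, # Cercopithecus vs papionins
    papionini      = 10, # Lophocebus vs macaques
    macaca         = 5,
    hominoidea     = 20, # gibbons vs great apes
    hominidae      = 16, # Pongo vs African apes + humans
    homininae      = 9,  # Gorilla vs (Homo, Pan)
    hominini       = 7,  # Homo vs Pan
    pan            = 3   # P. troglodytes vs P. paniscus
  )
}

# Nested topology of the surrogate chronogram. Internal nodes refer to
# entries of the age table by name; leaves are tip labels.
rn_topology <- function() {
  node <- function(name, ...) list(node = name, children = list(...))
  node("primates",
    node("prosimians",
      "Tarsius_bancanus",
      node("strepsirrhini",
        node("lorisiformes", "Nycticebus_coucang", "Galago_senegalensis"),
        node("lemuriformes",
          "Daubentonia_madagescariensis",
          node("lepilemuroidea",
            "Lepilemur_ruficaudatus",
            node("lemur_indri", "Lemur_catta", "Indri_indri"))))),
    node("simiiformes",
      node("platyrrhini",
        "Aotus_trivirgatus",
        node("cebidae", "Saimiri_scuireus", "Callithrix_jacchus")),
      node("catarrhini",
        node("cercopithecidae",
          "Cercopithecus_Spec",
          node("papionini",
            "Lophocebus_albigena",
            node("macaca", "Macaca_mulatta", "Macaca_fascicularis"))),
        node("hominoidea",
          "Hylobates_lar",
          node("hominidae",
            "Pongo_pygmaeus",
            node("homininae",
              "Gorilla_gorilla",
              node("hominini",
                "Homo_sapiens",
                node("pan", "Pan_troglodytes", "Pan_paniscus"))))))))
}

#' Surrogate chronogram for the study species
#'
#' Builds an ultrametric tree over (a subset of) the twenty study species
#' from a fixed topology -- prosimians sister to all simians, platyrrhines
#' sister to catarrhines, cercopithecids sister to hominoids, humans nested
#' within the hominoids -- with node ages taken from a configurable
#' divergence-date table ([rn_node_ages()]). It stands in for externally
#' dated chronograms (which are not redistributable) and can be replaced by
#' any user-supplied Newick tree throughout the package.
#'
#' @param species Character vector of tip labels to keep (default: all 20
#'   study species). Must be a subset of `rn_species_groups()$species`.
#' @param ages Named numeric vector of node ages (Ma); see [rn_node_ages()].
#'   Every internal node must be younger than its parent.
#' @param depth Optional total root-to-tip depth to rescale the pruned tree
#'   to (the analyses are invariant to this global rescaling).
#' @return An ultrametric `phylo` object.
#' @examples
#' tr <- rn_chronogram()
#' length(tr$tip.label)
#' @export
rn_chronogram <- function(species = NULL, ages = rn_node_ages(),
                          depth = NULL) {
  all_species <- rn_species_groups()$species
  species <- species %||% all_species
  species <- species_label(species)
  unknown <- setdiff(species, all_species)
  if (length(unknown)) {
    stop_input("species not covered by the surrogate topology: ",
               paste(unknown, collapse = ", "),
               class = "rubrovol_config_error")
  }
  if (length(species) < 2) stop_input("need at least 2 species")

  build <- function(x, parent_age) {
    if (is.character(x)) {
      return(sprintf("%s:%.10g", x, parent_age))
    }
    age <- ages[[x$node]]
    if (is.null(age) || is.na(age)) {
      stop_input("no age for node '", x$node, "' in `ages`",
                 class = "rubrovol_config_error")
    }
    if (!is.na(parent_age) && age >= parent_age) {
      stop_input("node '", x$node, "' (age ", age,
                 ") must be younger than its parent (age ", parent_age, ")",
                 class = "rubrovol_config_error")
    }
    inner <- paste(vapply(x$children, build, "", parent_age = age),
                   collapse = ",")
    if (is.na(parent_age)) {
      sprintf("(%s);", inner)
    } else {
      sprintf("(%s):%.10g", inner, parent_age - age)
    }
  }
  tree <- read_newick(build(rn_topology(), NA_real_))
  if (length(species) < length(all_species)) {
    tree <- ape::keep.tip(tree, species)
  }
  if (!is.null(depth)) {
    check_number(depth, "depth", positive = TRUE)
    tree$edge.length <- tree$edge.length * (depth / max(tip_depths(tree)))
  }
  validate_phylo(tree, ultrametric = TRUE)
  tree
}
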