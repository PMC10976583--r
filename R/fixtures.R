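#' Load a packaged data fixture
#'
#' Two plain-text fixtures ship with the package:
#' \describe{
#'   \item{`"table3"`}{The species trait table: fresh brain volume (cm^3)
#'     and right/left RNp and RNm volumes (mm^3) for the twenty study
#'     species, with group labels and specimen counts. Species names are
#'     returned as underscore tip labels matching [rn_chronogram()]. A
#'     `source_row` column records the published table row each entry was
#'     transcribed from; volumes are stored exactly as printed (one
#'     decimal).}
#'   \item{`"table1"`}{The human specimen table: eleven post-mortem
#'     brains with section plane, sex, age and fresh brain weight (g).
#'     `mapped` marks the ten brains used for the probabilistic maps (the
#'     eleventh is the high-resolution single-brain reference).}
#' }
#'
#' @param name `"table3"` or `"table1"`.
#' @return A tibble.
#' @examples
#' load_rn_fixture("table3")
#' @export
load_rn_fixture <- function(name = c("table3", "table1")) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop_input("unknown fixture '", paste(name, collapse = ","),
               "'; available: table3, table1",
               class = "rubrovol_lookup_error")
  })
  file <- switch(name,
    table3 = "rn_species_volumes_table3.tsv",
    table1 = "human_specimens_table1.tsv"
  )
  path <- system.file("extdata", file, package = "rubrovol",
                      mustWork = TRUE)
  out <- tibble::as_tibble(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  )
  if (name == "table3") {
    out$species <- species_label(out$species)
    out$n <- as.integer(out$n)
    validate_trait_table(out)
  }
  out
}
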