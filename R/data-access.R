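#' Published per-taxon cluster counts bundled with the package
#'
#' Loads the bundled table of core/pan/singleton cluster counts for eight
#' bacterial taxon samples (two species, three genera, one family, one
#' order, one phylum; 60 genomes per sample, 26 for *L. monocytogenes*)
#' from a published comparative study of domain-architecture-based
#' clustering (with Pfam and with InterPro signatures) against
#' sequence-similarity-based clustering. Used as worked-example input for
#' [counts_to_summary()] and [singleton_ratio()]; the underlying genome
#' set is not redistributed.
#'
#' @return A tibble with columns `level`, `taxon`, `n_genomes`, `method`
#'   (`DAB_Pfam`, `DAB_InterPro`, `SB`), `core`, `pan`, `singletons`.
#' @export
#' @examples
#' counts <- taxon_cluster_counts()
#' hp <- dplyr::filter(counts, taxon == "H_pylori", method == "DAB_Pfam")
#' counts_to_summary(hp$core, hp$pan, hp$singletons)
taxon_cluster_counts <- function() {
  path <- system.file("extdata", "taxon_cluster_counts.tsv",
    package = "domarch", mustWork = TRUE
  )
  readr::read_tsv(
    path,
    col_types = readr::cols(
      level = readr::col_character(),
      taxon = readr::col_character(),
      n_genomes = readr::col_integer(),
      method = readr::col_character(),
      core = readr::col_integer(),
      pan = readr::col_integer(),
      singletons = readr::col_integer()
    ),
    progress = FALSE
  )
}
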