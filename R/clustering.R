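#' Cluster proteins by identical domain architecture
#'
#' Architecture-based (DAB) clustering groups proteins whose canonical
#' labels are identical. The cluster id *is* the label, so cluster sets
#' computed independently on different genome collections can be merged by
#' name. The result is a partition of all labeled proteins with one
#' cluster per distinct label.
#'
#' @param labels A label table from [assign_labels()] (columns
#'   `protein_id`, `architecture`; `genome_id` is ignored here).
#' @return A cluster table (`cluster_id`, `protein_id`) ordered by label
#'   then protein id.
#' @export
#' @examples
#' labels <- tibble::tibble(
#'   genome_id = "g1", protein_id = c("p1", "p2", "p3"),
#'   architecture = c("A", "A", "A;B")
#' )
#' dab_clusters(labels)
dab_clusters <- function(labels) {
  check_columns(labels, c("protein_id", "architecture"), "`labels`")
  if (anyDuplicated(labels$protein_id) > 0) {
    abort("`labels` assigns more than one architecture to the same protein id")
  }
  labels |>
    dplyr::transmute(cluster_id = .data$architecture, protein_id = .data$protein_id) |>
    dplyr::arrange(.data$cluster_id, .data$protein_id)
}

#' Genome-by-architecture abundance matrix
#'
#' Counts, for every genome, the number of proteins carrying each
#' architecture. The wide layout (one row per genome, one column per
#' architecture, lexicographic column order) is the package's working
#' matrix for persistence, Heaps and ordination computations; the
#' binarized presence/absence view is derived with [binarize()].
#'
#' @param labels A label table from [assign_labels()].
#' @param genomes Optional character vector fixing the genome set and row
#'   order. Genomes with no labeled protein are kept as all-zero rows with
#'   a warning; by default the genomes observed in `labels`, sorted.
#' @return A tibble with column `genome_id` followed by one integer count
#'   column per architecture.
#' @export
abundance_matrix <- function(labels, genomes = NULL) {
  check_columns(labels, c("genome_id", "protein_id", "architecture"), "`labels`")
  genomes <- genomes %||% sort(unique(labels$genome_id))
  labs <- sort(unique(labels$architecture))
  counts <- labels |>
    dplyr::filter(.data$genome_id %in% genomes) |>
    dplyr::count(.data$genome_id, .data$architecture) |>
    tidyr::pivot_wider(
      names_from = "architecture", values_from = "n", values_fill = 0L
    )
  out <- tibble::tibble(genome_id = genomes) |>
    dplyr::left_join(counts, by = "genome_id")
  out[is.na(out)] <- 0L
  missing_cols <- setdiff(labs, names(out))
  for (m in missing_cols) out[[m]] <- 0L
  out <- out[, c("genome_id", labs)]
  zero_rows <- rowSums(out[, -1, drop = FALSE]) == 0
  if (any(zero_rows) && length(labs) > 0) {
    warn(sprintf(
      "genome(s) with no labeled proteins kept as all-zero rows: %s",
      paste(out$genome_id[zero_rows], collapse = ", ")
    ))
  }
  out
}

#' Presence/absence view of an abundance matrix
#'
#' @param abundance A wide abundance table from [abundance_matrix()].
#' @return The same layout with counts replaced by 0/1 presence.
#' @export
binarize <- function(abundance) {
  check_columns(abundance, "genome_id", "`abundance`")
  vals <- abundance[, setdiff(names(abundance), "genome_id"), drop = FALSE]
  out <- tibble::as_tibble(lapply(vals, function(x) as.integer(x >= 1)))
  dplyr::bind_cols(abundance["genome_id"], out)
}

# Numeric matrix (genomes x architectures) from the wide tibble layout.
pa_matrix <- function(abundance) {
  m <- as.matrix(abundance[, setdiff(names(abundance), "genome_id"), drop = FALSE])
  rownames(m) <- abundance$genome_id
  storage.mode(m) <- "numeric"
  m
}

#' Write / read an abundance matrix as TSV
#'
#' Plain tab-separated output: header row of architecture labels with a
#' leading `genome_id` column. Round-trips through [read_abundance_matrix()].
#'
#' @param abundance A wide abundance table.
#' @param path File path.
#' @return `path` (write) or the abundance tibble (read).
#' @export
write_abundance_matrix <- function(abundance, path) {
  readr::write_tsv(abundance, path)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      genome_id = readr::col_character(), .default = readr::col_integer()
    ),
    progress = FALSE
  )
}
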