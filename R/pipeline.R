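#' Run the full architecture-based pan-genome pipeline
#'
#' Ties the package's stages together: parse per-genome annotation files,
#' assign architecture labels, build clusters and the abundance matrix,
#' compute pan-genome statistics and the Heaps openness fit, and — when an
#' external sequence-similarity clustering is supplied — restrict it to
#' the annotated universe and classify mismatches. All outputs are plain
#' tab-separated files carrying a provenance header (`#` comment lines
#' with the package version, seed and parameters); a rerun with the same
#' configuration is bit-identical.
#'
#' @param config A list, or path to a YAML file, with entries:
#'   * `annotations`: named list or data frame mapping `genome_id` to
#'     annotation file `path` (required);
#'   * `allowed_dbs`: databases to keep (default `"Pfam"`);
#'   * `out_dir`: output directory (required);
#'   * `heaps`: list with `n_permutations` (default 5000), `seed`
#'     (default 1) and optional `exclude` genome ids;
#'   * `sb_clusters`: optional path to an external clustering in the
#'     one-cluster-per-line dialect;
#'   * `pca`: list with `n_components` (default 2).
#' @return Invisibly, a list with the in-memory results: `labels`,
#'   `clusters`, `abundance`, `summary`, `persistence`, `heaps`, `pca`
#'   and (if configured) `comparison`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  manifest <- normalize_manifest(config$annotations)
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing) > 0) {
    abort(sprintf(
      "annotation file(s) missing: %s", paste(missing, collapse = ", ")
    ))
  }
  if (is.null(config$out_dir)) {
    abort("config entry `out_dir` is required")
  }
  if (!is.null(config$sb_clusters) && !file.exists(config$sb_clusters)) {
    abort(sprintf("sb_clusters file missing: %s", config$sb_clusters))
  }
  allowed_dbs <- config$allowed_dbs %||% "Pfam"
  heaps_cfg <- config$heaps %||% list()
  n_perm <- heaps_cfg$n_permutations %||% 5000
  seed <- heaps_cfg$seed %||% 1
  n_components <- (config$pca %||% list())$n_components %||% 2

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- c(
    sprintf("# domarch %s", as.character(utils::packageVersion("domarch"))),
    sprintf("# allowed_dbs: %s", paste(allowed_dbs, collapse = ",")),
    sprintf("# heaps: n_permutations=%d seed=%d", as.integer(n_perm), as.integer(seed))
  )
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    writeLines(header, path)
    suppressMessages(readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
    path
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  hits <- stage("parse", read_annotations(manifest, allowed_dbs = allowed_dbs))
  labels <- stage("label", assign_labels(hits))
  clusters <- stage("cluster", dab_clusters(labels))
  abundance <- stage(
    "matrix",
    abundance_matrix(labels, genomes = sort(manifest$genome_id))
  )
  genome_map <- dplyr::distinct(labels, .data$protein_id, .data$genome_id)
  persistence <- stage(
    "stats",
    cluster_persistence(clusters, genome_map, n_genomes = nrow(manifest))
  )
  summary <- stage(
    "stats",
    pangenome_summary(clusters, genome_map, n_genomes = nrow(manifest))
  )
  presence <- binarize(abundance)
  heaps <- stage("heaps", {
    if (length(heaps_cfg$exclude %||% character()) > 0) {
      heaps_fit_excluding(presence, heaps_cfg$exclude,
        n_permutations = n_perm, seed = seed
      )
    } else {
      heaps_fit(presence, n_permutations = n_perm, seed = seed)
    }
  })
  pca <- stage("pca", presence_pca(presence, n_components = n_components))

  emit(labels, "labels.tsv")
  write_clusters(clusters, file.path(config$out_dir, "clusters.txt"))
  emit(abundance, "matrix.tsv")
  emit(persistence, "persistence.tsv")
  emit(summary, "summary.tsv")
  emit(glance(heaps), "heaps.tsv")
  emit(tidy(pca), "pca.tsv")

  out <- list(
    labels = labels, clusters = clusters, abundance = abundance,
    summary = summary, persistence = persistence, heaps = heaps, pca = pca
  )

  if (!is.null(config$sb_clusters)) {
    comparison <- stage("compare", {
      sb <- read_clusters(config$sb_clusters, label = "SB")
      sb <- restrict_to_annotated(sb, labels$protein_id)
      dab <- restrict_to_annotated(clusters, sb$protein_id)
      classify_mismatches(dab, sb)
    })
    emit(tidy(comparison), "comparison.tsv")
    out$comparison <- comparison
  }

  invisible(out)
}

normalize_manifest <- function(annotations) {
  if (is.null(annotations)) {
    abort("config entry `annotations` is required")
  }
  if (is.data.frame(annotations)) {
    check_columns(annotations, c("genome_id", "path"), "`annotations`")
    return(tibble::as_tibble(annotations[, c("genome_id", "path")]))
  }
  tibble::tibble(
    genome_id = names(annotations),
    path = unname(unlist(annotations))
  )
}
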