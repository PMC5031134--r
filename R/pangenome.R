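#' Per-cluster persistence
#'
#' Persistence of a cluster is the number of genomes containing at least
#' one of its members divided by the total number of genomes considered.
#' It lies in (0, 1]; persistence 1 means the cluster is part of the core
#' genome. Persistence counts genomes, not proteins: a cluster of many
#' paralogs confined to one genome of sixty has persistence 1/60.
#'
#' @param clusters A cluster table (`cluster_id`, `protein_id`).
#' @param genome_map A data frame mapping `protein_id` to `genome_id`.
#'   Every clustered protein must be mapped; unmapped proteins are an
#'   error, not a silent drop.
#' @param n_genomes Total genomes considered. Defaults to the number of
#'   distinct genomes in `genome_map`, which should cover the whole sample
#'   even if some genome contributes no clustered protein.
#' @return A tibble with one row per cluster: `cluster_id`, `n_proteins`,
#'   `n_genomes_present`, `persistence`.
#' @export
cluster_persistence <- function(clusters, genome_map, n_genomes = NULL) {
  validate_clusters(clusters)
  validate_genome_map(genome_map)
  n_genomes <- n_genomes %||% dplyr::n_distinct(genome_map$genome_id)
  if (n_genomes < 1) {
    abort("`n_genomes` must be at least 1")
  }
  joined <- dplyr::left_join(clusters, genome_map, by = "protein_id")
  if (anyNA(joined$genome_id)) {
    missing <- unique(joined$protein_id[is.na(joined$genome_id)])
    abort(sprintf(
      "protein(s) without a genome mapping: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  joined |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_genomes_present = dplyr::n_distinct(.data$genome_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(persistence = .data$n_genomes_present / n_genomes)
}

#' Histogram of cluster persistence
#'
#' Bins persistence values into equal-width bins on (0, 1] (default 20).
#' On bacterial samples the distribution is typically bimodal: a peak
#' near 1/n from rare, possibly horizontally acquired clusters and a peak
#' at 1 from the vertically inherited core.
#'
#' @param persistence A tibble from [cluster_persistence()], or a numeric
#'   vector of persistence values.
#' @param bins Number of equal bins on (0, 1].
#' @return A tibble with `bin` (index), `lower`, `upper` (bin interval,
#'   lower-open) and `count`; counts sum to the number of clusters.
#' @export
persistence_histogram <- function(persistence, bins = 20) {
  p <- if (is.data.frame(persistence)) persistence$persistence else persistence
  if (any(p <= 0 | p > 1)) {
    abort("persistence values must lie in (0, 1]")
  }
  idx <- pmin(ceiling(p * bins), bins)
  tibble::tibble(
    bin = seq_len(bins),
    lower = (seq_len(bins) - 1) / bins,
    upper = seq_len(bins) / bins,
    count = as.integer(tabulate(idx, nbins = bins))
  )
}

#' Pan-genome summary statistics
#'
#' Computes the classical pan-genome descriptors of a clustering: pan size
#' (total clusters), core size (clusters with persistence exactly 1),
#' singleton count (clusters containing exactly one protein), and the
#' core/pan and core/singleton ratios. Ratios are plain quotients; use
#' [round_half_up()] for table-style printing at 2 decimals. When there
#' are no singletons the core/singleton ratio is `NA`, never infinity.
#'
#' @inheritParams cluster_persistence
#' @return A one-row tibble: `n_genomes`, `pan`, `core`, `singletons`,
#'   `core_pan`, `core_singletons`.
#' @export
#' @examples
#' clusters <- tibble::tibble(
#'   cluster_id = c("a", "a", "b", "c"),
#'   protein_id = c("p1", "p2", "p3", "p4")
#' )
#' genome_map <- tibble::tibble(
#'   protein_id = c("p1", "p2", "p3", "p4"),
#'   genome_id = c("g1", "g2", "g1", "g2")
#' )
#' pangenome_summary(clusters, genome_map)
pangenome_summary <- function(clusters, genome_map, n_genomes = NULL) {
  per <- cluster_persistence(clusters, genome_map, n_genomes = n_genomes)
  n_genomes <- n_genomes %||% dplyr::n_distinct(genome_map$genome_id)
  counts_to_summary(
    n_genomes = n_genomes,
    pan = nrow(per),
    core = sum(per$persistence == 1),
    singletons = sum(per$n_proteins == 1)
  )
}

#' Summary from published pan/core/singleton counts
#'
#' Builds the same summary row as [pangenome_summary()] directly from
#' already-tabulated counts, e.g. when re-deriving the ratios printed in a
#' published comparison table.
#'
#' @param core,pan,singletons Cluster counts (vectors recycle).
#' @param n_genomes Optional genome count, `NA` when unknown.
#' @return A tibble with the same columns as [pangenome_summary()].
#' @export
counts_to_summary <- function(core, pan, singletons, n_genomes = NA_integer_) {
  tibble::tibble(
    n_genomes = n_genomes,
    pan = pan,
    core = core,
    singletons = singletons,
    core_pan = ifelse(pan > 0, core / pan, NA_real_),
    core_singletons = ifelse(singletons > 0, core / singletons, NA_real_)
  )
}

#' Ratio of singleton counts between two clusterings
#'
#' The singleton-count ratio between an architecture-based and a
#' sequence-similarity-based clustering of the same genomes measures how
#' many similarity singletons collapse into shared-function clusters.
#'
#' @param summary_a,summary_b Summary rows from [pangenome_summary()] /
#'   [counts_to_summary()], or bare singleton counts.
#' @return `singletons_a / singletons_b`, `NA` when the denominator is 0.
#' @export
singleton_ratio <- function(summary_a, summary_b) {
  a <- if (is.data.frame(summary_a)) summary_a$singletons else summary_a
  b <- if (is.data.frame(summary_b)) summary_b$singletons else summary_b
  ifelse(b > 0, a / b, NA_real_)
}

#' Principal component analysis of architecture presence/absence
#'
#' Ordination of genomes by which architectures they carry. Columns are
#' mean-centered but not variance-scaled (standard for binary
#' presence/absence data); scores are deterministic up to component sign.
#'
#' @param presence A binarized abundance table from [binarize()].
#' @param n_components Number of components to retain.
#' @return An object of class `presence_pca` with elements `scores` (a
#'   tibble: `genome_id`, `PC1`, ...) and `explained` (fraction of
#'   variance per retained component). Identical genomes give all-zero
#'   scores and a warning.
#' @export
presence_pca <- function(presence, n_components = 2) {
  m <- pa_matrix(presence)
  if (nrow(m) < 2) {
    abort("PCA needs at least 2 genomes")
  }
  n_components <- min(n_components, nrow(m) - 1, ncol(m))
  centered <- scale(m, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2) / (nrow(m) - 1)
  if (total_var == 0) {
    warn("all genomes carry identical architecture sets; PCA scores are zero")
    scores <- matrix(0, nrow(m), n_components,
      dimnames = list(NULL, paste0("PC", seq_len(n_components)))
    )
    out <- list(
      scores = dplyr::bind_cols(
        tibble::tibble(genome_id = rownames(m)), tibble::as_tibble(scores)
      ),
      explained = rep(0, n_components)
    )
    return(structure(out, class = "presence_pca"))
  }
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  scores <- fit$x[, seq_len(k), drop = FALSE]
  out <- list(
    scores = dplyr::bind_cols(
      tibble::tibble(genome_id = rownames(m)),
      tibble::as_tibble(scores)
    ),
    explained = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)]
  )
  structure(out, class = "presence_pca")
}

#' @export
print.presence_pca <- function(x, ...) {
  cat(sprintf(
    "Presence/absence PCA: %d genomes, %d components (%s%% variance)\n",
    nrow(x$scores), length(x$explained),
    paste(round(100 * x$explained, 1), collapse = "%, ")
  ))
  print(x$scores, n = 10)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.presence_pca <- function(x, ...) {
  x$scores
}

#' @exportS3Method generics::glance
glance.presence_pca <- function(x, ...) {
  tibble::tibble(
    n_genomes = nrow(x$scores),
    n_components = length(x$explained),
    explained_total = sum(x$explained)
  )
}

#' Flag genomes with divergent architecture content
#'
#' Advisory screen for non-uniform sampling before Heaps regression: a
#' genome whose centered presence/absence profile lies much farther from
#' the sample centroid than is typical is flagged. The distance used is
#' the full-rank Euclidean distance from the column-mean profile, i.e. the
#' genome's total PCA score distance from the centroid; a genome is
#' flagged when its distance exceeds `multiple` times the median distance.
#' Exclusion remains a user decision.
#'
#' @param presence A binarized abundance table.
#' @param multiple Threshold multiple of the median distance (default 4);
#'   `Inf` disables flagging.
#' @return Character vector of flagged genome ids (possibly empty).
#' @export
flag_outliers <- function(presence, multiple = 4) {
  m <- pa_matrix(presence)
  if (nrow(m) < 3) {
    abort("outlier flagging needs at least 3 genomes")
  }
  if (!is.finite(multiple)) {
    return(character())
  }
  centered <- scale(m, center = TRUE, scale = FALSE)
  d <- sqrt(rowSums(centered^2))
  med <- median(d)
  rownames(m)[d > multiple * med]
}
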