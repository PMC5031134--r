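# Membership signature: a canonical string per cluster identifying its
# protein set, used for exact set-equality tests between partitions.
cluster_signatures <- function(clusters) {
  clusters |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      signature = paste(sort(.data$protein_id), collapse = "\r"),
      .groups = "drop"
    )
}

check_shared_universe <- function(a, b, names = c("first", "second")) {
  ua <- a$protein_id
  ub <- b$protein_id
  only_a <- setdiff(ua, ub)
  only_b <- setdiff(ub, ua)
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort(sprintf(
      paste0(
        "cluster sets do not share a universe (restrict both to the same ",
        "annotated proteins first); only in %s: %s; only in %s: %s"
      ),
      names[1], paste(head(only_a, 5), collapse = ", ") %||% "",
      names[2], paste(head(only_b, 5), collapse = ", ") %||% ""
    ))
  }
  invisible(TRUE)
}

#' Number of counterpart clusters per reference cluster
#'
#' For each cluster of `reference`, counts the number of distinct clusters
#' of `other` its members fall into. Both clusterings must partition the
#' same protein universe; silent intersection is refused because the two
#' methods must be restricted to the same domain-bearing proteins before
#' they are comparable.
#'
#' @param reference,other Cluster tables (`cluster_id`, `protein_id`)
#'   over the same universe.
#' @return A tibble `cluster_id`, `n_counterparts` (always >= 1), one row
#'   per reference cluster.
#' @export
counterpart_counts <- function(reference, other) {
  validate_clusters(reference, "`reference`")
  validate_clusters(other, "`other`")
  check_shared_universe(reference, other, c("reference", "other"))
  dplyr::inner_join(
    reference,
    dplyr::rename(other, other_id = "cluster_id"),
    by = "protein_id"
  ) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      n_counterparts = dplyr::n_distinct(.data$other_id), .groups = "drop"
    )
}

#' Number of identical clusters between two partitions
#'
#' Counts protein sets that appear as a cluster in both partitions
#' (complete agreement, the one-to-one case). Symmetric in its arguments.
#'
#' @param a,b Cluster tables over the same universe.
#' @return Integer count.
#' @export
identical_cluster_count <- function(a, b) {
  validate_clusters(a, "`a`")
  validate_clusters(b, "`b`")
  check_shared_universe(a, b, c("a", "b"))
  length(intersect(cluster_signatures(a)$signature, cluster_signatures(b)$signature))
}

#' Classify mismatches between architecture-based and similarity-based clusters
#'
#' Compares two partitions of the same proteins with the directional
#' mismatch taxonomy used for architecture (D) versus sequence-similarity
#' (S) cluster comparison. In each direction, every reference cluster is
#' characterized by N, the number of counterpart clusters its members are
#' assigned to. Clusters with an exactly matching counterpart are the
#' one-to-one cases, counted once and reported with both directions.
#' Non-identical clusters with N = 1 are strict subsets of a counterpart
#' (an insertion or domain expansion splitting an S cluster, or
#' same-architecture proteins too diverged to co-cluster by similarity);
#' N >= 2 clusters spread over several counterparts. Histograms use bins
#' {1, ..., 5, 6+} over the non-identical clusters; raw N values are kept
#' for re-binning, including renderings that count one-to-one clusters
#' inside the N = 1 bin.
#'
#' @param dab Architecture-based cluster table.
#' @param sb Sequence-similarity cluster table over the same universe.
#' @return An object of class `cluster_comparison`: `one_to_one` (count of
#'   identical clusters), `profiles` (tibble `direction`, `bin`, `count`
#'   over non-identical clusters with `direction` in `"D->S"`, `"S->D"`
#'   and `bin` in `"1"`...`"5"`, `"6+"`), `subsets` (the N = 1 strict
#'   subset counts per direction) and `counterparts` (per-cluster raw N
#'   and identical flag). Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
classify_mismatches <- function(dab, sb) {
  validate_clusters(dab, "`dab`")
  validate_clusters(sb, "`sb`")
  check_shared_universe(dab, sb, c("dab", "sb"))

  sig_d <- cluster_signatures(dab)
  sig_s <- cluster_signatures(sb)
  shared <- intersect(sig_d$signature, sig_s$signature)

  per_direction <- function(reference, other, ref_sigs, direction) {
    counterpart_counts(reference, other) |>
      dplyr::left_join(ref_sigs, by = "cluster_id") |>
      dplyr::mutate(
        direction = direction,
        identical = .data$signature %in% shared
      ) |>
      dplyr::select("direction", "cluster_id", n = "n_counterparts", "identical")
  }
  counterparts <- dplyr::bind_rows(
    per_direction(dab, sb, sig_d, "D->S"),
    per_direction(sb, dab, sig_s, "S->D")
  )

  bins <- c(as.character(1:5), "6+")
  profiles <- counterparts |>
    dplyr::filter(!.data$identical) |>
    dplyr::mutate(bin = dplyr::if_else(.data$n >= 6, "6+", as.character(.data$n))) |>
    dplyr::count(.data$direction, .data$bin, name = "count") |>
    tidyr::complete(
      direction = c("D->S", "S->D"),
      bin = bins,
      fill = list(count = 0L)
    ) |>
    dplyr::mutate(bin = factor(.data$bin, levels = bins)) |>
    dplyr::arrange(.data$direction, .data$bin)

  subsets <- profiles |>
    dplyr::filter(.data$bin == "1") |>
    dplyr::transmute(.data$direction, n_subset = .data$count)

  structure(
    list(
      one_to_one = length(shared),
      profiles = profiles,
      subsets = subsets,
      counterparts = counterparts
    ),
    class = "cluster_comparison"
  )
}

#' @export
print.cluster_comparison <- function(x, ...) {
  n_d <- sum(x$counterparts$direction == "D->S")
  n_s <- sum(x$counterparts$direction == "S->D")
  cat(sprintf(
    "Cluster comparison: %d D clusters vs %d S clusters, %d one-to-one\n",
    n_d, n_s, x$one_to_one
  ))
  wide <- tidyr::pivot_wider(
    x$profiles,
    names_from = "bin", values_from = "count"
  )
  print(wide)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      direction = c("D->S", "S->D"),
      bin = "one-to-one",
      count = x$one_to_one
    ),
    dplyr::mutate(x$profiles, bin = as.character(.data$bin))
  )
}

#' @exportS3Method generics::glance
glance.cluster_comparison <- function(x, ...) {
  tibble::tibble(
    n_dab = sum(x$counterparts$direction == "D->S"),
    n_sb = sum(x$counterparts$direction == "S->D"),
    one_to_one = x$one_to_one,
    subset_d_in_s = x$subsets$n_subset[x$subsets$direction == "D->S"],
    subset_s_in_d = x$subsets$n_subset[x$subsets$direction == "S->D"]
  )
}

#' Domain-count composition of one-to-one clusters
#'
#' For the clusters on which both methods agree exactly, tabulates the
#' number of domains in the shared architecture label. On real bacterial
#' data, single-domain architectures dominate this table. Every protein
#' of an identical cluster carries the same label by architecture-cluster
#' construction; a cluster violating that is an error.
#'
#' @param dab,sb Cluster tables over the same universe.
#' @param labels A label table (`protein_id`, `architecture`).
#' @return A tibble `n_domains`, `count` over one-to-one clusters (zero
#'   rows when there are none).
#' @export
one_to_one_composition <- function(dab, sb, labels) {
  check_columns(labels, c("protein_id", "architecture"), "`labels`")
  check_shared_universe(dab, sb, c("dab", "sb"))
  sig_s <- cluster_signatures(sb)$signature
  shared <- cluster_signatures(dab) |>
    dplyr::filter(.data$signature %in% sig_s)
  if (nrow(shared) == 0) {
    return(tibble::tibble(n_domains = integer(), count = integer()))
  }
  members <- dab |>
    dplyr::filter(.data$cluster_id %in% shared$cluster_id) |>
    dplyr::left_join(labels[, c("protein_id", "architecture")], by = "protein_id")
  arch <- members |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      n_arch = dplyr::n_distinct(.data$architecture),
      architecture = .data$architecture[1],
      .groups = "drop"
    )
  if (any(arch$n_arch != 1)) {
    abort("one-to-one cluster members carry differing architecture labels")
  }
  arch |>
    dplyr::mutate(n_domains = domain_count(.data$architecture)) |>
    dplyr::count(.data$n_domains, name = "count")
}
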