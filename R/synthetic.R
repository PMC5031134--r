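#' Configuration for the synthetic pan-genome generator
#'
#' Describes a pan-genome model from which genomes of architecture labels
#' are drawn: a core set present in every genome, accessory strata whose
#' architectures occur in each genome independently with a stratum
#' probability, and private singleton architectures arriving per genome at
#' a Poisson rate. Defaults describe a 60-genome bacterial species-level
#' sample: ~700 core architectures, two accessory strata (a common one at
#' occurrence probability 0.5 and a rarer one at 0.15) and ~2.4 private
#' architectures per genome, with the architecture length distribution
#' following the steep single-domain-dominated decay observed in
#' bacterial one-to-one clusters.
#'
#' @param n_genomes Number of genomes.
#' @param n_core Number of core architectures.
#' @param accessory A data frame with columns `prob` (per-genome
#'   occurrence probability) and `n` (architectures in the stratum).
#' @param singleton_rate Expected private architectures per genome
#'   (Poisson).
#' @param paralog_rate Probability that a genome carrying a core or
#'   accessory architecture carries it in two copies rather than one.
#' @param length_probs Probabilities of architecture lengths 1, 2, ...
#'   (normalized internally).
#' @param n_domain_pool Size of the domain-accession alphabet.
#' @return A `pangenome_config` list.
#' @export
pangenome_config <- function(n_genomes = 60,
                             n_core = 700,
                             accessory = tibble::tibble(
                               prob = c(0.5, 0.15), n = c(220L, 250L)
                             ),
                             singleton_rate = 2.4,
                             paralog_rate = 0.1,
                             length_probs = c(0.750, 0.175, 0.052, 0.015, 0.005, 0.002, 0.001),
                             n_domain_pool = 3000) {
  stopifnot(
    n_genomes >= 1, n_core >= 0, singleton_rate >= 0,
    paralog_rate >= 0, paralog_rate <= 1,
    all(accessory$prob >= 0), all(accessory$prob <= 1), all(accessory$n >= 0)
  )
  structure(
    list(
      n_genomes = as.integer(n_genomes),
      n_core = as.integer(n_core),
      accessory = tibble::as_tibble(accessory),
      singleton_rate = singleton_rate,
      paralog_rate = paralog_rate,
      length_probs = length_probs / sum(length_probs),
      n_domain_pool = as.integer(n_domain_pool)
    ),
    class = "pangenome_config"
  )
}

# Draw n distinct architecture labels from the domain alphabet, avoiding
# labels already in `taken`.
draw_labels <- function(n, config, taken = character()) {
  if (n == 0) {
    return(character())
  }
  pool <- sprintf("PF%05d", seq_len(config$n_domain_pool))
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    len <- sample.int(length(config$length_probs), need,
      replace = TRUE, prob = config$length_probs
    )
    cand <- vapply(
      len,
      function(k) paste(sample(pool, k, replace = TRUE), collapse = ";"),
      character(1)
    )
    out <- setdiff(unique(c(out, setdiff(cand, taken))), character(0))
  }
  out[seq_len(n)]
}

#' Simulate a pan-genome of architecture labels with known ground truth
#'
#' Draws per-genome protein label tables from the model described by a
#' [pangenome_config()]. Core architectures appear in every genome;
#' accessory architectures appear in each genome by an independent coin
#' flip with their stratum probability; singleton architectures are
#' private to one genome with exactly one protein. Ground-truth pan-genome
#' statistics are computed from the generator's own realization records,
#' independently of the analysis path, so generator-analyzer agreement is
#' a meaningful check.
#'
#' @param config A `pangenome_config`.
#' @param seed Integer seed; the same seed reproduces the fixture exactly.
#' @return A list with elements
#'   * `labels`: tibble (`genome_id`, `protein_id`, `architecture`,
#'     `n_domains`) — one row per simulated protein;
#'   * `truth`: list with `pan`, `core`, `singletons`, `n_genomes` and a
#'     per-architecture tibble `architectures` (`architecture`, `class`,
#'     `prob`, `n_genomes_present`, `n_proteins`, `persistence`).
#' @export
simulate_pangenome <- function(config = pangenome_config(), seed = 1) {
  stopifnot(inherits(config, "pangenome_config"))
  local_seed(seed, {
    n_g <- config$n_genomes
    genomes <- sprintf("G%03d", seq_len(n_g))

    core <- draw_labels(config$n_core, config)
    strata <- config$accessory
    acc <- draw_labels(sum(strata$n), config, taken = core)
    acc_prob <- rep(strata$prob, strata$n)

    # occurrence[g, a]: copies of architecture a in genome g
    occurs <- function(labels, probs) {
      if (length(labels) == 0) {
        return(matrix(0L, n_g, 0))
      }
      present <- matrix(
        rbinom(n_g * length(labels), 1L, rep(probs, each = n_g)),
        nrow = n_g
      )
      extra <- matrix(
        rbinom(n_g * length(labels), 1L, config$paralog_rate),
        nrow = n_g
      )
      present * (1L + extra)
    }
    core_occ <- occurs(core, rep(1, length(core)))
    acc_occ <- occurs(acc, acc_prob)

    n_private <- rpois(n_g, config$singleton_rate)
    private <- draw_labels(sum(n_private), config, taken = c(core, acc))
    private_genome <- rep(seq_len(n_g), n_private)

    # assemble protein tables
    rows <- vector("list", n_g)
    for (g in seq_len(n_g)) {
      copies <- c(core_occ[g, ], acc_occ[g, ])
      archs <- rep(c(core, acc), times = copies)
      archs <- c(archs, private[private_genome == g])
      rows[[g]] <- tibble::tibble(
        genome_id = genomes[g],
        protein_id = sprintf("%s_p%05d", genomes[g], seq_along(archs)),
        architecture = archs
      )
    }
    labels <- dplyr::bind_rows(rows)
    labels$n_domains <- domain_count(labels$architecture)

    arch_truth <- tibble::tibble(
      architecture = c(core, acc, private),
      class = rep(
        c("core", "accessory", "singleton"),
        c(length(core), length(acc), length(private))
      ),
      prob = c(rep(1, length(core)), acc_prob, rep(NA_real_, length(private))),
      n_genomes_present = c(
        colSums(core_occ > 0), colSums(acc_occ > 0), rep(1L, length(private))
      ),
      n_proteins = c(
        colSums(core_occ), colSums(acc_occ), rep(1L, length(private))
      )
    ) |>
      dplyr::filter(.data$n_genomes_present > 0) |>
      dplyr::mutate(persistence = .data$n_genomes_present / n_g)

    list(
      labels = labels,
      truth = list(
        n_genomes = n_g,
        pan = nrow(arch_truth),
        core = sum(arch_truth$n_genomes_present == n_g),
        singletons = sum(arch_truth$n_proteins == 1),
        architectures = arch_truth
      )
    )
  })
}

#' Write simulated genomes as InterProScan-style TSV files
#'
#' Emits one annotation file per genome in the 11+ column InterProScan
#' dialect accepted by [read_interproscan()]. Coordinates are fabricated
#' to be consistent with the label order: domain k of a protein occupies
#' positions 60(k-1)+1 to 60(k-1)+50, so starts are strictly increasing,
#' more than 3 apart and non-overlapping — re-parsing and re-labeling
#' reproduces the generating labels exactly without ever touching the
#' tie-break path.
#'
#' @param labels A label table as produced by [simulate_pangenome()].
#' @param dir Output directory (created if needed).
#' @param db Analysis name written in the database column.
#' @return A manifest tibble (`genome_id`, `path`) usable with
#'   [read_annotations()].
#' @export
write_interproscan_tsv <- function(labels, dir, db = "Pfam") {
  check_columns(labels, c("genome_id", "protein_id", "architecture"), "`labels`")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_domain <- labels |>
    dplyr::mutate(domains = architecture_domains(.data$architecture)) |>
    tidyr::unnest_longer("domains", values_to = "domain_id") |>
    dplyr::group_by(.data$genome_id, .data$protein_id) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      start = 60L * (.data$k - 1L) + 1L,
      end = .data$start + 49L
    )
  genomes <- unique(labels$genome_id)
  paths <- file.path(dir, paste0(genomes, ".tsv"))
  for (i in seq_along(genomes)) {
    rows <- dplyr::filter(per_domain, .data$genome_id == genomes[i])
    protein_len <- 60L * max(rows$k, 1L)
    writeLines(
      sprintf(
        "%s\tmd5\t%d\t%s\t%s\tsimulated domain\t%d\t%d\t1e-10\tT\t-",
        rows$protein_id, protein_len, db, rows$domain_id, rows$start, rows$end
      ),
      paths[i]
    )
  }
  tibble::tibble(genome_id = genomes, path = paths)
}

#' Simulate paired clusterings with a configured mismatch taxonomy
#'
#' Builds an architecture-style (D) and a similarity-style (S) partition
#' of a shared protein universe whose comparison by
#' [classify_mismatches()] is known by construction: `n_one_to_one`
#' identical clusters, `n_split` D clusters whose members are split
#' across `split_k` S clusters (each of those S clusters being a strict
#' subset), and `n_merge` S clusters merging `merge_m` D clusters each.
#'
#' @param n_one_to_one Identical clusters.
#' @param n_split D clusters split across S clusters.
#' @param split_k Number of S clusters each split D cluster maps to.
#' @param n_merge S clusters merging D clusters.
#' @param merge_m Number of D clusters each merging S cluster absorbs.
#' @param cluster_size Proteins per elementary block.
#' @param seed Integer seed (protein ids are shuffled so cluster structure
#'   is not encoded in id order).
#' @return A list `dab`, `sb` (cluster tables) and `truth` (expected
#'   `one_to_one` and per-direction histogram tibble `profiles` in the
#'   layout of `classify_mismatches()$profiles`).
#' @export
simulate_paired_clusterings <- function(n_one_to_one = 5, n_split = 3,
                                        split_k = 2, n_merge = 3, merge_m = 2,
                                        cluster_size = 3, seed = 1) {
  stopifnot(
    n_one_to_one >= 0, n_split >= 0, n_merge >= 0,
    split_k >= 2 || n_split == 0, merge_m >= 2 || n_merge == 0,
    cluster_size >= 1
  )
  local_seed(seed, {
    n_proteins <- cluster_size *
      (n_one_to_one + n_split * split_k + n_merge * merge_m)
    ids <- sample(sprintf("p%05d", seq_len(max(n_proteins, 1))))
    take <- local({
      used <- 0L
      function(k) {
        out <- ids[used + seq_len(k)]
        used <<- used + k
        out
      }
    })
    d_rows <- list()
    s_rows <- list()
    add <- function(store, cluster, members) {
      store[[length(store) + 1]] <- tibble::tibble(
        cluster_id = cluster, protein_id = members
      )
      store
    }
    for (i in seq_len(n_one_to_one)) {
      m <- take(cluster_size)
      d_rows <- add(d_rows, sprintf("D_one%03d", i), m)
      s_rows <- add(s_rows, sprintf("S_one%03d", i), m)
    }
    for (i in seq_len(n_split)) {
      blocks <- lapply(seq_len(split_k), function(b) take(cluster_size))
      d_rows <- add(d_rows, sprintf("D_split%03d", i), unlist(blocks))
      for (b in seq_len(split_k)) {
        s_rows <- add(s_rows, sprintf("S_split%03d_%d", i, b), blocks[[b]])
      }
    }
    for (i in seq_len(n_merge)) {
      blocks <- lapply(seq_len(merge_m), function(b) take(cluster_size))
      s_rows <- add(s_rows, sprintf("S_merge%03d", i), unlist(blocks))
      for (b in seq_len(merge_m)) {
        d_rows <- add(d_rows, sprintf("D_merge%03d_%d", i, b), blocks[[b]])
      }
    }
    dab <- dplyr::bind_rows(d_rows)
    sb <- dplyr::bind_rows(s_rows)

    bins <- c(as.character(1:5), "6+")
    bin_of <- function(n) dplyr::if_else(n >= 6, "6+", as.character(n))
    prof <- function(direction, ns) {
      tibble::tibble(direction = direction, bin = bin_of(ns)) |>
        dplyr::count(.data$direction, .data$bin, name = "count")
    }
    profiles <- dplyr::bind_rows(
      prof("D->S", c(
        rep(split_k, n_split), # split D clusters span split_k S clusters
        rep(1L, n_merge * merge_m) # merged D clusters are strict subsets
      )),
      prof("S->D", c(
        rep(1L, n_split * split_k),
        rep(merge_m, n_merge)
      ))
    ) |>
      tidyr::complete(
        direction = c("D->S", "S->D"), bin = bins, fill = list(count = 0L)
      ) |>
      dplyr::mutate(bin = factor(.data$bin, levels = bins)) |>
      dplyr::arrange(.data$direction, .data$bin)

    list(
      dab = dab, sb = sb,
      truth = list(one_to_one = n_one_to_one, profiles = profiles)
    )
  })
}

#' Simulate pooled Heaps accumulation counts from a known decay
#'
#' Draws new-cluster counts `y ~ Poisson(kappa * j^(-alpha))` for genome
#' indices j = 2..n over repeated orderings — the standard parameter
#' recovery fixture for [fit_heaps_decay()].
#'
#' @param kappa,alpha Generating decay parameters.
#' @param n_genomes Number of genomes (j runs to this value).
#' @param n_permutations Replicates per j.
#' @param seed Integer seed.
#' @return A tibble (`j`, `y`).
#' @export
simulate_accumulation <- function(kappa, alpha, n_genomes = 50,
                                  n_permutations = 200, seed = 1) {
  stopifnot(kappa > 0, n_genomes >= 3, n_permutations >= 1)
  local_seed(seed, {
    j <- rep(seq(2, n_genomes), times = n_permutations)
    tibble::tibble(j = j, y = rpois(length(j), kappa * j^(-alpha)))
  })
}
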