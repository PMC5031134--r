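#' Read an InterProScan tab-separated annotation file
#'
#' Parses the standard InterProScan 5 tab-separated output (the 15-column
#' dialect) into a tidy table of domain hits for one genome. Only columns
#' 1 (protein accession), 4 (analysis / signature database), 5 (signature
#' accession), 7 (start) and 8 (stop) are required; column 9 is kept as an
#' informational score when present. Coordinates are 1-based inclusive
#' amino-acid positions, as written by InterProScan; no conversion is
#' applied here or anywhere downstream.
#'
#' Hits are filtered to `allowed_dbs`. Database names are matched
#' case-insensitively onto the controlled vocabulary `Pfam`, `TIGRFAM`,
#' `InterPro`; anything else maps to `other`. Duplicate hits (same protein,
#' domain, start, end) are retained: redundant signature matches are part
#' of the record and are never silently pruned.
#'
#' @param path Path to the TSV file.
#' @param genome_id Identifier attached to every hit from this file.
#' @param allowed_dbs Character vector of source databases to keep. The
#'   default keeps Pfam only, the database used for the main
#'   architecture-based analyses; pass e.g. `c("Pfam", "TIGRFAM")` to mix.
#' @return A tibble with columns `genome_id`, `protein_id`, `source_db`,
#'   `domain_id`, `start`, `end`, `score`, one row per retained hit. The
#'   attribute `proteins_seen` holds all protein ids present in the file,
#'   including proteins whose hits were all filtered out.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "p1\tmd5\t300\tPfam\tPF00005\tABC transporter\t10\t240\t1e-30\tT\t01-01-2020",
#'   "p1\tmd5\t300\tTIGRFAM\tTIGR00001\tdesc\t20\t100\t1e-10\tT\t01-01-2020"
#' ), tsv)
#' read_interproscan(tsv, genome_id = "g1")
read_interproscan <- function(path, genome_id, allowed_dbs = "Pfam") {
  if (!file.exists(path)) {
    abort(sprintf("annotation file does not exist: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]

  empty <- tibble::tibble(
    genome_id = character(), protein_id = character(),
    source_db = character(), domain_id = character(),
    start = integer(), end = integer(), score = double()
  )
  if (length(lines) == 0) {
    warn(sprintf("annotation file is empty: %s", path))
    attr(empty, "proteins_seen") <- character()
    return(empty)
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 8)) {
    bad <- lineno[which(nfield < 8)[1]]
    abort(sprintf("%s line %d: expected at least 8 tab-separated columns", path, bad))
  }

  col <- function(i) vapply(fields, `[[`, character(1), i)
  protein_id <- col(1)
  analysis <- col(4)
  domain_id <- col(5)
  start_raw <- col(7)
  end_raw <- col(8)
  score_raw <- vapply(fields, function(f) if (length(f) >= 9) f[[9]] else NA_character_, character(1))

  start <- suppressWarnings(as.integer(start_raw))
  end <- suppressWarnings(as.integer(end_raw))
  bad_coord <- is.na(start) | is.na(end) | start_raw != as.character(start) |
    end_raw != as.character(end)
  if (any(bad_coord)) {
    abort(sprintf(
      "%s line %d: non-integer coordinates ('%s', '%s')",
      path, lineno[which(bad_coord)[1]],
      start_raw[which(bad_coord)[1]], end_raw[which(bad_coord)[1]]
    ))
  }
  bad_order <- start > end | start < 1L
  if (any(bad_order)) {
    i <- which(bad_order)[1]
    abort(sprintf(
      "%s line %d: invalid interval start=%d end=%d (need 1 <= start <= end)",
      path, lineno[i], start[i], end[i]
    ))
  }
  if (any(domain_id == "")) {
    abort(sprintf("%s line %d: empty signature accession", path, lineno[which(domain_id == "")[1]]))
  }
  if (any(grepl(";", domain_id, fixed = TRUE))) {
    abort(sprintf(
      "%s line %d: signature accession contains ';', reserved as the architecture separator",
      path, lineno[which(grepl(";", domain_id, fixed = TRUE))[1]]
    ))
  }

  hits <- tibble::tibble(
    genome_id = genome_id,
    protein_id = protein_id,
    source_db = normalize_source_db(analysis),
    domain_id = domain_id,
    start = start,
    end = end,
    score = suppressWarnings(as.double(score_raw))
  )
  out <- dplyr::filter(hits, .data$source_db %in% allowed_dbs)
  out <- dplyr::arrange(out, .data$protein_id, .data$start, .data$domain_id, .data$end)
  attr(out, "proteins_seen") <- unique(protein_id)
  out
}

# Case-insensitive mapping of the InterProScan "analysis" column onto the
# controlled vocabulary; unknown databases become "other".
normalize_source_db <- function(x) {
  lx <- tolower(x)
  dplyr::case_when(
    lx == "pfam" ~ "Pfam",
    lx %in% c("tigrfam", "tigrfams") ~ "TIGRFAM",
    lx == "interpro" ~ "InterPro",
    TRUE ~ "other"
  )
}

#' Read annotations for many genomes
#'
#' Applies [read_interproscan()] to each genome in a manifest and row-binds
#' the results. Protein ids are expected to be globally unique; if the same
#' protein id occurs in two genomes, every id is prefixed with
#' `"<genome_id>|"` to restore uniqueness and a message is emitted.
#'
#' @param manifest A data frame with columns `genome_id` and `path`.
#' @param allowed_dbs Passed to [read_interproscan()].
#' @return A tibble of hits across all genomes.
#' @export
read_annotations <- function(manifest, allowed_dbs = "Pfam") {
  check_columns(manifest, c("genome_id", "path"), "`manifest`")
  per_genome <- purrr::map2(
    manifest$genome_id, manifest$path,
    function(g, p) read_interproscan(p, genome_id = g, allowed_dbs = allowed_dbs)
  )
  hits <- dplyr::bind_rows(per_genome)
  if (nrow(hits) > 0) {
    owners <- dplyr::distinct(hits, .data$genome_id, .data$protein_id)
    if (anyDuplicated(owners$protein_id) > 0) {
      inform("protein ids collide across genomes; prefixing with 'genome_id|'")
      hits$protein_id <- paste(hits$genome_id, hits$protein_id, sep = "|")
    }
  }
  hits
}

#' Read a cluster file (MCL output dialect)
#'
#' Reads a protein clustering in the "one cluster per line,
#' whitespace-separated protein ids" format written by MCL and similar
#' tools. Cluster ids are assigned deterministically from the file line
#' number, so re-reading the same file always yields the same ids. Blank
#' lines are ignored. A protein id appearing on two lines violates the
#' partition contract and is a hard error.
#'
#' @param path Path to the cluster file.
#' @param label Short method tag used as the cluster-id prefix,
#'   conventionally `"DAB"` or `"SB"`.
#' @return A tibble with columns `cluster_id` and `protein_id`; one row per
#'   cluster member.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("p1 p2", "p3"), f)
#' read_clusters(f, label = "SB")
read_clusters <- function(path, label = "SB") {
  if (!file.exists(path)) {
    abort(sprintf("cluster file does not exist: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (length(nonblank) == 0) {
    return(tibble::tibble(cluster_id = character(), protein_id = character()))
  }
  members <- strsplit(trimws(lines[nonblank]), "\\s+")
  out <- tibble::tibble(
    cluster_id = rep(paste0(label, nonblank), lengths(members)),
    protein_id = unlist(members)
  )
  dup <- out$protein_id[duplicated(out$protein_id)]
  if (length(dup) > 0) {
    abort(sprintf(
      "%s: protein(s) appear in more than one cluster: %s",
      path, paste(unique(head(dup, 5)), collapse = ", ")
    ))
  }
  out
}

#' Write a cluster table in the MCL output dialect
#'
#' Inverse of [read_clusters()]: one line per cluster, members separated by
#' single spaces, clusters in order of first appearance. This makes
#' architecture-based cluster sets interchangeable with externally produced
#' sequence-similarity clusterings downstream.
#'
#' @param clusters A cluster table (`cluster_id`, `protein_id`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  validate_clusters(clusters)
  lines <- clusters |>
    dplyr::group_by(cluster_id = factor(.data$cluster_id, levels = unique(.data$cluster_id))) |>
    dplyr::summarise(line = paste(.data$protein_id, collapse = " "), .groups = "drop")
  writeLines(lines$line, path)
  invisible(path)
}

#' Restrict a clustering to annotated proteins
#'
#' Drops every protein not in `annotated` from the clustering; clusters left
#' empty disappear. Used to put an external sequence-similarity clustering
#' on the same universe as the architecture-based one, which by construction
#' only contains proteins bearing at least one domain.
#'
#' @param clusters A cluster table (`cluster_id`, `protein_id`).
#' @param annotated Character vector of protein ids to keep.
#' @return The filtered cluster table; a partition of the intersection of
#'   the original universe with `annotated`.
#' @export
restrict_to_annotated <- function(clusters, annotated) {
  validate_clusters(clusters)
  dplyr::filter(clusters, .data$protein_id %in% annotated)
}
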