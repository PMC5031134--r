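# Shared fixture builders and independent oracles.

hit_row <- function(domain_id, start, end,
                    protein_id = "p1", genome_id = "g1") {
  tibble::tibble(
    genome_id = genome_id, protein_id = protein_id,
    domain_id = domain_id, start = as.integer(start), end = as.integer(end)
  )
}

hits_tbl <- function(domain_id, start, end, ...) {
  tibble::tibble(
    genome_id = "g1", protein_id = "p1",
    domain_id = domain_id, start = as.integer(start), end = as.integer(end)
  )
}

# Literal brute-force comparator of the ordering rule: hits ordered by
# start position; overlapping hits with start distance < 3 (and hits with
# identical starts) ordered alphabetically. The pairwise relation is
# turned into a total order by repeatedly extracting a minimal element
# (topological sort); random realistic instances define a total order.
oracle_order <- function(hits) {
  cmp <- function(i, j) {
    si <- hits$start[i]
    sj <- hits$start[j]
    overlap <- si <= hits$end[j] && sj <= hits$end[i]
    if (si == sj || (overlap && abs(si - sj) < 3)) {
      di <- hits$domain_id[i]
      dj <- hits$domain_id[j]
      if (di == dj) si <= sj else di < dj
    } else {
      si < sj
    }
  }
  idx <- seq_len(nrow(hits))
  out <- integer(0)
  while (length(idx) > 0) {
    minimal <- idx[vapply(
      idx,
      function(i) all(vapply(setdiff(idx, i), function(j) cmp(i, j), logical(1))),
      logical(1)
    )]
    if (length(minimal) == 0) {
      stop("pairwise rule is intransitive on this instance")
    }
    out <- c(out, minimal[1])
    idx <- setdiff(idx, minimal[1])
  }
  hits[out, , drop = FALSE]
}

random_protein_hits <- function(n_hits, alphabet = sprintf("PF%05d", 1:40)) {
  start <- sample.int(200, n_hits, replace = TRUE)
  len <- sample(10:120, n_hits, replace = TRUE)
  tibble::tibble(
    genome_id = "g1", protein_id = "p1",
    domain_id = sample(alphabet, n_hits, replace = TRUE),
    start = as.integer(start), end = as.integer(start + len)
  )
}

# Random partition of ids into roughly n_clusters clusters.
random_partition <- function(ids, n_clusters, prefix = "C") {
  assignment <- sample.int(n_clusters, length(ids), replace = TRUE)
  tibble::tibble(
    cluster_id = paste0(prefix, assignment),
    protein_id = ids
  )
}

# Brute-force bipartite comparison by explicit double loop over
# membership sets, independent of the package's join-based path.
oracle_compare <- function(a, b) {
  sets_a <- split(a$protein_id, a$cluster_id)
  sets_b <- split(b$protein_id, b$cluster_id)
  n_counterparts <- function(set, others) {
    sum(vapply(others, function(o) length(intersect(set, o)) > 0, logical(1)))
  }
  identical_count <- sum(vapply(
    sets_a,
    function(sa) any(vapply(sets_b, function(sb) setequal(sa, sb), logical(1))),
    logical(1)
  ))
  list(
    n_a = vapply(sets_a, n_counterparts, numeric(1), others = sets_b),
    n_b = vapply(sets_b, n_counterparts, numeric(1), others = sets_a),
    identical_a = vapply(
      sets_a,
      function(sa) any(vapply(sets_b, function(sb) setequal(sa, sb), logical(1))),
      logical(1)
    ),
    identical_count = identical_count
  )
}

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
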