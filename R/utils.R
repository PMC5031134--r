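#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (away from zero),
#' matching how pan-genome ratios are conventionally printed. Base R's
#' `round()` rounds halves to even, which differs on values such as 0.545.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(0.545, 2) # 0.55, where round() gives 0.54
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Shared column checks -------------------------------------------------------

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must have columns %s; missing: %s",
      what, paste(cols, collapse = ", "), paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# A cluster table is a partition: tibble(cluster_id, protein_id), each
# protein in exactly one cluster, no empty clusters (empty clusters cannot
# be represented in the long form).
validate_clusters <- function(clusters, what = "`clusters`") {
  check_columns(clusters, c("cluster_id", "protein_id"), what)
  dup <- clusters$protein_id[duplicated(clusters$protein_id)]
  if (length(dup) > 0) {
    abort(sprintf(
      "%s is not a partition: protein(s) in more than one cluster: %s",
      what, paste(unique(head(dup, 5)), collapse = ", ")
    ))
  }
  invisible(clusters)
}

validate_genome_map <- function(genome_map) {
  check_columns(genome_map, c("protein_id", "genome_id"), "`genome_map`")
  dup <- genome_map$protein_id[duplicated(genome_map$protein_id)]
  if (length(dup) > 0) {
    abort(sprintf(
      "`genome_map` maps protein(s) to more than one genome: %s",
      paste(unique(head(dup, 5)), collapse = ", ")
    ))
  }
  invisible(genome_map)
}
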