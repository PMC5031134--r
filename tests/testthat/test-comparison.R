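test_that("counterpart counts follow the membership overlap", {
  d <- tibble::tibble(cluster_id = c("d1", "d1"), protein_id = c("p1", "p2"))
  s <- tibble::tibble(cluster_id = c("s1", "s2"), protein_id = c("p1", "p2"))
  expect_equal(counterpart_counts(d, s)$n_counterparts, 2L)
  expect_equal(counterpart_counts(s, d)$n_counterparts, c(1L, 1L))
  # identical partitions: all N = 1
  expect_true(all(counterpart_counts(d, d)$n_counterparts == 1))
  expect_error(
    counterpart_counts(d, s[1, ]),
    "do not share a universe"
  )
})

test_that("split and merge directions are classified as in the taxonomy", {
  # two D singletons merged in one S cluster
  d <- tibble::tibble(cluster_id = c("d1", "d2"), protein_id = c("p1", "p2"))
  s <- tibble::tibble(cluster_id = c("s1", "s1"), protein_id = c("p1", "p2"))
  cmp <- classify_mismatches(d, s)
  expect_equal(cmp$one_to_one, 0)
  # D->S: both D clusters sit inside one S cluster (strict subsets, N = 1)
  d_to_s <- dplyr::filter(cmp$profiles, direction == "D->S")
  expect_equal(d_to_s$count[d_to_s$bin == "1"], 2L)
  # S->D: the S cluster spans two D clusters
  s_to_d <- dplyr::filter(cmp$profiles, direction == "S->D")
  expect_equal(s_to_d$count[s_to_d$bin == "2"], 1L)
  expect_equal(cmp$subsets$n_subset[cmp$subsets$direction == "D->S"], 2L)

  # full agreement
  agree <- classify_mismatches(s, s)
  expect_equal(agree$one_to_one, 1)
  expect_true(all(agree$profiles$count == 0))
})

test_that("identical cluster counting is symmetric and exact-set based", {
  a <- tibble::tibble(
    cluster_id = c("c1", "c1", "c2", "c3"),
    protein_id = c("p1", "p2", "p3", "p4")
  )
  b <- tibble::tibble(
    cluster_id = c("x", "x", "y", "z"),
    protein_id = c("p1", "p2", "p4", "p3")
  )
  expect_equal(identical_cluster_count(a, b), 3)
  expect_equal(identical_cluster_count(b, a), 3)
  shifted <- tibble::tibble(
    cluster_id = c("x", "x", "x", "y"),
    protein_id = c("p1", "p2", "p3", "p4")
  )
  expect_equal(identical_cluster_count(a, shifted), 1) # only {p4}
  expect_equal(identical_cluster_count(a, a), 3)
})

test_that("random paired partitions match the brute-force oracle", {
  withr::local_seed(1234)
  for (i in 1:40) {
    n <- sample(20:60, 1)
    ids <- sprintf("p%03d", seq_len(n))
    a <- random_partition(ids, sample(3:10, 1), prefix = "A")
    b <- random_partition(ids, sample(3:10, 1), prefix = "B")
    oracle <- oracle_compare(a, b)

    ca <- counterpart_counts(a, b)
    expect_equal(
      ca$n_counterparts[match(names(oracle$n_a), ca$cluster_id)],
      unname(as.integer(oracle$n_a))
    )
    expect_equal(identical_cluster_count(a, b), oracle$identical_count)

    cmp <- classify_mismatches(a, b)
    expect_equal(cmp$one_to_one, oracle$identical_count)
    # one_to_one + non-identical histogram mass = reference cluster count
    expect_equal(
      cmp$one_to_one + sum(cmp$profiles$count[cmp$profiles$direction == "D->S"]),
      dplyr::n_distinct(a$cluster_id)
    )
    # histogram equals binned oracle counts in both directions
    oracle_bins <- function(ns, identical) {
      ns <- ns[!identical]
      table(factor(
        ifelse(ns >= 6, "6+", as.character(ns)),
        levels = c(as.character(1:5), "6+")
      ))
    }
    ident_b <- vapply(
      split(b$protein_id, b$cluster_id),
      function(sb) {
        any(vapply(split(a$protein_id, a$cluster_id),
          function(sa) setequal(sa, sb), logical(1)
        ))
      },
      logical(1)
    )
    expect_equal(
      cmp$profiles$count[cmp$profiles$direction == "D->S"],
      unname(as.integer(oracle_bins(oracle$n_a, oracle$identical_a)))
    )
    expect_equal(
      cmp$profiles$count[cmp$profiles$direction == "S->D"],
      unname(as.integer(oracle_bins(oracle$n_b, ident_b)))
    )
  }
})

test_that("refinement gives N = 1 everywhere in the refined direction", {
  withr::local_seed(55)
  ids <- sprintf("p%03d", 1:60)
  coarse <- random_partition(ids, 5, prefix = "S")
  # refine each S cluster by splitting members in two
  fine <- coarse |>
    dplyr::group_by(cluster_id) |>
    dplyr::mutate(cluster_id = paste0(cluster_id, "_", (dplyr::row_number() %% 2) + 1)) |>
    dplyr::ungroup()
  expect_true(all(counterpart_counts(fine, coarse)$n_counterparts == 1))
  # coarse-side counts equal the number of refined parts per cluster
  parts <- fine |>
    dplyr::mutate(parent = sub("_[12]$", "", cluster_id)) |>
    dplyr::distinct(parent, cluster_id) |>
    dplyr::count(parent)
  cc <- counterpart_counts(coarse, fine)
  expect_equal(
    cc$n_counterparts[match(parts$parent, cc$cluster_id)],
    parts$n
  )
  # conservation: S->D mass >= number of D clusters, equality iff nested
  expect_equal(
    sum(counterpart_counts(coarse, fine)$n_counterparts),
    dplyr::n_distinct(fine$cluster_id)
  )
})

test_that("one-to-one composition tabulates shared-label domain counts", {
  labels <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p4", "p5"),
    architecture = c("A", "A", "A;B", "C", "D;E;F")
  )
  dab <- tibble::tibble(
    cluster_id = labels$architecture, protein_id = labels$protein_id
  )
  sb <- tibble::tibble(
    cluster_id = c("s1", "s1", "s2", "s3", "s4"),
    protein_id = c("p1", "p2", "p3", "p4", "p5")
  )
  comp <- one_to_one_composition(dab, sb, labels)
  expect_equal(comp$n_domains, c(1L, 2L, 3L))
  expect_equal(comp$count, c(2L, 1L, 1L))

  disjoint_sb <- tibble::tibble(
    cluster_id = c("s1", "s2", "s1", "s2", "s1"),
    protein_id = c("p1", "p2", "p3", "p4", "p5")
  )
  expect_equal(nrow(one_to_one_composition(dab, disjoint_sb, labels)), 0)
})

test_that("comparison accessors expose the taxonomy tidily", {
  pair <- simulate_paired_clusterings(
    n_one_to_one = 2, n_split = 1, split_k = 2,
    n_merge = 1, merge_m = 2, seed = 9
  )
  cmp <- classify_mismatches(pair$dab, pair$sb)
  td <- tidy(cmp)
  expect_setequal(unique(td$bin), c("one-to-one", as.character(1:5), "6+"))
  gl <- glance(cmp)
  expect_equal(gl$one_to_one, 2)
  expect_s3_class(autoplot(cmp), "ggplot")
})
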