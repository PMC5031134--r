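test_that("persistence counts genomes, not proteins", {
  # a cluster spanning 30 of 60 genomes
  spread <- tibble::tibble(
    cluster_id = "c1",
    protein_id = sprintf("p%02d", 1:30)
  )
  map30 <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:30),
    genome_id = sprintf("g%02d", 1:30)
  )
  per <- cluster_persistence(spread, map30, n_genomes = 60)
  expect_equal(per$persistence, 0.5)

  # 3 paralogs confined to one genome of 60
  paralogs <- tibble::tibble(cluster_id = "c1", protein_id = c("a", "b", "c"))
  map1 <- tibble::tibble(protein_id = c("a", "b", "c"), genome_id = "g01")
  expect_equal(
    cluster_persistence(paralogs, map1, n_genomes = 60)$persistence,
    1 / 60
  )

  # present in all genomes: persistence exactly 1, counted in the core
  core <- tibble::tibble(cluster_id = "c1", protein_id = c("a", "b"))
  map2 <- tibble::tibble(protein_id = c("a", "b"), genome_id = c("g1", "g2"))
  expect_equal(cluster_persistence(core, map2)$persistence, 1)
  expect_equal(pangenome_summary(core, map2)$core, 1)

  expect_error(
    cluster_persistence(core, map2[1, ]),
    "without a genome mapping"
  )
})

test_that("summary matches brute-force counting on a toy partition", {
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c1", "c2", "c3"),
    protein_id = c("p1", "p2", "p3", "p4")
  )
  genome_map <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p4"),
    genome_id = c("g1", "g2", "g1", "g2")
  )
  s <- pangenome_summary(clusters, genome_map)
  expect_equal(s$pan, 3)
  expect_equal(s$core, 1)
  expect_equal(s$singletons, 2)
  expect_equal(round_half_up(s$core_pan), 0.33)
  # cross-check against the matrix path: core = all-ones columns, pan = columns
  labels <- tibble::tibble(
    genome_id = genome_map$genome_id,
    protein_id = genome_map$protein_id,
    architecture = c("c1", "c1", "c2", "c3")
  )
  pres <- pa_matrix(binarize(abundance_matrix(labels)))
  expect_equal(s$pan, ncol(pres))
  expect_equal(s$core, sum(colSums(pres) == nrow(pres)))
})

test_that("core/singleton ratios handle empty denominators", {
  s <- counts_to_summary(core = 5, pan = 5, singletons = 0)
  expect_true(is.na(s$core_singletons))
  expect_true(is.na(singleton_ratio(3, 0)))
  expect_equal(singleton_ratio(142, 295), 142 / 295)
  expect_equal(singleton_ratio(s, s), NA_real_)
})

test_that("removing a genome can only grow the core and shrink the pan", {
  withr::local_seed(31)
  for (i in 1:5) {
    sim <- simulate_pangenome(pangenome_config(
      n_genomes = 10, n_core = 15,
      accessory = tibble::tibble(prob = c(0.6, 0.2), n = c(10L, 10L)),
      singleton_rate = 1.5
    ), seed = 100 + i)
    labels <- sim$labels
    genome_map <- dplyr::distinct(labels, protein_id, genome_id)
    full <- pangenome_summary(dab_clusters(labels), genome_map)
    drop_g <- sample(unique(labels$genome_id), 1)
    rest <- dplyr::filter(labels, genome_id != drop_g)
    rest_map <- dplyr::distinct(rest, protein_id, genome_id)
    part <- pangenome_summary(dab_clusters(rest), rest_map)
    expect_gte(part$core, full$core)
    expect_lte(part$pan, full$pan)
  }
})

test_that("persistence histogram covers (0,1] and preserves totals", {
  h <- persistence_histogram(c(0.01, 0.04, 0.05, 0.5, 1, 1), bins = 20)
  expect_equal(sum(h$count), 6)
  expect_equal(h$count[1], 3) # 0.05 belongs to the lowest bin (0, 0.05]
  expect_equal(h$count[20], 2)
  expect_error(persistence_histogram(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("presence PCA separates architecture-disjoint genome groups", {
  # two groups with disjoint architecture sets
  labels <- dplyr::bind_rows(
    tidyr::expand_grid(genome_id = c("a1", "a2", "a3"), architecture = c("A", "B", "C")),
    tidyr::expand_grid(genome_id = c("b1", "b2", "b3"), architecture = c("X", "Y", "Z"))
  ) |>
    dplyr::mutate(protein_id = paste0(genome_id, "_", architecture))
  pca <- presence_pca(binarize(abundance_matrix(labels)), n_components = 2)
  scores <- pca$scores
  a_side <- scores$PC1[startsWith(scores$genome_id, "a")]
  b_side <- scores$PC1[startsWith(scores$genome_id, "b")]
  expect_true(all(sign(a_side) == sign(a_side[1])))
  expect_true(all(sign(b_side) == -sign(a_side[1])))
  expect_lte(sum(pca$explained), 1)
  expect_true(all(diff(pca$explained) <= 1e-12))
  # eigen cross-check: with two disjoint blocks PC1 carries all the variance
  expect_equal(pca$explained[1], 1, tolerance = 1e-10)

  # identical genomes: no structure, zero scores
  same <- dplyr::mutate(labels, architecture = "A", protein_id = paste0(genome_id, "_p"))
  expect_warning(
    flat <- presence_pca(binarize(abundance_matrix(same))),
    "identical"
  )
  expect_true(all(flat$scores$PC1 == 0))
})

test_that("outlier flagging finds a genome with divergent domain content", {
  withr::local_seed(9)
  shared <- sprintf("A%02d", 1:20)
  labels <- tidyr::expand_grid(
    genome_id = sprintf("g%02d", 1:9),
    architecture = shared
  )
  outlier <- tibble::tibble(
    genome_id = "g10",
    architecture = c(shared[1:10], sprintf("X%02d", 1:10))
  )
  labels <- dplyr::bind_rows(labels, outlier) |>
    dplyr::mutate(protein_id = paste0(genome_id, "_", architecture))
  pres <- binarize(abundance_matrix(labels))
  expect_equal(flag_outliers(pres), "g10")
  # direct distance computation agrees with the flag
  m <- pa_matrix(pres)
  d <- sqrt(rowSums(scale(m, center = TRUE, scale = FALSE)^2))
  expect_equal(names(which(d > 4 * median(d))), "g10")

  homogeneous <- dplyr::filter(labels, genome_id != "g10")
  expect_equal(flag_outliers(binarize(abundance_matrix(homogeneous))), character())
  expect_equal(flag_outliers(pres, multiple = Inf), character())
})
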