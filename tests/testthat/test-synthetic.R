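small_config <- function(...) {
  pangenome_config(
    n_genomes = 5, n_core = 10,
    accessory = tibble::tibble(prob = numeric(), n = integer()),
    singleton_rate = 0, paralog_rate = 0, ...
  )
}

test_that("a pure-core model yields pan = core and no singletons", {
  sim <- simulate_pangenome(small_config(), seed = 1)
  expect_equal(sim$truth$pan, 10)
  expect_equal(sim$truth$core, 10)
  expect_equal(sim$truth$singletons, 0)
  expect_true(all(sim$truth$architectures$persistence == 1))
  # analyzer agrees
  s <- pangenome_summary(
    dab_clusters(sim$labels),
    dplyr::distinct(sim$labels, protein_id, genome_id)
  )
  expect_equal(s$pan, 10)
  expect_equal(s$core, 10)
  expect_equal(s$singletons, 0)
})

test_that("the generator is deterministic per seed", {
  cfg <- pangenome_config(
    n_genomes = 6, n_core = 8,
    accessory = tibble::tibble(prob = 0.4, n = 10L),
    singleton_rate = 1.5
  )
  a <- simulate_pangenome(cfg, seed = 42)
  b <- simulate_pangenome(cfg, seed = 42)
  expect_equal(a, b)
  c <- simulate_pangenome(cfg, seed = 43)
  expect_false(identical(a$labels, c$labels))
})

test_that("singleton arrivals follow the configured Poisson rate", {
  rate <- 2
  n_genomes <- 10
  counts <- vapply(1:20, function(s) {
    sim <- simulate_pangenome(
      pangenome_config(
        n_genomes = n_genomes, n_core = 5,
        accessory = tibble::tibble(prob = numeric(), n = integer()),
        singleton_rate = rate, paralog_rate = 0
      ),
      seed = 1000 + s
    )
    sim$truth$singletons
  }, numeric(1))
  total <- sum(counts)
  lambda <- 20 * n_genomes * rate
  bounds <- qpois(c(0.005, 0.995), lambda)
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])
})

test_that("ground truth equals the analyzer output on varied fixtures", {
  withr::local_seed(246)
  for (s in 1:10) {
    n_g <- sample(5:25, 1)
    sim <- simulate_pangenome(
      pangenome_config(
        n_genomes = n_g, n_core = sample(5:30, 1),
        accessory = tibble::tibble(prob = c(0.5, 0.1), n = c(10L, 15L)),
        singleton_rate = 1, paralog_rate = 0.15
      ),
      seed = 2000 + s
    )
    genome_map <- dplyr::distinct(sim$labels, protein_id, genome_id)
    s_obs <- pangenome_summary(
      dab_clusters(sim$labels), genome_map,
      n_genomes = sim$truth$n_genomes
    )
    expect_equal(s_obs$pan, sim$truth$pan)
    expect_equal(s_obs$core, sim$truth$core)
    expect_equal(s_obs$singletons, sim$truth$singletons)
    per <- cluster_persistence(
      dab_clusters(sim$labels), genome_map,
      n_genomes = sim$truth$n_genomes
    )
    truth <- sim$truth$architectures
    expect_equal(
      per$persistence[match(truth$architecture, per$cluster_id)],
      truth$persistence
    )
  }
})

test_that("emitted annotation files round-trip to the generating labels", {
  sim <- simulate_pangenome(
    pangenome_config(
      n_genomes = 4, n_core = 6,
      accessory = tibble::tibble(prob = 0.5, n = 6L),
      singleton_rate = 1
    ),
    seed = 11
  )
  dir <- withr::local_tempdir()
  manifest <- write_interproscan_tsv(sim$labels, dir)
  expect_equal(nrow(manifest), 4)
  hits <- read_annotations(manifest)
  relabeled <- assign_labels(hits)
  joined <- dplyr::inner_join(
    sim$labels, relabeled,
    by = c("genome_id", "protein_id"), suffix = c("_true", "_obs")
  )
  expect_equal(nrow(joined), nrow(sim$labels))
  expect_equal(joined$architecture_obs, joined$architecture_true)
})

test_that("a repeated-domain label round-trips through emission", {
  labels <- tibble::tibble(
    genome_id = "g1", protein_id = "p1", architecture = "PF00005;PF00005"
  )
  dir <- withr::local_tempdir()
  manifest <- write_interproscan_tsv(labels, dir)
  hits <- read_interproscan(manifest$path, genome_id = "g1")
  expect_equal(nrow(hits), 2)
  expect_true(all(diff(hits$start) >= 3))
  expect_equal(assign_labels(hits)$architecture, "PF00005;PF00005")
})

test_that("paired clusterings reproduce their configured taxonomy", {
  pure <- simulate_paired_clusterings(
    n_one_to_one = 5, n_split = 0, n_merge = 0, seed = 1
  )
  cmp <- classify_mismatches(pure$dab, pure$sb)
  expect_equal(cmp$one_to_one, 5)
  expect_true(all(cmp$profiles$count == 0))

  splits <- simulate_paired_clusterings(
    n_one_to_one = 0, n_split = 3, split_k = 2, n_merge = 0, seed = 2
  )
  cmp2 <- classify_mismatches(splits$dab, splits$sb)
  d_hist <- dplyr::filter(cmp2$profiles, direction == "D->S")
  expect_equal(d_hist$count[d_hist$bin == "2"], 3L)
  s_hist <- dplyr::filter(cmp2$profiles, direction == "S->D")
  expect_equal(s_hist$count[s_hist$bin == "1"], 6L)
  expect_equal(cmp2$profiles, splits$truth$profiles)

  mixed <- simulate_paired_clusterings(
    n_one_to_one = 2, n_split = 1, split_k = 3, n_merge = 1, merge_m = 2, seed = 3
  )
  cmp3 <- classify_mismatches(mixed$dab, mixed$sb)
  expect_equal(cmp3$one_to_one, mixed$truth$one_to_one)
  expect_equal(cmp3$profiles, mixed$truth$profiles)
})

test_that("a core plus rare-accessory mixture gives a bimodal persistence histogram", {
  sim <- simulate_pangenome(
    pangenome_config(
      n_genomes = 60, n_core = 300,
      accessory = tibble::tibble(prob = 0.03, n = 400L),
      singleton_rate = 5, paralog_rate = 0.05
    ),
    seed = 19
  )
  per <- cluster_persistence(
    dab_clusters(sim$labels),
    dplyr::distinct(sim$labels, protein_id, genome_id),
    n_genomes = 60
  )
  h <- persistence_histogram(per, bins = 20)
  interior <- h$count[2:19]
  expect_gt(h$count[1], max(interior))
  expect_gt(h$count[20], max(interior))
})
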