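test_that("pairwise identity matches hand-aligned cases", {
  expect_equal(pairwise_identity("MKLVTTTTGA", "MKLVTTTTGA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  # single substitution: 7 matched columns over alignment length 8
  expect_equal(pairwise_identity("ACGTACGT", "ACGAACGT"), 7 / 8)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("greedy clustering handles forced cases", {
  # identical sequences from two genomes -> one family present in both
  pr <- protein_records(c("g1", "g2"), c("p1", "p1"),
                        c("MKLVANDPQRST", "MKLVANDPQRST"))
  m <- cluster_proteins(pr)
  expect_equal(length(m$families), 1)
  expect_true(all(m$presence))

  # unrelated sequences -> two families
  pr2 <- protein_records(c("g1", "g2"), c("p1", "p1"),
                         c("MKLVANDPQRST", "WWEEFFYYHHGG"))
  m2 <- cluster_proteins(pr2)
  expect_equal(length(m2$families), 2)
})

test_that("clustering recovers planted families exactly and is
           order-insensitive", {
  cfg <- pangenome_sim_config(n_genomes = 4L, core_families = 8L,
                              accessory_families = 5L,
                              unique_families_per_genome = 3L,
                              protein_length = 120L, seed = 1L)
  prot <- simulate_pangenome(cfg)
  m <- cluster_proteins(prot)
  key <- paste(prot$genome_id, prot$protein_id, sep = "|")
  expect_equal(
    mclust::adjustedRandIndex(prot$planted_family, m$family_of[key]), 1.0)
  withr::local_seed(55)
  shuffled <- prot[sample(nrow(prot)), ]
  m2 <- cluster_proteins(shuffled)
  expect_identical(m$family_of[key], m2$family_of[key])
})

test_that("partition splits families into core/accessory/unique exactly", {
  pres <- rbind(
    f1 = c(TRUE, TRUE, TRUE),
    f2 = c(TRUE, FALSE, FALSE),
    f3 = c(TRUE, TRUE, FALSE))
  colnames(pres) <- paste0("g", 1:3)
  m <- structure(list(presence = pres, families = rownames(pres),
                      genomes = colnames(pres)),
                 class = "pangenome_matrix")
  part <- pangenome_partition(m)
  expect_equal(part$core, "f1")
  expect_equal(part$unique, "f2")
  expect_equal(part$accessory, "f3")
  expect_equal(unname(part$counts), c(1L, 1L, 1L, 3L))
  expect_equal(part$unique_per_genome$n_unique, c(1L, 0L, 0L))
  expect_equal(sum(part$unique_per_genome$n_unique), length(part$unique))

  one <- structure(list(presence = pres[, 1, drop = FALSE],
                        families = rownames(pres), genomes = "g1"),
                   class = "pangenome_matrix")
  expect_error(pangenome_partition(one), ">= 2 genomes")
})

test_that("partition recovers planted core/accessory/unique counts", {
  cfg <- pangenome_sim_config(seed = 2)
  prot <- simulate_pangenome(cfg)
  part <- pangenome_partition(planted_pangenome_matrix(prot))
  expect_equal(unname(part$counts["core"]), cfg$core_families)
  expect_equal(unname(part$counts["accessory"]), cfg$accessory_families)
  expect_equal(unname(part$counts["unique"]),
               cfg$n_genomes * cfg$unique_families_per_genome)
  expect_equal(unname(part$counts["total"]),
               unname(sum(part$counts[c("core", "accessory", "unique")])))
})

test_that("rarefaction curves are monotone with the forced endpoints", {
  prot <- simulate_pangenome(pangenome_sim_config(seed = 3))
  m <- planted_pangenome_matrix(prot)
  rare <- rarefaction(m, iterations = 200, seed = 5)
  expect_true(all(apply(rare$pan, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(rare$core, 1, function(r) all(diff(r) <= 0))))
  # pan(1) = core(1) = family count of the first genome drawn
  expect_true(all(rare$pan[, 1] == rare$core[, 1]))
  expect_true(all(rare$pan[, 1] %in% colSums(m$presence)))
  # pan(N_total) is the total family count in every permutation
  expect_true(all(rare$pan[, ncol(rare$pan)] == length(m$families)))
  # seeded reproducibility
  rare2 <- rarefaction(m, iterations = 200, seed = 5)
  expect_identical(rare$pan, rare2$pan)
  expect_error(rarefaction(m, iterations = 0), "iterations")
})

test_that("Heaps fit recovers a noiseless power law to 1e-6", {
  curve <- 100 * (1:12)^0.4
  fit <- fit_heaps(curve)
  expect_equal(fit$kappa, 100, tolerance = 1e-6)
  expect_equal(fit$gamma, 0.4, tolerance = 1e-6)
  # constant curve after N = 1: gamma ~ 0, closed call
  flat <- fit_heaps(c(50, 50, 50, 50, 50))
  expect_equal(flat$gamma, 0, tolerance = 1e-9)
  expect_false(flat$open)
  expect_error(fit_heaps(c(10, 0, 30)), "positive")
  expect_error(fit_heaps(c(10, 20)), "length >= 3")
})

test_that("a planted-open pan-genome is called open in every seed", {
  for (s in 1:5) {
    prot <- simulate_pangenome(
      pangenome_sim_config(n_genomes = 12L,
                           unique_families_per_genome = 20L, seed = s))
    rare <- rarefaction(planted_pangenome_matrix(prot),
                        iterations = 500, seed = s)
    fit <- fit_heaps(rare)
    expect_true(fit$open)
    expect_gt(fit$gamma_ci[["lower"]], 0.02)
  }
})

test_that("protein FASTA with genome|protein headers round-trips", {
  prot <- simulate_pangenome(
    pangenome_sim_config(n_genomes = 3L, core_families = 4L,
                         accessory_families = 2L,
                         unique_families_per_genome = 2L,
                         protein_length = 60L, seed = 4L))
  p <- withr::local_tempfile(fileext = ".faa")
  write_protein_fasta(prot, p)
  back <- read_protein_fasta(p)
  ord <- order(back$genome_id, back$protein_id)
  ord0 <- order(prot$genome_id, prot$protein_id)
  expect_identical(back$sequence[ord], prot$sequence[ord0])
  expect_identical(back$genome_id[ord], prot$genome_id[ord0])
})
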