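test_that("compute_bini reproduces hand-computable cases exactly", {
  cfg_mean <- bini_config(mode = "mean_all", tau = 900)
  cfg_thr <- bini_config(mode = "thresholded_sum", tau = 900)
  expect_equal(compute_bini(c(0, 0, 0), cfg_mean), 0)
  expect_equal(compute_bini(c(0, 0, 0), cfg_thr), 0)
  expect_equal(compute_bini(c(100, 200, 300), cfg_mean), 200)
  # only d > tau enter the numerator; n counts all three clusters
  expect_equal(compute_bini(c(1000, 500, 1400), cfg_thr), 800)
  # boundary: d == tau is not novel, so it drops from the thresholded sum
  expect_equal(compute_bini(c(900, 901), cfg_thr), 901 / 2)
  expect_error(compute_bini(numeric(), cfg_mean), class = "bini_undefined_score")
})

test_that("compute_bini invariances hold on 1000 random cases", {
  withr::local_seed(17)
  for (i in 1:1000) {
    d <- runif(sample(1:40, 1), 0, 2000)
    tau <- runif(1, 1, 1500)
    cfg_mean <- bini_config("mean_all", tau = tau)
    cfg_thr <- bini_config("thresholded_sum", tau = tau)
    m <- compute_bini(d, cfg_mean)
    t <- compute_bini(d, cfg_thr)
    # permutation invariance
    expect_identical(compute_bini(d[sample.int(length(d))], cfg_mean), m)
    # bounds and mode ordering
    expect_true(m >= min(d) - 1e-12 && m <= max(d) + 1e-12)
    expect_true(t <= m + 1e-12)
    # scaling covariance: scaling d and tau by c scales both scores by c
    c0 <- runif(1, 0.1, 10)
    expect_equal(compute_bini(c0 * d, bini_config("mean_all", tau = c0 * tau)),
                 c0 * m)
    expect_equal(compute_bini(c0 * d,
                              bini_config("thresholded_sum", tau = c0 * tau)),
                 c0 * t)
  }
})

test_that("score_strain composes featurization with the nearest oracle", {
  land <- simulate_landscape(landscape_config(n_gcfs = 8, seed = 3))
  ref <- build_reference(land$records, vocabulary = land$vocabulary)
  strains <- simulate_strains(
    land, strain_sim_config(n_strains = 1, novelty_fraction = 0.4, seed = 6))
  rec <- strains[[1]]
  res <- score_strain(rec, ref)
  expect_equal(res$n, nrow(rec))
  X <- featurize_records(rec, ref$vocabulary, ref$scaling, ref$cap)
  want <- vapply(seq_len(nrow(X)),
                 function(i) oracle_nearest(X[i, ], ref$centroids)$d, 1)
  expect_equal(unname(res$distances), want)
  expect_equal(res$bini, mean(want))
  expect_equal(res$novel_fraction, mean(want > ref$novelty_tau))
  expect_equal(sum(res$class_tally), res$n)
})

test_that("a member BGC identical to a centroid scores zero", {
  rec <- toy_records(list(c("A", "B", "C")))
  ref <- build_reference(rec, novelty_tau = 1)
  res <- score_strain(rec, ref, bini_config(tau = 1))
  expect_equal(res$n, 1L)
  expect_equal(res$bini, 0)
  expect_equal(res$novel_fraction, 0)
})

test_that("empty scope raises an undefined-score error, never zero", {
  rec <- toy_records(list(c("A", "B")), complete = FALSE)
  ref <- build_reference(toy_records(list(c("A", "B"))), novelty_tau = 1)
  expect_error(
    score_strain(rec, ref, bini_config(tau = 1,
                                       cluster_scope = "complete_only")),
    class = "bini_undefined_score")
})

test_that("scoring from a distance table is a pass-through to compute_bini", {
  tbl <- tibble::tibble(
    strain_id = rep(c("s1", "s2"), c(3, 2)),
    bgc_id = sprintf("b%d", 1:5),
    d = c(1000, 500, 1400, 10, 20), reference_tag = NA_character_)
  res <- score_from_distance_table(tbl, bini_config(tau = 900))
  expect_equal(res$s1$bini, mean(c(1000, 500, 1400)))
  expect_equal(res$s1$novel_fraction, 2 / 3)
  expect_equal(res$s2$bini, 15)
  thr <- score_from_distance_table(tbl,
                                   bini_config("thresholded_sum", tau = 900))
  expect_equal(thr$s1$bini, 800)
})

test_that("cohort summaries rank correctly and group means are exact", {
  mk <- function(id, bini) structure(
    list(strain_id = id, n = 10L, bini = bini, novel_fraction = 0.1),
    class = "strain_bini")
  res <- list(mk("a", 100), mk("b", 300), mk("c", 500))
  summ <- summarize_cohort(res, group_of = c(a = "g1", b = "g2", c = "g2"))
  expect_equal(summ$per_strain$strain_id, c("c", "b", "a"))
  expect_equal(summ$per_strain$rank, 1:3)
  g <- summ$groups
  expect_equal(g$mean_bini[g$group == "g1"], 100)
  expect_equal(g$mean_bini[g$group == "g2"], 400)
  # missing strains fall into "ungrouped"; single result is rank 1
  summ2 <- summarize_cohort(res[1], group_of = c(zzz = "g1"))
  expect_equal(summ2$per_strain$group, "ungrouped")
  expect_equal(summ2$groups$mean_bini, 100)
})

test_that("ranking is invariant to strain input order", {
  withr::local_seed(23)
  mk <- function(id, bini) structure(
    list(strain_id = id, n = 10L, bini = bini, novel_fraction = 0.1),
    class = "strain_bini")
  res <- lapply(1:12, function(i) mk(sprintf("s%02d", i), runif(1, 0, 500)))
  ranked <- summarize_cohort(res)$per_strain$strain_id
  for (i in 1:5) {
    expect_identical(summarize_cohort(sample(res))$per_strain$strain_id,
                     ranked)
  }
})

test_that("BiNI tracks planted novelty across a cohort (ranking property)", {
  land <- simulate_landscape(landscape_config(seed = 2))
  ref <- build_reference(land$records, vocabulary = land$vocabulary)
  strains <- simulate_strains(land, strain_sim_config(
    novelty_fraction = seq(0, 0.9, length.out = 20), seed = 12))
  res <- score_strains(do.call(biniR:::bind_bgc_records, unname(strains)), ref)
  pf <- vapply(strains, function(r) mean(r$planted_novel), 1)
  bi <- vapply(res, `[[`, 1, "bini")[names(pf)]
  expect_gte(cor(pf, bi, method = "spearman"), 0.9)
})

test_that("zero break rate leaves the fragmentation experiment at identity", {
  land <- simulate_landscape(landscape_config(n_gcfs = 6, seed = 8))
  ref <- build_reference(land$records, vocabulary = land$vocabulary)
  strains <- simulate_strains(land, strain_sim_config(n_strains = 3, seed = 4))
  fr <- fragmentation_experiment(strains, ref,
                                 frag_cfg = fragmentation_config(0),
                                 seeds = 1:2)
  expect_equal(fr$pairs$fragmented_bini, fr$pairs$intact_bini)
})

test_that("complete-only scope with every BGC broken reports undefined
           scores per strain without failing", {
  land <- simulate_landscape(landscape_config(n_gcfs = 6, seed = 8))
  ref <- build_reference(land$records, vocabulary = land$vocabulary)
  strains <- simulate_strains(land, strain_sim_config(n_strains = 2, seed = 4))
  fr <- fragmentation_experiment(
    strains, ref,
    cfg = bini_config(tau = ref$novelty_tau, cluster_scope = "complete_only"),
    frag_cfg = fragmentation_config(breaks_per_bgc = 50),
    seeds = 1)
  expect_true(all(is.na(fr$pairs$fragmented_bini)))
  expect_true(all(fr$pairs$note == "undefined_score"))
})

test_that("class tallies partition the records", {
  rec <- toy_records(list(c("A"), c("B"), c("C")),
                     product_class = c("NRPS", "NRPS", "terpene"))
  tally <- tally_classes(rec)
  expect_equal(sum(tally$count), 3)
  expect_equal(tally$count[tally$product_class == "NRPS"], 2L)
})
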