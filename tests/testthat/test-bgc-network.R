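test_that("raw distance matches hand-computed values", {
  cfg <- network_config()
  expect_equal(pairwise_raw_distance(c("A", "B", "C"), c("A", "B", "C"), cfg), 0)
  expect_equal(pairwise_raw_distance(c("A", "B"), c("X", "Y"), cfg), 1)
  # J = 2/4, AI = |{AB}| / |{AB, BC, BD}| = 1/3
  expect_equal(pairwise_raw_distance(c("A", "B", "C"), c("A", "B", "D"), cfg),
               1 - (0.7 * 0.5 + 0.3 * (1 / 3)))
  # both empty -> distance 1 by convention
  expect_equal(pairwise_raw_distance(character(), character(), cfg), 1)
  # single-domain records have no adjacency pairs: AI = 0 against anything
  expect_equal(pairwise_raw_distance("A", "A", cfg), 1 - 0.7)
})

test_that("raw distance is symmetric, bounded, and zero iff sets and
           adjacencies coincide", {
  withr::local_seed(31)
  cfg <- network_config()
  vocab <- sprintf("D%02d", 1:10)
  lists <- random_domain_lists(30, vocab, min_len = 1, max_len = 8)
  for (i in 1:30) {
    a <- lists[[sample(30, 1)]]
    b <- lists[[sample(30, 1)]]
    dab <- pairwise_raw_distance(a, b, cfg)
    expect_equal(dab, pairwise_raw_distance(b, a, cfg))
    expect_true(dab >= 0 && dab <= 1)
  }
  # same set + same adjacency pair set -> 0 even for different lists
  expect_equal(pairwise_raw_distance(c("A", "B", "A", "B"),
                                     c("B", "A", "B"), cfg), 0)
  # a repeated tail changes the adjacency pair set, so distance > 0
  expect_gt(pairwise_raw_distance(c("A", "B", "A", "B"), c("A", "B"), cfg), 0)
})

test_that("trivial networks behave as forced", {
  net <- build_network(toy_records(list(c("A", "B"), c("A", "B"))))
  expect_equal(nrow(net$edges), 1)
  expect_equal(length(unique(net$nodes$component_id)), 1)
  expect_false(any(net$nodes$singleton))

  net <- build_network(toy_records(list(c("A", "B"), c("C", "D"), c("E"))))
  expect_equal(nrow(net$edges), 0)
  expect_true(all(net$nodes$singleton))

  # fewer than 2 in-scope records: a network with no edges, not an error
  net <- build_network(toy_records(list(c("A", "B"))))
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 1)
})

test_that("incomplete records are excluded under the default scope", {
  rec <- toy_records(list(c("A", "B"), c("A", "B"), c("A", "B")),
                     complete = c(TRUE, TRUE, FALSE))
  net <- build_network(rec)
  expect_equal(nrow(net$nodes), 2)
  net_all <- build_network(rec, scope = "all_regions")
  expect_equal(nrow(net_all$nodes), 3)
})

test_that("edges and components match the exhaustive oracle on 60 records", {
  withr::local_seed(19)
  cfg <- network_config(cutoff = 0.5)
  vocab <- sprintf("D%02d", 1:12)
  recs <- toy_records(random_domain_lists(60, vocab, min_len = 2,
                                          max_len = 10))
  net <- build_network(recs, cfg)
  want <- oracle_network(recs, cfg)
  got_edges <- net$edges[order(net$edges$node_a, net$edges$node_b), ]
  expect_equal(nrow(got_edges), nrow(want$edges))
  expect_identical(got_edges$node_a, unname(want$edges[, 1]))
  expect_identical(got_edges$node_b, unname(want$edges[, 2]))
  # identical partitions: same label iff oracle assigns the same component
  got_comp <- setNames(net$nodes$component_id, net$nodes$bgc_id)
  ids <- names(want$components)
  same_got <- outer(got_comp[ids], got_comp[ids], "==")
  same_want <- outer(want$components, want$components, "==")
  expect_true(all(same_got == same_want))
  # degree-0 bookkeeping
  deg0 <- setdiff(ids, c(net$edges$node_a, net$edges$node_b))
  expect_setequal(net$nodes$bgc_id[net$nodes$singleton], deg0)
})

test_that("raising the cutoff never decreases the edge count", {
  withr::local_seed(37)
  recs <- toy_records(random_domain_lists(40, sprintf("D%02d", 1:10),
                                          min_len = 2, max_len = 8))
  cuts <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0)
  counts <- vapply(cuts, function(cf)
    nrow(build_network(recs, network_config(cutoff = cf))$edges), 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("every node sits in exactly one component", {
  withr::local_seed(41)
  recs <- toy_records(random_domain_lists(50, sprintf("D%02d", 1:14)))
  net <- build_network(recs, network_config(cutoff = 0.6))
  expect_equal(nrow(net$nodes), nrow(recs))
  sizes <- table(net$nodes$component_id)
  expect_equal(sum(sizes), nrow(recs))
  expect_false(anyNA(net$nodes$component_id))
})

test_that("reference annotation labels exactly the planted twin families", {
  withr::local_seed(43)
  vocab <- sprintf("D%03d", 1:200)
  # 12 disjoint families of 2 identical members each
  fam_doms <- lapply(1:12, function(i) vocab[((i - 1) * 12 + 1):(i * 12)])
  recs <- toy_records(rep(fam_doms, each = 2))
  net <- build_network(recs)
  expect_equal(length(unique(net$nodes$component_id)), 12)
  # reference twins for 5 of the 12 families
  twin_idx <- c(1, 3, 5, 7, 9)
  ref_recs <- bgc_records(
    strain_id = "mibig", bgc_id = sprintf("BGC%07d", twin_idx),
    start_bp = 0L, end_bp = 1000L, domains = fam_doms[twin_idx],
    planted_gcf = sprintf("known_family_%02d", twin_idx))
  ann <- annotate_with_reference(net, recs, ref_recs)
  expect_equal(sum(!is.na(ann$label)), 5)
  labelled_members <- net$nodes$bgc_id[net$nodes$component_id %in%
                                         ann$component_id[!is.na(ann$label)]]
  expect_setequal(labelled_members, recs$bgc_id[rep(1:12 %in% twin_idx,
                                                    each = 2)])
  # an exact twin is labelled at distance 0 with its own family name
  exact <- ann[!is.na(ann$label), ]
  expect_true(all(exact$distance == 0))
  expect_setequal(exact$label, sprintf("known_family_%02d", twin_idx))
  # empty reference: no labels
  ann0 <- annotate_with_reference(net, recs, ref_recs[0, ])
  expect_true(all(is.na(ann0$label)))
})
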