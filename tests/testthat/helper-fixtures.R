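# Shared fixtures and independent oracles. The oracles are deliberately
# naive (loops, exhaustive scans) so they exercise none of the package's
# vectorized code paths.

# brute-force nearest-centroid scan: O(n * k) loop with explicit
# min-tracking and lexicographic tie-break
oracle_nearest <- function(x, centroids) {
  best_d <- Inf
  best_id <- NA_character_
  for (id in rownames(centroids)) {
    d <- sqrt(sum((x - centroids[id, ])^2))
    if (d < best_d || (d == best_d && id < best_id)) {
      best_d <- d
      best_id <- id
    }
  }
  list(gcf_id = best_id, d = best_d)
}

# exhaustive O(n^2) edge scan + transitive closure for components
oracle_network <- function(records, cfg) {
  n <- nrow(records)
  edges <- list()
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- pairwise_raw_distance(records$domains[[i]],
                                   records$domains[[j]], cfg)
        if (d <= cfg$cutoff) {
          edges[[length(edges) + 1L]] <-
            sort(c(records$bgc_id[i], records$bgc_id[j]))
          adj[i, j] <- adj[j, i] <- TRUE
        }
      }
    }
  }
  # transitive closure by repeated boolean multiplication
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[adj[i, ]] <- cid
    }
  }
  list(
    edges = if (length(edges)) {
      do.call(rbind, edges)[order(vapply(edges, paste, "", collapse = "\r")), ,
                            drop = FALSE]
    } else matrix(character(), ncol = 2),
    components = setNames(comp, records$bgc_id)
  )
}

# small hand-buildable record tables
toy_records <- function(domains, strain_id = "s1", complete = TRUE,
                        product_class = "other") {
  bgc_records(
    strain_id = strain_id,
    bgc_id = sprintf("%s_b%02d", strain_id, seq_along(domains)),
    start_bp = 0L, end_bp = 1000L,
    product_class = product_class, complete = complete, domains = domains)
}

# random domain lists over a toy vocabulary
random_domain_lists <- function(n, vocab, min_len = 3, max_len = 12) {
  lapply(seq_len(n), function(i) {
    sample(vocab, sample(min_len:max_len, 1), replace = TRUE)
  })
}
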