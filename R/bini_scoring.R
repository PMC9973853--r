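# BiNI scoring: per-strain biosynthetic novelty index BiNI = sum(d)/n,
# cohort summaries and rankings, product-class tallies, and the
# assembly-fragmentation robustness experiment.

#' BiNI scoring configuration
#'
#' `mode` selects how distances enter the numerator: `mean_all` (default)
#' is the plain mean sum(d)/n over all in-scope clusters; `thresholded_sum`
#' keeps only distances strictly above `tau` in the numerator while n still
#' counts every in-scope cluster. `cluster_scope` selects whether n counts
#' all antiSMASH regions (`all_regions`, default) or only clusters not
#' truncated by a contig edge (`complete_only`).
#'
#' @param mode `"mean_all"` or `"thresholded_sum"`.
#' @param tau novelty threshold used for `novel_fraction` and for the
#'   `thresholded_sum` numerator (900 on the BiG-FAM distance scale;
#'   [calibrate_tau()] for local references).
#' @param cluster_scope `"all_regions"` or `"complete_only"`.
#' @return a `bini_config` list.
#' @export
bini_config <- function(mode = c("mean_all", "thresholded_sum"), tau,
                        cluster_scope = c("all_regions", "complete_only")) {
  mode <- match.arg(mode)
  cluster_scope <- match.arg(cluster_scope)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("tau must be a positive scalar")
  }
  structure(list(mode = mode, tau = tau, cluster_scope = cluster_scope),
            class = "bini_config")
}

#' Compute the biosynthetic novelty index from distances
#'
#' BiNI = sum(d) / n, with n the number of in-scope clusters. In
#' `thresholded_sum` mode only distances strictly greater than `cfg$tau`
#' enter the numerator, but n is unchanged, so the thresholded score is
#' never larger than the plain mean.
#'
#' @param distances non-negative nearest-GCF distances, one per cluster.
#' @param cfg a [bini_config()].
#' @return the BiNI score (scalar).
#' @export
compute_bini <- function(distances, cfg) {
  n <- length(distances)
  if (n == 0L) {
    stop(undefined_score_error("(no strain)", "no distances supplied"))
  }
  if (any(distances < 0)) stop("distances must be non-negative")
  num <- switch(cfg$mode,
    mean_all = sum(distances),
    thresholded_sum = sum(distances[distances > cfg$tau])
  )
  num / n
}

undefined_score_error <- function(strain_id, reason) {
  structure(
    class = c("bini_undefined_score", "error", "condition"),
    list(message = sprintf(
      "BiNI undefined for strain '%s': %s (a score of 0 would mis-rank)",
      strain_id, reason),
      call = NULL, strain_id = strain_id)
  )
}

#' Score one strain's BGC repertoire
#'
#' Filters the strain's records to the configured scope, featurizes them on
#' the reference vocabulary, takes each record's nearest-GCF distance, and
#' assembles the per-strain result: n, the distances, BiNI, the fraction of
#' clusters beyond tau, and the product-class tally.
#'
#' A strain with zero in-scope clusters raises a `bini_undefined_score`
#' condition rather than returning 0.
#'
#' @param records [bgc_records] for a single strain.
#' @param ref a `gcf_reference`.
#' @param cfg a [bini_config()]; defaults to `mean_all` over all regions
#'   with the reference's calibrated tau.
#' @return a `strain_bini` list: `strain_id`, `n`, `distances`,
#'   `nearest_gcf`, `bini`, `novel_fraction`, `class_tally`, `mode`,
#'   `cluster_scope`, `tau`.
#' @export
score_strain <- function(records, ref, cfg = NULL) {
  if (is.null(cfg)) cfg <- bini_config(tau = ref$novelty_tau)
  sid <- unique(records$strain_id)
  if (length(sid) != 1L) stop("score_strain expects records from one strain")
  if (cfg$cluster_scope == "complete_only") {
    records <- records[records$complete, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop(undefined_score_error(sid, paste0("no clusters in scope '",
                                           cfg$cluster_scope, "'")))
  }
  X <- featurize_records(records, ref$vocabulary, ref$scaling, ref$cap)
  nn <- nearest_gcf_distances(X, ref)
  d <- nn$d
  tally <- table(factor(records$product_class, levels = product_classes))
  structure(list(
    strain_id = sid,
    n = nrow(records),
    distances = setNames(d, records$bgc_id),
    nearest_gcf = setNames(nn$gcf_id, records$bgc_id),
    bini = compute_bini(d, cfg),
    novel_fraction = mean(d > cfg$tau),
    class_tally = tally,
    mode = cfg$mode, cluster_scope = cfg$cluster_scope, tau = cfg$tau
  ), class = "strain_bini")
}

#' @export
print.strain_bini <- function(x, ...) {
  cat(sprintf(
    "<strain_bini> %s: n = %d, BiNI = %.4g (%s, %s), novel fraction %.2f\n",
    x$strain_id, x$n, x$bini, x$mode, x$cluster_scope, x$novel_fraction))
  invisible(x)
}

#' Score every strain in a record table
#'
#' @param records [bgc_records] covering one or more strains.
#' @inheritParams score_strain
#' @return list of `strain_bini` results, named by strain.
#' @export
score_strains <- function(records, ref, cfg = NULL) {
  sids <- unique(records$strain_id)
  setNames(lapply(sids, function(s)
    score_strain(records[records$strain_id == s, , drop = FALSE], ref, cfg)),
    sids)
}

#' Score strains from an external distance table
#'
#' Bypasses featurization entirely: the d values of an ingested table
#' (e.g. a BiG-FAM query export, where tau = 900) are grouped by strain and
#' passed to [compute_bini()].
#'
#' @param tbl a tibble from [read_distance_table()].
#' @param cfg a [bini_config()]; for true BiG-FAM distances use
#'   `bini_config(tau = 900)`.
#' @return list of `strain_bini` results (class tallies unavailable).
#' @export
score_from_distance_table <- function(tbl, cfg) {
  sids <- unique(tbl$strain_id)
  setNames(lapply(sids, function(s) {
    rows <- tbl[tbl$strain_id == s, , drop = FALSE]
    d <- setNames(rows$d, rows$bgc_id)
    structure(list(
      strain_id = s, n = length(d), distances = d, nearest_gcf = NULL,
      bini = compute_bini(d, cfg), novel_fraction = mean(d > cfg$tau),
      class_tally = NULL, mode = cfg$mode, cluster_scope = "all_regions",
      tau = cfg$tau
    ), class = "strain_bini")
  }), sids)
}

#' Summarize and rank a scored cohort
#'
#' Produces the per-strain table ranked by BiNI (descending, ties broken by
#' strain id), plus per-group means and medians of the strain scores.
#' Strains absent from `group_of` are assigned to group `"ungrouped"`.
#'
#' @param results list of `strain_bini` results.
#' @param group_of named character vector mapping strain id to group label
#'   (e.g. genus); may be `NULL` for a single implicit group.
#' @return a `cohort_summary` list: `per_strain` (ranked tibble), `groups`
#'   (tibble of group, n_strains, mean_bini, median_bini).
#' @export
summarize_cohort <- function(results, group_of = NULL) {
  if (!length(results)) stop("no results to summarize")
  per <- tibble::tibble(
    strain_id = vapply(results, `[[`, "", "strain_id"),
    group = NA_character_,
    n = vapply(results, `[[`, 1L, "n"),
    bini = vapply(results, `[[`, 1, "bini"),
    novel_fraction = vapply(results, `[[`, 1, "novel_fraction")
  )
  per$group <- if (is.null(group_of)) "all" else {
    g <- unname(group_of[per$strain_id])
    ifelse(is.na(g), "ungrouped", g)
  }
  per <- per[order(-per$bini, per$strain_id, method = "radix"), ]
  per$rank <- seq_len(nrow(per))
  groups <- do.call(rbind, lapply(split(per, per$group), function(gp) {
    tibble::tibble(group = gp$group[1], n_strains = nrow(gp),
                   mean_bini = mean(gp$bini), median_bini = median(gp$bini))
  }))
  groups <- groups[order(-groups$mean_bini, groups$group), ]
  structure(list(per_strain = per, groups = tibble::as_tibble(groups)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d strains in %d groups; top strain %s (BiNI %.4g)\n",
              nrow(x$per_strain), nrow(x$groups),
              x$per_strain$strain_id[1], x$per_strain$bini[1]))
  invisible(x)
}

#' Assembly-fragmentation robustness experiment
#'
#' Measures how contig fragmentation depresses BiNI. Each strain is scored
#' intact, then its records are fragmented with [fragment_records()]
#' (Poisson contig breaks inside each cluster) and re-scored, once per
#' seed. Because fragments of a far-from-everything cluster tend to land
#' near small common families, fragmented scores are expected to drop --
#' the mechanism by which low-quality assemblies understate biosynthetic
#' novelty.
#'
#' @param strain_records list of [bgc_records] tibbles, one per strain (or
#'   a single tibble, split by strain).
#' @param ref a `gcf_reference`.
#' @param cfg a [bini_config()]; `all_regions` scope is the meaningful
#'   choice, since fragments are incomplete by construction.
#' @param frag_cfg a [fragmentation_config()].
#' @param seeds integer vector of fragmentation seeds.
#' @return a `fragmentation_result` list: `pairs` (tibble strain_id, seed,
#'   intact_bini, fragmented_bini, note), `sign_test` (one-sided binomial
#'   test that fragmented < intact), `medians` (per-seed medians).
#' @export
fragmentation_experiment <- function(strain_records, ref, cfg = NULL,
                                     frag_cfg = fragmentation_config(),
                                     seeds = 1:10) {
  if (is.data.frame(strain_records)) {
    strain_records <- split(strain_records, strain_records$strain_id)
  }
  if (is.null(cfg)) cfg <- bini_config(tau = ref$novelty_tau)
  intact <- vapply(strain_records, function(r)
    score_strain(validate_bgc_records(tibble::as_tibble(r)), ref, cfg)$bini, 1)
  rows <- list()
  for (seed in seeds) {
    for (i in seq_along(strain_records)) {
      rec <- validate_bgc_records(tibble::as_tibble(strain_records[[i]]))
      frag <- fragment_records(rec, frag_cfg, seed = seed)
      fb <- tryCatch(score_strain(frag, ref, cfg)$bini,
                     bini_undefined_score = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        strain_id = rec$strain_id[1], seed = seed,
        intact_bini = unname(intact[i]), fragmented_bini = fb,
        note = if (is.na(fb)) "undefined_score" else NA_character_)
    }
  }
  pairs <- do.call(rbind, rows)
  ok <- !is.na(pairs$fragmented_bini)
  st <- if (any(ok)) {
    binom.test(sum(pairs$fragmented_bini[ok] < pairs$intact_bini[ok]),
               sum(ok), alternative = "greater")
  } else NULL
  med <- do.call(rbind, lapply(split(pairs, pairs$seed), function(p) {
    tibble::tibble(seed = p$seed[1],
                   median_intact = median(p$intact_bini, na.rm = TRUE),
                   median_fragmented = median(p$fragmented_bini, na.rm = TRUE))
  }))
  structure(list(pairs = pairs, sign_test = st,
                 medians = tibble::as_tibble(med)),
            class = "fragmentation_result")
}

#' @export
print.fragmentation_result <- function(x, ...) {
  frac <- mean(x$medians$median_fragmented < x$medians$median_intact)
  cat(sprintf(
    "<fragmentation_result> %d strain-seed pairs; fragmented < intact medians in %.0f%% of seeds\n",
    nrow(x$pairs), 100 * frac))
  invisible(x)
}

#' Tally BGC product classes across strains
#'
#' @param records a [bgc_records] tibble.
#' @param by_strain if `TRUE`, one row per strain; otherwise pooled counts.
#' @return tibble of class counts over the seven-class scheme.
#' @export
tally_classes <- function(records, by_strain = FALSE) {
  if (by_strain) {
    do.call(rbind, lapply(split(records, records$strain_id), function(r) {
      tab <- table(factor(r$product_class, levels = product_classes))
      tibble::tibble(strain_id = r$strain_id[1],
                     product_class = names(tab), count = as.integer(tab))
    })) -> out
    tibble::as_tibble(out)
  } else {
    tab <- table(factor(records$product_class, levels = product_classes))
    tibble::tibble(product_class = names(tab), count = as.integer(tab))
  }
}
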