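# BGC similarity networks: pairwise raw distances on complete clusters,
# edges at a fixed cutoff, connected components as gene cluster families,
# degree-0 nodes as singletons, and annotation against a reference
# (MIBiG-style) collection.

#' Network construction configuration
#'
#' The raw distance between two BGCs combines the Jaccard similarity of
#' their domain sets with the Jaccard similarity of their adjacent ordered
#' domain pairs. The domain sequence similarity term of the full BiG-SCAPE
#' raw distance needs per-domain alignments and is deliberately omitted;
#' the two remaining weights are renormalized to sum to 1.
#'
#' @param cutoff edge threshold on the raw distance, in (0, 1]; an edge is
#'   drawn when distance <= cutoff (inclusive). Default 0.3.
#' @param w_jaccard,w_adjacency non-negative weights for the domain-set and
#'   adjacency components; must sum to 1. Defaults 0.7 / 0.3.
#' @return a `network_config` list.
#' @export
network_config <- function(cutoff = 0.3, w_jaccard = 0.7, w_adjacency = 0.3) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (w_jaccard < 0 || w_adjacency < 0 ||
      abs(w_jaccard + w_adjacency - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  structure(list(cutoff = cutoff, w_jaccard = w_jaccard,
                 w_adjacency = w_adjacency),
            class = "network_config")
}

#' Raw distance between two BGCs
#'
#' distance = 1 - (w_jaccard * J + w_adjacency * AI), where J is the
#' Jaccard index of the two domain sets and AI the Jaccard index of the
#' sets of adjacent ordered domain pairs (genomic order). Two records with
#' empty domain lists are at distance 1 by convention; a single-domain
#' record has no adjacent pairs, so AI = 0 against anything.
#'
#' @param a,b character vectors of domain identifiers in genomic order (or
#'   single rows of a [bgc_records] tibble).
#' @param cfg a [network_config()].
#' @return distance in \[0, 1\].
#' @export
pairwise_raw_distance <- function(a, b, cfg = network_config()) {
  if (is.data.frame(a)) a <- a$domains[[1]]
  if (is.data.frame(b)) b <- b$domains[[1]]
  J <- jaccard(unique(a), unique(b))
  AI <- jaccard(adjacent_pairs(a), adjacent_pairs(b))
  1 - (cfg$w_jaccard * J + cfg$w_adjacency * AI)
}

jaccard <- function(x, y) {
  u <- length(union(x, y))
  if (u == 0L) return(0)          # both empty: similarity 0, distance 1
  length(intersect(x, y)) / u
}

adjacent_pairs <- function(d) {
  if (length(d) < 2L) return(character())
  unique(paste(d[-length(d)], d[-1], sep = "\r"))
}

#' Build a BGC similarity network
#'
#' Computes all pairwise raw distances among the in-scope records (complete
#' clusters by default, mirroring networks built only with complete BGCs),
#' draws an undirected edge wherever distance <= cutoff, labels connected
#' components as gene cluster families, and reports degree-0 nodes as
#' singletons -- clusters with no neighbor within the cutoff, the
#' candidates for novel chemistry.
#'
#' @param records a [bgc_records] tibble.
#' @param cfg a [network_config()].
#' @param scope `"complete_only"` (default) or `"all_regions"`.
#' @return a `bgc_network` list: `nodes` (tibble bgc_id, strain, class,
#'   component_id, singleton), `edges` (tibble node_a, node_b,
#'   raw_distance with node_a < node_b), `cutoff`.
#' @export
build_network <- function(records, cfg = network_config(),
                          scope = c("complete_only", "all_regions")) {
  scope <- match.arg(scope)
  if (scope == "complete_only") {
    records <- records[records$complete, , drop = FALSE]
  }
  n <- nrow(records)
  ids <- records$bgc_id
  ea <- character(); eb <- character(); ed <- numeric()
  if (n >= 2L) {
    pairsets <- lapply(records$domains, function(d) unique(d))
    adjsets <- lapply(records$domains, adjacent_pairs)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        J <- jaccard(pairsets[[i]], pairsets[[j]])
        AI <- jaccard(adjsets[[i]], adjsets[[j]])
        dist <- 1 - (cfg$w_jaccard * J + cfg$w_adjacency * AI)
        if (dist <= cfg$cutoff) {
          a <- ids[i]; b <- ids[j]
          if (a > b) { tmp <- a; a <- b; b <- tmp }
          ea <- c(ea, a); eb <- c(eb, b); ed <- c(ed, dist)
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ea, to = eb, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  # stable component ids: number components by their smallest member id
  comp_min <- vapply(split(names(comp), comp), min, "")
  relabel <- setNames(sprintf("FAM_%04d", rank(comp_min)),
                      names(comp_min))
  component_id <- unname(relabel[as.character(comp[ids])])
  deg <- igraph::degree(g)[ids]
  structure(list(
    nodes = tibble::tibble(
      bgc_id = ids, strain = records$strain_id,
      class = records$product_class,
      component_id = component_id, singleton = unname(deg) == 0),
    edges = tibble::tibble(node_a = ea, node_b = eb, raw_distance = ed),
    cutoff = cfg$cutoff
  ), class = "bgc_network")
}

#' @export
print.bgc_network <- function(x, ...) {
  cat(sprintf(
    "<bgc_network> %d nodes, %d edges (cutoff %.2f), %d families, %d singletons\n",
    nrow(x$nodes), nrow(x$edges), x$cutoff,
    length(unique(x$nodes$component_id)), sum(x$nodes$singleton)))
  invisible(x)
}

#' Annotate network families against a reference collection
#'
#' Labels a connected component with a known family (e.g. a MIBiG entry)
#' when any member BGC lies within the network cutoff of any reference
#' record; among qualifying reference records the nearest wins, with ties
#' broken by the lexicographically smallest label. Components with no
#' reference neighbor stay unlabelled -- in practice most do, which is what
#' makes a collection look novel.
#'
#' @param net a `bgc_network` from [build_network()].
#' @param records the same records the network was built from (domain
#'   lists are needed to compute distances).
#' @param reference_records a [bgc_records] tibble whose `planted_gcf`
#'   column (or `bgc_id` as fallback) carries the known family label.
#' @param cfg the [network_config()] used to build the network.
#' @return tibble: `component_id`, `label` (NA when unmatched),
#'   `distance`.
#' @export
annotate_with_reference <- function(net, records, reference_records,
                                    cfg = network_config()) {
  comps <- sort(unique(net$nodes$component_id))
  labs <- reference_records$planted_gcf
  if (all(is.na(labs))) labs <- reference_records$bgc_id
  out <- lapply(comps, function(cid) {
    members <- net$nodes$bgc_id[net$nodes$component_id == cid]
    rows <- records[match(members, records$bgc_id), , drop = FALSE]
    best_d <- Inf; best_lab <- NA_character_
    if (nrow(reference_records)) {
      for (i in seq_len(nrow(rows))) {
        for (j in seq_len(nrow(reference_records))) {
          dd <- pairwise_raw_distance(rows$domains[[i]],
                                      reference_records$domains[[j]], cfg)
          lab <- labs[j]
          if (dd < best_d || (dd == best_d && !is.na(best_lab) &&
                              lab < best_lab)) {
            best_d <- dd; best_lab <- lab
          }
        }
      }
    }
    matched <- is.finite(best_d) && best_d <= cfg$cutoff
    tibble::tibble(component_id = cid,
                   label = if (matched) best_lab else NA_character_,
                   distance = if (is.finite(best_d)) best_d else NA_real_)
  })
  do.call(rbind, out)
}
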