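# TSV/JSON plumbing: externally computed distance tables (e.g. BiG-FAM
# query exports), network edge/node lists, GCF reference serialization.

#' Read an external per-BGC distance table
#'
#' Tab-separated with header columns `strain_id`, `bgc_id`, `d` and an
#' optional `reference_tag`. These are nearest-GCF distances computed by an
#' external platform (e.g. BiG-FAM, where the novelty line is d > 900);
#' they can be fed straight into [compute_bini()] via
#' [score_from_distance_table()].
#'
#' @param path TSV file.
#' @return a tibble with columns `strain_id`, `bgc_id`, `d`,
#'   `reference_tag`.
#' @export
read_distance_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("strain_id", "bgc_id", "d")
  if (!all(need %in% names(df))) {
    stop("validation error: distance table needs columns ",
         paste(need, collapse = ", "))
  }
  df$d <- as.numeric(df$d)
  if (anyNA(df$d)) stop("validation error: non-numeric d")
  if (any(df$d < 0)) stop("validation error: negative d")
  key <- paste(df$strain_id, df$bgc_id)
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (strain_id, bgc_id): ",
         key[duplicated(key)][1])
  }
  if (is.null(df$reference_tag)) df$reference_tag <- NA_character_
  tibble::as_tibble(df[, c("strain_id", "bgc_id", "d", "reference_tag")])
}

#' @rdname read_distance_table
#' @param tbl a distance-table tibble.
#' @export
write_distance_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a BGC network as edge and node TSVs
#'
#' Serializes a [build_network()] result as two tab-separated files: an
#' edge list (`node_a`, `node_b`, `raw_distance`; `node_a < node_b`) and a
#' node attribute table (`bgc_id`, `strain`, `class`, `component_id`,
#' `singleton`). Rows are written in lexicographic order so output is
#' deterministic.
#'
#' @param net a `bgc_network` object.
#' @param edge_path,node_path output TSV paths.
#' @return invisibly, a list with the two paths.
#' @export
write_network_edgelist <- function(net, edge_path, node_path) {
  edges <- net$edges[order(net$edges$node_a, net$edges$node_b), , drop = FALSE]
  nodes <- net$nodes[order(net$nodes$bgc_id), , drop = FALSE]
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(edge_path = edge_path, node_path = node_path))
}

#' @rdname write_network_edgelist
#' @export
read_network_edgelist <- function(edge_path, node_path) {
  edges <- tibble::as_tibble(utils::read.delim(edge_path, sep = "\t",
                                               stringsAsFactors = FALSE))
  nodes <- tibble::as_tibble(utils::read.delim(node_path, sep = "\t",
                                               stringsAsFactors = FALSE))
  list(edges = edges, nodes = nodes)
}

#' Serialize a GCF reference to JSON
#'
#' Stores the centroid matrix, feature space (vocabulary plus the reserved
#' unknown bin), per-model membership statistics and the thresholds, so a
#' reference built once can be re-used to score new strains.
#'
#' @param ref a `gcf_reference` from [build_reference()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_gcf_reference()` returns the
#'   `gcf_reference`.
#' @export
write_gcf_reference <- function(ref, path) {
  obj <- list(
    vocabulary = ref$vocabulary,
    scaling = ref$scaling,
    cap = ref$cap,
    build_threshold = ref$build_threshold,
    novelty_tau = ref$novelty_tau,
    models = lapply(seq_len(nrow(ref$models)), function(i) {
      list(gcf_id = ref$models$gcf_id[i],
           n_members = ref$models$n_members[i],
           member_radius_p95 = ref$models$member_radius_p95[i],
           centroid = unname(ref$centroids[i, ]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gcf_reference
#' @export
read_gcf_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  vocab <- as.character(unlist(obj$vocabulary))
  cents <- do.call(rbind, lapply(obj$models, function(m)
    as.numeric(unlist(m$centroid))))
  rownames(cents) <- vapply(obj$models, `[[`, "", "gcf_id")
  colnames(cents) <- feature_names(vocab)
  structure(list(
    models = tibble::tibble(
      gcf_id = vapply(obj$models, `[[`, "", "gcf_id"),
      n_members = vapply(obj$models, function(m) as.integer(m$n_members), 1L),
      member_radius_p95 = vapply(obj$models, function(m)
        as.numeric(m$member_radius_p95), 1)
    ),
    centroids = cents,
    vocabulary = vocab,
    scaling = as.character(obj$scaling),
    cap = if (is.null(obj$cap)) 5 else as.numeric(obj$cap),
    build_threshold = as.numeric(obj$build_threshold),
    novelty_tau = as.numeric(obj$novelty_tau)
  ), class = "gcf_reference")
}
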