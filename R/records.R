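#' Construct a table of BGC records
#'
#' The package-wide container for detected biosynthetic gene clusters: one
#' row per cluster, with the domain content kept as a list-column of domain
#' identifiers in genomic order. Coordinates are 0-based half-open, so
#' `end_bp - start_bp` is the cluster length.
#'
#' @param strain_id,bgc_id,contig_id character vectors, recycled to the
#'   number of records. `bgc_id` must be unique within the table.
#' @param start_bp,end_bp integer coordinates, 0-based half-open
#'   (`start_bp < end_bp`).
#' @param product_class one of `"NRPS"`, `"PKS"`, `"hybrid"`, `"terpene"`,
#'   `"RiPP"`, `"saccharide"`, `"other"`.
#' @param complete logical; `FALSE` when the cluster runs off a contig edge
#'   (antiSMASH `contig_edge="True"`).
#' @param domains list of character vectors, domain identifiers in genomic
#'   order (repeats allowed; may be empty).
#' @param planted_novel,planted_gcf optional ground-truth labels recorded by
#'   the synthetic-data generators; `NA` for real data.
#' @return a tibble of class `bgc_records`.
#' @export
bgc_records <- function(strain_id, bgc_id, contig_id = bgc_id,
                        start_bp = 0L, end_bp = 1L,
                        product_class = "other", complete = TRUE,
                        domains = list(character()),
                        planted_novel = NA, planted_gcf = NA_character_) {
  out <- tibble::tibble(
    strain_id = as.character(strain_id),
    bgc_id = as.character(bgc_id),
    contig_id = as.character(contig_id),
    start_bp = as.integer(start_bp),
    end_bp = as.integer(end_bp),
    product_class = as.character(product_class),
    complete = as.logical(complete),
    domains = domains,
    planted_novel = as.logical(planted_novel),
    planted_gcf = as.character(planted_gcf)
  )
  validate_bgc_records(out)
}

product_classes <- c("NRPS", "PKS", "hybrid", "terpene", "RiPP",
                     "saccharide", "other")

validate_bgc_records <- function(x) {
  stopifnot(is.data.frame(x))
  if (anyDuplicated(x$bgc_id)) {
    stop("duplicate bgc_id: ", x$bgc_id[duplicated(x$bgc_id)][1])
  }
  if (any(x$start_bp >= x$end_bp)) {
    stop("start_bp must be < end_bp (0-based half-open coordinates)")
  }
  bad <- setdiff(unique(x$product_class), product_classes)
  if (length(bad)) stop("unknown product_class: ", paste(bad, collapse = ", "))
  if (!is.list(x$domains)) stop("domains must be a list-column")
  class(x) <- unique(c("bgc_records", class(x)))
  x
}

#' @export
print.bgc_records <- function(x, ...) {
  cat(sprintf("<bgc_records> %d clusters, %d strains, %d complete\n",
              nrow(x), length(unique(x$strain_id)), sum(x$complete)))
  NextMethod()
}

# rbind that keeps the class; used by generators and fragmentation
bind_bgc_records <- function(...) {
  pieces <- list(...)
  pieces <- pieces[vapply(pieces, NROW, 1L) > 0L]
  if (!length(pieces)) {
    return(bgc_records(character(), character())[0, ])
  }
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  validate_bgc_records(tibble::as_tibble(out))
}
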