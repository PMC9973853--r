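# Domain-composition feature space. Each BGC becomes a fixed-length
# non-negative vector over a domain vocabulary plus one reserved bin that
# accumulates domains absent from the vocabulary, so unrecognized content
# raises (never hides) novelty.

UNKNOWN_BIN <- "__unknown__"

feature_names <- function(vocabulary) c(vocabulary, UNKNOWN_BIN)

#' Build a domain vocabulary from BGC records
#'
#' The vocabulary is the sorted union of all domain identifiers seen in the
#' records, so it is deterministic and invariant to record order.
#'
#' @param records a [bgc_records] tibble.
#' @return character vector of unique domain identifiers, sorted.
#' @export
build_vocabulary <- function(records) {
  doms <- unique(unlist(records$domains, use.names = FALSE))
  if (is.null(doms) || !length(doms)) {
    stop("all records are domain-free; supply annotated or synthetic input")
  }
  sort(doms, method = "radix")
}

#' Featurize a BGC's domain content
#'
#' Counts domain occurrences over `vocabulary` (domains not in the
#' vocabulary are pooled into a reserved unknown bin appended as the last
#' coordinate), then applies the chosen scaling: `raw_count` keeps
#' multiplicities, `capped` truncates each count at `cap` (the default; a
#' single giant multi-module PKS should not dominate every distance), and
#' `unit_l2` divides raw counts by their Euclidean norm.
#'
#' @param domains character vector of domain identifiers (one BGC, genomic
#'   order; order does not affect the result), or a single row of a
#'   [bgc_records] tibble.
#' @param vocabulary character vector from [build_vocabulary()].
#' @param scaling one of `"capped"`, `"raw_count"`, `"unit_l2"`.
#' @param cap truncation level for `capped` scaling.
#' @return named numeric vector of length `length(vocabulary) + 1`.
#' @export
featurize <- function(domains, vocabulary,
                      scaling = c("capped", "raw_count", "unit_l2"),
                      cap = 5) {
  scaling <- match.arg(scaling)
  if (is.data.frame(domains)) domains <- domains$domains[[1]]
  nm <- feature_names(vocabulary)
  v <- setNames(numeric(length(nm)), nm)
  if (length(domains)) {
    known <- domains %in% vocabulary
    if (any(known)) {
      tab <- table(domains[known])
      v[names(tab)] <- as.numeric(tab)
    }
    v[UNKNOWN_BIN] <- sum(!known)
  }
  switch(scaling,
    raw_count = v,
    capped = pmin(v, cap),
    unit_l2 = {
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) v / nrm else v
    }
  )
}

#' Featurize every record into a matrix
#'
#' @param records a [bgc_records] tibble.
#' @inheritParams featurize
#' @return numeric matrix, one row per record (rownames = `bgc_id`), one
#'   column per feature.
#' @export
featurize_records <- function(records, vocabulary, scaling = "capped",
                              cap = 5) {
  m <- t(vapply(records$domains,
                function(d) featurize(d, vocabulary, scaling, cap),
                numeric(length(vocabulary) + 1L)))
  rownames(m) <- records$bgc_id
  m
}
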