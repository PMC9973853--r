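# Pan-genome stage: greedy protein family clustering at 0.5 identity,
# presence/absence matrix, core/accessory/unique partition, rarefaction
# over random genome orderings, and a Heaps' law fit that calls the
# pan-genome open or closed.

#' Construct a protein record table
#'
#' @param genome_id,protein_id character vectors; the pair must be unique.
#' @param sequence amino-acid sequences (non-empty).
#' @param planted_family optional ground-truth family labels (synthetic
#'   data only).
#' @return a tibble of class `protein_records`.
#' @export
protein_records <- function(genome_id, protein_id, sequence,
                            planted_family = NA_character_) {
  out <- tibble::tibble(
    genome_id = as.character(genome_id),
    protein_id = as.character(protein_id),
    sequence = toupper(as.character(sequence)),
    planted_family = as.character(planted_family)
  )
  if (any(nchar(out$sequence) == 0L)) stop("empty protein sequence")
  key <- paste(out$genome_id, out$protein_id)
  if (anyDuplicated(key)) {
    stop("duplicate (genome_id, protein_id): ", key[duplicated(key)][1])
  }
  class(out) <- unique(c("protein_records", class(out)))
  out
}

#' Read proteins from FASTA with `genome|protein` headers
#'
#' @param path FASTA file whose headers are `>genome_id|protein_id`.
#' @return a `protein_records` tibble.
#' @export
read_protein_fasta <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("format error: protein headers must be 'genome|protein'")
  }
  protein_records(
    genome_id = vapply(parts, `[[`, "", 1L),
    protein_id = vapply(parts, function(p) paste(p[-1], collapse = "|"), ""),
    sequence = as.character(seqs)
  )
}

#' @rdname read_protein_fasta
#' @param proteins a `protein_records` tibble.
#' @export
write_protein_fasta <- function(proteins, path) {
  seqs <- setNames(proteins$sequence,
                   paste(proteins$genome_id, proteins$protein_id, sep = "|"))
  write_fasta(seqs, path)
}

# identity substitution matrix over A-Z: match +1, mismatch 0
identity_submat <- local({
  m <- diag(1, 26)
  dimnames(m) <- list(LETTERS, LETTERS)
  m
})

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and a
#' linear gap penalty of 1 per gap column; identity is the number of
#' matched columns divided by the alignment length (including gap
#' columns). This is the similarity underlying the 0.5 clustering
#' threshold.
#'
#' @param a,b non-empty sequences (amino-acid or nucleotide).
#' @return identity in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    toupper(a), toupper(b), type = "global",
    substitutionMatrix = identity_submat, gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

# identity of one query against several centroid sequences in one call
identities_vs <- function(query, centroids) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(centroids), Biostrings::AAString(query),
    type = "global", substitutionMatrix = identity_submat,
    gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

kmer_set <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(s)
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Cluster proteins into families by greedy centroid clustering
#'
#' usearch-style greedy clustering: records are processed in deterministic
#' order (descending length, then genome and protein id); each record
#' joins the first existing family whose centroid identity is at least
#' `threshold`, otherwise it founds a new family with itself as centroid.
#' A word filter skips the alignment against centroids sharing fewer than
#' `min_shared_kmers` 4-mers with the query (sequences this dissimilar
#' cannot reach a 0.5 identity in practice); sequences shorter than 12
#' residues are always aligned.
#'
#' @param proteins a `protein_records` tibble.
#' @param threshold identity threshold for joining a family (default 0.5).
#' @param min_shared_kmers word-filter floor; set to 0 to disable the
#'   filter and align against every centroid.
#' @return a `pangenome_matrix`: `presence` (logical family x genome
#'   matrix), `families`, `genomes`, `family_of` (named vector protein ->
#'   family), `members` (tibble family, genome_id, protein_id).
#' @export
cluster_proteins <- function(proteins, threshold = 0.5,
                             min_shared_kmers = 4L) {
  stopifnot(nrow(proteins) >= 1L)
  ord <- order(-nchar(proteins$sequence), proteins$genome_id,
               proteins$protein_id, method = "radix")
  proteins <- proteins[ord, ]
  cent_seq <- character()
  cent_kmers <- list()
  fam_of <- integer(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    s <- proteins$sequence[i]
    assigned <- 0L
    if (length(cent_seq)) {
      cand <- seq_along(cent_seq)
      if (min_shared_kmers > 0L && nchar(s) >= 12L) {
        qk <- kmer_set(s)
        shared <- vapply(cent_kmers, function(ck) sum(qk %in% ck), 1L)
        cand <- cand[shared >= min_shared_kmers]
      }
      for (j in cand) {     # first fit in centroid creation order
        if (identities_vs(s, cent_seq[j]) >= threshold) {
          assigned <- j
          break
        }
      }
    }
    if (assigned == 0L) {
      cent_seq <- c(cent_seq, s)
      cent_kmers <- c(cent_kmers, list(kmer_set(s)))
      assigned <- length(cent_seq)
    }
    fam_of[i] <- assigned
  }
  fam_ids <- sprintf("FAM_%05d", seq_along(cent_seq))
  members <- tibble::tibble(
    family = fam_ids[fam_of],
    genome_id = proteins$genome_id,
    protein_id = proteins$protein_id
  )
  genomes <- sort(unique(proteins$genome_id))
  presence <- vapply(genomes, function(g)
    fam_ids %in% members$family[members$genome_id == g],
    logical(length(fam_ids)))
  if (is.null(dim(presence))) presence <- matrix(presence, nrow = 1L)
  dimnames(presence) <- list(fam_ids, genomes)
  structure(list(presence = presence, families = fam_ids,
                 genomes = genomes,
                 family_of = setNames(fam_ids[fam_of],
                                      paste(proteins$genome_id,
                                            proteins$protein_id, sep = "|")),
                 members = members, centroids = setNames(cent_seq, fam_ids)),
            class = "pangenome_matrix")
}

#' @export
print.pangenome_matrix <- function(x, ...) {
  cat(sprintf("<pangenome_matrix> %d families x %d genomes (%d proteins)\n",
              nrow(x$presence), ncol(x$presence), nrow(x$members)))
  invisible(x)
}

#' Presence matrix from planted family labels
#'
#' Builds a `pangenome_matrix` directly from the `planted_family` column of
#' a synthetic protein set, bypassing clustering; useful for testing the
#' partition and rarefaction stages against ground truth.
#'
#' @param proteins a `protein_records` tibble with `planted_family` set.
#' @return a `pangenome_matrix` (without centroid sequences).
#' @export
planted_pangenome_matrix <- function(proteins) {
  if (anyNA(proteins$planted_family)) stop("planted_family labels required")
  fam_ids <- sort(unique(proteins$planted_family))
  genomes <- sort(unique(proteins$genome_id))
  presence <- vapply(genomes, function(g)
    fam_ids %in% proteins$planted_family[proteins$genome_id == g],
    logical(length(fam_ids)))
  if (is.null(dim(presence))) presence <- matrix(presence, nrow = 1L)
  dimnames(presence) <- list(fam_ids, genomes)
  structure(list(presence = presence, families = fam_ids, genomes = genomes,
                 family_of = setNames(proteins$planted_family,
                                      paste(proteins$genome_id,
                                            proteins$protein_id, sep = "|")),
                 members = tibble::tibble(family = proteins$planted_family,
                                          genome_id = proteins$genome_id,
                                          protein_id = proteins$protein_id),
                 centroids = NULL),
            class = "pangenome_matrix")
}

#' Partition families into core, accessory and unique
#'
#' Core families are present in every genome, unique families in exactly
#' one, accessory families in between. The three sets partition the family
#' universe; per-genome unique counts sum to the unique total.
#'
#' @param m a `pangenome_matrix` with at least two genomes.
#' @return a `pangenome_partition` list: `core`, `accessory`, `unique`
#'   (family id vectors), `counts` (named integer vector), and
#'   `unique_per_genome` (tibble genome_id, n_unique).
#' @export
pangenome_partition <- function(m) {
  if (ncol(m$presence) < 2L) {
    stop("partition needs >= 2 genomes (core/unique are degenerate for one)")
  }
  hits <- rowSums(m$presence)
  core <- m$families[hits == ncol(m$presence)]
  uniq <- m$families[hits == 1L]
  acc <- setdiff(m$families, c(core, uniq))
  upg <- vapply(m$genomes, function(g)
    sum(m$presence[uniq, g, drop = FALSE]), 1)
  structure(list(
    core = core, accessory = acc, unique = uniq,
    counts = c(core = length(core), accessory = length(acc),
               unique = length(uniq), total = length(m$families)),
    unique_per_genome = tibble::tibble(genome_id = m$genomes,
                                       n_unique = as.integer(upg))
  ), class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cat(sprintf("<pangenome_partition> core %d, accessory %d, unique %d (total %d)\n",
              x$counts["core"], x$counts["accessory"], x$counts["unique"],
              x$counts["total"]))
  invisible(x)
}

#' Core-/pan-genome rarefaction curves
#'
#' For each of `iterations` random genome orderings and each prefix size
#' N, counts the families seen in the first N genomes (pan) and the
#' families present in all of them (core). Returns per-N medians and
#' quartiles plus the full per-permutation pan curves, which
#' [fit_heaps()] bootstraps for its confidence interval.
#'
#' @param m a `pangenome_matrix` with >= 2 genomes.
#' @param iterations number of random orderings (default 500).
#' @param seed RNG seed; curves are reproducible given the seed.
#' @return a `rarefaction_curves` list: `summary` (tibble N, pan_median,
#'   pan_q1, pan_q3, core_median, core_q1, core_q3), `pan` and `core`
#'   (iterations x N matrices).
#' @export
rarefaction <- function(m, iterations = 500L, seed = 1L) {
  if (iterations < 1L) stop("iterations must be >= 1")
  P <- m$presence
  ng <- ncol(P)
  if (ng < 2L) stop("rarefaction needs >= 2 genomes")
  pan <- matrix(0L, iterations, ng)
  core <- matrix(0L, iterations, ng)
  withr::with_seed(seed, {
    for (it in seq_len(iterations)) {
      ordg <- sample.int(ng)
      Pm <- P[, ordg, drop = FALSE] + 0
      # first genome (in this ordering) containing each family
      first_in <- max.col(Pm, ties.method = "first")
      first_in[rowSums(Pm) == 0L] <- NA_integer_
      pan[it, ] <- cumsum(tabulate(first_in, ng))
      # first genome missing each family (never, for core families)
      absent <- 1 - Pm
      first_out <- max.col(absent, ties.method = "first")
      first_out[rowSums(absent) == 0L] <- ng + 1L
      # family is core at N iff first absence occurs after N
      core[it, ] <- rev(cumsum(rev(tabulate(first_out, ng + 1L))))[-1L]
    }
  })
  q <- function(mat, p) apply(mat, 2, quantile, probs = p, names = FALSE)
  structure(list(
    summary = tibble::tibble(
      N = seq_len(ng),
      pan_median = q(pan, 0.5), pan_q1 = q(pan, 0.25), pan_q3 = q(pan, 0.75),
      core_median = q(core, 0.5), core_q1 = q(core, 0.25),
      core_q3 = q(core, 0.75)
    ),
    pan = pan, core = core, seed = seed
  ), class = "rarefaction_curves")
}

#' Fit Heaps' law to a pan-genome curve and call it open or closed
#'
#' Fits pan(N) = kappa * N^gamma by least squares on the log-log scale.
#' Given a [rarefaction()] result, the fit uses the median pan curve and
#' the confidence interval for gamma comes from a bootstrap over the
#' stored permutations (resampling permutations, refitting the median
#' curve). The pan-genome is called open when the lower CI bound exceeds
#' `open_threshold`: every added genome keeps contributing new families.
#'
#' @param x a `rarefaction_curves` object, or a numeric pan curve of
#'   length >= 3 (in which case no CI is available and the point estimate
#'   is compared to the threshold).
#' @param open_threshold smallest gamma still considered open
#'   (default 0.02).
#' @param n_boot bootstrap replicates (default 199).
#' @param conf confidence level for the gamma CI.
#' @return a `heaps_fit` list: `kappa`, `gamma`, `gamma_ci`, `open`.
#' @export
fit_heaps <- function(x, open_threshold = 0.02, n_boot = 199L, conf = 0.95) {
  if (inherits(x, "rarefaction_curves")) {
    curve <- x$summary$pan_median
    pan_mat <- x$pan
  } else {
    curve <- as.numeric(x)
    pan_mat <- NULL
  }
  if (length(curve) < 3L) stop("need a pan curve of length >= 3")
  if (any(curve <= 0)) stop("pan curve values must be positive")
  fit_gamma <- function(y) {
    N <- seq_along(y)
    co <- coef(lm(log(y) ~ log(N)))
    c(kappa = exp(unname(co[1])), gamma = unname(co[2]))
  }
  est <- fit_gamma(curve)
  ci <- c(NA_real_, NA_real_)
  if (!is.null(pan_mat) && nrow(pan_mat) >= 2L) {
    gb <- withr::with_seed(x$seed + 1L, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(pan_mat), replace = TRUE)
        med <- apply(pan_mat[idx, , drop = FALSE], 2, median)
        if (any(med <= 0)) return(NA_real_)
        fit_gamma(med)["gamma"]
      }, 1)
    })
    gb <- gb[!is.na(gb)]
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(gb, c(alpha, 1 - alpha)))
  }
  open <- if (!is.na(ci[1])) ci[1] > open_threshold else
    est["gamma"] > open_threshold
  structure(list(kappa = unname(est["kappa"]), gamma = unname(est["gamma"]),
                 gamma_ci = c(lower = ci[1], upper = ci[2]),
                 open = unname(open), open_threshold = open_threshold),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf(
    "<heaps_fit> pan(N) ~ %.4g * N^%.4g [CI %.4g, %.4g] -> %s pan-genome\n",
    x$kappa, x$gamma, x$gamma_ci[1], x$gamma_ci[2],
    if (isTRUE(x$open)) "open" else "closed"))
  invisible(x)
}
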