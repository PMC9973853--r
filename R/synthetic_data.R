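# Synthetic-data generators with planted ground truth: a GCF landscape
# (centroid domain sets, including small common families), strain BGC
# repertoires at controlled novelty, Poisson contig-break fragmentation,
# and multi-genome protein sets with planted core/accessory/unique
# structure. All generators are pure functions of (config, seed).

#' Configuration for a synthetic GCF landscape
#'
#' The landscape stands in for a GCF reference database: `n_gcfs` centroid
#' domain sets drawn from a vocabulary, each with `members_per_gcf` member
#' BGCs obtained by `within_gcf_jitter` random domain substitutions. When
#' `include_small_common_families` is `TRUE`, a few of the families are
#' small (3 domains) -- the ubiquitous short clusters real strain
#' collections share -- which matters for fragmentation: fragments of long
#' novel clusters land near these small centroids and lose their apparent
#' novelty. Centroids are resampled until all pairwise distances in
#' feature space reach `centroid_min_separation`, so family recovery is
#' well-posed.
#'
#' @param n_gcfs number of families (default 20).
#' @param vocab_size domain vocabulary size (default 300).
#' @param domains_per_centroid min/max domains per ordinary centroid
#'   (default 14-28, the scale of multi-gene clusters).
#' @param include_small_common_families include `n_small` 3-domain
#'   families (default `TRUE`, 4 families).
#' @param n_small how many of the `n_gcfs` families are small.
#' @param members_per_gcf members per family (default 10).
#' @param within_gcf_jitter domain substitutions per member (default 1).
#' @param centroid_min_separation minimum pairwise centroid distance in
#'   capped-count feature space (default 5.1; each substitution moves a
#'   vector by about sqrt(2), so families stay well separated relative to
#'   the member jitter).
#' @param seed RNG seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_gcfs = 20L, vocab_size = 300L,
                             domains_per_centroid = c(14L, 28L),
                             include_small_common_families = TRUE,
                             n_small = 4L, members_per_gcf = 10L,
                             within_gcf_jitter = 1L,
                             centroid_min_separation = 5.1, seed = 1L) {
  stopifnot(n_gcfs >= 1, vocab_size >= max(domains_per_centroid),
            members_per_gcf >= 1, within_gcf_jitter >= 0)
  if (!include_small_common_families) n_small <- 0L
  n_small <- min(n_small, max(0L, n_gcfs - 1L))
  structure(list(n_gcfs = n_gcfs, vocab_size = vocab_size,
                 domains_per_centroid = domains_per_centroid,
                 include_small_common_families = include_small_common_families,
                 n_small = n_small, members_per_gcf = members_per_gcf,
                 within_gcf_jitter = within_gcf_jitter,
                 centroid_min_separation = centroid_min_separation,
                 seed = seed),
            class = "landscape_config")
}

landscape_vocab <- function(vocab_size) sprintf("PF%04d", seq_len(vocab_size))

# sample n integers uniformly from [lo, hi]; safe for lo == hi (where
# sample() would misread the scalar as 1:lo)
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n) else
    sample(seq.int(lo, hi), n, replace = TRUE)
}

# substitute k random domain occurrences for domains absent from the
# cluster; drawing replacements outside the current set keeps every count
# change at +/-1, so one substitution displaces the count vector by
# exactly sqrt(2)
jitter_domains <- function(domains, vocabulary, k) {
  # minimal clusters are copied verbatim: swapping a domain of a 3-domain
  # cluster replaces a third of its content, which would be a different
  # family, not a variant of this one
  if (length(domains) <= 3L) k <- 0L
  k <- min(k, max(0L, length(domains) - 2L))
  if (k == 0L) return(domains)
  pos <- sample.int(length(domains), k)
  for (p in pos) {
    repl <- sample(setdiff(vocabulary, domains), 1L)
    domains[p] <- repl
  }
  domains
}

#' Simulate a GCF landscape with planted family labels
#'
#' @param cfg a [landscape_config()].
#' @return list with `records` (a [bgc_records] tibble; `planted_gcf`
#'   holds the true family of every member) and `vocabulary`.
#' @export
simulate_landscape <- function(cfg = landscape_config()) {
  vocab <- landscape_vocab(cfg$vocab_size)
  withr::with_seed(cfg$seed, {
    sizes <- c(rep(3L, cfg$n_small),
               sample_range(cfg$domains_per_centroid[1],
                            cfg$domains_per_centroid[2],
                            cfg$n_gcfs - cfg$n_small))
    centroids <- list()
    feats <- NULL
    # pairwise required separation: the full centroid_min_separation between
    # two ordinary families, but only disjointness (count distance sqrt(6),
    # i.e. >= 2.4) when a small family is involved -- a 3-domain set cannot
    # be farther than sqrt(3 + |other|) from anything. Size asymmetry alone
    # already keeps small and large families apart at the build threshold.
    req_of <- function(size) if (size <= 3L) 2.4 else
      cfg$centroid_min_separation
    reqs <- numeric()
    tries <- 0L
    for (i in seq_len(cfg$n_gcfs)) {
      repeat {
        tries <- tries + 1L
        if (tries > 10000L) {
          stop("cannot place centroids at the requested separation; ",
               "increase vocab_size or lower centroid_min_separation")
        }
        cand <- sort(sample(vocab, sizes[i]))
        v <- featurize(cand, vocab, "capped")
        sep_ok <- is.null(feats) ||
          all(sqrt(rowSums(sweep(feats, 2, v)^2)) >=
                pmin(req_of(sizes[i]), reqs))
        if (sep_ok) break
      }
      centroids[[i]] <- cand
      feats <- rbind(feats, v)
      reqs <- c(reqs, req_of(sizes[i]))
    }
    gcf_names <- sprintf("SIMGCF_%03d", seq_len(cfg$n_gcfs))
    rec_domains <- list(); rec_gcf <- character()
    for (i in seq_len(cfg$n_gcfs)) {
      for (m in seq_len(cfg$members_per_gcf)) {
        rec_domains[[length(rec_domains) + 1L]] <-
          jitter_domains(centroids[[i]], vocab, cfg$within_gcf_jitter)
        rec_gcf <- c(rec_gcf, gcf_names[i])
      }
    }
    n <- length(rec_domains)
    lens <- lengths(rec_domains) * 1000L
    records <- bgc_records(
      strain_id = "reference",
      bgc_id = sprintf("ref_bgc_%04d", seq_len(n)),
      contig_id = sprintf("ref_ctg_%04d", seq_len(n)),
      start_bp = 0L, end_bp = lens,
      product_class = "other", complete = TRUE,
      domains = rec_domains, planted_novel = FALSE, planted_gcf = rec_gcf
    )
    list(records = records, vocabulary = vocab,
         centroid_domains = setNames(centroids, gcf_names))
  })
}

#' Configuration for simulated strain repertoires
#'
#' @param n_strains number of strains (default 20).
#' @param bgcs_per_strain min/max clusters per strain (default 15-35,
#'   bracketing the ~25 clusters a typical actinobacterial genome
#'   carries).
#' @param novelty_fraction per-strain fraction of novel clusters: a single
#'   value, a range `c(lo, hi)` sampled uniformly per strain, or a vector
#'   of length `n_strains`.
#' @param novel_min_separation minimum feature-space distance of a novel
#'   cluster to every landscape centroid (default 5, comfortably above the
#'   member jitter scale so planted novelty is unambiguous).
#' @param novel_domains min/max domains of a novel cluster (default
#'   15-30).
#' @param small_family_weight sampling weight of small families when
#'   drawing member clusters (default 3: small families are common across
#'   strains).
#' @param seed RNG seed.
#' @return a `strain_sim_config` list.
#' @export
strain_sim_config <- function(n_strains = 20L, bgcs_per_strain = c(15L, 35L),
                              novelty_fraction = 0.5,
                              novel_min_separation = 5,
                              novel_domains = c(15L, 30L),
                              small_family_weight = 3, seed = 1L) {
  stopifnot(all(novelty_fraction >= 0), all(novelty_fraction <= 1),
            n_strains >= 1)
  structure(list(n_strains = n_strains, bgcs_per_strain = bgcs_per_strain,
                 novelty_fraction = novelty_fraction,
                 novel_min_separation = novel_min_separation,
                 novel_domains = novel_domains,
                 small_family_weight = small_family_weight, seed = seed),
            class = "strain_sim_config")
}

#' Simulate strain BGC repertoires with planted novelty
#'
#' Each strain draws `floor((1 - f) * n)` member clusters (jittered copies
#' of landscape centroids, small common families oversampled) and makes
#' the remaining clusters novel: random domain sets rejected and resampled
#' until they sit at least `novel_min_separation` from every centroid in
#' feature space. `planted_novel` records the truth for every cluster.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param cfg a [strain_sim_config()].
#' @return list of [bgc_records] tibbles, one per strain, named by strain.
#' @export
simulate_strains <- function(landscape, cfg = strain_sim_config()) {
  vocab <- landscape$vocabulary
  cents <- landscape$centroid_domains
  cent_feats <- t(vapply(cents, function(d) featurize(d, vocab, "capped"),
                         numeric(length(vocab) + 1L)))
  sizes <- lengths(cents)
  w <- ifelse(sizes <= 3L, cfg$small_family_weight, 1)
  fvec <- cfg$novelty_fraction
  fractions <- if (length(fvec) == cfg$n_strains) fvec else
    if (length(fvec) == 2L && fvec[1] != fvec[2]) NULL else rep(fvec[1],
                                                                cfg$n_strains)
  withr::with_seed(cfg$seed, {
    if (is.null(fractions)) {
      fractions <- runif(cfg$n_strains, min(fvec), max(fvec))
    }
    out <- vector("list", cfg$n_strains)
    for (s in seq_len(cfg$n_strains)) {
      sid <- sprintf("strain_%03d", s)
      n_bgc <- sample_range(cfg$bgcs_per_strain[1], cfg$bgcs_per_strain[2])
      n_member <- floor((1 - fractions[s]) * n_bgc)
      n_novel <- n_bgc - n_member
      doms <- vector("list", n_bgc)
      novel <- logical(n_bgc)
      gcf <- rep(NA_character_, n_bgc)
      if (n_member > 0L) {
        picks <- sample(seq_along(cents), n_member, replace = TRUE, prob = w)
        for (i in seq_len(n_member)) {
          doms[[i]] <- jitter_domains(cents[[picks[i]]], vocab, 1L)
          gcf[i] <- names(cents)[picks[i]]
        }
      }
      if (n_novel > 0L) {
        for (i in seq_len(n_novel)) {
          ok <- FALSE
          for (try in seq_len(10000L)) {
            nd <- sample_range(cfg$novel_domains[1], cfg$novel_domains[2])
            cand <- sample(vocab, nd)
            v <- featurize(cand, vocab, "capped")
            dmin <- min(sqrt(rowSums(sweep(cent_feats, 2, v)^2)))
            if (dmin >= cfg$novel_min_separation) { ok <- TRUE; break }
          }
          if (!ok) {
            stop("rejection sampling failed for a novel cluster; ",
                 "increase vocab_size or lower novel_min_separation")
          }
          doms[[n_member + i]] <- cand
          novel[n_member + i] <- TRUE
        }
      }
      classes <- sample(product_classes, n_bgc, replace = TRUE,
                        prob = c(0.14, 0.10, 0.04, 0.17, 0.21, 0.02, 0.32))
      lens <- lengths(doms) * 1000L
      out[[s]] <- bgc_records(
        strain_id = sid,
        bgc_id = sprintf("%s.region%03d", sid, seq_len(n_bgc)),
        contig_id = sprintf("%s_ctg%03d", sid, seq_len(n_bgc)),
        start_bp = 0L, end_bp = lens,
        product_class = classes, complete = TRUE,
        domains = doms, planted_novel = novel, planted_gcf = gcf
      )
      attr(out[[s]], "planted_novelty_fraction") <- n_novel / n_bgc
    }
    setNames(out, vapply(out, function(r) r$strain_id[1], ""))
  })
}

#' Fragmentation configuration
#'
#' Models assembly quality loss as contig breaks falling inside clusters:
#' each cluster receives k ~ Poisson(`breaks_per_bgc`) breaks at distinct
#' cut points between adjacent domains, producing k + 1 incomplete
#' fragments. The default rate 1.5 mimics the contrast between highly
#' fragmented and near-complete assemblies of the same genome.
#'
#' @param breaks_per_bgc Poisson rate of breaks per cluster (default 1.5).
#' @param min_fragment_domains smallest fragment retained (default 1).
#' @return a `fragmentation_config` list.
#' @export
fragmentation_config <- function(breaks_per_bgc = 1.5,
                                 min_fragment_domains = 1L) {
  stopifnot(breaks_per_bgc >= 0, min_fragment_domains >= 1)
  structure(list(breaks_per_bgc = breaks_per_bgc,
                 min_fragment_domains = min_fragment_domains),
            class = "fragmentation_config")
}

#' Fragment BGC records by simulated contig breaks
#'
#' For each record draws k ~ Poisson(rate) and, when k > 0, chooses k
#' distinct cut points between domain positions, emitting k + 1 fragment
#' records whose domain lists partition the original in order; fragments
#' are flagged incomplete (`complete = FALSE`). Records drawing k = 0 (and
#' records with too few domains to cut) pass through untouched. The total
#' domain multiset is conserved.
#'
#' @param records a [bgc_records] tibble.
#' @param cfg a [fragmentation_config()].
#' @param seed RNG seed.
#' @return a [bgc_records] tibble with `sum(k)` more rows than the input.
#' @export
fragment_records <- function(records, cfg = fragmentation_config(),
                             seed = 1L) {
  if (cfg$breaks_per_bgc == 0) return(records)
  withr::with_seed(seed, {
    pieces <- vector("list", nrow(records))
    for (i in seq_len(nrow(records))) {
      d <- records$domains[[i]]
      n_cutpoints <- length(d) - 1L
      k <- min(rpois(1L, cfg$breaks_per_bgc), max(0L, n_cutpoints))
      if (k == 0L) {
        pieces[[i]] <- records[i, , drop = FALSE]
        next
      }
      cuts <- sort(sample.int(n_cutpoints, k))
      bounds <- c(0L, cuts, length(d))
      frag_doms <- lapply(seq_len(k + 1L), function(j)
        d[(bounds[j] + 1L):bounds[j + 1L]])
      keep <- lengths(frag_doms) >= cfg$min_fragment_domains
      frag_doms <- frag_doms[keep]
      nf <- length(frag_doms)
      row <- records[i, , drop = FALSE]
      span <- max(1L, (row$end_bp - row$start_bp) %/% nf)
      pieces[[i]] <- bgc_records(
        strain_id = row$strain_id,
        bgc_id = sprintf("%s.frag%02d", row$bgc_id, seq_len(nf)),
        contig_id = sprintf("%s.frag%02d", row$contig_id, seq_len(nf)),
        start_bp = row$start_bp + (seq_len(nf) - 1L) * span,
        end_bp = row$start_bp + seq_len(nf) * span,
        product_class = row$product_class, complete = FALSE,
        domains = frag_doms, planted_novel = row$planted_novel,
        planted_gcf = row$planted_gcf
      )
    }
    do.call(bind_bgc_records, pieces)
  })
}

#' Configuration for a simulated pan-genome
#'
#' One random ancestral protein per family. Core families appear in every
#' genome, accessory families in a Bernoulli(`presence_prob`) subset
#' (redrawn if degenerate, so planted accessory families are truly
#' accessory), and each genome additionally carries
#' `unique_families_per_genome` private families. Every ortholog copy is
#' independently mutated at `within_family_mutation_rate` per residue
#' (substitutions only), keeping within-family identity near
#' (1 - rate)^2 while unrelated families stay near the random-alignment
#' floor, far below the 0.5 clustering threshold.
#'
#' @param n_genomes number of genomes (default 8).
#' @param core_families,accessory_families family counts (defaults 30, 20).
#' @param presence_prob per-genome presence probability of an accessory
#'   family (default 0.5).
#' @param unique_families_per_genome private families per genome
#'   (default 10).
#' @param protein_length ancestral protein length (default 200 residues).
#' @param within_family_mutation_rate per-residue substitution probability
#'   (default 0.1).
#' @param seed RNG seed.
#' @return a `pangenome_sim_config` list.
#' @export
pangenome_sim_config <- function(n_genomes = 8L, core_families = 30L,
                                 accessory_families = 20L,
                                 presence_prob = 0.5,
                                 unique_families_per_genome = 10L,
                                 protein_length = 200L,
                                 within_family_mutation_rate = 0.1,
                                 seed = 1L) {
  stopifnot(n_genomes >= 2, presence_prob >= 0, presence_prob <= 1,
            within_family_mutation_rate >= 0,
            within_family_mutation_rate <= 1)
  structure(list(n_genomes = n_genomes, core_families = core_families,
                 accessory_families = accessory_families,
                 presence_prob = presence_prob,
                 unique_families_per_genome = unique_families_per_genome,
                 protein_length = protein_length,
                 within_family_mutation_rate = within_family_mutation_rate,
                 seed = seed),
            class = "pangenome_sim_config")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

mutate_protein <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit],
                         function(c) sample(setdiff(AA20, c), 1L), "")
  }
  paste(chars, collapse = "")
}

#' Simulate a multi-genome protein set with planted family structure
#'
#' @param cfg a [pangenome_sim_config()].
#' @return a `protein_records` tibble with `planted_family` labels.
#' @export
simulate_pangenome <- function(cfg = pangenome_sim_config()) {
  withr::with_seed(cfg$seed, {
    genomes <- sprintf("genome_%02d", seq_len(cfg$n_genomes))
    rows <- list()
    add <- function(fam, genome, seqs) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        genome_id = genome,
        protein_id = sprintf("%s_%s", fam, genome),
        sequence = seqs, planted_family = fam)
    }
    for (i in seq_len(cfg$core_families)) {
      fam <- sprintf("core_%04d", i)
      anc <- random_protein(cfg$protein_length)
      for (g in genomes) {
        add(fam, g, mutate_protein(anc, cfg$within_family_mutation_rate))
      }
    }
    for (i in seq_len(cfg$accessory_families)) {
      fam <- sprintf("acc_%04d", i)
      anc <- random_protein(cfg$protein_length)
      repeat {
        present <- runif(cfg$n_genomes) < cfg$presence_prob
        if (sum(present) >= 2L && sum(present) < cfg$n_genomes) break
      }
      for (g in genomes[present]) {
        add(fam, g, mutate_protein(anc, cfg$within_family_mutation_rate))
      }
    }
    for (g in seq_along(genomes)) {
      for (i in seq_len(cfg$unique_families_per_genome)) {
        fam <- sprintf("uniq_%s_%03d", genomes[g], i)
        add(fam, genomes[g], random_protein(cfg$protein_length))
      }
    }
    df <- do.call(rbind, rows)
    protein_records(df$genome_id, df$protein_id, df$sequence,
                    df$planted_family)
  })
}
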