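# antiSMASH region ingest: GenBank flat files with `region` features
# (qualifiers `product`, `contig_edge`) and domain features (`aSDomain`,
# `PFAM_domain`), or this package's own JSON region export.

# antiSMASH product string -> 7-class scheme. Anything unlisted falls back
# to "other"; a region whose products map to both NRPS and PKS is "hybrid".
antismash_product_map <- c(
  "NRPS" = "NRPS", "NRPS-like" = "NRPS", "NRP-metallophore" = "NRPS",
  "thioamide-NRP" = "NRPS", "CDPS" = "NRPS",
  "T1PKS" = "PKS", "T2PKS" = "PKS", "T3PKS" = "PKS",
  "transAT-PKS" = "PKS", "transAT-PKS-like" = "PKS", "PKS-like" = "PKS",
  "hglE-KS" = "PKS", "PUFA" = "PKS", "arylpolyene" = "PKS", "ladderane" = "PKS",
  "terpene" = "terpene",
  "RiPP-like" = "RiPP", "lanthipeptide-class-i" = "RiPP",
  "lanthipeptide-class-ii" = "RiPP", "lanthipeptide-class-iii" = "RiPP",
  "lanthipeptide-class-iv" = "RiPP", "lanthipeptide-class-v" = "RiPP",
  "lassopeptide" = "RiPP", "thiopeptide" = "RiPP", "linaridin" = "RiPP",
  "LAP" = "RiPP", "bacteriocin" = "RiPP", "ranthipeptide" = "RiPP",
  "sactipeptide" = "RiPP", "lipolanthine" = "RiPP", "thioamitides" = "RiPP",
  "RRE-containing" = "RiPP", "epipeptide" = "RiPP", "cyanobactin" = "RiPP",
  "saccharide" = "saccharide", "oligosaccharide" = "saccharide",
  "amglyccycl" = "saccharide", "aminoglycoside" = "saccharide"
)

#' Map antiSMASH product strings to the seven-class scheme
#'
#' Collapses the free-form antiSMASH `product` qualifiers of a region into
#' one of `NRPS`, `PKS`, `hybrid`, `terpene`, `RiPP`, `saccharide`,
#' `other`. A region listing both NRPS- and PKS-type products is `hybrid`;
#' otherwise the first matching class in the priority order NRPS, PKS,
#' terpene, RiPP, saccharide wins, and unrecognized products fall back to
#' `other`.
#'
#' @param products character vector of product strings for one region.
#' @return a single class label.
#' @export
classify_products <- function(products) {
  mapped <- unname(antismash_product_map[products])
  mapped[is.na(mapped)] <- "other"
  if (all(c("NRPS", "PKS") %in% mapped)) return("hybrid")
  for (cls in c("NRPS", "PKS", "terpene", "RiPP", "saccharide")) {
    if (cls %in% mapped) return(cls)
  }
  "other"
}

# canonical product string emitted by the fixture writer for each class;
# chosen so classify_products() inverts it
class_to_products <- list(
  NRPS = "NRPS", PKS = "T1PKS", hybrid = c("NRPS", "T1PKS"),
  terpene = "terpene", RiPP = "RiPP-like", saccharide = "saccharide",
  other = "other"
)

#' Parse antiSMASH region output into BGC records
#'
#' Reads an antiSMASH-style GenBank file (features `region`, `aSDomain`,
#' `PFAM_domain`) or this package's JSON region export (files ending in
#' `.json`, as written by [write_regions_json()]) and returns one
#' [bgc_records] row per region. Domains are collected from domain features
#' that fall inside the region, in genomic order. GenBank coordinates
#' (1-based inclusive) are converted to the internal 0-based half-open
#' convention; `complete` is the negation of the `contig_edge` qualifier.
#'
#' @param path GenBank (`.gbk`/`.gb`) or JSON region file.
#' @param strain_id strain label attached to every record.
#' @return a `bgc_records` tibble; empty (zero rows) when the file contains
#'   no region features.
#' @export
parse_antismash_regions <- function(path, strain_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(read_regions_json(path, strain_id = strain_id))
  }
  lines <- readLines(path, warn = FALSE)
  contigs <- split_genbank_records(lines)
  regions <- list()
  for (contig in contigs) {
    feats <- parse_genbank_features(contig$lines)
    reg <- feats[vapply(feats, function(f) f$key == "region", TRUE)]
    dom <- feats[vapply(feats, function(f)
      f$key %in% c("aSDomain", "PFAM_domain"), TRUE)]
    if (!length(reg)) next
    dom_starts <- vapply(dom, function(f) f$start, 1L)
    dom_order <- order(dom_starts)
    dom <- dom[dom_order]
    dom_starts <- dom_starts[dom_order]
    for (r in reg) {
      inside <- dom_starts >= r$start & dom_starts <= r$end
      dnames <- vapply(dom[inside], function(f) {
        q <- f$qualifiers
        q[["aSDomain"]] %||% q[["domain"]] %||% q[["description"]] %||%
          q[["label"]] %||% "unknown_domain"
      }, "")
      edge <- identical(tolower(r$qualifiers[["contig_edge"]] %||% "false"),
                        "true")
      prods <- r$qualifiers[names(r$qualifiers) == "product"]
      rn <- r$qualifiers[["region_number"]]
      regions[[length(regions) + 1L]] <- list(
        contig_id = contig$locus,
        start_bp = r$start - 1L, end_bp = r$end,
        product_class = classify_products(unlist(prods)),
        complete = !edge,
        domains = as.character(dnames),
        region_number = if (is.null(rn)) NA_integer_ else as.integer(rn)
      )
    }
  }
  if (!length(regions)) return(empty_bgc_records())
  bgc_records(
    strain_id = strain_id,
    bgc_id = sprintf("%s.region%03d", strain_id, seq_along(regions)),
    contig_id = vapply(regions, `[[`, "", "contig_id"),
    start_bp = vapply(regions, `[[`, 1L, "start_bp"),
    end_bp = vapply(regions, `[[`, 1L, "end_bp"),
    product_class = vapply(regions, `[[`, "", "product_class"),
    complete = vapply(regions, `[[`, TRUE, "complete"),
    domains = lapply(regions, `[[`, "domains")
  )
}

empty_bgc_records <- function() {
  tibble::tibble(
    strain_id = character(), bgc_id = character(), contig_id = character(),
    start_bp = integer(), end_bp = integer(), product_class = character(),
    complete = logical(), domains = list(), planted_novel = logical(),
    planted_gcf = character()
  ) -> x
  class(x) <- unique(c("bgc_records", class(x)))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a multi-record GenBank flat file at LOCUS/'//' boundaries;
# each record is one contig of the same strain
split_genbank_records <- function(lines) {
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("format error: no LOCUS line")
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    chunk <- lines[starts[i]:ends[i]]
    locus <- strsplit(trimws(sub("^LOCUS", "", chunk[1])), "\\s+")[[1]][1]
    list(locus = locus, lines = chunk)
  })
}

# minimal GenBank FEATURES parser: feature key + location + qualifiers.
# Handles complement()/join() locations and < > partial markers by taking
# the extreme coordinates.
parse_genbank_features <- function(lines) {
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) return(list())
  body <- lines[(fstart[1] + 1L):length(lines)]
  stop_at <- grep("^(ORIGIN|CONTIG|//)", body)
  if (length(stop_at)) body <- head(body, stop_at[1] - 1L)
  feats <- list()
  cur <- NULL
  cur_qual <- NULL
  flush_qual <- function(f, q) {
    if (is.null(q)) return(f)
    m <- regmatches(q, regexec("^/([A-Za-z_0-9]+)=?(.*)$", q))[[1]]
    if (length(m) == 3L) {
      val <- gsub("^\"|\"$", "", m[3])
      f$qualifiers <- c(f$qualifiers, setNames(list(val), m[2]))
    }
    f
  }
  for (ln in body) {
    if (grepl("^ {5}\\S", ln)) {            # new feature
      if (!is.null(cur)) {
        cur <- flush_qual(cur, cur_qual); cur_qual <- NULL
        feats[[length(feats) + 1L]] <- cur
      }
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      loc <- parse_genbank_location(paste(parts[-1], collapse = ""))
      cur <- list(key = parts[1], start = loc[1], end = loc[2],
                  qualifiers = list())
    } else if (grepl("^ {21}/", ln)) {      # new qualifier
      cur <- flush_qual(cur, cur_qual)
      cur_qual <- trimws(ln)
    } else if (!is.null(cur_qual)) {        # qualifier continuation
      cur_qual <- paste0(cur_qual, trimws(ln))
    }
  }
  if (!is.null(cur)) {
    cur <- flush_qual(cur, cur_qual)
    feats[[length(feats) + 1L]] <- cur
  }
  feats
}

parse_genbank_location <- function(loc) {
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (length(nums) < 1L) stop("format error: malformed location '", loc, "'")
  nums <- as.integer(nums)
  rng <- range(nums)
  if (rng[1] > rng[2] || rng[1] < 1L) {
    stop("format error: malformed location '", loc, "'")
  }
  rng
}

#' Write BGC records as a minimal antiSMASH-style GenBank fixture
#'
#' Emits one GenBank record per contig with `region` features (`product`,
#' `contig_edge`, `region_number` qualifiers) and one `aSDomain` feature
#' per domain, positioned in genomic order, such that
#' [parse_antismash_regions()] recovers the records exactly (strain, contig,
#' coordinates, product class, completeness and domain lists).
#'
#' @param records a [bgc_records] tibble from one strain.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixture_genbank <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  contigs <- if (nrow(records)) unique(records$contig_id) else "ctg_empty"
  for (ctg in contigs) {
    rows <- if (nrow(records)) which(records$contig_id == ctg) else integer()
    ctg_len <- if (length(rows)) max(records$end_bp[rows]) + 1000L else 1000L
    writeLines(sprintf(
      "LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-2026", ctg, ctg_len),
      con)
    writeLines("DEFINITION  synthetic antiSMASH-style fixture.", con)
    writeLines("FEATURES             Location/Qualifiers", con)
    rnum <- 0L
    for (i in rows) {
      rnum <- rnum + 1L
      s1 <- records$start_bp[i] + 1L   # back to 1-based inclusive
      e1 <- records$end_bp[i]
      writeLines(sprintf("     region          %d..%d", s1, e1), con)
      writeLines(sprintf("                     /region_number=\"%d\"", rnum),
                 con)
      for (p in class_to_products[[records$product_class[i]]]) {
        writeLines(sprintf("                     /product=\"%s\"", p), con)
      }
      writeLines(sprintf("                     /contig_edge=\"%s\"",
                         if (records$complete[i]) "False" else "True"), con)
      doms <- records$domains[[i]]
      if (length(doms)) {
        # synthetic in-region positions preserving domain order
        span <- max(1, (e1 - s1) %/% (length(doms) + 1L))
        for (j in seq_along(doms)) {
          ds <- s1 + (j - 1L) * span
          writeLines(sprintf("     aSDomain        %d..%d", ds,
                             min(ds + span - 1L, e1)), con)
          writeLines(sprintf("                     /aSDomain=\"%s\"", doms[j]),
                     con)
        }
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write and read BGC records as JSON
#'
#' A plain JSON serialization of [bgc_records] (one object per region with
#' the same fields as the tibble). This is the JSON region format
#' [parse_antismash_regions()] accepts for `.json` inputs.
#'
#' @param records a [bgc_records] tibble.
#' @param path file path.
#' @return `write_regions_json()` returns `path` invisibly;
#'   `read_regions_json()` returns a `bgc_records` tibble.
#' @export
write_regions_json <- function(records, path) {
  recs <- lapply(seq_len(nrow(records)), function(i) {
    list(strain_id = records$strain_id[i], bgc_id = records$bgc_id[i],
         contig_id = records$contig_id[i], start_bp = records$start_bp[i],
         end_bp = records$end_bp[i], product_class = records$product_class[i],
         complete = records$complete[i],
         domains = as.list(records$domains[[i]]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_regions_json
#' @param strain_id optional override for the strain label; defaults to the
#'   labels stored in the file.
#' @export
read_regions_json <- function(path, strain_id = NULL) {
  recs <- jsonlite::read_json(path)
  if (!length(recs)) return(empty_bgc_records())
  bgc_records(
    strain_id = strain_id %||% vapply(recs, `[[`, "", "strain_id"),
    bgc_id = vapply(recs, `[[`, "", "bgc_id"),
    contig_id = vapply(recs, `[[`, "", "contig_id"),
    start_bp = vapply(recs, function(r) as.integer(r$start_bp), 1L),
    end_bp = vapply(recs, function(r) as.integer(r$end_bp), 1L),
    product_class = vapply(recs, `[[`, "", "product_class"),
    complete = vapply(recs, `[[`, TRUE, "complete"),
    domains = lapply(recs, function(r) as.character(unlist(r$domains)))
  )
}
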