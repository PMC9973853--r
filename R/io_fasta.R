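#' Read a FASTA file
#'
#' Reads nucleotide or protein FASTA into a named, upper-cased
#' [Biostrings::BStringSet]. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a `BStringSet` with one element per record; the source path is
#'   attached as the `source_path` attribute of the element metadata.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("format error: no FASTA records in ", path)
  # FASTA ids are everything up to the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("format error: duplicate FASTA id '",
         names(seqs)[duplicated(names(seqs))][1], "' in ", path)
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("format error: empty sequence in ", path)
  }
  seqs <- Biostrings::BStringSet(toupper(seqs))
  attr(seqs, "source_path") <- path
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs a named character vector or `XStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Assembly summary statistics
#'
#' Computes the Table-1 style statistics for a genome assembly: contig
#' count, total length, G+C mol% and N50. N50 is the length of the contig
#' at which the cumulative sum of descending contig lengths first reaches
#' half the assembly size. G+C is computed over unambiguous A/C/G/T only
#' (Ns and IUPAC ambiguity codes are excluded from the denominator) and
#' reported to one decimal.
#'
#' @param seqs a nucleotide `XStringSet` or named character vector of
#'   contig sequences.
#' @return a one-row tibble with `n_contigs`, `total_length_bp`,
#'   `gc_mol_percent`, `n50_bp`.
#' @export
compute_assembly_stats <- function(seqs) {
  if (inherits(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (length(seqs) == 0L) stop("empty sequence set")
  seqs <- toupper(seqs)
  all_chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  iupac <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "-", ".")
  bad <- setdiff(unique(all_chars), iupac)
  if (length(bad)) {
    stop("non-nucleotide characters beyond IUPAC codes: ",
         paste(bad, collapse = ""))
  }
  lens <- nchar(seqs)
  total <- sum(lens)
  counts <- table(factor(all_chars, levels = c("A", "C", "G", "T")))
  acgt <- sum(counts)
  if (acgt == 0L) stop("no unambiguous A/C/G/T bases in input")
  gc <- round(100 * (counts[["G"]] + counts[["C"]]) / acgt, 1)
  desc <- sort(lens, decreasing = TRUE)
  n50 <- desc[which(cumsum(desc) >= total / 2)[1]]
  tibble::tibble(
    n_contigs = length(seqs),
    total_length_bp = as.integer(total),
    gc_mol_percent = as.numeric(gc),
    n50_bp = as.integer(n50)
  )
}
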