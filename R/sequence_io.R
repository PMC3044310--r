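#' Read short reads from a FASTQ file
#'
#' Parses a FASTQ file into a tibble of reads. Bases are uppercased and any
#' record containing a character outside A/C/G/T (e.g. an `N` call) is
#' dropped, so downstream kmer counts are never contaminated by ambiguous
#' bases; the number of dropped records is reported with a message and
#' attached as the `n_dropped` attribute. Quality strings are accepted but
#' ignored throughout the package.
#'
#' @param path Path to a FASTQ file (4-line records, Sanger/Illumina 1.8+).
#' @return A tibble with columns `id` and `seq`, one row per retained read.
#' @seealso [write_fastq()], [read_fasta()]
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", use.names = TRUE)
  .reads_from_stringset(x)
}

#' Read sequences from a FASTA file
#'
#' Each contig becomes one row. Genome sequences are sanitized by removing
#' all non-ACGT characters (after uppercasing), mirroring standard practice
#' when preparing repeat-rich references.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`, one row per contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fasta", use.names = TRUE)
  seqs <- toupper(as.character(x))
  seqs <- gsub("[^ACGT]", "", seqs)
  tibble::tibble(id = .first_word(names(x)), seq = unname(seqs))
}

.reads_from_stringset <- function(x) {
  seqs <- toupper(as.character(x))
  ids <- .first_word(names(x))
  ok <- grepl("^[ACGT]*$", seqs)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message("dropped ", n_dropped, " read(s) containing non-ACGT characters")
  }
  out <- tibble::tibble(id = ids[ok], seq = unname(seqs[ok]))
  attr(out, "n_dropped") <- n_dropped
  out
}

.first_word <- function(x) sub("\\s.*$", "", x)

#' Write reads to FASTQ
#'
#' Inverse of [read_fastq()] for sanitized reads. A constant quality
#' character is used for every base (qualities carry no information in this
#' package).
#'
#' @param reads A data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param quality Single quality character recycled over all bases.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$id
  quals <- Biostrings::BStringSet(
    vapply(nchar(reads$seq), function(n) strrep(quality, n), character(1))
  )
  Biostrings::writeXStringSet(set, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param x A data frame with columns `id` and `seq` (reads or genome).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  set <- Biostrings::DNAStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}
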