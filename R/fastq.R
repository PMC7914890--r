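# FASTQ I/O. Reads are held in a plain data.frame with one row per read:
# id, seq (ACGTN string) and qual (Phred+33 string). File parsing and
# writing go through Biostrings, which transparently handles gzip.

#' Read a FASTQ file into a read table
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path; a `.gz` suffix triggers compression.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(
    dna, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

# Validate a read table (used by trim entry points).
validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence and quality lengths differ for some reads")
  }
  invisible(reads)
}
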