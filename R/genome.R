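# Reference genome container and FASTA I/O.
#
# The genome is kept both as a DNAStringSet (for C-level matching in the
# aligner) and as plain character strings (for cheap substring extraction
# elsewhere). Coordinates throughout the package are 0-based half-open;
# conversion to the 1-based conventions of FASTA-adjacent formats (SAM,
# GFF3) happens only at the file boundary.

#' Construct a genome object
#'
#' @param dna a named [Biostrings::DNAStringSet] (one entry per chromosome).
#' @return an object of class `sf_genome`.
#' @export
new_genome <- function(dna) {
  if (!methods::is(dna, "DNAStringSet")) dna <- Biostrings::DNAStringSet(dna)
  if (is.null(names(dna)) || anyDuplicated(names(dna))) {
    stop("genome sequences must have unique names")
  }
  names(dna) <- sub("\\s.*$", "", names(dna))
  seqs <- stats::setNames(toupper(as.character(dna)), names(dna))
  dna <- Biostrings::DNAStringSet(seqs)
  structure(list(dna = dna, seq = seqs), class = "sf_genome")
}

#' Read a reference genome from FASTA
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return an `sf_genome` object.
#' @export
read_genome <- function(path) {
  new_genome(Biostrings::readDNAStringSet(path))
}

#' Write a genome object to FASTA
#'
#' @param genome an `sf_genome`.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome$dna, filepath = path)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome an `sf_genome`.
#' @return named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(genome$seq), names(genome$seq))
}

#' Extract a genomic subsequence
#'
#' @param genome an `sf_genome`.
#' @param chrom chromosome name.
#' @param start0,end0 0-based half-open interval.
#' @param strand `"+"` returns the forward sequence, `"-"` its reverse
#'   complement (i.e. the RNA-sense sequence of a minus-strand feature).
#' @return a character scalar.
#' @export
genome_subseq <- function(genome, chrom, start0, end0, strand = "+") {
  n <- nchar(genome$seq[[chrom]])
  if (start0 < 0 || end0 > n || start0 > end0) {
    stop("interval [", start0, ",", end0, ") outside chromosome ", chrom)
  }
  s <- substr(genome$seq[[chrom]], start0 + 1L, end0)
  if (strand == "-") s <- revcomp(s)
  s
}

print.sf_genome <- function(x, ...) {
  cat("<sf_genome> ", length(x$seq), " sequence(s), ",
      sum(nchar(x$seq)), " bp total\n", sep = "")
  invisible(x)
}
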