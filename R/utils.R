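# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  out <- vapply(comp, function(s) {
    if (!nzchar(s)) "" else intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
  out
}

# Phred+33 string -> integer vector (one read).
phred_ints <- function(qual) {
  if (!nzchar(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

# Integer Phred vector -> Phred+33 string.
phred_string <- function(v) {
  if (length(v) == 0L) return("")
  intToUtf8(v + 33L)
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(s) {
  if (!nzchar(s)) return(character(0))
  strsplit(s, "", fixed = TRUE)[[1L]]
}

stopifnot_scalar <- function(x, what) {
  if (length(x) != 1L || is.na(x)) stop(what, " must be a non-missing scalar", call. = FALSE)
  invisible(x)
}

# Empty alignment table with the canonical column set.
empty_alignments <- function() {
  data.frame(
    read_id = character(0), chrom = character(0), strand = character(0),
    start0 = integer(0), end0 = integer(0), score = integer(0),
    nm = integer(0), mate = integer(0), seq = character(0),
    qual = character(0), stringsAsFactors = FALSE
  )
}

# rbind a list of data.frames that may be empty/NULL.
rbind_tables <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}
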