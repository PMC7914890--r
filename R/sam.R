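# Minimal SAM writer/reader for the ungapped records this pipeline
# produces. Only <len>M CIGARs occur; scores travel in AS, mismatch
# counts in NM, reported-alignment counts in NH and exempted terminal
# oligo(A) lengths in the custom ZA tag.
#
# Alignment tables store `seq`/`qual` in read orientation; SAM stores
# them in reference orientation, so minus-strand records are
# reverse-complemented on the way out and back in.

sam_flag <- function(strand, mate, secondary) {
  f <- integer(length(strand))
  paired <- mate > 0L
  f <- f + ifelse(paired, 1L, 0L)
  f <- f + ifelse(strand == "-", 16L, 0L)
  f <- f + ifelse(mate == 1L, 64L, ifelse(mate == 2L, 128L, 0L))
  f <- f + ifelse(secondary, 256L, 0L)
  f
}

#' Write alignment records to a SAM file
#'
#' @param aln alignment table (columns `read_id`, `chrom`, `strand`,
#'   `start0`, `end0`, `seq`, `qual`, `score`, `nm`, `mate`; optional
#'   `nh`, `za`). Record order is preserved; for paired data, mates of
#'   the same placement are expected on consecutive rows.
#' @param seqlengths named vector of chromosome lengths for the `@SQ`
#'   header, or an `sf_genome`.
#' @param path output path.
#' @export
write_sam <- function(aln, seqlengths, path) {
  if (inherits(seqlengths, "sf_genome")) seqlengths <- genome_lengths(seqlengths)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)), con)
  if (is.null(aln) || nrow(aln) == 0L) return(invisible(path))

  mate <- if ("mate" %in% names(aln)) aln$mate else rep(0L, nrow(aln))
  # first placement of each (read, mate) is primary, the rest secondary
  key <- paste(aln$read_id, mate)
  secondary <- duplicated(key)
  flag <- sam_flag(aln$strand, mate, secondary)

  minus <- aln$strand == "-"
  seq_out <- aln$seq
  qual_out <- aln$qual
  seq_out[minus] <- revcomp(seq_out[minus])
  qual_out[minus] <- vapply(qual_out[minus], function(q)
    paste(rev(seq_chars(q)), collapse = ""), character(1))

  fields <- cbind(
    aln$read_id, flag, aln$chrom, aln$start0 + 1L, 255L,
    paste0(aln$end0 - aln$start0, "M"), "*", 0L, 0L, seq_out, qual_out
  )
  tags <- sprintf("AS:i:%d\tNM:i:%d", as.integer(aln$score), as.integer(aln$nm))
  if ("nh" %in% names(aln)) {
    has <- !is.na(aln$nh)
    tags[has] <- paste0(tags[has], sprintf("\tNH:i:%d", as.integer(aln$nh[has])))
  }
  if ("za" %in% names(aln)) {
    has <- !is.na(aln$za)
    tags[has] <- paste0(tags[has], sprintf("\tZA:i:%d", as.integer(aln$za[has])))
  }
  writeLines(paste(apply(fields, 1L, paste, collapse = "\t"), tags, sep = "\t"), con)
  invisible(path)
}

parse_sam_tag <- function(tags, name) {
  pat <- paste0("(^|\t)", name, ":i:(-?[0-9]+)")
  m <- regmatches(tags, regexec(pat, tags))
  vapply(m, function(x) if (length(x)) as.integer(x[3]) else NA_integer_, integer(1))
}

#' Read a SAM file into an alignment table
#'
#' Round trip: `read_sam(write_sam(x))` reproduces `x` (for the ungapped
#' records this package writes).
#'
#' @param path path to a SAM file.
#' @return list with `alignments` (table as in [write_sam()], plus `nh`
#'   and `za` columns) and `seqlengths`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ", lines)]
  seqlengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    seqlengths <- stats::setNames(ln, sn)
  }
  body <- lines[!hdr]
  if (length(body) == 0L) {
    return(list(alignments = cbind(empty_alignments(),
                                   nh = integer(0), za = integer(0)),
                seqlengths = seqlengths))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    stop("malformed SAM line ", which(!hdr)[which(nf < 11L)[1L]],
         ": fewer than 11 fields")
  }
  getf <- function(i) vapply(parts, `[[`, character(1), i)
  flag <- as.integer(getf(2))
  cigar <- getf(6)
  bad <- !grepl("^[0-9]+M$", cigar)
  if (any(bad)) {
    stop("malformed SAM line ", which(!hdr)[which(bad)[1L]],
         ": unsupported CIGAR '", cigar[which(bad)[1L]], "'")
  }
  mlen <- as.integer(sub("M$", "", cigar))
  start0 <- as.integer(getf(4)) - 1L
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                 ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L))
  seqs <- getf(10)
  quals <- getf(11)
  minus <- strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  quals[minus] <- vapply(quals[minus], function(q)
    paste(rev(seq_chars(q)), collapse = ""), character(1))
  tags <- vapply(parts, function(x)
    paste(x[-seq_len(11L)], collapse = "\t"), character(1))
  aln <- data.frame(
    read_id = getf(1), chrom = getf(3), strand = strand,
    start0 = start0, end0 = start0 + mlen,
    score = parse_sam_tag(tags, "AS"), nm = parse_sam_tag(tags, "NM"),
    mate = mate, seq = seqs, qual = quals,
    nh = parse_sam_tag(tags, "NH"), za = parse_sam_tag(tags, "ZA"),
    stringsAsFactors = FALSE
  )
  list(alignments = aln, seqlengths = seqlengths)
}
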