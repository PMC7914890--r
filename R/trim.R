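# Read cleaning: 3' quality trimming, 3' adapter removal, minimum-length
# filtering. Paired and single-end modes differ in the minimum adapter
# overlap (1 vs 3 bases) and in the fate of untrimmed reads: an SE read
# without an adapter hit cannot have its RNA 3' end determined and is
# rejected; a PE read pair keeps full-insert information through the
# mate, so untrimmed PE reads are kept.

#' Trim low-quality bases from the 3' end of a read
#'
#' Implements the running-sum rule: subtract the cutoff from each
#' quality, form partial sums from the 3' end, and cut at the position
#' minimizing the partial sum (no cut when the minimum is >= 0). Ties
#' are resolved towards the leftmost minimum, i.e. maximal trimming.
#'
#' @param seq,qual read bases and Phred+33 quality string.
#' @param cutoff Phred cutoff (default 30).
#' @return list with trimmed `seq`, `qual` and `n_trimmed`.
#' @export
quality_trim_3prime <- function(seq, qual, cutoff = 30L) {
  q <- phred_ints(qual)
  keep <- quality_keep_length(q, cutoff)
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep),
       n_trimmed = length(q) - keep)
}

quality_keep_length <- function(q, cutoff) {
  if (length(q) == 0L) return(0L)
  s <- rev(cumsum(rev(q - cutoff)))  # s[i] = sum over positions i..L
  if (min(s) >= 0) length(q) else which.min(s) - 1L
}

#' Remove a 3' adapter from a read
#'
#' Scans cut positions from the 5' side and removes the read suffix at
#' the first (leftmost, hence longest-removal) position where the read
#' matches the adapter prefix with at most `floor(max_error_rate *
#' overlap)` substitutions and at least `min_overlap` compared bases.
#' Bases beyond the end of the adapter are removed without comparison
#' (read-through into downstream sequence).
#'
#' @param seq,qual read bases and qualities.
#' @param adapter3 adapter sequence.
#' @param min_overlap minimum number of compared bases (1 for PE, 3 for SE).
#' @param max_error_rate allowed mismatch fraction within the overlap.
#' @return list with `seq`, `qual`, `adapter_found`, `n_trimmed`.
#' @export
trim_adapter <- function(seq, qual, adapter3, min_overlap = 1L,
                         max_error_rate = 0.1) {
  if (!nzchar(adapter3)) stop("adapter3 must be non-empty")
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  L <- nchar(seq)
  achars <- seq_chars(adapter3)
  rchars <- seq_chars(seq)
  alen <- length(achars)
  cut <- NA_integer_
  if (L >= min_overlap) {
    for (p in 1:(L - min_overlap + 1L)) {
      ov <- min(L - p + 1L, alen)
      mm <- sum(rchars[p:(p + ov - 1L)] != achars[1:ov])
      if (mm <= floor(max_error_rate * ov)) {
        cut <- p
        break
      }
    }
  }
  if (is.na(cut)) {
    list(seq = seq, qual = qual, adapter_found = FALSE, n_trimmed = 0L)
  } else {
    list(seq = substr(seq, 1L, cut - 1L), qual = substr(qual, 1L, cut - 1L),
         adapter_found = TRUE, n_trimmed = L - cut + 1L)
  }
}

#' Trimming configuration
#'
#' @param adapter3 3' adapter sequence.
#' @param quality_cutoff Phred cutoff for 3' quality trimming.
#' @param min_length minimum kept read length after trimming.
#' @param max_error_rate adapter mismatch fraction.
#' @param min_overlap_pe,min_overlap_se minimum adapter overlap in
#'   paired / single-end mode.
#' @return named list of parameters.
#' @export
trim_params <- function(adapter3 = DEFAULT_ADAPTER3, quality_cutoff = 30L,
                        min_length = 18L, max_error_rate = 0.1,
                        min_overlap_pe = 1L, min_overlap_se = 3L) {
  list(adapter3 = adapter3, quality_cutoff = quality_cutoff,
       min_length = min_length, max_error_rate = max_error_rate,
       min_overlap_pe = min_overlap_pe, min_overlap_se = min_overlap_se)
}

# Trim every read in a table; returns the trimmed table plus per-read
# adapter_found flags. Quality trimming precedes adapter trimming.
trim_read_table <- function(reads, params, min_overlap) {
  n <- nrow(reads)
  adapter_found <- logical(n)
  for (i in seq_len(n)) {
    qt <- quality_trim_3prime(reads$seq[i], reads$qual[i],
                              params$quality_cutoff)
    at <- trim_adapter(qt$seq, qt$qual, params$adapter3, min_overlap,
                       params$max_error_rate)
    reads$seq[i] <- at$seq
    reads$qual[i] <- at$qual
    adapter_found[i] <- at$adapter_found
  }
  reads$adapter_found <- adapter_found
  reads
}

#' Trim a library of reads
#'
#' @param r1 read table (R1 or SE reads).
#' @param r2 mate table for paired-end mode, or `NULL` for single-end.
#' @param params a [trim_params()] list.
#' @return list with `kept_r1`, `kept_r2`, `too_short` (both mates of a
#'   rejected pair), `untrimmed` (SE only) and `tallies`. The
#'   conservation identity kept + too_short + untrimmed == input holds
#'   exactly (in pairs for PE).
#' @export
trim_reads <- function(r1, r2 = NULL, params = trim_params()) {
  validate_reads(r1)
  paired <- !is.null(r2)
  if (paired) {
    validate_reads(r2)
    if (nrow(r1) != nrow(r2) || any(r1$id != r2$id)) {
      stop("R1/R2 mate IDs do not match")
    }
  }
  min_ov <- if (paired) params$min_overlap_pe else params$min_overlap_se
  t1 <- trim_read_table(r1, params, min_ov)
  if (paired) {
    t2 <- trim_read_table(r2, params, min_ov)
    short <- nchar(t1$seq) < params$min_length |
      nchar(t2$seq) < params$min_length
    res <- list(
      kept_r1 = t1[!short, c("id", "seq", "qual"), drop = FALSE],
      kept_r2 = t2[!short, c("id", "seq", "qual"), drop = FALSE],
      too_short = rbind(t1[short, c("id", "seq", "qual"), drop = FALSE],
                        t2[short, c("id", "seq", "qual"), drop = FALSE]),
      untrimmed = r1[0L, c("id", "seq", "qual"), drop = FALSE],
      tallies = c(input = nrow(r1), kept = sum(!short),
                  rejected_short = sum(short), rejected_untrimmed = 0L)
    )
  } else {
    untr <- !t1$adapter_found
    short <- !untr & nchar(t1$seq) < params$min_length
    kept <- !untr & !short
    res <- list(
      kept_r1 = t1[kept, c("id", "seq", "qual"), drop = FALSE],
      kept_r2 = NULL,
      too_short = t1[short, c("id", "seq", "qual"), drop = FALSE],
      untrimmed = r1[untr, c("id", "seq", "qual"), drop = FALSE],
      tallies = c(input = nrow(r1), kept = sum(kept),
                  rejected_short = sum(short),
                  rejected_untrimmed = sum(untr))
    )
  }
  rownames(res$kept_r1) <- NULL
  if (!is.null(res$kept_r2)) rownames(res$kept_r2) <- NULL
  res
}

#' Trim a library from/to FASTQ files
#'
#' Writes kept reads and the sidecar files `<lib>.too_short.fastq` and
#' (SE only) `<lib>.untrimmed.fastq` under `out_dir`.
#'
#' @param lib library identifier used in file names.
#' @param r1_path,r2_path input FASTQ paths (`r2_path = NULL` for SE).
#' @param out_dir output directory.
#' @param params a [trim_params()] list.
#' @return tallies vector (invisibly alongside written paths).
#' @export
trim_fastq <- function(lib, r1_path, r2_path = NULL, out_dir,
                       params = trim_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  r1 <- read_fastq(r1_path)
  r2 <- if (!is.null(r2_path)) read_fastq(r2_path) else NULL
  res <- trim_reads(r1, r2, params)
  out <- list(lib = lib)
  out$r1 <- file.path(out_dir, paste0(lib, "_R1.trim.fastq.gz"))
  write_fastq(res$kept_r1, out$r1)
  if (!is.null(res$kept_r2)) {
    out$r2 <- file.path(out_dir, paste0(lib, "_R2.trim.fastq.gz"))
    write_fastq(res$kept_r2, out$r2)
  }
  write_fastq(res$too_short, file.path(out_dir, paste0(lib, ".too_short.fastq")))
  if (is.null(r2)) {
    write_fastq(res$untrimmed,
                file.path(out_dir, paste0(lib, ".untrimmed.fastq")))
  }
  out$tallies <- res$tallies
  write_tsv(data.frame(lib = lib, metric = names(res$tallies),
                       value = as.integer(res$tallies)),
            file.path(out_dir, paste0(lib, ".trim_stats.tsv")))
  invisible(out)
}
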