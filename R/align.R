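# Native ungapped all-alignments read mapper. Candidate loci come from
# exact k-mer seed hits (every read window, stride 1), from hits of the
# first window with one substitution allowed, and from a pigeonhole tier
# of guaranteed_mm + 1 non-overlapping exact segments which makes the
# mapper provably complete for alignments with at most `guaranteed_mm`
# mismatches. Candidates are extended ungapped over the full read and
# kept when the linear minimum-score function admits them; all valid
# placements are reported.

#' Alignment parameters
#'
#' The score of an ungapped placement is `-mismatch_penalty * mismatches`
#' and a placement of a read of length L is valid when its score is at
#' least `min_score_a + min_score_b * L` (defaults admit `floor(L/3)`
#' mismatches, deliberately permissive so that modified RNAs such as
#' oligo(A)-tailed species survive).
#'
#' @param seed_len exact seed window length (default 22).
#' @param seed_mismatches 0 or 1; with 1 the first seed window is also
#'   queried with one substitution allowed.
#' @param guaranteed_mm completeness guarantee: every placement with at
#'   most this many mismatches is found (pigeonhole seeding with
#'   `guaranteed_mm + 1` read segments). Set to 0 to disable the
#'   pigeonhole tier and rely on seed windows alone.
#' @param min_score_a,min_score_b linear minimum-score function
#'   coefficients f(L) = a + b * L.
#' @param mismatch_penalty score penalty per mismatch.
#' @param report_all report all valid alignments (multi-mapping).
#' @param max_insert maximum paired-end insert span (bp).
#' @param sensitive two-pass mode: unaligned reads are re-seeded with
#'   `sensitive_seed_len`.
#' @param sensitive_seed_len seed length of the second pass (default 14).
#' @return named parameter list.
#' @export
align_params <- function(seed_len = 22L, seed_mismatches = 1L,
                         guaranteed_mm = 3L, min_score_a = 0,
                         min_score_b = -2, mismatch_penalty = 6L,
                         report_all = TRUE, max_insert = 400L,
                         sensitive = TRUE, sensitive_seed_len = 14L) {
  stopifnot(seed_mismatches %in% c(0L, 1L))
  list(seed_len = as.integer(seed_len), seed_mismatches = as.integer(seed_mismatches),
       guaranteed_mm = as.integer(guaranteed_mm), min_score_a = min_score_a,
       min_score_b = min_score_b, mismatch_penalty = as.integer(mismatch_penalty),
       report_all = isTRUE(report_all), max_insert = as.integer(max_insert),
       sensitive = isTRUE(sensitive),
       sensitive_seed_len = as.integer(sensitive_seed_len))
}

max_mismatches <- function(L, params) {
  m <- floor(-(params$min_score_a + params$min_score_b * L) /
               params$mismatch_penalty)
  max(0L, as.integer(m))
}

#' Build an exact k-mer seed index over a genome
#'
#' Maps every k-mer of the forward strand to its (0-based) positions;
#' reverse-strand hits are found by querying the reverse complement of
#' the read. k-mers containing non-ACGT characters are skipped.
#'
#' @param genome an `sf_genome`.
#' @param k seed length (>= 8).
#' @return an `sf_seed_index`.
#' @export
build_seed_index <- function(genome, k = 22L) {
  k <- as.integer(k)
  if (k < 8L) stop("seed length k must be >= 8")
  kmer_env <- function(s, kk) {
    e <- new.env(hash = TRUE, parent = emptyenv())
    n <- nchar(s)
    if (n >= kk) {
      km <- substring(s, 1:(n - kk + 1L), kk:n)
      ok <- !grepl("[^ACGT]", km)
      list2env(split((0:(n - kk))[ok], km[ok]), envir = e)
    }
    e
  }
  tabs <- lapply(genome$seq, kmer_env, kk = k)
  # coarse 4-mer sub-index backing variable-length segment lookups
  sub4 <- lapply(genome$seq, kmer_env, kk = 4L)
  structure(list(genome = genome, k = k, tabs = tabs, sub4 = sub4),
            class = "sf_seed_index")
}

#' Look up the genomic positions of a k-mer in a seed index
#'
#' Queries of the index's own k use the precomputed hash; other lengths
#' fall back to an exact scan.
#'
#' @param index an `sf_seed_index`.
#' @param kmer query sequence.
#' @param chrom chromosome name.
#' @return integer vector of 0-based start positions (possibly empty).
#' @export
seed_lookup <- function(index, kmer, chrom) {
  if (nchar(kmer) == index$k) {
    hit <- get0(kmer, envir = index$tabs[[chrom]], inherits = FALSE)
    if (is.null(hit)) integer(0) else hit
  } else {
    m <- Biostrings::matchPattern(kmer, index$genome$dna[[chrom]])
    Biostrings::start(m) - 1L
  }
}

# Exact-window hits via the 4-mer sub-index: positions where the window
# matches the genome exactly (verified against the genome string).
exact_window_hits <- function(win, index, chrom) {
  wl <- nchar(win)
  h4 <- get0(substr(win, 1L, 4L), envir = index$sub4[[chrom]],
             inherits = FALSE)
  if (is.null(h4)) return(integer(0))
  if (wl == 4L) return(h4)
  gseq <- index$genome$seq[[chrom]]
  h4 <- h4[h4 + wl <= nchar(gseq)]
  h4[substring(gseq, h4 + 1L, h4 + wl) == win]
}

# All single-substitution neighbors of a k-mer (excluding itself).
one_sub_neighbors <- function(w) {
  k <- nchar(w)
  ch <- seq_chars(w)
  out <- character(0)
  for (p in seq_len(k)) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      v <- ch; v[p] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# Candidate 0-based start positions for `query` on one chromosome.
candidate_starts <- function(query, index, chrom, params) {
  L <- nchar(query)
  clen <- nchar(index$genome$seq[[chrom]])
  if (L > clen) return(integer(0))
  k <- min(params$seed_len, L)
  cand <- list()

  # tier 1: every exact k-window, stride 1
  offs <- 0:(L - k)
  if (k == index$k) {
    wins <- substring(query, offs + 1L, offs + k)
    hits <- mget(unique(wins), envir = index$tabs[[chrom]],
                 ifnotfound = list(NULL))
    for (oi in seq_along(offs)) {
      h <- hits[[wins[oi]]]
      if (!is.null(h)) cand[[length(cand) + 1L]] <- h - offs[oi]
    }
  } else {
    for (oi in seq_along(offs)) {
      h <- exact_window_hits(substring(query, offs[oi] + 1L, offs[oi] + k),
                             index, chrom)
      if (length(h)) cand[[length(cand) + 1L]] <- h - offs[oi]
    }
  }

  # tier 2: first window with one substitution allowed
  if (params$seed_mismatches >= 1L) {
    w0 <- substr(query, 1L, k)
    if (k == index$k) {
      hits <- mget(one_sub_neighbors(w0), envir = index$tabs[[chrom]],
                   ifnotfound = list(NULL))
      cand <- c(cand, Filter(Negate(is.null), hits))
    } else {
      # pigeonhole for 1 substitution: one half of the window is exact
      half <- k %/% 2L
      h1 <- exact_window_hits(substr(w0, 1L, half), index, chrom)
      h2 <- exact_window_hits(substr(w0, half + 1L, k), index, chrom) - half
      h <- unique(c(h1, h2))
      if (length(h)) {
        # verify the full window carries at most one substitution
        h <- h[h >= 0L & h + k <= clen]
        if (length(h)) {
          gseq <- index$genome$seq[[chrom]]
          wch <- seq_chars(w0)
          mm <- vapply(h, function(p)
            sum(seq_chars(substr(gseq, p + 1L, p + k)) != wch), integer(1))
          cand[[length(cand) + 1L]] <- h[mm <= 1L]
        }
      }
    }
  }

  # tier 3: pigeonhole segments -> completeness up to guaranteed_mm
  g <- min(params$guaranteed_mm, max_mismatches(L, params))
  if (g > 0L) {
    nseg <- g + 1L
    if (L %/% nseg >= 4L) {
      bounds <- as.integer(round(seq(0L, L, length.out = nseg + 1L)))
      for (si in seq_len(nseg)) {
        h <- get0(substr(query, bounds[si] + 1L, bounds[si] + 4L),
                  envir = index$sub4[[chrom]], inherits = FALSE)
        if (!is.null(h)) cand[[length(cand) + 1L]] <- h - bounds[si]
      }
    }
  }
  cand <- unique(unlist(cand, use.names = FALSE)) %||% integer(0)
  sort(cand[cand >= 0L & cand <= clen - L])
}

# Align one read sequence; returns list of vectors (internal).
align_one <- function(seq, index, params) {
  L <- nchar(seq)
  if (L == 0L) stop("cannot align an empty read")
  mm_max <- max_mismatches(L, params)
  out <- list(chrom = character(0), strand = character(0),
              start0 = integer(0), nm = integer(0))
  for (chrom in names(index$genome$seq)) {
    for (strand in c("+", "-")) {
      query <- if (strand == "+") seq else revcomp(seq)
      starts <- candidate_starts(query, index, chrom, params)
      if (!length(starts)) next
      nm <- Biostrings::neditStartingAt(
        Biostrings::DNAString(query), index$genome$dna[[chrom]],
        starting.at = starts + 1L, with.indels = FALSE
      )
      ok <- nm <= mm_max
      if (any(ok)) {
        out$chrom <- c(out$chrom, rep(chrom, sum(ok)))
        out$strand <- c(out$strand, rep(strand, sum(ok)))
        out$start0 <- c(out$start0, starts[ok])
        out$nm <- c(out$nm, as.integer(nm[ok]))
      }
    }
  }
  out
}

#' Align one read and return all valid placements
#'
#' @param seq read sequence.
#' @param index an `sf_seed_index` from [build_seed_index()].
#' @param params an [align_params()] list.
#' @param read_id,mate,qual metadata carried into the records.
#' @return alignment table (possibly empty) with columns `read_id`,
#'   `chrom`, `strand`, `start0`, `end0`, `score`, `nm`, `mate`, `seq`,
#'   `qual`.
#' @export
align_read <- function(seq, index, params = align_params(),
                       read_id = "read", mate = 0L, qual = NULL) {
  hits <- align_one(seq, index, params)
  n <- length(hits$start0)
  if (!params$report_all && n > 1L) {
    best <- which.min(hits$nm)  # single best placement, leftmost tie
    hits <- lapply(hits, `[`, best)
    n <- 1L
  }
  L <- nchar(seq)
  data.frame(
    read_id = rep(read_id, n), chrom = hits$chrom, strand = hits$strand,
    start0 = hits$start0, end0 = hits$start0 + L,
    score = -params$mismatch_penalty * hits$nm, nm = hits$nm,
    mate = rep(as.integer(mate), n), seq = rep(seq, n),
    qual = rep(qual %||% strrep("I", L), n), stringsAsFactors = FALSE
  )
}

#' Align a table of reads
#'
#' @param reads read table (`id`, `seq`, `qual`).
#' @param index an `sf_seed_index`.
#' @param params an [align_params()] list.
#' @param mate mate number recorded in the records (0 for SE).
#' @return alignment table.
#' @export
align_reads <- function(reads, index, params = align_params(), mate = 0L) {
  acc <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    hits <- align_one(reads$seq[i], index, params)
    acc[[i]] <- hits
  }
  n_per <- vapply(acc, function(h) length(h$start0), integer(1))
  idx <- rep(seq_len(nrow(reads)), n_per)
  L <- nchar(reads$seq)[idx]
  start0 <- unlist(lapply(acc, `[[`, "start0"), use.names = FALSE) %||% integer(0)
  nm <- unlist(lapply(acc, `[[`, "nm"), use.names = FALSE) %||% integer(0)
  data.frame(
    read_id = reads$id[idx],
    chrom = unlist(lapply(acc, `[[`, "chrom"), use.names = FALSE) %||% character(0),
    strand = unlist(lapply(acc, `[[`, "strand"), use.names = FALSE) %||% character(0),
    start0 = start0, end0 = start0 + L,
    score = -params$mismatch_penalty * nm, nm = nm,
    mate = rep(as.integer(mate), length(idx)),
    seq = reads$seq[idx], qual = reads$qual[idx],
    stringsAsFactors = FALSE
  )
}
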