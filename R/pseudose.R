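# Conversion of paired-end placements to pseudo single-end full-insert
# records. Overlapping mate positions are merged base-wise by sequencing
# quality; gaps between non-overlapping mates are filled from the genome
# at the maximum quality. Records are then filtered by mismatch count
# (with an optional exemption of untemplated terminal 3' adenosines) and
# by the number of genomic placements.
#
# Pseudo-SE tables store `seq`/`qual` in read (RNA 5'->3') orientation,
# like alignment tables, so the SAM writer handles them uniformly.

#' Pseudo-SE filtering parameters
#'
#' @param max_mm maximum mismatches after exemptions (default 2).
#' @param max_nh maximum genomic placements per read (default 50).
#' @param oligoA_exempt exempt untemplated terminal 3' A runs from the
#'   mismatch count (default TRUE).
#' @param qmax maximum Phred score, used as the merged-quality cap and
#'   the gap-fill quality (default 41, the Phred+33 ceiling).
#' @return named parameter list.
#' @export
pseudose_params <- function(max_mm = 2L, max_nh = 50L, oligoA_exempt = TRUE,
                            qmax = 41L) {
  list(max_mm = as.integer(max_mm), max_nh = as.integer(max_nh),
       oligoA_exempt = isTRUE(oligoA_exempt), qmax = as.integer(qmax))
}

# Orient one mate's bases/qualities to the forward genome strand.
forward_mate <- function(seq, qual, strand) {
  ch <- seq_chars(seq); q <- phred_ints(qual)
  if (strand == "-") {
    ch <- seq_chars(revcomp(seq))
    q <- rev(q)
  }
  list(ch = ch, q = q)
}

#' Merge a mate pair into one full-insert record
#'
#' The insert spans from the leftmost mate start to the rightmost mate
#' end. At positions covered by both mates, agreeing bases keep the base
#' with quality `min(q1 + q2, qmax)`; disagreeing positions take the
#' higher-quality base with quality `|q1 - q2|` (mate 1 wins exact
#' quality ties). Positions covered by neither mate are filled with the
#' genomic base at quality `qmax`.
#'
#' @param pair one row of a [join_pairs()] table.
#' @param genome an `sf_genome`.
#' @param qmax quality cap / gap-fill quality.
#' @return one-row pseudo-SE table (`seq`/`qual` in read orientation)
#'   with `gap_filled` = number of genome-filled positions.
#' @export
merge_pair <- function(pair, genome, qmax = 41L) {
  core <- merge_pair_core(pair, genome, qmax)
  data.frame(
    read_id = pair$read_id, chrom = pair$chrom, strand = pair$strand,
    start0 = pair$start0, end0 = pair$end0, seq = core$seq,
    qual = core$qual, score = pair$score, nm = NA_integer_, mate = 0L,
    nh = if (!is.null(pair$nh)) pair$nh else NA_integer_,
    za = NA_integer_, gap_filled = core$gap_filled,
    stringsAsFactors = FALSE
  )
}

# Core of the merge for one pair; `pair` is any list-like with the pair
# fields. Returns read-oriented seq/qual and the gap-fill count.
merge_pair_core <- function(pair, genome, qmax = 41L) {
  s <- pair$start0; e <- pair$end0
  gch <- seq_chars(genome_subseq(genome, pair$chrom, s, e, "+"))
  len <- e - s
  base <- gch
  qv <- rep.int(qmax, len)
  cov1 <- cov2 <- logical(len)

  f1 <- forward_mate(pair$r1_seq, pair$r1_qual, pair$r1_strand)
  f2 <- forward_mate(pair$r2_seq, pair$r2_qual, pair$r2_strand)
  i1 <- (pair$r1_start0 - s + 1L):(pair$r1_end0 - s)
  i2 <- (pair$r2_start0 - s + 1L):(pair$r2_end0 - s)
  cov1[i1] <- TRUE; cov2[i2] <- TRUE

  m1base <- rep(NA_character_, len); m1q <- rep(NA_integer_, len)
  m2base <- rep(NA_character_, len); m2q <- rep(NA_integer_, len)
  m1base[i1] <- f1$ch; m1q[i1] <- f1$q
  m2base[i2] <- f2$ch; m2q[i2] <- f2$q

  only1 <- cov1 & !cov2
  only2 <- cov2 & !cov1
  base[only1] <- m1base[only1]; qv[only1] <- m1q[only1]
  base[only2] <- m2base[only2]; qv[only2] <- m2q[only2]

  both <- cov1 & cov2
  if (any(both)) {
    agree <- both & m1base == m2base
    base[agree] <- m1base[agree]
    qv[agree] <- pmin(m1q[agree] + m2q[agree], qmax)
    dis <- both & m1base != m2base
    if (any(dis)) {
      take2 <- dis & m2q > m1q
      base[dis] <- m1base[dis]
      base[take2] <- m2base[take2]
      qv[dis] <- abs(m1q[dis] - m2q[dis])
    }
  }
  gap_filled <- sum(!cov1 & !cov2)

  strand <- pair$strand
  seq_fwd <- paste(base, collapse = "")
  seq_read <- if (strand == "-") revcomp(seq_fwd) else seq_fwd
  qual_read <- if (strand == "-") phred_string(rev(qv)) else phred_string(qv)
  list(seq = seq_read, qual = qual_read, gap_filled = gap_filled)
}

#' Convert an SE alignment table to pseudo-SE records
#'
#' Identity conversion (no merging, `gap_filled = 0`); the same
#' downstream filtering applies as for merged records.
#'
#' @param aln SE alignment table (with `nh` from the stratum filter).
#' @return pseudo-SE table.
#' @export
passthrough_se <- function(aln) {
  data.frame(
    read_id = aln$read_id, chrom = aln$chrom, strand = aln$strand,
    start0 = aln$start0, end0 = aln$end0, seq = aln$seq, qual = aln$qual,
    score = aln$score, nm = aln$nm, mate = 0L,
    nh = if ("nh" %in% names(aln)) aln$nh else NA_integer_,
    za = NA_integer_,
    gap_filled = rep(0L, nrow(aln)), stringsAsFactors = FALSE
  )
}

# Count mismatches of one pseudo-SE record against the genome and
# measure the exempted terminal oligo(A) run (read orientation).
count_mismatches <- function(rec, genome, oligoA_exempt) {
  gfwd <- seq_chars(genome_subseq(genome, rec$chrom, rec$start0, rec$end0, "+"))
  rfwd <- seq_chars(if (rec$strand == "-") revcomp(rec$seq) else rec$seq)
  mism_fwd <- rfwd != gfwd
  # read-orientation views
  rch <- seq_chars(rec$seq)
  mism <- if (rec$strand == "-") rev(mism_fwd) else mism_fwd
  L <- length(rch)
  oligoA <- 0L
  if (oligoA_exempt && L > 0L) {
    i <- L
    while (i >= 1L && rch[i] == "A" && mism[i]) {
      oligoA <- oligoA + 1L
      i <- i - 1L
    }
  }
  list(n_mismatch = sum(mism) - oligoA, oligoA_len = oligoA)
}

#' Filter pseudo-SE records by mismatches and placement count
#'
#' Mismatches are counted against the genome; with `oligoA_exempt`, a
#' maximal terminal run of mismatching A's at the read's 3' end is
#' excluded from the count and recorded (templated, genome-matching A's
#' never count towards the run). A record is kept when `n_mismatch <=
#' max_mm` and its read has at most `max_nh` placements.
#'
#' @param ps pseudo-SE table.
#' @param genome an `sf_genome`.
#' @param params a [pseudose_params()] list.
#' @return list of tables `kept`, `discarded_mm`, `discarded_multi`,
#'   `oligoA` (kept records with a non-zero exempted run) and `tallies`.
#'   Kept records carry updated `nm`, `za` and recomputed `nh`.
#' @export
mismatch_filter <- function(ps, genome, params = pseudose_params()) {
  n <- nrow(ps)
  status <- character(n)
  if (n > 0L) {
    cols <- as.list(ps)  # column access avoids per-row data.frame cost
    for (i in seq_len(n)) {
      rec <- list(chrom = cols$chrom[i], strand = cols$strand[i],
                  start0 = cols$start0[i], end0 = cols$end0[i],
                  seq = cols$seq[i])
      mm <- count_mismatches(rec, genome, params$oligoA_exempt)
      ps$nm[i] <- mm$n_mismatch
      ps$za[i] <- if (mm$oligoA_len > 0L) mm$oligoA_len else NA_integer_
      status[i] <- if (!is.na(cols$nh[i]) && cols$nh[i] > params$max_nh) {
        "discarded_multi"
      } else if (mm$n_mismatch > params$max_mm) {
        "discarded_mm"
      } else "kept"
    }
  }
  kept <- ps[status == "kept", , drop = FALSE]
  if (nrow(kept) > 0L) {
    nh <- table(kept$read_id)
    kept$nh <- as.integer(nh[kept$read_id])
    rownames(kept) <- NULL
  }
  list(
    kept = kept,
    discarded_mm = ps[status == "discarded_mm", , drop = FALSE],
    discarded_multi = ps[status == "discarded_multi", , drop = FALSE],
    oligoA = kept[!is.na(kept$za) & kept$za > 0L, , drop = FALSE],
    tallies = c(input = n, kept = sum(status == "kept"),
                discarded_mm = sum(status == "discarded_mm"),
                discarded_multi = sum(status == "discarded_multi"),
                oligoA = sum(!is.na(kept$za) & kept$za > 0L))
  )
}

#' Full pseudo-SE stage
#'
#' Merges stratum-retained pair placements (or passes SE placements
#' through) and applies the mismatch/multi-placement filter.
#'
#' @param retained stratum output: pair table (PE) or alignment table (SE).
#' @param genome an `sf_genome`.
#' @param params a [pseudose_params()] list.
#' @param paired whether `retained` is a pair table.
#' @return as [mismatch_filter()].
#' @export
pseudose <- function(retained, genome, params = pseudose_params(),
                     paired = TRUE) {
  ps <- if (paired) {
    if (is.null(retained) || nrow(retained) == 0L) {
      passthrough_se(cbind(empty_alignments(), nh = integer(0)))
    } else {
      n <- nrow(retained)
      cols <- as.list(retained)
      seqs <- character(n); quals <- character(n); gaps <- integer(n)
      for (i in seq_len(n)) {
        core <- merge_pair_core(lapply(cols, `[`, i), genome, params$qmax)
        seqs[i] <- core$seq; quals[i] <- core$qual
        gaps[i] <- core$gap_filled
      }
      data.frame(
        read_id = cols$read_id, chrom = cols$chrom, strand = cols$strand,
        start0 = cols$start0, end0 = cols$end0, seq = seqs, qual = quals,
        score = cols$score, nm = NA_integer_, mate = 0L,
        nh = cols$nh %||% NA_integer_, za = NA_integer_,
        gap_filled = gaps, stringsAsFactors = FALSE
      )
    }
  } else {
    passthrough_se(retained)
  }
  mismatch_filter(ps, genome, params)
}
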