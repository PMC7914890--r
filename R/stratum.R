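# Best-stratum filtering: keep only the alignments achieving each
# read's (or pair's) maximal score, and orchestrate the sensitive
# two-pass alignment (default seed length first, shorter seed on the
# leftovers, union of both retained sets).

#' Join mate alignments into candidate pair placements
#'
#' Mates must lie on the same chromosome in opposite orientations
#' (forward mate leftmost), with an insert span of at most
#' `max_insert`. The pair score is the sum of the mate scores.
#'
#' @param aln alignment table with `mate` 1/2 rows.
#' @param max_insert maximum insert span (bp).
#' @return pair table: `read_id`, `chrom`, `strand` (insert strand =
#'   strand of mate 1), `start0`, `end0` (insert span), `score`, and the
#'   per-mate fields `r1_*`, `r2_*`.
#' @export
join_pairs <- function(aln, max_insert = 400L) {
  i1 <- which(aln$mate == 1L)
  i2 <- which(aln$mate == 2L)
  s1 <- split(i1, aln$read_id[i1])
  s2 <- split(i2, aln$read_id[i2])
  common <- intersect(names(s1), names(s2))
  # all mate1 x mate2 index combinations per read
  ii <- vector("list", length(common)); jj <- vector("list", length(common))
  for (k in seq_along(common)) {
    g <- expand.grid(i = s1[[common[k]]], j = s2[[common[k]]])
    ii[[k]] <- g$i; jj[[k]] <- g$j
  }
  i <- unlist(ii, use.names = FALSE) %||% integer(0)
  j <- unlist(jj, use.names = FALSE) %||% integer(0)

  ok <- aln$chrom[i] == aln$chrom[j] & aln$strand[i] != aln$strand[j]
  i <- i[ok]; j <- j[ok]
  # forward mate on the left, reverse mate on the right (FR orientation)
  plus_is_1 <- aln$strand[i] == "+"
  p <- ifelse(plus_is_1, i, j)
  m <- ifelse(plus_is_1, j, i)
  ok <- aln$start0[p] <= aln$start0[m] & aln$end0[p] <= aln$end0[m] &
    aln$end0[m] - aln$start0[p] <= max_insert
  i <- i[ok]; j <- j[ok]; p <- p[ok]; m <- m[ok]

  data.frame(
    read_id = aln$read_id[i], chrom = aln$chrom[i], strand = aln$strand[i],
    start0 = aln$start0[p], end0 = aln$end0[m],
    score = aln$score[i] + aln$score[j],
    r1_strand = aln$strand[i], r1_start0 = aln$start0[i],
    r1_end0 = aln$end0[i], r1_seq = aln$seq[i], r1_qual = aln$qual[i],
    r1_nm = aln$nm[i], r1_score = aln$score[i],
    r2_strand = aln$strand[j], r2_start0 = aln$start0[j],
    r2_end0 = aln$end0[j], r2_seq = aln$seq[j], r2_qual = aln$qual[j],
    r2_nm = aln$nm[j], r2_score = aln$score[j],
    stringsAsFactors = FALSE
  )
}

#' Keep only best-stratum alignments
#'
#' Retains, per read, exactly the rows achieving the maximal score
#' (pair score for joined pairs). Ties are all kept: they are the
#' multi-mapped placements.
#'
#' @param aln alignment or pair table with `read_id` and `score`.
#' @return the filtered table with an `nh` column (retained placements
#'   per read).
#' @export
best_stratum_filter <- function(aln) {
  if (is.null(aln) || nrow(aln) == 0L) {
    if (!is.null(aln)) aln$nh <- integer(0)
    return(aln)
  }
  best <- stats::ave(aln$score, aln$read_id, FUN = max)
  kept <- aln[aln$score == best, , drop = FALSE]
  nh <- table(kept$read_id)
  kept$nh <- as.integer(nh[kept$read_id])
  rownames(kept) <- NULL
  kept
}

# One alignment pass: align, (join pairs), stratum-filter.
align_pass <- function(r1, r2, index, params) {
  if (is.null(r2)) {
    aln <- align_reads(r1, index, params, mate = 0L)
    best_stratum_filter(aln)
  } else {
    a1 <- align_reads(r1, index, params, mate = 1L)
    a2 <- align_reads(r2, index, params, mate = 2L)
    pairs <- join_pairs(rbind(a1, a2), params$max_insert)
    best_stratum_filter(pairs)
  }
}

#' Sensitive two-pass alignment with best-stratum filtering
#'
#' Pass 1 uses `params$seed_len`; reads (pairs) without a valid
#' placement are re-aligned with `params$sensitive_seed_len` and the
#' retained sets are combined. A read never appears in both sets. With
#' `params$sensitive = FALSE` only pass 1 runs.
#'
#' @param r1 read table (R1 or SE).
#' @param r2 mate table or `NULL` for SE.
#' @param genome an `sf_genome`.
#' @param params an [align_params()] list.
#' @return list with `retained` (stratum-filtered alignment or pair
#'   table with `nh`), `unaligned_r1`, `unaligned_r2` (read tables) and
#'   `tallies`.
#' @export
sensitive_align <- function(r1, r2 = NULL, genome, params = align_params()) {
  idx1 <- build_seed_index(genome, params$seed_len)
  kept <- align_pass(r1, r2, idx1, params)
  aligned_ids <- unique(kept$read_id)
  left <- !(r1$id %in% aligned_ids)
  if (params$sensitive && any(left)) {
    idx2 <- build_seed_index(genome, params$sensitive_seed_len)
    params2 <- params
    params2$seed_len <- params$sensitive_seed_len
    kept2 <- align_pass(r1[left, , drop = FALSE],
                        if (is.null(r2)) NULL else r2[left, , drop = FALSE],
                        idx2, params2)
    kept <- rbind_tables(list(kept, kept2)) %||% kept
    aligned_ids <- unique(kept$read_id)
    left <- !(r1$id %in% aligned_ids)
  }
  list(
    retained = kept,
    unaligned_r1 = r1[left, , drop = FALSE],
    unaligned_r2 = if (is.null(r2)) NULL else r2[left, , drop = FALSE],
    tallies = c(input = nrow(r1), aligned = length(aligned_ids),
                unaligned = sum(left),
                retained_placements = if (is.null(kept)) 0L else nrow(kept))
  )
}
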