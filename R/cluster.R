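# Redundancy reduction across libraries: count / relative-coverage
# filtering, overlap clustering with greedy representative selection,
# and sequence-identity clustering gated by similarity of the coverage
# contigs surrounding each product (so that identical sequences in
# genuinely different genomic contexts are kept apart).

#' Clustering parameters
#'
#' @param tolerance overlap-cluster distance tolerance: maximum
#'   `|start difference| + |end difference|` between a member and its
#'   representative (default 2, mirroring the counting tolerance).
#' @param min_count minimum assigned read count (default 10).
#' @param min_relcov minimum relative coverage (default 0.5).
#' @param id_product sequence identity required between products
#'   (default 1.0: the shorter is a perfect ungapped match within the
#'   longer).
#' @param id_contig identity required between their coverage contigs
#'   (default 0.9).
#' @param len_cutoff minimum shorter/longer contig length ratio
#'   (default 0.5).
#' @return named parameter list.
#' @export
cluster_params <- function(tolerance = 2L, min_count = 10L, min_relcov = 0.5,
                           id_product = 1.0, id_contig = 0.9,
                           len_cutoff = 0.5) {
  list(tolerance = as.integer(tolerance), min_count = as.integer(min_count),
       min_relcov = min_relcov, id_product = id_product,
       id_contig = id_contig, len_cutoff = len_cutoff)
}

# Sum, per product, of overlap widths with a set of read intervals
# (same chrom/strand assumed filtered by caller).
overlap_base_sum <- function(p_start0, p_end0, r_start0, r_end0) {
  if (!length(r_start0)) return(numeric(length(p_start0)))
  ip <- IRanges::IRanges(p_start0 + 1L, p_end0)
  ir <- IRanges::IRanges(r_start0 + 1L, r_end0)
  hits <- IRanges::findOverlaps(ip, ir)
  if (!length(hits)) return(numeric(length(p_start0)))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- pmin(p_end0[qh], r_end0[sh]) - pmax(p_start0[qh], r_start0[sh])
  as.numeric(tapply(w, factor(qh, levels = seq_along(p_start0)), sum,
                    default = 0))
}

#' Relative coverage of products
#'
#' Mean per-position depth over the product interval from its assigned
#' reads, divided by the mean depth from all (same-strand) aligned
#' reads over the same interval; 0 when the denominator is 0.
#'
#' @param products product table.
#' @param reads pseudo-SE table (all placements of the library/pool).
#' @param assignment assignment table from
#'   [assign_reads_to_products()] linking `reads` rows to `products`
#'   rows.
#' @return numeric vector in \[0, 1\], one value per product.
#' @export
relative_coverage <- function(products, reads, assignment) {
  n <- nrow(products)
  if (n == 0L) return(numeric(0))
  assigned <- numeric(n); total <- numeric(n)
  key_p <- paste(products$chrom, products$strand)
  key_r <- paste(reads$chrom, reads$strand)
  for (key in unique(key_p)) {
    pi <- which(key_p == key); ri <- which(key_r == key)
    total[pi] <- overlap_base_sum(products$start0[pi], products$end0[pi],
                                  reads$start0[ri], reads$end0[ri])
  }
  for (pi in unique(assignment$product_row)) {
    ri <- assignment$read_row[assignment$product_row == pi]
    w <- pmin(products$end0[pi], reads$end0[ri]) -
      pmax(products$start0[pi], reads$start0[ri])
    assigned[pi] <- sum(pmax(0L, w))
  }
  ifelse(total > 0, assigned / total, 0)
}

#' Filter candidate products by count and relative coverage
#'
#' @param products product table with `count` and `relcov` columns.
#' @param min_count minimum assigned read count.
#' @param min_relcov minimum relative coverage (0 disables the
#'   background filter).
#' @return filtered table.
#' @export
filter_candidates <- function(products, min_count = 10L, min_relcov = 0.5) {
  keep <- products$count >= min_count & products$relcov >= min_relcov
  out <- products[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine per-library products into a unique candidate set
#'
#' Identical intervals are collapsed; per-library counts are summed
#' into `total_count` and end supports keep their maxima.
#'
#' @param product_list list of per-library product tables.
#' @return combined unique product table.
#' @export
combine_libraries <- function(product_list) {
  all <- rbind_tables(product_list)
  if (is.null(all)) return(NULL)
  key <- paste(all$chrom, all$strand, all$start0, all$end0)
  out <- do.call(rbind, lapply(split(all, key), function(g) {
    data.frame(chrom = g$chrom[1L], strand = g$strand[1L],
               start0 = g$start0[1L], end0 = g$end0[1L],
               five_support = max(g$five_support),
               three_support = max(g$three_support),
               total_count = sum(g$count), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$strand, out$start0, out$end0), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Endpoint distance between products i and all products (Inf across
# chrom/strand).
product_distance <- function(products) {
  n <- nrow(products)
  d <- abs(outer(products$start0, products$start0, "-")) +
    abs(outer(products$end0, products$end0, "-"))
  same <- outer(products$chrom, products$chrom, "==") &
    outer(products$strand, products$strand, "==")
  d[!same] <- Inf
  d
}

#' Cluster products by overlap and select representatives
#'
#' Products P and Q are compatible when they share chromosome and
#' strand and `|startP - startQ| + |endP - endQ| <= tolerance`.
#' Representatives are chosen greedily: the product compatible with the
#' most not-yet-represented products forms the next cluster (ties go to
#' the higher total read count, then the leftmost start, then the
#' leftmost end). Clusters are disjoint and cover the input.
#'
#' @param products unique product table (needs `total_count`; a `count`
#'   column is used as fallback).
#' @param tolerance distance tolerance (see [cluster_params()]).
#' @return the input table with `cluster` and `is_representative`
#'   columns added.
#' @export
cluster_by_overlap <- function(products, tolerance = 2L) {
  n <- nrow(products)
  products$cluster <- integer(n)
  products$is_representative <- logical(n)
  if (n == 0L) return(products)
  cnt <- products$total_count %||% products$count %||% rep(0, n)
  if (is.null(products$total_count) && !is.null(products$count)) {
    cnt <- products$count
  }
  d <- product_distance(products)
  compat <- d <= tolerance
  represented <- logical(n)
  cl <- 0L
  while (!all(represented)) {
    open <- which(!represented)
    cover <- vapply(open, function(i) sum(compat[i, open]), integer(1))
    ord <- order(-cover, -cnt[open], products$start0[open],
                 products$end0[open], products$chrom[open],
                 products$strand[open])
    rep_i <- open[ord[1L]]
    members <- open[compat[rep_i, open]]
    cl <- cl + 1L
    products$cluster[members] <- cl
    products$is_representative[rep_i] <- TRUE
    represented[members] <- TRUE
  }
  products
}

#' Build coverage contigs from pooled reads
#'
#' Maximal intervals of strictly positive pooled read coverage, per
#' chromosome and strand.
#'
#' @param reads pseudo-SE table pooled over libraries.
#' @return data.frame with `chrom`, `strand`, `start0`, `end0`.
#' @export
build_contigs <- function(reads) {
  out <- list()
  for (grp in split(reads, paste(reads$chrom, reads$strand))) {
    red <- IRanges::reduce(IRanges::IRanges(grp$start0 + 1L, grp$end0))
    out[[length(out) + 1L]] <- data.frame(
      chrom = grp$chrom[1L], strand = grp$strand[1L],
      start0 = IRanges::start(red) - 1L, end0 = IRanges::end(red),
      stringsAsFactors = FALSE
    )
  }
  res <- rbind_tables(out)
  res <- res[order(res$chrom, res$strand, res$start0), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Maximal ungapped sliding identity between two sequences
#'
#' The shorter sequence is slid along the longer; identity is the
#' maximal fraction of matching positions over the shorter length.
#'
#' @param a,b sequences.
#' @return identity in \[0, 1\].
#' @export
sliding_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L) return(0)
  ach <- seq_chars(a); bch <- seq_chars(b)
  best <- 0
  for (off in 0:(lb - la)) {
    best <- max(best, sum(ach == bch[(off + 1L):(off + la)]) / la)
    if (best == 1) break
  }
  best
}

# Map each product to its containing (max-overlap) contig row.
product_contig <- function(products, contigs) {
  idx <- rep(NA_integer_, nrow(products))
  key_p <- paste(products$chrom, products$strand)
  key_c <- paste(contigs$chrom, contigs$strand)
  for (key in unique(key_p)) {
    pi <- which(key_p == key); ci <- which(key_c == key)
    if (!length(ci)) next
    ip <- IRanges::IRanges(products$start0[pi] + 1L, products$end0[pi])
    ic <- IRanges::IRanges(contigs$start0[ci] + 1L, contigs$end0[ci])
    hits <- IRanges::findOverlaps(ip, ic, select = "first")
    idx[pi] <- ci[hits]
  }
  idx
}

#' Cluster representatives by sequence identity with contig support
#'
#' Greedy longest-first clustering: a product joins an earlier
#' representative when their sequences match at `id_product` identity
#' (default 1.0: the shorter is an exact ungapped submatch of the
#' longer) AND their containing coverage contigs match at `id_contig`
#' identity with a shorter/longer length ratio of at least
#' `len_cutoff`. The longer product (tie: higher count) represents the
#' merged cluster.
#'
#' @param reps representative product table (from overlap clustering).
#' @param contigs contig table from [build_contigs()].
#' @param genome an `sf_genome` (for sequence extraction).
#' @param params a [cluster_params()] list.
#' @return list with `representatives` (final table) and `members`
#'   (map of each input row to its final representative row).
#' @export
cluster_by_sequence <- function(reps, contigs, genome,
                                params = cluster_params()) {
  n <- nrow(reps)
  if (n == 0L) return(list(representatives = reps, members = integer(0)))
  cnt <- reps$total_count %||% reps$count %||% rep(0, n)
  if (is.null(reps$total_count) && !is.null(reps$count)) cnt <- reps$count
  len <- reps$end0 - reps$start0
  ord <- order(-len, -cnt, reps$chrom, reps$strand, reps$start0)
  pseq <- vapply(seq_len(n), function(i)
    genome_subseq(genome, reps$chrom[i], reps$start0[i], reps$end0[i],
                  reps$strand[i]), character(1))
  cidx <- product_contig(reps, contigs)
  cseq <- rep(NA_character_, n)
  has_c <- !is.na(cidx)
  cseq[has_c] <- vapply(which(has_c), function(i)
    genome_subseq(genome, contigs$chrom[cidx[i]], contigs$start0[cidx[i]],
                  contigs$end0[cidx[i]], contigs$strand[cidx[i]]),
    character(1))

  head_of <- rep(NA_integer_, n)  # final representative row per input row
  heads <- integer(0)
  for (i in ord) {
    joined <- NA_integer_
    for (h in heads) {
      if (sliding_identity(pseq[i], pseq[h]) < params$id_product) next
      if (is.na(cseq[i]) || is.na(cseq[h])) next
      lc <- nchar(cseq[i]); lh <- nchar(cseq[h])
      if (min(lc, lh) / max(lc, lh) < params$len_cutoff) next
      if (sliding_identity(cseq[i], cseq[h]) < params$id_contig) next
      joined <- h
      break
    }
    if (is.na(joined)) {
      heads <- c(heads, i)
      head_of[i] <- i
    } else {
      head_of[i] <- joined
    }
  }
  out <- reps[heads, , drop = FALSE]
  rownames(out) <- NULL
  list(representatives = out, members = head_of)
}
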