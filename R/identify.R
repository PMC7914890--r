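# Per-library prediction of processing products. Reads are first
# fractionated by insert size so that overlapping products of different
# lengths stay separable; 5' and 3' end-position densities are then
# peak-called within each fraction and paired into fragments. Accepted
# fragments suppress later candidates whose BOTH ends lie within the
# mask window, which is what limits resolution to products sharing one
# end only when their lengths differ by more than that window.

#' Default insert-size fractionation bins (nt, inclusive)
#' @export
DEFAULT_SIZE_BINS <- "18-26,27-40,41-70,71-120,121-200,201-300"

#' Identification parameters
#'
#' @param bins comma-separated `lo-hi` insert-size bins (nt, inclusive).
#' @param quant_threshold read-count threshold used downstream; the
#'   end-support filter uses half of it (default 10).
#' @param min_end_reads minimum end support during peak calling
#'   (default `ceiling(quant_threshold / 2)` so calling and filtering
#'   agree).
#' @param mask_window resolution window (nt): an accepted fragment
#'   suppresses later candidates with both ends within this distance
#'   (default 15).
#' @param nonoverlap_read,nonoverlap_feature allowed non-overlapping
#'   bases between a read and a product during counting (default 2).
#' @return named parameter list.
#' @export
identify_params <- function(bins = DEFAULT_SIZE_BINS, quant_threshold = 10L,
                            min_end_reads = NULL, mask_window = 15L,
                            nonoverlap_read = 2L, nonoverlap_feature = 2L) {
  b <- parse_size_bins(bins)
  list(bins = b, quant_threshold = as.integer(quant_threshold),
       min_end_reads = as.integer(min_end_reads %||%
                                    ceiling(quant_threshold / 2)),
       mask_window = as.integer(mask_window),
       nonoverlap_read = as.integer(nonoverlap_read),
       nonoverlap_feature = as.integer(nonoverlap_feature))
}

#' Parse size bins from text
#'
#' @param bins string like `"18-26,27-40"` or a two-column matrix/data
#'   frame of bounds.
#' @return data.frame with `lo`, `hi`, `label`; errors on overlap.
#' @export
parse_size_bins <- function(bins) {
  if (is.character(bins)) {
    parts <- strsplit(strsplit(bins, ",")[[1]], "-")
    b <- data.frame(lo = as.integer(vapply(parts, `[`, "", 1)),
                    hi = as.integer(vapply(parts, `[`, "", 2)))
  } else {
    b <- as.data.frame(bins)
    names(b) <- c("lo", "hi")
  }
  b <- b[order(b$lo), , drop = FALSE]
  if (any(b$lo > b$hi)) stop("size bin with lo > hi")
  if (nrow(b) > 1L && any(b$lo[-1L] <= b$hi[-nrow(b)])) {
    stop("size bins overlap")
  }
  b$label <- sprintf("%d-%d", b$lo, b$hi)
  rownames(b) <- NULL
  b
}

#' Fractionate reads by insert size
#'
#' @param ps pseudo-SE table.
#' @param bins data.frame from [parse_size_bins()].
#' @return list with `fractions` (named list of sub-tables) and
#'   `dropped` (reads outside every bin).
#' @export
fractionate_by_size <- function(ps, bins) {
  len <- ps$end0 - ps$start0
  bin <- rep(NA_integer_, nrow(ps))
  for (i in seq_len(nrow(bins))) {
    bin[len >= bins$lo[i] & len <= bins$hi[i]] <- i
  }
  fr <- lapply(seq_len(nrow(bins)), function(i)
    ps[!is.na(bin) & bin == i, , drop = FALSE])
  names(fr) <- bins$label
  list(fractions = fr, dropped = sum(is.na(bin)))
}

# Biological end positions (0-based; 3' inclusive) of pseudo-SE reads.
biological_ends <- function(ps) {
  plus <- ps$strand == "+"
  list(five = ifelse(plus, ps$start0, ps$end0 - 1L),
       three = ifelse(plus, ps$end0 - 1L, ps$start0))
}

#' Call end-density peaks and pair them into fragments
#'
#' Iterative greedy pairing within one chromosome/strand of one size
#' fraction: take the highest remaining 5' peak, pair it with the
#' highest eligible 3' peak (fragment length inside the bin, not both
#' ends within `mask_window` of an accepted fragment), emit the
#' fragment, subtract the exactly-matching read support from both end
#' counts, and allow further 3' peaks for the same 5' end only when the
#' implied length differs by more than `mask_window`; then consume the
#' 5' position and repeat while any end exceeds `min_end_reads`. Ties
#' are broken towards the leftmost genomic coordinate.
#'
#' @param reads pseudo-SE reads of one fraction, one chrom, one strand.
#' @param bin c(lo, hi) insert-length bounds (nt).
#' @param min_end_reads minimum end support.
#' @param mask_window resolution window (nt).
#' @return product table (`chrom`, `strand`, `start0`, `end0`,
#'   `five_support`, `three_support`).
#' @export
call_end_peaks <- function(reads, bin, min_end_reads = 5L, mask_window = 15L) {
  out <- list()
  if (nrow(reads) == 0L) return(NULL)
  chrom <- reads$chrom[1L]; strand <- reads$strand[1L]
  ends <- biological_ends(reads)
  t5 <- table(ends$five); t3 <- table(ends$three)
  p5v <- as.integer(names(t5)); c5 <- as.integer(t5)
  p3v <- as.integer(names(t3)); c3 <- as.integer(t3)
  pairkey <- table(paste(ends$five, ends$three))
  acc5 <- integer(0); acc3 <- integer(0)

  repeat {
    el5 <- which(c5 >= min_end_reads)
    if (!length(el5)) break
    k5 <- el5[order(-c5[el5], p5v[el5])][1L]
    p5 <- p5v[k5]
    used3 <- integer(0)
    repeat {
      len3 <- if (strand == "+") p3v - p5 + 1L else p5 - p3v + 1L
      el3 <- which(c3 >= min_end_reads & len3 >= bin[1L] & len3 <= bin[2L])
      el3 <- setdiff(el3, used3)
      if (length(el3) && length(acc5)) {
        masked <- vapply(el3, function(k) any(
          abs(p5 - acc5) <= mask_window & abs(p3v[k] - acc3) <= mask_window
        ), logical(1))
        el3 <- el3[!masked]
      }
      if (!length(el3)) break
      k3 <- el3[order(-c3[el3], p3v[el3])][1L]
      p3 <- p3v[k3]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, strand = strand,
        start0 = min(p5, p3), end0 = max(p5, p3) + 1L,
        five_support = c5[k5], three_support = c3[k3],
        stringsAsFactors = FALSE
      )
      acc5 <- c(acc5, p5); acc3 <- c(acc3, p3)
      used3 <- c(used3, k3)
      paired <- pairkey[paste(p5, p3)]
      paired <- if (is.na(paired)) 0L else as.integer(paired)
      c5[k5] <- max(0L, c5[k5] - paired)
      c3[k3] <- max(0L, c3[k3] - paired)
    }
    c5[k5] <- 0L  # this 5' end is fully processed
  }
  rbind_tables(out)
}

#' Filter products by end support
#'
#' Keeps a product when the better-supported end reaches at least
#' `ceiling(quant_threshold / 2)` reads.
#'
#' @param products product table with `five_support`, `three_support`.
#' @param quant_threshold quantification threshold (default 10).
#' @return filtered product table.
#' @export
filter_by_end_support <- function(products, quant_threshold = 10L) {
  if (is.null(products) || nrow(products) == 0L) return(products)
  thr <- ceiling(quant_threshold / 2)
  keep <- pmax(products$five_support, products$three_support) >= thr
  out <- products[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign read placements to products with overlap tolerance
#'
#' A placement is assigned to a product when both lie on the same
#' chromosome and strand, at most `nonoverlap_read` read bases fall
#' outside the product and at most `nonoverlap_feature` product bases
#' are not covered by the read. Every placement of a multi-mapped read
#' may be assigned, and one placement may be assigned to several
#' overlapping products.
#'
#' @param reads pseudo-SE table.
#' @param products product table.
#' @param nonoverlap_read,nonoverlap_feature tolerances (bases).
#' @return data.frame of assignments (`read_row`, `product_row`).
#' @export
assign_reads_to_products <- function(reads, products, nonoverlap_read = 2L,
                                     nonoverlap_feature = 2L) {
  acc <- list()
  if (nrow(reads) == 0L || is.null(products) || nrow(products) == 0L) {
    return(data.frame(read_row = integer(0), product_row = integer(0)))
  }
  key_r <- paste(reads$chrom, reads$strand)
  key_p <- paste(products$chrom, products$strand)
  for (key in unique(key_p)) {
    ri <- which(key_r == key); pi <- which(key_p == key)
    if (!length(ri)) next
    ir <- IRanges::IRanges(reads$start0[ri] + 1L, reads$end0[ri])
    ip <- IRanges::IRanges(products$start0[pi] + 1L, products$end0[pi])
    hits <- IRanges::findOverlaps(ir, ip)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    rs <- reads$start0[ri][qh]; re <- reads$end0[ri][qh]
    pss <- products$start0[pi][sh]; pe <- products$end0[pi][sh]
    outside_read <- pmax(0L, pss - rs) + pmax(0L, re - pe)
    uncovered <- pmax(0L, rs - pss) + pmax(0L, pe - re)
    ok <- outside_read <= nonoverlap_read & uncovered <= nonoverlap_feature
    if (any(ok)) {
      acc[[length(acc) + 1L]] <- data.frame(read_row = ri[qh[ok]],
                                            product_row = pi[sh[ok]])
    }
  }
  rbind_tables(acc) %||%
    data.frame(read_row = integer(0), product_row = integer(0))
}

#' Count read placements per product
#'
#' @inheritParams assign_reads_to_products
#' @return integer vector of counts, one per product row.
#' @export
count_reads_to_products <- function(reads, products, nonoverlap_read = 2L,
                                    nonoverlap_feature = 2L) {
  asg <- assign_reads_to_products(reads, products, nonoverlap_read,
                                  nonoverlap_feature)
  tabulate(asg$product_row, nbins = nrow(products))
}

#' Identify processing products in one library
#'
#' Runs size fractionation, per-fraction peak calling, cross-fraction
#' deduplication (identical intervals keep their maximal end supports),
#' the end-support filter and overlap-tolerant counting.
#'
#' @param ps kept pseudo-SE table of one library.
#' @param params an [identify_params()] list.
#' @return list with `products` (including `count`), `assignment` and
#'   `tallies`.
#' @export
identify_products <- function(ps, params = identify_params()) {
  fr <- fractionate_by_size(ps, params$bins)
  prods <- list()
  for (bi in seq_len(nrow(params$bins))) {
    reads_b <- fr$fractions[[bi]]
    if (nrow(reads_b) == 0L) next
    for (grp in split(reads_b, paste(reads_b$chrom, reads_b$strand))) {
      p <- call_end_peaks(grp, c(params$bins$lo[bi], params$bins$hi[bi]),
                          params$min_end_reads, params$mask_window)
      if (!is.null(p)) {
        p$fraction <- params$bins$label[bi]
        prods[[length(prods) + 1L]] <- p
      }
    }
  }
  products <- rbind_tables(prods)
  if (is.null(products)) {
    products <- data.frame(chrom = character(0), strand = character(0),
                           start0 = integer(0), end0 = integer(0),
                           five_support = integer(0),
                           three_support = integer(0),
                           fraction = character(0), count = integer(0))
    return(list(products = products,
                assignment = data.frame(read_row = integer(0),
                                        product_row = integer(0)),
                tallies = c(reads = nrow(ps), dropped_size = fr$dropped,
                            called = 0L, end_filtered = 0L)))
  }
  # identical intervals from different fractions: keep max supports
  key <- paste(products$chrom, products$strand, products$start0,
               products$end0)
  if (anyDuplicated(key)) {
    products <- do.call(rbind, lapply(split(products, key), function(g) {
      g1 <- g[1L, , drop = FALSE]
      g1$five_support <- max(g$five_support)
      g1$three_support <- max(g$three_support)
      g1
    }))
  }
  products <- products[order(products$chrom, products$strand,
                             products$start0, products$end0), , drop = FALSE]
  rownames(products) <- NULL
  n_called <- nrow(products)
  products <- filter_by_end_support(products, params$quant_threshold)
  asg <- assign_reads_to_products(ps, products, params$nonoverlap_read,
                                  params$nonoverlap_feature)
  products$count <- tabulate(asg$product_row, nbins = nrow(products))
  list(products = products, assignment = asg,
       tallies = c(reads = nrow(ps), dropped_size = fr$dropped,
                   called = n_called, end_filtered = nrow(products)))
}
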