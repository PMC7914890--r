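# Quantification of representative products across libraries: raw
# per-placement counts, per-candidate statistics (relative coverage,
# positional coverage, consensus sequence/quality, genomic sequence,
# uniqueness), biotype assignment, RPM normalization layers, the RPM
# retention filter and the single run-statistics report.

#' Quantification parameters
#'
#' @param nonoverlap_read,nonoverlap_feature assignment tolerances (bases).
#' @param rpm_threshold retention threshold in reads per million: a
#'   product is retained when it reaches this RPM in at least one
#'   library (default 10).
#' @param biotype_priority overlap resolution order.
#' @param biotype_groups named list mapping group -> biotype classes.
#' @return named parameter list.
#' @export
quantify_params <- function(nonoverlap_read = 2L, nonoverlap_feature = 2L,
                            rpm_threshold = 10,
                            biotype_priority = c("rRNA", "tRNA", "ncRNA",
                                                 "CDS"),
                            biotype_groups = list(
                              structural = c("rRNA", "tRNA"),
                              ncRNA = "ncRNA",
                              mRNA_derived = "CDS",
                              other = c("intergenic", "antisense"))) {
  list(nonoverlap_read = as.integer(nonoverlap_read),
       nonoverlap_feature = as.integer(nonoverlap_feature),
       rpm_threshold = rpm_threshold, biotype_priority = biotype_priority,
       biotype_groups = biotype_groups)
}

#' Canonical product identifier
#'
#' `"FM_" + strand + chrom + "_" + 1-based start + "_" + length`, with
#' the start zero-padded to the digit count of the chromosome length
#' (e.g. `FM_+NC_000913.2_4541696_34`).
#'
#' @param chrom,strand,start0,end0 product coordinates.
#' @param seqlengths named chromosome lengths (or an `sf_genome`).
#' @return character vector of identifiers.
#' @export
product_id <- function(chrom, strand, start0, end0, seqlengths) {
  if (inherits(seqlengths, "sf_genome")) seqlengths <- genome_lengths(seqlengths)
  width <- nchar(as.character(seqlengths[chrom]))
  sprintf("FM_%s%s_%0*d_%d", strand, chrom, width, start0 + 1L,
          end0 - start0)
}

# Map a feature type to its biotype class and priority rank.
biotype_rank <- function(type, priority) {
  cls <- ifelse(type %in% c("rRNA", "tRNA", "CDS"), type, "ncRNA")
  rank <- match(cls, priority)
  list(class = cls, rank = rank)
}

#' Assign biotypes to intervals from an annotation
#'
#' Same-strand feature overlaps win by priority (default rRNA > tRNA >
#' other ncRNA > CDS); intervals overlapping features only on the
#' opposite strand are "antisense"; the rest are "intergenic".
#'
#' @param x table with `chrom`, `strand`, `start0`, `end0`.
#' @param annotation annotation table (see [read_annotation_gff3()]) or
#'   a GFF3 path.
#' @param priority biotype priority order.
#' @return character vector of biotype labels.
#' @export
assign_biotype <- function(x, annotation,
                           priority = c("rRNA", "tRNA", "ncRNA", "CDS")) {
  if (is.character(annotation)) annotation <- read_annotation_gff3(annotation)
  n <- nrow(x)
  out <- rep("intergenic", n)
  if (n == 0L || nrow(annotation) == 0L) return(out)
  br <- biotype_rank(annotation$type, priority)
  for (chrom in unique(x$chrom)) {
    xi <- which(x$chrom == chrom); ai <- which(annotation$chrom == chrom)
    if (!length(ai)) next
    ix <- IRanges::IRanges(x$start0[xi] + 1L, x$end0[xi])
    ia <- IRanges::IRanges(annotation$start0[ai] + 1L, annotation$end0[ai])
    hits <- IRanges::findOverlaps(ix, ia)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    same <- x$strand[xi][qh] == annotation$strand[ai][sh]
    # same-strand: best-priority class
    if (any(same)) {
      best <- tapply(br$rank[ai][sh[same]], qh[same], min)
      out[xi[as.integer(names(best))]] <- priority[as.integer(best)]
    }
    # antisense only where no same-strand overlap exists
    anti_only <- setdiff(unique(qh[!same]), unique(qh[same]))
    out[xi[anti_only]] <- "antisense"
  }
  out
}

# Consensus sequence/quality and positional coverage for one product
# from its assigned placements.
consensus_one <- function(prod, reads, read_rows, genome) {
  s <- prod$start0; e <- prod$end0; w <- e - s
  gseq_fwd <- genome_subseq(genome, prod$chrom, s, e, "+")
  gch <- seq_chars(gseq_fwd)
  posv <- integer(0); basev <- character(0); qualv <- integer(0)
  for (ri in read_rows) {
    fwd <- forward_mate(reads$seq[ri], reads$qual[ri], reads$strand[ri])
    ovs <- max(s, reads$start0[ri]); ove <- min(e, reads$end0[ri])
    if (ove <= ovs) next
    widx <- (ovs - s + 1L):(ove - s)
    ridx <- (ovs - reads$start0[ri] + 1L):(ove - reads$start0[ri])
    posv <- c(posv, widx)
    basev <- c(basev, fwd$ch[ridx])
    qualv <- c(qualv, fwd$q[ridx])
  }
  depth <- tabulate(posv, nbins = w)
  cons <- gch
  cq <- integer(w)
  if (length(posv)) {
    tab <- table(factor(posv, levels = seq_len(w)),
                 factor(basev, levels = c("A", "C", "G", "T", "N")))
    mx <- apply(tab, 1L, max)
    for (p in which(depth > 0L)) {
      winners <- colnames(tab)[tab[p, ] == mx[p]]
      cons[p] <- if (gch[p] %in% winners) gch[p] else winners[1L]
    }
    qmean <- tapply(qualv, factor(posv, levels = seq_len(w)), mean)
    cq[depth > 0L] <- as.integer(round(qmean[depth > 0L]))
  }
  if (prod$strand == "-") {
    cons_out <- revcomp(paste(cons, collapse = ""))
    cq <- rev(cq)
    depth <- rev(depth)
    gseq <- revcomp(gseq_fwd)
  } else {
    cons_out <- paste(cons, collapse = "")
    gseq <- gseq_fwd
  }
  list(consensus_seq = cons_out, consensus_qual = phred_string(cq),
       genomic_seq = gseq, coverage = depth)
}

#' Quantify representatives in one library
#'
#' Placements are assigned with the same overlap-tolerant, stranded,
#' multi-counting rule as during identification; every placement of a
#' multi-mapped read contributes one count.
#'
#' @param ps kept pseudo-SE table of the library.
#' @param reps representative product table.
#' @param genome an `sf_genome`.
#' @param params a [quantify_params()] list.
#' @return list with `counts` (per product), `stats` (per-candidate
#'   statistics table) and `total_reads` (distinct mapped reads, the
#'   RPM denominator).
#' @export
quantify_library <- function(ps, reps, genome, params = quantify_params()) {
  bad <- !(ps$chrom %in% names(genome$seq))
  if (any(bad)) {
    stop("alignment references unknown chromosome: ", unique(ps$chrom[bad])[1])
  }
  asg <- assign_reads_to_products(ps, reps, params$nonoverlap_read,
                                  params$nonoverlap_feature)
  counts <- tabulate(asg$product_row, nbins = nrow(reps))
  stats <- NULL
  if (nrow(reps) > 0L) {
    relcov <- relative_coverage(reps, ps, asg)
    rows <- lapply(seq_len(nrow(reps)), function(i) {
      rr <- asg$read_row[asg$product_row == i]
      cons <- consensus_one(reps[i, ], ps, rr, genome)
      uniq <- if (length(rr)) mean(ps$nh[rr] == 1L, na.rm = TRUE) else NA_real_
      data.frame(
        count = counts[i], relative_coverage = relcov[i],
        uniqueness = uniq, consensus_seq = cons$consensus_seq,
        consensus_qual = cons$consensus_qual,
        genomic_seq = cons$genomic_seq,
        coverage = paste(cons$coverage, collapse = ","),
        stringsAsFactors = FALSE
      )
    })
    stats <- do.call(rbind, rows)
  }
  list(counts = counts, stats = stats,
       total_reads = length(unique(ps$read_id)))
}

#' Build the normalized count matrix
#'
#' Layers: `rpm` (per million distinct mapped reads), `rpm_biotype`
#' (per million placements of the product's biotype class) and
#' `rpm_biotype_group` (analogous over the configured group mapping).
#' Biotype denominators count placements, consistent with
#' per-placement product counting.
#'
#' @param raw products x libraries integer matrix (rownames = product
#'   ids).
#' @param library_totals distinct mapped reads per library.
#' @param biotypes biotype class per product.
#' @param biotype_totals libraries x biotype-class matrix of placement
#'   counts.
#' @param groups named list mapping group -> biotype classes.
#' @return an `sf_count_matrix` list.
#' @export
normalize_counts <- function(raw, library_totals, biotypes, biotype_totals,
                             groups = quantify_params()$biotype_groups) {
  stopifnot(ncol(raw) == length(library_totals))
  if (any(library_totals <= 0)) stop("library totals must be positive")
  rpm <- sweep(raw, 2L, library_totals, "/") * 1e6

  group_of <- stats::setNames(
    rep(names(groups), lengths(groups)), unlist(groups))
  bt_den <- t(vapply(seq_len(nrow(raw)), function(i) {
    biotype_totals[, biotypes[i]]
  }, numeric(ncol(raw))))
  if (ncol(raw) == 1L) bt_den <- matrix(bt_den, ncol = 1L)
  if (any(raw > 0 & bt_den == 0)) {
    stop("nonzero count with zero biotype total; inconsistent classification")
  }
  rpm_biotype <- ifelse(bt_den > 0, raw / bt_den * 1e6, 0)

  grp_totals <- vapply(names(groups), function(g) {
    cols <- intersect(groups[[g]], colnames(biotype_totals))
    if (!length(cols)) rep(0, nrow(biotype_totals))
    else rowSums(biotype_totals[, cols, drop = FALSE])
  }, numeric(nrow(biotype_totals)))
  if (nrow(biotype_totals) == 1L) grp_totals <- matrix(
    grp_totals, nrow = 1L, dimnames = list(NULL, names(groups)))
  gr_den <- t(vapply(seq_len(nrow(raw)), function(i) {
    grp_totals[, group_of[[biotypes[i]]]]
  }, numeric(ncol(raw))))
  if (ncol(raw) == 1L) gr_den <- matrix(gr_den, ncol = 1L)
  rpm_group <- ifelse(gr_den > 0, raw / gr_den * 1e6, 0)
  dimnames(rpm_biotype) <- dimnames(rpm_group) <- dimnames(raw)

  structure(list(
    raw = raw, rpm = rpm, rpm_biotype = rpm_biotype,
    rpm_biotype_group = rpm_group, library_totals = library_totals,
    biotypes = biotypes, biotype_totals = biotype_totals,
    groups = groups
  ), class = "sf_count_matrix")
}

#' RPM retention filter
#'
#' A product is retained when its RPM reaches `threshold` in at least
#' one library.
#'
#' @param cm an `sf_count_matrix`.
#' @param threshold RPM threshold (default 10).
#' @return logical vector over products.
#' @export
rpm_retention_filter <- function(cm, threshold = 10) {
  apply(cm$rpm, 1L, max) >= threshold
}

#' Collect per-library stage tallies into one report table
#'
#' @param tallies named list: library id -> named numeric vector of
#'   stage tallies.
#' @return wide data.frame, one row per library.
#' @export
run_statistics <- function(tallies) {
  metrics <- unique(unlist(lapply(tallies, names)))
  rows <- lapply(names(tallies), function(lib) {
    v <- stats::setNames(rep(0, length(metrics)), metrics)
    v[names(tallies[[lib]])] <- tallies[[lib]]
    cbind(data.frame(library = lib, stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  do.call(rbind, rows)
}
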