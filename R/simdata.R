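# Synthetic data generation: toy genome, biotype annotation, planted
# processing products and simulated adaptered reads. Every downstream
# stage of the pipeline is testable against the planted truth; a fixed
# seed reproduces byte-identical output files.

#' Default 3' sequencing adapter used by the simulator and trimmer
#' (Illumina small-RNA kit adapter).
#' @export
DEFAULT_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"

rand_dna <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Draw insert lengths from a three-component mixture: tRF-half-sized
# (~25 nt), miRNA/tRF-sized (~34 nt) and tRNA/5S-sized (~90 nt) species.
draw_insert_lengths <- function(n, min_len = 18L, max_len = 120L) {
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  mu <- c(25, 34, 90)[comp]
  sdv <- c(2, 2, 6)[comp]
  len <- as.integer(round(stats::rnorm(n, mu, sdv)))
  pmin(pmax(len, min_len), max_len)
}

new_truth <- function(genome_id, genome_length, seed) {
  structure(list(
    genome_id = genome_id,
    genome_length = as.integer(genome_length),
    products = data.frame(
      name = character(0), chrom = character(0), strand = character(0),
      start0 = integer(0), end0 = integer(0), biotype = character(0),
      abundance = numeric(0), stringsAsFactors = FALSE
    ),
    duplicated_loci = data.frame(
      src_start0 = integer(0), src_end0 = integer(0),
      copy_start0 = integer(0), copy_end0 = integer(0)
    ),
    seed = as.integer(seed)
  ), class = "sf_truth")
}

#' Generate a random toy genome with optional duplicated loci
#'
#' Duplicated segments are copied verbatim to a second location so that
#' multi-mapping behaviour (all-alignments reporting, NH counting,
#' sequence/contig clustering of repeated loci) can be exercised.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc GC fraction in (0, 1).
#' @param n_duplicated_loci number of segments to copy.
#' @param dup_len length of each duplicated segment (bp).
#' @param seed RNG seed; the same seed reproduces the genome exactly.
#' @param genome_id chromosome name.
#' @return list with `genome` (an `sf_genome`) and `truth` (an
#'   `sf_truth` skeleton recording the duplications).
#' @export
make_genome <- function(length = 50000L, gc = 0.5, n_duplicated_loci = 0L,
                        dup_len = 60L, seed = 1L, genome_id = "chrS") {
  length <- as.integer(length)
  if (length < 1000L) stop("genome length must be >= 1000 bp")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  if (n_duplicated_loci > 0L && 4L * n_duplicated_loci * dup_len > length) {
    stop("genome too small to host ", n_duplicated_loci,
         " duplicated loci of ", dup_len, " bp")
  }
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)

  truth <- new_truth(genome_id, length, seed)
  if (n_duplicated_loci > 0L) {
    taken <- integer(0)
    pick <- function() {
      for (i in 1:1000) {
        s <- sample.int(length - dup_len, 1L) - 1L
        if (!any(abs(s - taken) < dup_len + 20L)) {
          taken <<- c(taken, s)
          return(s)
        }
      }
      stop("could not place duplicated loci")
    }
    dup <- lapply(seq_len(n_duplicated_loci), function(i) {
      src <- pick(); cp <- pick()
      bases[(cp + 1L):(cp + dup_len)] <<- bases[(src + 1L):(src + dup_len)]
      c(src, src + dup_len, cp, cp + dup_len)
    })
    dup <- do.call(rbind, dup)
    truth$duplicated_loci <- data.frame(
      src_start0 = dup[, 1], src_end0 = dup[, 2],
      copy_start0 = dup[, 3], copy_end0 = dup[, 4]
    )
  }
  dna <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(dna) <- genome_id
  list(genome = new_genome(dna), truth = truth)
}

# Intervals (0-based half-open) occupied on the genome; used to place
# features and products without conflicts.
overlaps_any <- function(start0, end0, starts, ends, pad = 0L) {
  if (length(starts) == 0L) return(FALSE)
  any(start0 < ends + pad & end0 > starts - pad)
}

#' Generate a toy biotype annotation
#'
#' Places non-overlapping features of types rRNA, tRNA, ncRNA and CDS on
#' the genome (intergenic space is simply the absence of features).
#'
#' @param genome an `sf_genome` from [make_genome()].
#' @param truth the matching `sf_truth`.
#' @param biotype_spec named integer vector: how many features of each
#'   type to place.
#' @param feature_lengths named integer vector of feature lengths (bp).
#' @param seed RNG seed (defaults to `truth$seed + 1`).
#' @return data.frame with columns `chrom`, `start0`, `end0`, `strand`,
#'   `type`, `id`.
#' @export
make_annotation <- function(genome, truth,
                            biotype_spec = c(rRNA = 1L, tRNA = 3L,
                                             ncRNA = 2L, CDS = 2L),
                            feature_lengths = c(rRNA = 400L, tRNA = 76L,
                                                ncRNA = 180L, CDS = 900L),
                            seed = truth$seed + 1L) {
  glen <- truth$genome_length
  if (sum(biotype_spec * feature_lengths[names(biotype_spec)]) > glen / 2) {
    stop("requested features do not fit in the genome")
  }
  set.seed(seed)
  dup <- truth$duplicated_loci
  occupied_s <- c(dup$src_start0, dup$copy_start0)
  occupied_e <- c(dup$src_end0, dup$copy_end0)
  rows <- list()
  for (type in names(biotype_spec)) {
    flen <- feature_lengths[[type]]
    for (i in seq_len(biotype_spec[[type]])) {
      placed <- FALSE
      for (try in 1:2000) {
        s <- sample.int(glen - flen, 1L) - 1L
        if (!overlaps_any(s, s + flen, occupied_s, occupied_e, pad = 50L)) {
          occupied_s <- c(occupied_s, s); occupied_e <- c(occupied_e, s + flen)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = truth$genome_id, start0 = s, end0 = s + flen,
            strand = sample(c("+", "-"), 1L), type = type,
            id = sprintf("%s_%d", type, i), stringsAsFactors = FALSE
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place ", type, " feature without overlap")
    }
  }
  ann <- do.call(rbind, rows)
  ann[order(ann$start0), , drop = FALSE]
}

#' Write an annotation table as GFF3
#'
#' @param annotation data.frame from [make_annotation()].
#' @param path output path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start0 + 1L, annotation$end0),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$source <- "stablefrag_sim"
  S4Vectors::mcols(gr)$type <- annotation$type
  S4Vectors::mcols(gr)$ID <- annotation$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation into the internal table form
#'
#' @param path GFF3 file.
#' @return data.frame with `chrom`, `start0`, `end0`, `strand`, `type`, `id`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    id = if ("ID" %in% names(mc)) as.character(mc$ID) else
      sprintf("feat_%d", seq_along(gr)),
    stringsAsFactors = FALSE
  )
}

#' Plant processing products on a synthetic genome
#'
#' Products are placed inside annotated features (taking the feature's
#' strand and biotype) and in intergenic space, pairwise separated by at
#' least `min_gap` bp so that end-density peaks of different products do
#' not interfere. Duplicated segments are avoided unless
#' `products_in_duplicates > 0`, in which case that many products are
#' centred inside duplicated source segments to create genuinely
#' multi-mapping species.
#'
#' @param genome an `sf_genome`.
#' @param truth the matching `sf_truth`.
#' @param annotation data.frame from [make_annotation()].
#' @param n_products number of products to plant.
#' @param products_in_duplicates how many products to centre in
#'   duplicated source segments.
#' @param min_gap minimum distance between planted products (bp).
#' @param min_len,max_len insert length range.
#' @param seed RNG seed (defaults to `truth$seed + 2`).
#' @return the updated `sf_truth`.
#' @export
plant_products <- function(genome, truth, annotation, n_products = 30L,
                           products_in_duplicates = 0L, min_gap = 25L,
                           min_len = 18L, max_len = 120L,
                           seed = truth$seed + 2L) {
  set.seed(seed)
  glen <- truth$genome_length
  dup <- truth$duplicated_loci
  dup_s <- c(dup$src_start0, dup$copy_start0)
  dup_e <- c(dup$src_end0, dup$copy_end0)
  prod_s <- integer(0); prod_e <- integer(0)
  rows <- list()
  push <- function(s, e, strand, biotype) {
    prod_s <<- c(prod_s, s); prod_e <<- c(prod_e, e)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = sprintf("P%03d", length(rows) + 1L), chrom = truth$genome_id,
      strand = strand, start0 = s, end0 = e, biotype = biotype,
      abundance = NA_real_, stringsAsFactors = FALSE
    )
  }

  if (products_in_duplicates > 0L) {
    if (nrow(dup) < products_in_duplicates) {
      stop("not enough duplicated loci for requested duplicated products")
    }
    for (i in seq_len(products_in_duplicates)) {
      seg_len <- dup$src_end0[i] - dup$src_start0[i]
      len <- min(max(min_len, seg_len - 30L), 40L)
      s <- dup$src_start0[i] + (seg_len - len) %/% 2L
      push(s, s + len, sample(c("+", "-"), 1L), "duplicated")
    }
  }

  # Round-robin over features plus an intergenic pseudo-slot.
  slots <- c(split(annotation, seq_len(nrow(annotation))), list("intergenic"))
  remaining <- n_products - products_in_duplicates
  si <- 0L
  placed <- 0L
  attempts <- 0L
  while (placed < remaining) {
    attempts <- attempts + 1L
    if (attempts > 500L * remaining) {
      stop("could not place ", remaining, " products with min_gap ", min_gap)
    }
    si <- si %% length(slots) + 1L
    slot <- slots[[si]]
    len <- draw_insert_lengths(1L, min_len, max_len)
    if (is.data.frame(slot)) {
      flen <- slot$end0 - slot$start0
      len <- min(len, flen)
      s <- slot$start0 + sample.int(flen - len + 1L, 1L) - 1L
      strand <- slot$strand
      biotype <- slot$type
    } else {
      s <- sample.int(glen - len, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      biotype <- "intergenic"
      # intergenic products must not touch features
      if (overlaps_any(s, s + len, annotation$start0, annotation$end0,
                       pad = 10L)) next
    }
    if (overlaps_any(s, s + len, prod_s, prod_e, pad = min_gap)) next
    if (overlaps_any(s, s + len, dup_s, dup_e, pad = 10L)) next
    if (s < 10L || s + len > glen - 10L) next
    push(s, s + len, strand, biotype)
    placed <- placed + 1L
  }
  truth$products <- do.call(rbind, rows)
  truth
}

#' Add a product to the truth at explicit coordinates
#'
#' @param truth an `sf_truth`.
#' @param start0,end0 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param biotype label recorded in the truth table.
#' @param name product name (auto-numbered when `NULL`).
#' @export
add_product <- function(truth, start0, end0, strand, biotype = "manual",
                        name = NULL) {
  stopifnot(start0 >= 0L, end0 <= truth$genome_length, start0 < end0)
  truth$products <- rbind(truth$products, data.frame(
    name = name %||% sprintf("P%03d", nrow(truth$products) + 1L),
    chrom = truth$genome_id, strand = strand,
    start0 = as.integer(start0), end0 = as.integer(end0),
    biotype = biotype, abundance = NA_real_, stringsAsFactors = FALSE
  ))
  truth
}

mutate_bases <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    L <- nchar(s)
    if (L == 0L) return(s)
    k <- stats::rbinom(1L, L, rate)
    if (k == 0L) return(s)
    pos <- sample.int(L, k)
    ch <- seq_chars(s)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

sim_quals <- function(n, read_len, lowq_tail_rate) {
  vapply(seq_len(n), function(i) {
    q <- sample(32:40, read_len, replace = TRUE)
    if (lowq_tail_rate > 0 && stats::runif(1) < lowq_tail_rate) {
      t <- sample(1:3, 1L)
      q[(read_len - t + 1L):read_len] <- sample(2:15, t, replace = TRUE)
    }
    phred_string(q)
  }, character(1))
}

#' Simulate adaptered sequencing reads from planted products
#'
#' For each product, `depth_per_product` inserts are drawn with both ends
#' independently jittered by a rounded Normal(0, `end_jitter_sd`). Reads
#' read through into the 3' adapter when the insert is shorter than the
#' read length; in paired mode R1 is the insert prefix and R2 the
#' reverse complement of the insert suffix. A fraction of reads gains
#' 1-4 untemplated terminal adenosines, and a fraction of extra reads
#' starts at uniformly random genomic positions (background noise).
#'
#' @param genome an `sf_genome`.
#' @param truth an `sf_truth` with planted products.
#' @param depth_per_product reads per product (scalar or per-product vector).
#' @param end_jitter_sd standard deviation (nt) of the end jitter.
#' @param adapter3 3' adapter sequence.
#' @param paired emit R1/R2 pairs (otherwise single-end).
#' @param read_len sequenced read length.
#' @param oligoA_rate fraction of reads receiving a 3' oligo(A) tail.
#' @param noise_read_rate noise reads as a fraction of planted reads.
#' @param seq_error_rate per-base substitution error rate.
#' @param lowq_tail_rate fraction of reads with a low-quality 3' tail.
#' @param seed RNG seed (defaults to `truth$seed + 3`).
#' @return list with `r1`, `r2` (read tables; `r2` is `NULL` for SE),
#'   the updated `truth` (abundance filled in) and `tallies`.
#' @export
simulate_reads <- function(genome, truth, depth_per_product = 100L,
                           end_jitter_sd = 1, adapter3 = DEFAULT_ADAPTER3,
                           paired = TRUE, read_len = 50L,
                           oligoA_rate = 0.05, noise_read_rate = 0.02,
                           seq_error_rate = 0.001, lowq_tail_rate = 0.05,
                           seed = truth$seed + 3L) {
  if (!nzchar(adapter3)) stop("adapter3 must be non-empty")
  prods <- truth$products
  if (nrow(prods) == 0L) stop("truth contains no products; plant some first")
  if (read_len < 18L) stop("read_len too small")
  depth <- rep_len(as.integer(depth_per_product), nrow(prods))
  set.seed(seed)
  glen <- truth$genome_length
  chrom <- truth$genome_id

  inserts <- character(0); ids <- character(0)
  for (i in seq_len(nrow(prods))) {
    d <- depth[i]
    s <- prods$start0[i] + as.integer(round(stats::rnorm(d, 0, end_jitter_sd)))
    e <- prods$end0[i] + as.integer(round(stats::rnorm(d, 0, end_jitter_sd)))
    s <- pmax(0L, s); e <- pmin(glen, e)
    e <- pmax(e, s + 10L)  # degenerate jitter guard (never hit at sd <= 2)
    ins <- vapply(seq_len(d), function(j)
      genome_subseq(genome, chrom, s[j], e[j], prods$strand[i]), character(1))
    tail_on <- stats::runif(d) < oligoA_rate
    if (any(tail_on)) {
      ins[tail_on] <- paste0(ins[tail_on],
                             strrep("A", sample(1:4, sum(tail_on), replace = TRUE)))
    }
    inserts <- c(inserts, ins)
    ids <- c(ids, sprintf("%s_r%04d", prods$name[i], seq_len(d)))
  }
  n_planted <- length(inserts)

  n_noise <- as.integer(round(noise_read_rate * n_planted))
  if (n_noise > 0L) {
    nlen <- draw_insert_lengths(n_noise)
    nstart <- vapply(nlen, function(l) sample.int(glen - l, 1L) - 1L, integer(1))
    nstrand <- sample(c("+", "-"), n_noise, replace = TRUE)
    nins <- vapply(seq_len(n_noise), function(j)
      genome_subseq(genome, chrom, nstart[j], nstart[j] + nlen[j], nstrand[j]),
      character(1))
    inserts <- c(inserts, nins)
    ids <- c(ids, sprintf("noise_r%04d", seq_len(n_noise)))
  }

  n <- length(inserts)
  filler1 <- vapply(seq_len(n), function(i) rand_dna(read_len), character(1))
  r1seq <- substr(paste0(inserts, adapter3, filler1), 1L, read_len)
  r1seq <- mutate_bases(r1seq, seq_error_rate)
  r1 <- data.frame(id = ids, seq = r1seq,
                   qual = sim_quals(n, read_len, lowq_tail_rate),
                   stringsAsFactors = FALSE)
  r2 <- NULL
  if (paired) {
    filler2 <- vapply(seq_len(n), function(i) rand_dna(read_len), character(1))
    r2seq <- substr(paste0(revcomp(inserts), adapter3, filler2), 1L, read_len)
    r2seq <- mutate_bases(r2seq, seq_error_rate)
    r2 <- data.frame(id = ids, seq = r2seq,
                     qual = sim_quals(n, read_len, lowq_tail_rate),
                     stringsAsFactors = FALSE)
  }
  truth$products$abundance <- as.numeric(depth)
  list(r1 = r1, r2 = r2, truth = truth,
       tallies = c(planted = n_planted, noise = n_noise, total = n))
}

#' Write the planted truth as BED6 plus an expected-count table
#'
#' @param truth an `sf_truth` with abundances.
#' @param bed_path,tsv_path output paths.
#' @export
write_truth <- function(truth, bed_path, tsv_path) {
  p <- truth$products
  gr <- GenomicRanges::GRanges(p$chrom,
                               IRanges::IRanges(p$start0 + 1L, p$end0),
                               strand = p$strand)
  S4Vectors::mcols(gr)$name <- p$name
  S4Vectors::mcols(gr)$score <- ifelse(is.na(p$abundance), 0, p$abundance)
  rtracklayer::export(gr, bed_path, format = "bed")
  write_tsv(p, tsv_path)
  invisible(truth)
}

#' Generate a complete synthetic dataset on disk
#'
#' Convenience wrapper: genome, annotation, planted products and one or
#' more read libraries, written under `out_dir` together with the truth
#' tables.
#'
#' @inheritParams make_genome
#' @inheritParams plant_products
#' @inheritParams simulate_reads
#' @param out_dir output directory (created if needed).
#' @param n_libraries number of replicate libraries (reads drawn with
#'   seeds `seed + 10 + 1:n`).
#' @return list with `genome`, `truth`, `annotation` and a `manifest` of
#'   written files.
#' @export
simulate_dataset <- function(out_dir, length = 50000L, gc = 0.5,
                             n_duplicated_loci = 2L,
                             biotype_spec = c(rRNA = 1L, tRNA = 3L,
                                              ncRNA = 2L, CDS = 2L),
                             n_products = 30L, products_in_duplicates = 0L,
                             depth_per_product = 100L, end_jitter_sd = 1,
                             adapter3 = DEFAULT_ADAPTER3, paired = TRUE,
                             read_len = 50L, oligoA_rate = 0.05,
                             noise_read_rate = 0.02, seq_error_rate = 0.001,
                             lowq_tail_rate = 0.05, n_libraries = 1L,
                             seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mg <- make_genome(length = length, gc = gc,
                    n_duplicated_loci = n_duplicated_loci, seed = seed)
  genome <- mg$genome; truth <- mg$truth
  ann <- make_annotation(genome, truth, biotype_spec = biotype_spec)
  truth <- plant_products(genome, truth, ann, n_products = n_products,
                          products_in_duplicates = products_in_duplicates)

  fa <- file.path(out_dir, "genome.fa")
  gff <- file.path(out_dir, "annotation.gff3")
  write_genome(genome, fa)
  write_annotation_gff3(ann, gff)

  libs <- list()
  for (li in seq_len(n_libraries)) {
    lib <- sprintf("lib%d", li)
    sim <- simulate_reads(genome, truth,
                          depth_per_product = depth_per_product,
                          end_jitter_sd = end_jitter_sd, adapter3 = adapter3,
                          paired = paired, read_len = read_len,
                          oligoA_rate = oligoA_rate,
                          noise_read_rate = noise_read_rate,
                          seq_error_rate = seq_error_rate,
                          lowq_tail_rate = lowq_tail_rate,
                          seed = seed + 10L + li)
    truth <- sim$truth
    r1p <- file.path(out_dir, paste0(lib, "_R1.fastq.gz"))
    write_fastq(sim$r1, r1p)
    entry <- list(id = lib, r1 = r1p, r2 = NULL)
    if (paired) {
      r2p <- file.path(out_dir, paste0(lib, "_R2.fastq.gz"))
      write_fastq(sim$r2, r2p)
      entry$r2 <- r2p
    }
    libs[[lib]] <- entry
  }
  write_truth(truth, file.path(out_dir, "truth.bed"),
              file.path(out_dir, "truth_counts.tsv"))
  list(genome = genome, truth = truth, annotation = ann,
       manifest = list(genome = fa, annotation = gff, libraries = libs,
                       adapter3 = adapter3, paired = paired))
}

#' Score recovery of planted products
#'
#' A planted product is recovered when a predicted product on the same
#' chromosome and strand has both ends within `end_tolerance` nt.
#' Matching is one-to-one and greedy by smallest total end offset.
#'
#' @param truth an `sf_truth` or a product data.frame
#'   (`chrom`, `strand`, `start0`, `end0`).
#' @param predicted data.frame of predicted products (same columns).
#' @param end_tolerance maximum per-end offset (nt).
#' @return list with `precision`, `recall`, `n_truth`, `n_predicted` and
#'   a per-match `offsets` table.
#' @export
evaluate_recovery <- function(truth, predicted, end_tolerance = 2L) {
  tp <- if (inherits(truth, "sf_truth")) truth$products else truth
  n_t <- nrow(tp); n_p <- nrow(predicted)
  if (n_t == 0L) stop("no truth products to evaluate")
  if (n_p == 0L) {
    return(list(precision = NA_real_, recall = 0, n_truth = n_t,
                n_predicted = 0L, offsets = NULL))
  }
  cand <- list()
  for (i in seq_len(n_t)) {
    same <- which(predicted$chrom == tp$chrom[i] &
                    predicted$strand == tp$strand[i])
    if (!length(same)) next
    d5 <- abs(predicted$start0[same] - tp$start0[i])
    d3 <- abs(predicted$end0[same] - tp$end0[i])
    ok <- d5 <= end_tolerance & d3 <= end_tolerance
    if (any(ok)) {
      cand[[length(cand) + 1L]] <- data.frame(
        t = i, p = same[ok], total = (d5 + d3)[ok],
        d5 = d5[ok], d3 = d3[ok]
      )
    }
  }
  cand <- rbind_tables(cand)
  matched <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand$total, cand$t, cand$p), , drop = FALSE]
    used_t <- logical(n_t); used_p <- logical(n_p)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!used_t[cand$t[k]] && !used_p[cand$p[k]]) {
        used_t[cand$t[k]] <- TRUE; used_p[cand$p[k]] <- TRUE
        keep[k] <- TRUE
      }
    }
    matched <- cand[keep, , drop = FALSE]
  }
  n_m <- if (is.null(matched)) 0L else nrow(matched)
  list(precision = n_m / n_p, recall = n_m / n_t,
       n_truth = n_t, n_predicted = n_p, offsets = matched)
}
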