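# Shared fixtures and independent oracles. Oracles deliberately avoid
# the implementation paths they check: the alignment oracle scans every
# genomic position with plain character comparison, and the clustering
# oracle re-enumerates coverage counts from scratch at every round.

tiny_genome <- function(seq, name = "chrT") {
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- name
  new_genome(dna)
}

random_genome <- function(n, seed) {
  set.seed(seed)
  tiny_genome(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                    collapse = ""))
}

qual_of <- function(v) intToUtf8(v + 33L)
uniform_qual <- function(len, q = 35L) qual_of(rep(q, len))

# All-positions, both-strands brute-force scorer: every placement with
# at most floor(-(a + b L)/penalty) mismatches.
brute_force_align <- function(seq, genome, params = align_params()) {
  L <- nchar(seq)
  mm_max <- floor(-(params$min_score_a + params$min_score_b * L) /
                    params$mismatch_penalty)
  rows <- list()
  rc <- seq_chars(revcomp(seq))
  fc <- seq_chars(seq)
  for (chrom in names(genome$seq)) {
    gch <- seq_chars(genome$seq[[chrom]])
    n <- length(gch)
    if (n < L) next
    for (strand in c("+", "-")) {
      qc <- if (strand == "+") fc else rc
      mm <- integer(n - L + 1L)
      for (k in seq_len(L)) {
        mm <- mm + (gch[k:(n - L + k)] != qc[k])
      }
      ok <- which(mm <= mm_max)
      if (length(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, start0 = ok - 1L,
          nm = mm[ok], stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), strand = character(0),
                      start0 = integer(0), nm = integer(0))
  }
  out
}

# Best-stratum subset of the brute-force placements.
brute_force_argmax <- function(seq, genome, params = align_params()) {
  all <- brute_force_align(seq, genome, params)
  if (nrow(all) == 0L) return(all)
  all[all$nm == min(all$nm), , drop = FALSE]
}

placement_key <- function(df) {
  sort(paste(df$chrom, df$strand, df$start0))
}

# Exhaustive greedy-max overlap clustering: identical selection rule as
# the spec'd contract, but coverage counts re-enumerated from scratch
# each round over explicit member sets.
oracle_overlap_cluster <- function(products, tolerance) {
  n <- nrow(products)
  cnt <- if (!is.null(products$total_count)) products$total_count
  else if (!is.null(products$count)) products$count else rep(0, n)
  compat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      compat[i, j] <- products$chrom[i] == products$chrom[j] &&
        products$strand[i] == products$strand[j] &&
        (abs(products$start0[i] - products$start0[j]) +
           abs(products$end0[i] - products$end0[j])) <= tolerance
    }
  }
  open <- seq_len(n)
  reps <- integer(0)
  members <- list()
  while (length(open)) {
    best <- NULL
    for (i in open) {
      cov <- sum(compat[i, open])
      # lexicographic preference: coverage desc, count desc, start asc,
      # end asc, chrom asc, strand asc ("+" sorts before "-")
      key <- list(-cov, -cnt[i], products$start0[i], products$end0[i],
                  products$chrom[i], products$strand[i])
      if (is.null(best)) { best <- list(i = i, key = key); next }
      for (k in seq_along(key)) {
        if (key[[k]] < best$key[[k]]) { best <- list(i = i, key = key); break }
        if (key[[k]] > best$key[[k]]) break
      }
    }
    mem <- open[compat[best$i, open]]
    reps <- c(reps, best$i)
    members[[length(members) + 1L]] <- mem
    open <- setdiff(open, mem)
  }
  list(representatives = reps, members = members)
}

random_product_fixture <- function(n, seed) {
  set.seed(seed)
  s <- sample(0:80, n, replace = TRUE)
  data.frame(
    chrom = "chrT", strand = sample(c("+", "-"), n, replace = TRUE),
    start0 = s, end0 = s + sample(18:40, n, replace = TRUE),
    five_support = 10L, three_support = 10L,
    total_count = sample(5:50, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Build a pseudo-SE read table from explicit intervals on a genome
# (sequence matching the genome, uniform quality).
ps_reads <- function(genome, chrom, strand, start0, end0,
                     ids = NULL, nh = 1L) {
  n <- length(start0)
  seqs <- vapply(seq_len(n), function(i)
    genome_subseq(genome, chrom, start0[i], end0[i], strand[i]),
    character(1))
  data.frame(
    read_id = ids %||% sprintf("r%04d", seq_len(n)),
    chrom = chrom, strand = strand, start0 = start0, end0 = end0,
    seq = seqs,
    qual = vapply(end0 - start0, uniform_qual, character(1)),
    score = 0L, nm = 0L, mate = 0L, nh = rep_len(nh, n),
    za = NA_integer_, gap_filled = 0L, stringsAsFactors = FALSE
  )
}

hash_dir <- function(dir, exclude = "run\\.log$") {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl(exclude, files)]
  unname(tools::md5sum(files))
}
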