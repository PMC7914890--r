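# Helper: build a join_pairs-style row from explicit mate placements on
# a genome, with given per-mate quality vectors and optional base edits.
mk_pair <- function(genome, s1, e1, s2, e2, q1, q2, strand1 = "+",
                    edit1 = NULL, edit2 = NULL, read_id = "p1", nh = 1L) {
  fwd1 <- genome_subseq(genome, "chrT", s1, e1, "+")
  fwd2 <- genome_subseq(genome, "chrT", s2, e2, "+")
  apply_edits <- function(s, edits) {
    if (is.null(edits)) return(s)
    ch <- seq_chars(s)
    for (k in seq_along(edits)) ch[as.integer(names(edits)[k])] <- edits[k]
    paste(ch, collapse = "")
  }
  fwd1 <- apply_edits(fwd1, edit1)
  fwd2 <- apply_edits(fwd2, edit2)
  strand2 <- if (strand1 == "+") "-" else "+"
  seq1 <- if (strand1 == "-") revcomp(fwd1) else fwd1
  seq2 <- if (strand2 == "-") revcomp(fwd2) else fwd2
  qs1 <- if (strand1 == "-") rev(q1) else q1
  qs2 <- if (strand2 == "-") rev(q2) else q2
  lo <- if (strand1 == "+") list(s = s1, e = e1) else list(s = s2, e = e2)
  hi <- if (strand1 == "+") list(s = s2, e = e2) else list(s = s1, e = e1)
  data.frame(
    read_id = read_id, chrom = "chrT", strand = strand1,
    start0 = min(s1, s2), end0 = max(e1, e2), score = 0,
    r1_strand = strand1, r1_start0 = s1, r1_end0 = e1,
    r1_seq = seq1, r1_qual = qual_of(qs1), r1_nm = 0L, r1_score = 0,
    r2_strand = strand2, r2_start0 = s2, r2_end0 = e2,
    r2_seq = seq2, r2_qual = qual_of(qs2), r2_nm = 0L, r2_score = 0,
    nh = nh, stringsAsFactors = FALSE
  )
}

test_that("overlap merging combines agreeing qualities with a cap", {
  g <- random_genome(400, 51)
  # R1 [100,130), R2 [110,140), all agreeing at q35 -> overlap quals 41
  pair <- mk_pair(g, 100, 130, 110, 140, rep(35L, 30), rep(35L, 30))
  ps <- merge_pair(pair, g, qmax = 41L)
  expect_equal(ps$start0, 100)
  expect_equal(ps$end0, 140)
  expect_equal(ps$seq, genome_subseq(g, "chrT", 100, 140, "+"))
  q <- phred_ints(ps$qual)
  expect_equal(q[11:30], rep(41, 20))   # overlap, capped
  expect_equal(q[1:10], rep(35, 10))    # mate-1-only positions
  expect_equal(q[31:40], rep(35, 10))
  expect_equal(ps$gap_filled, 0)
})

test_that("gaps are filled from the genome at maximum quality", {
  g <- random_genome(400, 52)
  # R1 [100,120), R2 [130,150) -> positions 120-129 genomic at q41
  pair <- mk_pair(g, 100, 120, 130, 150, rep(33L, 20), rep(33L, 20))
  ps <- merge_pair(pair, g)
  expect_equal(ps$end0 - ps$start0, 50)
  expect_equal(ps$seq, genome_subseq(g, "chrT", 100, 150, "+"))
  q <- phred_ints(ps$qual)
  expect_equal(q[21:30], rep(41, 10))
  expect_equal(ps$gap_filled, 10)
})

test_that("overlap disagreements take the higher-quality base at the quality difference", {
  g <- random_genome(400, 53)
  # disagree at overlap position: R1 has A at q40, R2 has C at q20
  ref <- seq_chars(genome_subseq(g, "chrT", 110, 140, "+"))
  a_base <- "A"; c_base <- if (ref[1] == "C") "G" else "C"
  pair <- mk_pair(g, 100, 130, 110, 140, rep(40L, 30), rep(20L, 30),
                  edit1 = stats::setNames(a_base, 11),  # fwd pos 110
                  edit2 = stats::setNames(c_base, 1))
  ps <- merge_pair(pair, g)
  merged <- seq_chars(ps$seq)
  expect_equal(merged[11], a_base)
  expect_equal(phred_ints(ps$qual)[11], 20)
  # merged quality never exceeds the cap, never below min(q1,q2) on
  # agreeing positions
  q <- phred_ints(ps$qual)
  expect_true(all(q <= 41))
  expect_true(all(q[-11] >= 20))
})

test_that("oligo(A) exemption keeps tailed reads and can be switched off", {
  # genome crafted so the 3 bases following the insert are not A:
  # untemplated tail A's are guaranteed to mismatch
  set.seed(54)
  g <- tiny_genome(paste0(
    paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
    "CGT",
    paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")))
  win <- genome_subseq(g, "chrT", 100, 130, "+")
  ps <- data.frame(
    read_id = "r1", chrom = "chrT", strand = "+", start0 = 100, end0 = 133,
    seq = paste0(win, "AAA"), qual = uniform_qual(33), score = 0,
    nm = NA_integer_, mate = 0L, nh = 1L, za = NA_integer_,
    gap_filled = 0L, stringsAsFactors = FALSE
  )
  res <- mismatch_filter(ps, g, pseudose_params(max_mm = 2,
                                                oligoA_exempt = TRUE))
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$za, 3L)
  expect_equal(res$kept$nm, 0L)
  expect_equal(nrow(res$oligoA), 1)

  res_off <- mismatch_filter(ps, g, pseudose_params(max_mm = 2,
                                                    oligoA_exempt = FALSE))
  expect_equal(nrow(res_off$kept), 0)
  expect_equal(nrow(res_off$discarded_mm), 1)

  # internal mismatches above the cutoff are discarded regardless
  ch <- seq_chars(win)
  for (p in c(5, 10, 15)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  ps2 <- ps
  ps2$seq <- paste0(paste(ch, collapse = ""), "AAA")
  res2 <- mismatch_filter(ps2, g, pseudose_params(max_mm = 2,
                                                  oligoA_exempt = TRUE))
  expect_equal(nrow(res2$kept), 0)
  expect_equal(nrow(res2$discarded_mm), 1)
})

test_that("oligo(A) runs are measured on the minus strand in read orientation", {
  # minus-strand read: the 3' tail sits at the genomic LEFT edge as
  # T's; bases 97-99 are fixed non-T so the tail cannot be templated
  set.seed(56)
  g <- tiny_genome(paste0(
    paste(sample(c("A", "C", "G", "T"), 97, TRUE), collapse = ""),
    "GCA",
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")))
  ins <- genome_subseq(g, "chrT", 100, 128, "-")
  ps <- data.frame(
    read_id = "r1", chrom = "chrT", strand = "-", start0 = 97, end0 = 128,
    seq = paste0(ins, "AAA"), qual = uniform_qual(31), score = 0,
    nm = NA_integer_, mate = 0L, nh = 1L, za = NA_integer_,
    gap_filled = 0L, stringsAsFactors = FALSE
  )
  res <- mismatch_filter(ps, g, pseudose_params())
  expect_equal(res$kept$za, 3L)
  expect_equal(res$kept$nm, 0L)
})

test_that("SE passthrough preserves records and filters identically", {
  g <- random_genome(300, 55)
  aln <- data.frame(
    read_id = c("a", "b"), chrom = "chrT", strand = "+",
    start0 = c(50, 80), end0 = c(80, 110),
    score = 0L, nm = 0L, mate = 0L,
    seq = c(genome_subseq(g, "chrT", 50, 80, "+"),
            genome_subseq(g, "chrT", 80, 110, "+")),
    qual = uniform_qual(30), nh = c(1L, 60L), stringsAsFactors = FALSE
  )
  ps <- passthrough_se(aln)
  expect_equal(ps$gap_filled, c(0L, 0L))
  res <- mismatch_filter(ps, g, pseudose_params(max_nh = 50))
  expect_equal(res$kept$read_id, "a")
  expect_equal(res$discarded_multi$read_id, "b")
  expect_equal(sum(res$tallies[c("kept", "discarded_mm",
                                 "discarded_multi")]),
               unname(res$tallies["input"]))
})

test_that("zero-noise paired simulation merges to exact genomic inserts", {
  g <- make_genome(8000, seed = 61)
  truth <- g$truth
  set.seed(62)
  for (i in 1:5) {
    s <- 200 + (i - 1) * 1500
    truth <- add_product(truth, s, s + c(25, 34, 60, 90, 110)[i],
                         sample(c("+", "-"), 1), "manual")
  }
  sim <- simulate_reads(g$genome, truth, depth_per_product = 20,
                        end_jitter_sd = 0, oligoA_rate = 0,
                        noise_read_rate = 0, seq_error_rate = 0,
                        lowq_tail_rate = 0, seed = 63)
  tp <- trim_reads(sim$r1, sim$r2, trim_params())
  res <- sensitive_align(tp$kept_r1, tp$kept_r2, g$genome, align_params())
  out <- pseudose(res$retained, g$genome, pseudose_params(), paired = TRUE)
  # conservation: kept + discarded == input pair placements
  expect_equal(sum(out$tallies[c("kept", "discarded_mm",
                                 "discarded_multi")]),
               nrow(res$retained))
  # every merged insert equals its genomic substring exactly
  k <- out$kept
  expect_equal(nrow(k), 100)
  for (i in seq_len(nrow(k))) {
    expect_identical(k$seq[i],
                     genome_subseq(g$genome, k$chrom[i], k$start0[i],
                                   k$end0[i], k$strand[i]))
  }
  expect_true(all(k$nm == 0))
  # full-insert reconstruction: lengths match the planted products
  expect_setequal(unique(k$end0 - k$start0), c(25, 34, 60, 90, 110))
})
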