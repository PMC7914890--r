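test_that("product identifiers follow the FM_ naming convention", {
  sl <- c(NC_000913.2 = 4641652)
  expect_equal(product_id("NC_000913.2", "+", 4541695L, 4541729L, sl),
               "FM_+NC_000913.2_4541696_34")
  expect_equal(product_id("NC_000913.2", "-", 848113L, 848166L, sl),
               "FM_-NC_000913.2_0848114_53")
  # unique across a representative set of distinct intervals
  ids <- product_id("NC_000913.2", c("+", "+", "-"), c(10L, 20L, 10L),
                    c(40L, 50L, 40L), sl)
  expect_false(anyDuplicated(ids) > 0)
})

test_that("biotype assignment respects strand and priority", {
  ann <- data.frame(
    chrom = "chrT",
    start0 = c(100L, 150L, 400L, 700L), end0 = c(200L, 300L, 500L, 800L),
    strand = c("+", "+", "+", "-"),
    type = c("tRNA", "CDS", "misc_RNA", "rRNA"),
    id = c("t1", "c1", "n1", "r1"), stringsAsFactors = FALSE
  )
  x <- data.frame(
    chrom = "chrT", strand = c("+", "+", "+", "+", "+"),
    start0 = c(120L, 160L, 420L, 720L, 900L),
    end0 = c(150L, 190L, 450L, 750L, 930L), stringsAsFactors = FALSE
  )
  bt <- assign_biotype(x, ann)
  # inside tRNA; overlapping tRNA+CDS -> tRNA by priority; generic
  # ncRNA type; antisense of an rRNA; feature-free -> intergenic
  expect_equal(bt, c("tRNA", "tRNA", "ncRNA", "antisense", "intergenic"))
})

test_that("each placement of a multi-mapped read contributes one count", {
  g <- make_genome(4000, n_duplicated_loci = 1, dup_len = 60, seed = 95)
  dup <- g$truth$duplicated_loci
  reps <- data.frame(
    chrom = "chrS", strand = "+",
    start0 = c(dup$src_start0 + 15L, dup$copy_start0 + 15L),
    end0 = c(dup$src_start0 + 45L, dup$copy_start0 + 45L),
    stringsAsFactors = FALSE
  )
  reps$product_id <- product_id(reps$chrom, reps$strand, reps$start0,
                                reps$end0, g$genome)
  # one read with two placements (NH = 2), one at each duplicated copy
  ps <- ps_reads(g$genome, "chrS", c("+", "+"),
                 reps$start0, reps$end0, ids = c("m1", "m1"), nh = 2L)
  ql <- quantify_library(ps, reps, g$genome, quantify_params())
  expect_equal(ql$counts, c(1, 1))            # total contribution 2
  expect_equal(ql$total_reads, 1)             # one distinct read
  expect_equal(ql$stats$uniqueness, c(0, 0))  # no NH == 1 placements
  # empty-safe: zero assigned reads for a far-away product
  far <- data.frame(chrom = "chrS", strand = "-", start0 = 10L,
                    end0 = 40L, product_id = "p_far",
                    stringsAsFactors = FALSE)
  ql2 <- quantify_library(ps, far, g$genome, quantify_params())
  expect_equal(ql2$counts, 0)
  expect_true(is.na(ql2$stats$uniqueness))
})

test_that("consensus takes the majority base, genomic on ties", {
  g <- random_genome(500, 96)
  prod <- data.frame(chrom = "chrT", strand = "+", start0 = 100L,
                     end0 = 130L, stringsAsFactors = FALSE)
  gseq <- genome_subseq(g, "chrT", 100, 130, "+")
  mutate_at <- function(s, p, b) { ch <- seq_chars(s); ch[p] <- b
                                   paste(ch, collapse = "") }
  alt <- setdiff(c("A", "C", "G", "T"), substr(gseq, 5, 5))[1]
  # 6 reads carry an alternative base at position 5, 4 match the genome
  reads <- ps_reads(g, "chrT", rep("+", 10), rep(100, 10), rep(130, 10))
  reads$seq[1:6] <- mutate_at(gseq, 5, alt)
  asg <- data.frame(read_row = 1:10, product_row = 1L)
  cons <- stablefrag:::consensus_one(prod[1, ], reads, 1:10, g)
  expect_equal(substr(cons$consensus_seq, 5, 5), alt)
  expect_equal(phred_ints(cons$consensus_qual)[5], 35)
  # 5 vs 5 tie -> genomic base wins
  reads$seq[6] <- gseq
  cons2 <- stablefrag:::consensus_one(prod[1, ], reads, 1:10, g)
  expect_equal(cons2$consensus_seq, gseq)
  expect_equal(cons2$coverage, rep(10L, 30))
  # all agreeing with genome -> consensus equals the genomic sequence
  reads$seq <- gseq
  cons3 <- stablefrag:::consensus_one(prod[1, ], reads, 1:10, g)
  expect_equal(cons3$consensus_seq, cons3$genomic_seq)
})

test_that("RPM layers scale as defined and biotype denominators separate", {
  raw <- matrix(c(50L, 20L, 100L, 40L), 2, 2,
                dimnames = list(c("p1", "p2"), c("l1", "l2")))
  bt <- matrix(c(60, 120, 1000, 2000), 2, 2,
               dimnames = list(c("l1", "l2"), c("tRNA", "intergenic")))
  cm <- normalize_counts(raw, c(l1 = 1e5, l2 = 2e5),
                         biotypes = c("tRNA", "intergenic"),
                         biotype_totals = bt)
  expect_equal(cm$rpm["p1", "l1"], 500)   # 50 / 100,000 * 1e6
  expect_equal(cm$rpm["p1", "l2"], 500)   # doubled totals, doubled count
  expect_equal(cm$rpm_biotype["p1", "l1"], 50 / 60 * 1e6)
  expect_equal(cm$rpm_biotype["p2", "l1"], 20 / 1000 * 1e6)
  # group layer: intergenic maps to "other"
  expect_equal(cm$rpm_biotype_group["p2", "l1"], 20 / 1000 * 1e6)
  # scale equivariance: doubling totals halves RPM
  cm2 <- normalize_counts(raw, c(l1 = 2e5, l2 = 4e5),
                          biotypes = c("tRNA", "intergenic"),
                          biotype_totals = bt)
  expect_equal(cm2$rpm, cm$rpm / 2)
  # zero biotype total with a nonzero count is impossible
  bt0 <- bt; bt0[, "tRNA"] <- 0
  expect_error(normalize_counts(raw, c(l1 = 1e5, l2 = 2e5),
                                c("tRNA", "intergenic"), bt0),
               "zero biotype total")
})

test_that("the RPM retention rule keeps any product reaching the bar once", {
  raw <- matrix(c(99L, 0L, 99L, 0L, 99L, 10L), 2, 3,
                dimnames = list(c("a", "b"), c("l1", "l2", "l3")))
  cm <- normalize_counts(raw, c(l1 = 1e7, l2 = 1e7, l3 = 1e6),
                         biotypes = c("intergenic", "intergenic"),
                         biotype_totals = matrix(
                           1e6, 3, 1, dimnames = list(NULL, "intergenic")))
  # a: RPM 9.9, 9.9, 99 -> kept; b: 0, 0, 10 -> kept at exactly 10
  expect_equal(unname(rpm_retention_filter(cm, 10)), c(TRUE, TRUE))
  # row staying below 10 everywhere drops
  raw2 <- raw; raw2["a", ] <- c(99L, 99L, 9L)
  cm2 <- normalize_counts(raw2, c(l1 = 1e7, l2 = 1e7, l3 = 1e6),
                          biotypes = c("intergenic", "intergenic"),
                          biotype_totals = matrix(
                            1e6, 3, 1, dimnames = list(NULL, "intergenic")))
  expect_equal(unname(rpm_retention_filter(cm2, 10)), c(FALSE, TRUE))
  # threshold 0 is the identity
  expect_true(all(rpm_retention_filter(cm2, 0)))
  # brute-force row-max rule agreement on a random matrix
  set.seed(97)
  raw3 <- matrix(rpois(60, 30), 20, 3,
                 dimnames = list(sprintf("p%02d", 1:20), c("a", "b", "c")))
  cm3 <- normalize_counts(raw3, c(a = 2e6, b = 3e6, c = 4e6),
                          biotypes = rep("intergenic", 20),
                          biotype_totals = matrix(
                            1e6, 3, 1, dimnames = list(NULL, "intergenic")))
  want <- vapply(seq_len(20), function(i)
    max(raw3[i, ] / c(2e6, 3e6, 4e6) * 1e6) >= 10, logical(1))
  expect_equal(unname(rpm_retention_filter(cm3, 10)), want)
})

test_that("run statistics produce one complete row per library", {
  tl <- list(lib1 = c(input = 100, kept = 90),
             lib2 = c(input = 80, kept = 70, oligoA = 3),
             empty = numeric(0))
  st <- run_statistics(tl)
  expect_equal(nrow(st), 3)
  expect_equal(st$library, c("lib1", "lib2", "empty"))
  expect_equal(st$oligoA, c(0, 3, 0))
  expect_equal(st$input[3], 0)
})
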