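test_that("relative coverage follows its defining ratio", {
  g <- random_genome(2000, 81)
  prod <- data.frame(chrom = "chrT", strand = "+", start0 = 100L,
                     end0 = 140L, stringsAsFactors = FALSE)
  # 8 assigned reads spanning the product, 2 background reads across it
  reads <- ps_reads(g, "chrT", rep("+", 10),
                    c(rep(100, 8), 80, 80), c(rep(140, 8), 160, 160))
  asg <- data.frame(read_row = 1:8, product_row = 1L)
  expect_equal(relative_coverage(prod, reads, asg), 0.8)
  # a product whose reads are the only reads there -> 1.0
  asg_all <- data.frame(read_row = 1:10, product_row = 1L)
  expect_equal(relative_coverage(prod, reads, asg_all), 1.0)
  # always within [0, 1]
  expect_true(relative_coverage(prod, reads,
                                data.frame(read_row = 1L,
                                           product_row = 1L)) <= 1)
})

test_that("candidate filtering applies count and background thresholds", {
  prods <- data.frame(chrom = "c", strand = "+", start0 = 0:3 * 100,
                      end0 = 0:3 * 100 + 30,
                      count = c(12L, 12L, 9L, 12L),
                      relcov = c(0.9, 0.1, 0.9, 0.5))
  kept <- filter_candidates(prods, min_count = 10, min_relcov = 0.5)
  expect_equal(kept$start0, c(0, 300))
  expect_equal(nrow(filter_candidates(prods, 10, 0)), 3)  # relcov disabled
})

test_that("overlap clustering follows the greedy representative rule", {
  # P1=[100,140), P2=[101,141), P3=[100,170), tol 2: P1 represents
  # {P1,P2} (leftmost tie-break over P2), P3 stands alone
  prods <- data.frame(chrom = "c", strand = "+",
                      start0 = c(100L, 101L, 100L),
                      end0 = c(140L, 141L, 170L),
                      total_count = c(10L, 10L, 10L))
  cl <- cluster_by_overlap(prods, tolerance = 2)
  expect_equal(which(cl$is_representative), c(1, 3))
  expect_equal(cl$cluster, c(1, 1, 2))
  # tolerance 0: only identical intervals share a cluster
  cl0 <- cluster_by_overlap(prods, tolerance = 0)
  expect_equal(sum(cl0$is_representative), 3)
})

test_that("greedy clustering matches the exhaustive oracle and its invariants", {
  for (trial in 1:200) {
    prods <- random_product_fixture(sample(2:12, 1), seed = 8000 + trial)
    prods <- prods[!duplicated(prods[c("chrom", "strand", "start0",
                                       "end0")]), , drop = FALSE]
    rownames(prods) <- NULL
    tol <- sample(c(0, 2, 4, 8), 1)
    got <- cluster_by_overlap(prods, tol)
    want <- oracle_overlap_cluster(prods, tol)
    expect_equal(which(got$is_representative), sort(want$representatives))
    # every member within tolerance of its representative; disjoint
    # clusters covering the input
    expect_true(all(got$cluster > 0))
    for (cid in unique(got$cluster)) {
      mem <- which(got$cluster == cid)
      rep_i <- mem[got$is_representative[mem]]
      expect_length(rep_i, 1)
      d <- abs(got$start0[mem] - got$start0[rep_i]) +
        abs(got$end0[mem] - got$end0[rep_i])
      expect_true(all(d <= tol))
    }
  }
})

test_that("re-clustering representatives is the identity; tolerance is monotone", {
  prods <- random_product_fixture(12, seed = 91)
  prods <- prods[!duplicated(prods[c("chrom", "strand", "start0",
                                     "end0")]), , drop = FALSE]
  cl <- cluster_by_overlap(prods, 4)
  reps <- cl[cl$is_representative, setdiff(names(cl),
                                           c("cluster",
                                             "is_representative"))]
  rownames(reps) <- NULL
  again <- cluster_by_overlap(reps, 4)
  expect_true(all(again$is_representative))
  n_reps <- vapply(c(0, 1, 2, 4, 8, 16), function(tol)
    sum(cluster_by_overlap(prods, tol)$is_representative), integer(1))
  expect_true(all(diff(n_reps) <= 0))
})

test_that("contigs are maximal positive-coverage islands", {
  g <- random_genome(1000, 92)
  reads <- ps_reads(g, "chrT", rep("+", 4),
                    c(95, 120, 200, 230), c(130, 160, 231, 260))
  ct <- build_contigs(reads)
  expect_equal(ct$start0, c(95, 200))
  expect_equal(ct$end0, c(160, 260))
  # islands separated by a single zero-coverage base stay apart
  reads2 <- ps_reads(g, "chrT", c("+", "+"), c(0, 31), c(30, 60))
  ct2 <- build_contigs(reads2)
  expect_equal(nrow(ct2), 2)
  # every product lies inside some contig
  prod <- data.frame(chrom = "chrT", strand = "+", start0 = 100L,
                     end0 = 140L)
  idx <- stablefrag:::product_contig(prod, ct)
  expect_false(is.na(idx))
})

test_that("sliding identity measures the best ungapped submatch", {
  expect_equal(sliding_identity("ACGT", "ACGT"), 1)
  expect_equal(sliding_identity("ACGT", "TTACGTTT"), 1)
  expect_equal(sliding_identity("AAAA", "AATA"), 0.75)
  expect_equal(sliding_identity("ACGTACGTAC", "ACGTTCGTAC"), 0.9)
})

test_that("sequence clustering merges only with matching contig context", {
  # two identical 30-bp loci; contexts built explicitly
  set.seed(93)
  core <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  ctxA <- paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = "")
  ctxB <- paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  g_same <- tiny_genome(paste0(pad(50), ctxA, core, ctxA, pad(50),
                               ctxA, core, ctxA, pad(50)))
  # identical product sequence and identical 60-bp contig context
  reps <- data.frame(chrom = "chrT", strand = "+",
                     start0 = c(65L, 175L), end0 = c(95L, 205L),
                     total_count = c(20L, 15L), stringsAsFactors = FALSE)
  contigs <- data.frame(chrom = "chrT", strand = "+",
                        start0 = c(50L, 160L), end0 = c(110L, 220L),
                        stringsAsFactors = FALSE)
  sq <- cluster_by_sequence(reps, contigs, g_same, cluster_params())
  expect_equal(nrow(sq$representatives), 1)
  expect_equal(length(unique(sq$members)), 1)

  # identical products, diverged contexts (< 90% contig identity)
  g_diff <- tiny_genome(paste0(pad(50), ctxA, core, ctxA, pad(50),
                               ctxB, core, ctxB, pad(50)))
  sq2 <- cluster_by_sequence(reps, contigs, g_diff, cluster_params())
  expect_equal(nrow(sq2$representatives), 2)

  # contig length ratio below the cutoff blocks merging too
  contigs3 <- data.frame(chrom = "chrT", strand = "+",
                         start0 = c(20L, 160L), end0 = c(150L, 220L),
                         stringsAsFactors = FALSE)  # 130 vs 60 bp: 0.46
  sq3 <- cluster_by_sequence(reps, contigs3, g_same, cluster_params())
  expect_equal(nrow(sq3$representatives), 2)
})
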