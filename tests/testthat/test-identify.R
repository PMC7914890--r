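test_that("size fractionation routes reads to unique bins and conserves them", {
  bins <- parse_size_bins(DEFAULT_SIZE_BINS)
  g <- random_genome(2000, 71)
  lens <- c(17, 18, 26, 27, 34, 40, 41, 120, 300, 301)
  ps <- ps_reads(g, "chrT", rep("+", 10), seq(0, 900, by = 100),
                 seq(0, 900, by = 100) + lens)
  fr <- fractionate_by_size(ps, bins)
  expect_equal(fr$dropped, 2)  # 17 below, 301 above
  expect_equal(sum(vapply(fr$fractions, nrow, integer(1))) + fr$dropped,
               nrow(ps))
  expect_equal(fr$fractions[["27-40"]]$end0 - fr$fractions[["27-40"]]$start0,
               c(27, 34, 40))
  expect_error(parse_size_bins("18-26,26-40"), "overlap")
})

test_that("a single sharp read stack yields exactly one fully supported product", {
  g <- random_genome(3000, 72)
  ps <- ps_reads(g, "chrT", rep("+", 100), rep(1000, 100), rep(1034, 100))
  p <- call_end_peaks(ps, c(27, 40), min_end_reads = 5, mask_window = 15)
  expect_equal(nrow(p), 1)
  expect_equal(p$start0, 1000)
  expect_equal(p$end0, 1034)
  expect_equal(p$five_support, 100)
  expect_equal(p$three_support, 100)
})

test_that("co-starting products are resolved only beyond the mask window", {
  g <- random_genome(3000, 73)
  # lengths 20 and 40 share the 5' end: difference 20 > 15 -> both
  ps <- rbind(ps_reads(g, "chrT", rep("+", 50), rep(500, 50), rep(520, 50),
                       ids = sprintf("a%03d", 1:50)),
              ps_reads(g, "chrT", rep("+", 50), rep(500, 50), rep(540, 50),
                       ids = sprintf("b%03d", 1:50)))
  p <- call_end_peaks(ps, c(18, 60), min_end_reads = 5, mask_window = 15)
  expect_equal(nrow(p), 2)
  expect_setequal(p$end0, c(520, 540))

  # lengths 20 and 25: difference 5 <= 15 -> only the stronger 3' peak
  ps2 <- rbind(ps_reads(g, "chrT", rep("+", 50), rep(500, 50), rep(520, 50),
                        ids = sprintf("a%03d", 1:50)),
               ps_reads(g, "chrT", rep("+", 60), rep(500, 60), rep(525, 60),
                        ids = sprintf("b%03d", 1:60)))
  p2 <- call_end_peaks(ps2, c(18, 60), min_end_reads = 5, mask_window = 15)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$end0, 525)
})

test_that("minus-strand densities use the biological 5' end (right edge)", {
  g <- random_genome(3000, 74)
  # two minus-strand populations sharing the biological 5' end at 839
  ps <- rbind(ps_reads(g, "chrT", rep("-", 40), rep(800, 40), rep(840, 40),
                       ids = sprintf("a%03d", 1:40)),
              ps_reads(g, "chrT", rep("-", 30), rep(820, 30), rep(840, 30),
                       ids = sprintf("b%03d", 1:30)))
  p <- call_end_peaks(ps, c(18, 60), min_end_reads = 5, mask_window = 15)
  expect_equal(nrow(p), 2)
  expect_setequal(p$start0, c(800, 820))
  # shared 5' peak at 839: full 70 at first emission, 30 left after the
  # exactly-paired reads of the first fragment are consumed
  expect_setequal(p$five_support, c(70, 30))
})

test_that("end-support filtering keeps products with one strong end", {
  prods <- data.frame(chrom = "c", strand = "+",
                      start0 = c(0, 100, 200), end0 = c(30, 130, 230),
                      five_support = c(6L, 4L, 5L),
                      three_support = c(3L, 3L, 5L))
  kept <- filter_by_end_support(prods, quant_threshold = 10)
  expect_equal(kept$start0, c(0, 200))   # max(6,3)>=5 and (5,5); (4,3) drops
  expect_equal(nrow(filter_by_end_support(prods, 0)), 3)
})

test_that("read assignment tolerates at most the configured non-overlap", {
  g <- random_genome(3000, 75)
  prod <- data.frame(chrom = "chrT", strand = "+", start0 = 1000L,
                     end0 = 1034L, stringsAsFactors = FALSE)
  reads <- ps_reads(g, "chrT", rep("+", 5),
                    c(1000, 998, 997, 1002, 1000),
                    c(1034, 1034, 1034, 1034, 1036))
  asg <- assign_reads_to_products(reads, prod, 2, 2)
  # exact; 2 bases outside ok; 3 outside not; 2 uncovered ok; 2 outside ok
  expect_setequal(asg$read_row, c(1, 2, 4, 5))
  expect_equal(count_reads_to_products(reads, prod, 2, 2), 4)
  # stranded: opposite-strand reads never count
  reads_m <- reads; reads_m$strand <- "-"
  expect_equal(count_reads_to_products(reads_m, prod, 2, 2), 0)
})

test_that("full identification recovers planted stacks with jittered ends", {
  g <- random_genome(6000, 76)
  set.seed(77)
  mkstack <- function(s, e, n, sd) {
    s2 <- s + round(rnorm(n, 0, sd)); e2 <- e + round(rnorm(n, 0, sd))
    ps_reads(g, "chrT", rep("+", n), pmax(0, s2), pmin(6000, e2),
             ids = sprintf("s%d_%03d", s, 1:n))
  }
  ps <- rbind(mkstack(1000, 1034, 80, 1), mkstack(2000, 2090, 60, 1),
              mkstack(3000, 3025, 70, 0))
  res <- identify_products(ps, identify_params())
  truth <- data.frame(chrom = "chrT", strand = "+",
                      start0 = c(1000, 2000, 3000),
                      end0 = c(1034, 2090, 3025))
  ev <- evaluate_recovery(truth, res$products, end_tolerance = 2)
  expect_equal(ev$recall, 1)
  # assigned counts at least the reads matching both ends exactly
  for (i in seq_len(nrow(res$products))) {
    exact <- sum(ps$start0 == res$products$start0[i] &
                   ps$end0 == res$products$end0[i])
    expect_gte(res$products$count[i], exact)
  }
  expect_equal(unname(res$tallies["reads"]), nrow(ps))
})
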