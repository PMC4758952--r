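test_that("binning follows the half-open convention and conserves tags", {
  expect_equal(bin_tags(tibble::tibble(chrom = "c", pos = integer(0),
                                       strand = character(0)),
                        bin_size = 200, span = 1000)$counts,
               rep(0L, 5))
  tr <- bin_tags(tibble::tibble(chrom = "c", pos = c(0L, 199L, 200L),
                                strand = "+"), bin_size = 200)
  expect_equal(tr$counts[1:2], c(2L, 1L))
  set.seed(4)
  pos <- sample.int(10000, 500, replace = TRUE) - 1L
  tr2 <- bin_tags(tibble::tibble(chrom = "c", pos = pos, strand = "+"),
                  bin_size = 200, span = 10000)
  expect_equal(sum(tr2$counts), 500L)
  expect_error(bin_tags(tibble::tibble(chrom = "c", pos = 1L,
                                       strand = "+"), bin_size = 0),
               "positive")
})

test_that("a constant-rate track yields a single segment", {
  tr <- bin_tags(tibble::tibble(chrom = "c", pos = integer(0),
                                strand = character(0)), 200, span = 20000)
  tr$counts <- rep(3L, 100)
  seg <- segment_track(tr)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$post_mean_rate, (1 + 300) / (1 + 100))
})

# restricted oracle: best boundary among single-change-point partitions,
# by direct evaluation of the same block score
oracle_segment_bruteforce_1cp <- function(counts, alpha = 1, beta = 1,
                                          p = 0.01) {
  n <- length(counts)
  sc <- function(i, j) {
    S <- sum(counts[i:j]); L <- j - i + 1
    alpha * log(beta) - lgamma(alpha) + lgamma(alpha + S) -
      (alpha + S) * log(beta + L) + (L - 1) * log1p(-p) + log(p)
  }
  which.max(vapply(1:(n - 1), function(k) sc(1, k) + sc(k + 1, n),
                   numeric(1)))
}

test_that("a planted rate step is found within one bin", {
  set.seed(11)
  counts <- c(rpois(50, 1), rpois(50, 10))
  tr <- structure(list(chrom = "c", bin_size = 200L, offset = 0L,
                       counts = as.integer(counts)),
                  class = "binned_track")
  seg <- segment_track(tr)
  expect_equal(nrow(seg), 2)
  expect_lte(abs(seg$end_bin[1] - 50), 1)
  # oracle: best single-change-point partition (same scoring)
  or <- oracle_segment_bruteforce_1cp(counts)
  expect_lte(abs(seg$end_bin[1] - or), 1)
})

test_that("three planted blocks are recovered across seeded replicates", {
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    counts <- c(rpois(40, 1), rpois(30, 12), rpois(40, 1))
    tr <- structure(list(chrom = "c", bin_size = 200L, offset = 0L,
                         counts = as.integer(counts)),
                    class = "binned_track")
    seg <- segment_track(tr)
    ok <- nrow(seg) == 3 &&
      abs(seg$end_bin[1] - 40) <= 1 && abs(seg$end_bin[2] - 70) <= 1
    hits <- hits + ok
  }
  expect_gte(hits, 19)
})

test_that("MAP segmentation matches brute-force enumeration on short tracks", {
  set.seed(21)
  for (n in c(5, 8, 10, 12)) {
    for (rep_i in 1:3) {
      counts <- rpois(n, sample(c(1, 6), n, replace = TRUE))
      tr <- structure(list(chrom = "c", bin_size = 10L, offset = 0L,
                           counts = as.integer(counts)),
                      class = "binned_track")
      seg <- segment_track(tr)
      or <- oracle_segment_bruteforce(counts)
      expect_equal(seg$end_bin, or$end_bin)
      expect_equal(attr(seg, "log_posterior"), or$score, tolerance = 1e-10)
    }
  }
})

test_that("identical treatment and control yield no enriched regions", {
  set.seed(31)
  tags <- tibble::tibble(chrom = "c",
                         pos = sample.int(50000, 2000, replace = TRUE) - 1L,
                         strand = "+")
  reg <- call_enriched_regions(tags, tags)
  expect_equal(nrow(reg), 0)
})

test_that("a planted enriched block is recovered against uniform mock", {
  set.seed(32)
  bg <- tibble::tibble(chrom = "c",
                       pos = sample.int(100000, 2000, replace = TRUE) - 1L,
                       strand = "+")
  blk <- tibble::tibble(chrom = "c",
                        pos = sample(40000:41999, 2000, replace = TRUE),
                        strand = "+")
  treatment <- dplyr::bind_rows(bg, blk)
  mock <- tibble::tibble(chrom = "c",
                         pos = sample.int(100000, 4000, replace = TRUE) - 1L,
                         strand = "+")
  reg <- call_enriched_regions(treatment, mock)
  expect_equal(nrow(reg), 1)
  cover <- min(reg$end, 42000) - max(reg$start, 40000)
  expect_gte(cover, 0.8 * 2000)
  expect_lte(max(40000 - reg$start, 0), 200)
  expect_lte(max(reg$end - 42000, 0), 200)

  # two blocks 10 kb apart give two disjoint regions
  blk2 <- dplyr::mutate(blk, pos = pos + 12000L)
  reg2 <- call_enriched_regions(dplyr::bind_rows(treatment, blk2), mock)
  expect_equal(nrow(reg2), 2)
  expect_true(all(reg2$start[-1] >= head(reg2$end, -1)))
})

test_that("enriched basepairs shrink as the fold threshold rises", {
  w <- test_world()
  tg <- w$tags
  bp <- vapply(c(1.5, 2, 4), function(f) {
    r <- call_enriched_regions(tg$K7me2, tg$mock, fold_threshold = f)
    sum(r$end - r$start)
  }, numeric(1))
  expect_true(all(diff(bp) <= 0))
})

test_that("empty control falls back to global background with a warning", {
  set.seed(33)
  treatment <- tibble::tibble(
    chrom = "c", pos = c(sample.int(50000, 1000, TRUE) - 1L,
                         sample(20000:20999, 800, TRUE)), strand = "+")
  empty <- treatment[0, ]
  expect_warning(reg <- call_enriched_regions(treatment, empty), "control")
  expect_gte(nrow(reg), 1)
})

test_that("region merging is idempotent and output sorted", {
  reg <- tibble::tibble(chrom = "c", start = c(400L, 0L, 200L),
                        end = c(600L, 200L, 400L),
                        rate_ratio = c(3, 2, 4))
  m1 <- ctdbalance:::merge_adjacent_regions(reg)
  expect_equal(nrow(m1), 1)
  expect_equal(c(m1$start, m1$end), c(0L, 600L))
  m2 <- ctdbalance:::merge_adjacent_regions(m1)
  expect_equal(m1, m2)
})
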