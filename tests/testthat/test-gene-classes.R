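mkgenes <- function(tss, strand = "+", len = 3000L) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  start <- ifelse(strand == "+", tss, tss - len + 1L)
  tibble::tibble(gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1",
                 start = as.integer(start),
                 end = as.integer(start + len),
                 strand = strand, tss = as.integer(tss),
                 tes = as.integer(ifelse(strand == "+", start + len, start)))
}

test_that("promoter positivity needs region overlap and the 10% tail cut", {
  genes <- mkgenes(seq(5000, 5000 + 9 * 10000, by = 10000))
  # enriched regions covering every promoter
  regions <- tibble::tibble(chrom = "chr1", start = genes$tss - 100L,
                            end = genes$tss + 100L, rate_ratio = 5)
  counts <- tibble::tibble(gene_id = genes$gene_id, count = 1:10)
  st <- classify_promoters(genes, regions, counts)
  # nearest-rank 10th percentile of 1..10 is 1: only the count-1 gene fails
  expect_equal(sum(st$status == "positive", na.rm = TRUE), 9)
  expect_equal(st$status[st$promoter_count == 1], "negative")

  # a gene with no overlapping region is negative regardless of count
  regions2 <- regions[-1, ]
  st2 <- classify_promoters(genes, regions2, counts)
  expect_equal(st2$status[1], "negative")
  expect_false(st2$passed_region_overlap[1])

  # empty gene set
  expect_equal(nrow(classify_promoters(genes[0, ], regions, counts)), 0)
})

test_that("overlap and containment exclusions set NA, never positive", {
  # two genes with intersecting 2 kb promoter windows, both positive; the
  # count-10 gene is the 10% tail so the others clear the percentile cut
  genes <- mkgenes(c(5000L, 6500L, 30000L, 60000L, 90000L))
  regions <- tibble::tibble(chrom = "chr1", start = genes$tss - 100L,
                            end = genes$tss + 100L, rate_ratio = 5)
  counts <- tibble::tibble(gene_id = genes$gene_id,
                           count = c(50L, 60L, 70L, 80L, 10L))
  st <- classify_promoters(genes, regions, counts)
  expect_true(all(is.na(st$status[1:2])))
  expect_equal(st$status[3:4], c("positive", "positive"))
  expect_equal(st$status[5], "negative")

  # positive gene strictly inside another positive gene: internal one NA;
  # TSS windows kept disjoint so only the containment rule fires
  genes2 <- tibble::tibble(
    gene_id = c("host", "inner", "far", "tail"), chrom = "chr1",
    start = c(30000L, 36000L, 90000L, 120000L),
    end = c(40000L, 37000L, 93000L, 123000L),
    strand = "+", tss = c(30000L, 36000L, 90000L, 120000L),
    tes = c(40000L, 37000L, 93000L, 123000L))
  regions2 <- tibble::tibble(chrom = "chr1",
                             start = genes2$tss - 100L,
                             end = genes2$tss + 100L, rate_ratio = 5)
  counts2 <- tibble::tibble(gene_id = genes2$gene_id,
                            count = c(60L, 60L, 70L, 10L))
  st2 <- classify_promoters(genes2, regions2, counts2)
  expect_equal(st2$status[st2$gene_id == "host"], "positive")
  expect_true(is.na(st2$status[st2$gene_id == "inner"]))
  # exclusions never convert a negative into anything else
  expect_false(any(st2$status[!st2$passed_percentile |
                                !st2$passed_region_overlap] == "positive",
                   na.rm = TRUE))
})

test_that("maximum-peak offsets are signed, tie-broken toward the TSS", {
  # tss on a bin center (bins are genome-anchored 10 bp, centers ...5005...)
  g <- tibble::tibble(gene_id = c("p", "m"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(5005L, 5005L),
                      tes = c(8000L, 2000L))
  mk_track <- function(pos, counts) {
    tg <- tibble::tibble(chrom = "chr1",
                         pos = rep(pos, counts), strand = "+")
    bin_tags(tg, bin_size = 10, span = 10000)
  }
  # peak bin centered at the TSS
  expect_equal(max_peak_offset(mk_track(5005L, 20L), g[1, ])$offset, 0)
  # peak at +140 in transcription orientation: excluded from anchored cohort
  off140 <- max_peak_offset(mk_track(5145L, 20L), g[1, ])$offset
  expect_equal(off140, 140)
  # on the minus strand a genomic peak 140 bp below the TSS is downstream
  offm <- max_peak_offset(mk_track(4865L, 20L), g[2, ])$offset
  expect_equal(offm, 140)
  # symmetric tie at +/-30: the smaller |offset| rule keeps it at 30
  tie <- tibble::tibble(chrom = "chr1", pos = c(rep(5035L, 5), rep(4975L, 5)),
                        strand = "+")
  off_tie <- max_peak_offset(bin_tags(tie, 10, span = 10000), g[1, ])$offset
  expect_equal(abs(off_tie), 30)
  # all-zero track -> NA offset
  empty <- bin_tags(tibble::tibble(chrom = "chr1", pos = integer(0),
                                   strand = character(0)), 10, span = 10000)
  expect_true(is.na(max_peak_offset(empty, g[1, ])$offset))
})

test_that("gene classes follow the mark-combination definitions", {
  status <- tibble::tibble(
    gene_id = c("act", "prc", "inact", "odd"),
    S5p = c("positive", "positive", "negative", "positive"),
    S7p = c("positive", "negative", "negative", "negative"),
    S2p = c("positive", "negative", "negative", "negative"),
    `8WG16` = c("positive", "negative", "negative", "positive"),
    H3K27me3 = c("negative", "positive", "negative", "negative"),
    H2Aub1 = c("negative", "positive", "negative", "negative"))
  fpkm <- tibble::tibble(gene_id = status$gene_id, fpkm = c(25, 0.1, 0, 3))
  cls <- assign_gene_classes(status, fpkm)
  expect_equal(cls$class, c("active", "PRCr", "inactive", NA))
})

test_that("top/bottom cohorts take exactly the extreme 15% of polycomb-negative genes", {
  n <- 100
  status <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    S5p = "positive", S7p = "positive", S2p = "positive",
    `8WG16` = "positive", H3K27me3 = "negative", H2Aub1 = "negative")
  fpkm <- tibble::tibble(gene_id = status$gene_id, fpkm = seq(2, 200, 2))
  cls <- assign_gene_classes(status, fpkm)
  expect_equal(sum(cls$top15), 15)
  expect_equal(sum(cls$bottom15), 15)
  expect_true(all(fpkm$fpkm[cls$top15] > fpkm$fpkm[cls$bottom15]))
  expect_false(any(cls$top15 & cls$bottom15))
})

test_that("anchored cohort is the subset within 50 bp and missing marks error", {
  status <- tibble::tibble(
    gene_id = c("a", "b"),
    S5p = "positive", S7p = "positive", S2p = "positive",
    `8WG16` = "positive", H3K27me3 = "negative", H2Aub1 = "negative")
  fpkm <- tibble::tibble(gene_id = c("a", "b"), fpkm = c(10, 10))
  off <- tibble::tibble(gene_id = c("a", "b"), offset = c(10, 140))
  cls <- assign_gene_classes(status, fpkm, peak_offset = off)
  expect_equal(cls$tss_anchored_active, c(TRUE, FALSE))
  expect_true(all(cls$tss_anchored_active <= cls$nonoverlapping_active))
  expect_error(assign_gene_classes(status[, -2], fpkm), "S5p")
})
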