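#' Remove excess duplicate tags
#'
#' ChIP tags mapping to exactly the same (chromosome, position, strand) more
#' often than a dataset-specific threshold are treated as amplification
#' artifacts.  The threshold is the nearest-rank 95th percentile of the
#' multiplicity distribution over occupied positions (rounded up to an
#' integer).  By default each over-represented stack is *capped* at the
#' threshold, keeping representative tags; `mode = "drop"` discards
#' offending stacks entirely.
#'
#' @param tags Tag tibble with columns `chrom`, `pos`, `strand`.
#' @param percentile Percentile of the multiplicity distribution defining
#'   the cap (default 0.95).
#' @param population Multiplicity population over which the percentile is
#'   taken: all occupied positions (default) or only duplicated ones.
#' @param mode `"cap"` (default) keeps `threshold` tags per position;
#'   `"drop"` removes entire stacks whose multiplicity exceeds it.
#' @return The deduplicated tag tibble with attribute `dedup_threshold`;
#'   retrieve it with [dedup_threshold()].
#' @examples
#' tags <- tibble::tibble(chrom = "chr1", pos = c(1L, 1L, 2L), strand = "+")
#' dedup_threshold(deduplicate_tags(tags))
#' @export
deduplicate_tags <- function(tags, percentile = 0.95,
                             population = c("all", "duplicated"),
                             mode = c("cap", "drop")) {
  population <- match.arg(population)
  mode <- match.arg(mode)
  if (nrow(tags) == 0) abort("cannot deduplicate an empty tag set")
  mult <- dplyr::count(tags, .data$chrom, .data$pos, .data$strand)
  pop <- if (population == "all") mult$n else mult$n[mult$n > 1]
  if (length(pop) == 0) pop <- mult$n
  threshold <- as.integer(ceiling(nearest_rank_quantile(pop, percentile)))
  kept <- if (mode == "cap") {
    mutate(mult, n = pmin(.data$n, .env$threshold))
  } else {
    filter(mult, .data$n <= .env$threshold)
  }
  out <- tidyr::uncount(kept, .data$n)
  out <- as_tibble(out[, c("chrom", "pos", "strand")])
  attr(out, "dedup_threshold") <- threshold
  out
}

#' @rdname deduplicate_tags
#' @param x A tag tibble returned by [deduplicate_tags()].
#' @export
dedup_threshold <- function(x) attr(x, "dedup_threshold")

#' Strand-aware promoter and post-TES windows
#'
#' `promoter_window()` returns the window of `2 * half_width` bp centered on
#' each gene's TSS; the extent is strand-symmetric and the gene strand is
#' carried as `orientation` (used only when profiles are flipped).
#' `tes_window()` returns the window of `length` bp immediately downstream
#' (in transcription orientation) of the TES.  Windows that would extend
#' below coordinate 0 are clipped and flagged.
#'
#' @param genes Gene tibble with `gene_id`, `chrom`, `strand`, `tss`, `tes`.
#' @param half_width Promoter half-width in bp (default 1000, i.e. the 2 kb
#'   window around the TSS).
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `orientation`,
#'   `clipped`.
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
#'                     tss = 5000L, tes = 9000L)
#' promoter_window(g)
#' tes_window(g)
#' @export
promoter_window <- function(genes, half_width = 1000) {
  start <- genes$tss - half_width
  end <- genes$tss + half_width
  clipped <- start < 0
  if (any(clipped)) warn("promoter window(s) clipped at coordinate 0")
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = as.integer(pmax(start, 0)), end = as.integer(end),
         orientation = genes$strand, clipped = clipped)
}

#' @rdname promoter_window
#' @param length Post-TES window length in bp (default 2000).
#' @export
tes_window <- function(genes, length = 2000) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tes, genes$tes - length)
  end <- ifelse(plus, genes$tes + length, genes$tes)
  clipped <- start < 0
  if (any(clipped)) warn("TES window(s) clipped at coordinate 0")
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = as.integer(pmax(start, 0)), end = as.integer(end),
         orientation = genes$strand, clipped = clipped)
}

#' Count tags falling in genomic windows
#'
#' Counts tag 5' positions inside each half-open window `[start, end)`.
#' Counting ignores tag strand unless `stranded` names the strand to keep.
#'
#' @param tags Tag tibble (`chrom`, `pos`, `strand`).
#' @param windows Window tibble from [promoter_window()] / [tes_window()],
#'   or any tibble with `chrom`, `start`, `end`.
#' @param stranded Optional: `"+"` or `"-"` to count only tags on that
#'   strand.
#' @return `windows` with an added integer `count` column.
#' @export
count_window <- function(tags, windows, stranded = NULL) {
  if (!is.null(stranded)) tags <- filter(tags, .data$strand == .env$stranded)
  counts <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    p <- sort(tags$pos[tags$chrom == ch])
    # tags with pos in [start, end): #(pos <= end-1) - #(pos <= start-1)
    counts[wi] <- findInterval(windows$end[wi] - 1L, p) -
      findInterval(windows$start[wi] - 1L, p)
  }
  mutate(windows, count = as.integer(counts))
}

#' Scale a count per 10 million mapped tags
#'
#' The depth normalization applied to promoter and TES counts before ratios
#' and correlation analyses: `count * 1e7 / total_mapped`, where
#' `total_mapped` is the number of non-duplicated mapped tags of the dataset.
#'
#' @param count Tag count(s).
#' @param total_mapped Total non-duplicated mapped tags (> 0).
#' @return Scaled count(s).
#' @examples
#' scale_per_10m(50, 2e7)  # 25
#' @export
scale_per_10m <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) abort("total_mapped must be positive")
  count * 1e7 / total_mapped
}
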