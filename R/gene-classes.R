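#' Promoter positivity for one mark
#'
#' A gene promoter is positive for a mark when (a) its 2 kb window centered
#' on the TSS intersects at least one region called enriched for the mark
#' and (b) its promoter tag count exceeds the nearest-rank 10th percentile
#' of the promoter counts of region-overlapping genes (the 10% tail cut).
#' Two exclusion rules then set genes to `NA` without ever turning a
#' negative positive: positive promoter windows that overlap another
#' positive window for the same mark are removed (both genes), and positive
#' genes lying entirely inside another positive gene are removed (only the
#' internal gene).
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`).
#' @param regions Enriched regions for the mark, from
#'   [call_enriched_regions()].
#' @param promoter_counts Tibble `gene_id`, `count` of tags in the promoter
#'   window (from [count_window()]).
#' @param mark Mark name recorded in the output.
#' @param half_width Promoter half-width in bp.
#' @param percentile Tail cut (default 0.10).
#' @param percentile_population Population over which the tail cut is
#'   computed: promoters overlapping an enriched region (default) or all
#'   promoters.
#' @param windows Optional window tibble replacing the default promoter
#'   windows (e.g. [tes_window()] output for post-TES S2p positivity); must
#'   be in `genes` order.
#' @return A tibble: `gene_id`, `mark`, `status`
#'   (`"positive"`/`"negative"`/`NA`), `promoter_count`,
#'   `passed_region_overlap`, `passed_percentile`.
#' @export
classify_promoters <- function(genes, regions, promoter_counts,
                               mark = "mark", half_width = 1000,
                               percentile = 0.10,
                               percentile_population = c("overlapping",
                                                         "all"),
                               windows = NULL) {
  percentile_population <- match.arg(percentile_population)
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(0), mark = character(0),
                  status = character(0), promoter_count = integer(0),
                  passed_region_overlap = logical(0),
                  passed_percentile = logical(0)))
  }
  win <- windows %||% suppressWarnings(promoter_window(genes, half_width))
  counts <- promoter_counts$count[match(genes$gene_id,
                                        promoter_counts$gene_id)]
  overlaps <- windows_overlap_regions(win, regions)
  pop <- if (percentile_population == "overlapping") {
    counts[overlaps]
  } else counts
  cut <- if (length(pop) > 0) nearest_rank_quantile(pop, percentile) else Inf
  passed_pct <- counts > cut
  positive <- overlaps & passed_pct
  status <- ifelse(positive, "positive", "negative")

  # exclusion 1: positive windows overlapping other positive windows
  if (sum(positive) > 1) {
    pw <- win[positive, ]
    ir <- IRanges::IRanges(start = pw$start + 1L, end = pw$end)
    hits <- IRanges::findOverlaps(ir, ir)
    clash <- unique(S4Vectors::queryHits(hits)[
      S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)])
    status[which(positive)[clash]] <- NA
  }
  # exclusion 2: positive genes contained in other positive genes
  pos_now <- !is.na(status) & status == "positive"
  if (sum(pos_now) > 1) {
    pg <- genes[pos_now, ]
    ir <- IRanges::IRanges(start = pg$start + 1L, end = pg$end)
    hits <- IRanges::findOverlaps(ir, ir, type = "within")
    internal <- unique(S4Vectors::queryHits(hits)[
      S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)])
    status[which(pos_now)[internal]] <- NA
  }
  tibble(gene_id = genes$gene_id, mark = mark, status = status,
         promoter_count = as.integer(counts),
         passed_region_overlap = overlaps,
         passed_percentile = passed_pct)
}

windows_overlap_regions <- function(windows, regions) {
  if (is.null(regions) || nrow(regions) == 0) {
    return(rep(FALSE, nrow(windows)))
  }
  out <- rep(FALSE, nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    ri <- which(regions$chrom == ch)
    if (length(ri) == 0) next
    qw <- IRanges::IRanges(start = windows$start[wi] + 1L,
                           end = windows$end[wi])
    sr <- IRanges::IRanges(start = regions$start[ri] + 1L,
                           end = regions$end[ri])
    out[wi] <- IRanges::overlapsAny(qw, sr)
  }
  out
}

#' Offset of the maximum polymerase peak from the TSS
#'
#' Finds, within the promoter span, the fine bin holding the maximum signal
#' of a total-polymerase track (8WG16) and returns the signed distance of
#' its center from the TSS in transcription orientation.  Ties are broken
#' toward the TSS.  Genes whose promoter span carries no signal get `NA`
#' and fail the TSS-anchored criterion.
#'
#' @param track A fine-resolution [bin_tags()] track (<= 10 bp bins).
#' @param genes Gene tibble.
#' @param half_width Promoter span searched on each side of the TSS.
#' @return A tibble `gene_id`, `offset` (bp; `NA` when no signal).
#' @export
max_peak_offset <- function(track, genes, half_width = 1000) {
  stopifnot(inherits(track, "binned_track"), track$bin_size <= 10)
  bs <- track$bin_size
  n_bins <- length(track$counts)
  offsets <- vapply(seq_len(nrow(genes)), function(i) {
    tss <- genes$tss[i]
    lo <- max(1L, (tss - half_width - track$offset) %/% bs + 1L)
    hi <- min(n_bins, (tss + half_width - track$offset) %/% bs + 1L)
    if (lo > hi) return(NA_real_)
    cnt <- track$counts[lo:hi]
    if (all(cnt == 0)) return(NA_real_)
    centers <- track$offset + (seq(lo, hi) - 1L) * bs + bs / 2
    off <- centers - tss
    cand <- which(cnt == max(cnt))
    pick <- cand[which.min(abs(off[cand]))]  # tie-break toward the TSS
    dir <- if (genes$strand[i] == "+") 1 else -1
    dir * off[pick]
  }, numeric(1))
  tibble(gene_id = genes$gene_id, offset = offsets)
}

#' Assign gene classes and analysis cohorts
#'
#' Combines per-mark promoter statuses with expression into the three gene
#' classes: *active* (positive for S5p, S7p and S2p, FPKM > 1, negative for
#' H3K27me3 and H2Aub1), *PRCr* (positive for H3K27me3, H2Aub1 and S5p,
#' negative for 8WG16 and post-TES S2p) and *inactive* (negative for all of
#' H3K27me3, H2Aub1, S5p, S2p, 8WG16).  Genes matching none of the
#' definitions, or with a missing required status, are `NA`.  Cohort flags:
#' `nonoverlapping_active` (active genes with non-overlapping promoter
#' windows), `tss_anchored_active` (additionally requiring the maximum
#' 8WG16 peak within `anchor_bp` of the TSS) and `top15`/`bottom15`
#' (extreme FPKM among polycomb-negative genes).
#'
#' @param status Long status tibble (rows from [classify_promoters()]) or a
#'   wide tibble of `gene_id` plus one status column per mark.  Required
#'   marks: S5p, S7p, S2p, 8WG16, H3K27me3, H2Aub1.
#' @param fpkm Tibble `gene_id`, `fpkm`.
#' @param nonoverlapping Optional logical vector or tibble
#'   (`gene_id`, `nonoverlapping`) flagging genes with non-overlapping
#'   promoter windows; defaults to all `TRUE`.
#' @param peak_offset Optional tibble from [max_peak_offset()].
#' @param top_frac Fraction defining the most/least active cohorts.
#' @param anchor_bp Maximum |8WG16 peak offset| for the anchored cohort.
#' @return A tibble: `gene_id`, `class`, cohort flags.
#' @export
assign_gene_classes <- function(status, fpkm, nonoverlapping = NULL,
                                peak_offset = NULL, top_frac = 0.15,
                                anchor_bp = 50) {
  required <- c("S5p", "S7p", "S2p", "8WG16", "H3K27me3", "H2Aub1")
  if (all(c("mark", "status") %in% names(status))) {
    status <- tidyr::pivot_wider(status, id_cols = "gene_id",
                                 names_from = "mark",
                                 values_from = "status")
  }
  missing_marks <- setdiff(required, names(status))
  if (length(missing_marks) > 0) {
    abort(paste0("missing mark status column(s): ",
                 paste(missing_marks, collapse = ", ")))
  }
  df <- left_join(status, fpkm, by = "gene_id")
  if (anyNA(df$fpkm)) warn("genes without FPKM are classified NA")

  pos <- function(m) !is.na(df[[m]]) & df[[m]] == "positive"
  neg <- function(m) !is.na(df[[m]]) & df[[m]] == "negative"
  active <- pos("S5p") & pos("S7p") & pos("S2p") &
    !is.na(df$fpkm) & df$fpkm > 1 & neg("H3K27me3") & neg("H2Aub1")
  prcr <- pos("H3K27me3") & pos("H2Aub1") & pos("S5p") &
    neg("8WG16") & neg("S2p")
  inactive <- neg("H3K27me3") & neg("H2Aub1") & neg("S5p") &
    neg("S2p") & neg("8WG16")
  class <- rep(NA_character_, nrow(df))
  class[inactive] <- "inactive"
  class[prcr] <- "PRCr"
  class[active] <- "active"

  if (is.null(nonoverlapping)) {
    nonov <- rep(TRUE, nrow(df))
  } else if (is.data.frame(nonoverlapping)) {
    nonov <- nonoverlapping$nonoverlapping[
      match(df$gene_id, nonoverlapping$gene_id)]
  } else nonov <- nonoverlapping
  nonov_active <- !is.na(class) & class == "active" & nonov %in% TRUE
  anchored <- if (is.null(peak_offset)) {
    nonov_active
  } else {
    off <- peak_offset$offset[match(df$gene_id, peak_offset$gene_id)]
    nonov_active & !is.na(off) & abs(off) <= anchor_bp
  }

  pc_neg <- neg("H3K27me3") & neg("H2Aub1") & !is.na(df$fpkm)
  top15 <- bottom15 <- rep(FALSE, nrow(df))
  m <- sum(pc_neg)
  if (m > 0) {
    k <- floor(top_frac * m)
    idx <- which(pc_neg)
    ord <- idx[order(-df$fpkm[idx])]
    if (k > 0) {
      top15[ord[seq_len(k)]] <- TRUE
      bottom15[rev(ord)[seq_len(k)]] <- TRUE
    }
  }
  tibble(gene_id = df$gene_id, class = class,
         nonoverlapping_active = nonov_active,
         tss_anchored_active = anchored,
         top15 = top15, bottom15 = bottom15)
}

#' Flag genes whose promoter windows overlap a neighbour's
#'
#' @param genes Gene tibble.
#' @param half_width Promoter half-width in bp.
#' @return Tibble `gene_id`, `nonoverlapping`.
#' @export
nonoverlapping_promoters <- function(genes, half_width = 1000) {
  win <- suppressWarnings(promoter_window(genes, half_width))
  cnt <- integer(nrow(win))
  for (ch in unique(win$chrom)) {
    wi <- which(win$chrom == ch)
    ir <- IRanges::IRanges(start = win$start[wi] + 1L, end = win$end[wi])
    cnt[wi] <- IRanges::countOverlaps(ir, ir)
  }
  tibble(gene_id = genes$gene_id, nonoverlapping = cnt == 1L)
}
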