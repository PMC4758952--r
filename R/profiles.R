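#' Metagene average profile around TSS or TES
#'
#' Computes the mean tag depth per fixed-width bin across a gene set, in a
#' window of `span` bp centered on the chosen anchor.  Depth is the count
#' of tag 5' positions per bin (no fragment extension).  Minus-strand genes
#' are reversed before averaging so all profiles read 5' to 3'.
#'
#' @param tags Tag tibble.
#' @param genes Gene tibble (non-empty).
#' @param anchor `"TSS"` or `"TES"`.
#' @param span Window span in bp (default 5000, i.e. +/- 2.5 kb).
#' @param bin_size Bin width in bp (default 10).
#' @return A tibble `offset` (bin center relative to the anchor, bp) and
#'   `depth` (mean tags per bin per gene).
#' @export
metagene_profile <- function(tags, genes, anchor = c("TSS", "TES"),
                             span = 5000, bin_size = 10) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0) abort("empty gene set")
  mat <- profile_matrix_raw(tags, genes, anchor,
                            upstream = span / 2, downstream = span / 2,
                            bin_size = bin_size)
  tibble(offset = as.numeric(colnames(mat)),
         depth = unname(colMeans(mat)))
}

# Gene x bin raw count matrix around an anchor, orientation-corrected.
# Column names are bin-center offsets in transcription orientation.
profile_matrix_raw <- function(tags, genes, anchor = "TSS",
                               upstream = 500, downstream = 500,
                               bin_size = 5) {
  n_bins <- as.integer(round((upstream + downstream) / bin_size))
  anchors <- if (anchor == "TSS") genes$tss else genes$tes
  dir <- ifelse(genes$strand == "+", 1L, -1L)
  mat <- matrix(0L, nrow = nrow(genes), ncol = n_bins,
                dimnames = list(genes$gene_id, NULL))
  for (ch in unique(genes$chrom)) {
    p <- sort(tags$pos[tags$chrom == ch])
    gi <- which(genes$chrom == ch)
    for (i in gi) {
      # bin edges in transcription orientation: offset -upstream..downstream
      edges <- anchors[i] + dir[i] * seq(-upstream, downstream, by = bin_size)
      if (dir[i] == 1L) {
        lo <- edges[-length(edges)]; hi <- edges[-1]
      } else {
        lo <- edges[-1] + 1L; hi <- edges[-length(edges)] + 1L
      }
      mat[i, ] <- findInterval(hi - 1L, p) - findInterval(lo - 1L, p)
    }
  }
  colnames(mat) <- seq(-upstream, downstream - bin_size,
                       by = bin_size) + bin_size / 2
  mat
}

#' Promoter heatmap matrix with per-gene z-scores
#'
#' Builds the gene-by-bin matrix of tag counts around the TSS (5 bp bins,
#' +/- 500 bp by default; the elongation mark S2p conventionally uses -500
#' to +1000 bp) and standardizes each row to mean 0 and sample standard
#' deviation 1; constant rows map to all zeros.  When `order_by` is given
#' (for example a K7me2/K7ac ratio), rows are sorted by it from highest to
#' lowest.
#'
#' @inheritParams metagene_profile
#' @param upstream,downstream Window extents in bp on each side of the TSS.
#' @param bin_size Bin width in bp (default 5).
#' @param zscore Standardize rows (default `TRUE`).
#' @param order_by Optional named numeric vector (names = gene ids) used to
#'   order rows from highest to lowest value.
#' @return A `profile_matrix` object: list with `values` (gene x bin
#'   matrix), `raw` (pre-standardization counts), `bin_size`, `upstream`,
#'   `downstream`, `anchor`.
#' @export
heatmap_matrix <- function(tags, genes, upstream = 500, downstream = 500,
                           bin_size = 5, zscore = TRUE, order_by = NULL) {
  raw <- profile_matrix_raw(tags, genes, "TSS", upstream, downstream,
                            bin_size)
  if (!is.null(order_by)) {
    ord <- order(-order_by[rownames(raw)])
    raw <- raw[ord, , drop = FALSE]
  }
  values <- raw
  if (zscore) values <- t(apply(raw, 1, row_zscore))
  dimnames(values) <- dimnames(raw)
  structure(list(values = values, raw = raw, bin_size = bin_size,
                 upstream = upstream, downstream = downstream,
                 anchor = "TSS"),
            class = "profile_matrix")
}

# Row z-score with sample (n-1) standard deviation; sd 0 -> all zeros.
row_zscore <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' @exportS3Method base::print
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d genes x %d bins (%d bp), %s -%d..+%d\n",
              nrow(x$values), ncol(x$values), x$bin_size, x$anchor,
              x$upstream, x$downstream))
  invisible(x)
}

#' Strand-separated nascent-transcription windows and RPKM
#'
#' For stranded (GRO-seq-like) tags, `groseq_windows()` returns sense and
#' antisense gene-by-bin count matrices for the window -500..+1000 bp
#' around the TSS at 10 bp resolution; sense means tags on the gene's
#' strand.  `groseq_rpkm()` computes per-gene RPKM from the sense tags
#' between TSS and TES: `count * 1e9 / (gene length * total mapped)`.
#'
#' @param tags Stranded tag tibble.
#' @param genes Gene tibble.
#' @param upstream,downstream Window extents around the TSS, bp.
#' @param bin_size Bin width in bp.
#' @return `groseq_windows()`: list with matrices `sense` and `antisense`.
#' @export
groseq_windows <- function(tags, genes, upstream = 500, downstream = 1000,
                           bin_size = 10) {
  sense_of <- function(g_strand) {
    same <- tags$strand == g_strand
    list(sense = tags[same, ], anti = tags[!same, ])
  }
  sense <- matrix(0L, nrow(genes),
                  as.integer((upstream + downstream) / bin_size),
                  dimnames = list(genes$gene_id, NULL))
  antisense <- sense
  for (st in c("+", "-")) {
    gi <- which(genes$strand == st)
    if (length(gi) == 0) next
    parts <- sense_of(st)
    sense[gi, ] <- profile_matrix_raw(parts$sense, genes[gi, ], "TSS",
                                      upstream, downstream, bin_size)
    antisense[gi, ] <- profile_matrix_raw(parts$anti, genes[gi, ], "TSS",
                                          upstream, downstream, bin_size)
  }
  list(sense = sense, antisense = antisense)
}

#' @rdname groseq_windows
#' @param total_mapped Library size; defaults to `nrow(tags)`.
#' @return `groseq_rpkm()`: tibble `gene_id`, `count`, `rpkm`.
#' @export
groseq_rpkm <- function(tags, genes, total_mapped = nrow(tags)) {
  len <- abs(genes$end - genes$start)
  if (any(len == 0)) abort("zero-length gene")
  counts <- integer(nrow(genes))
  for (st in c("+", "-")) {
    gi <- which(genes$strand == st)
    if (length(gi) == 0) next
    body <- tibble(gene_id = genes$gene_id[gi], chrom = genes$chrom[gi],
                   start = genes$start[gi], end = genes$end[gi])
    counts[gi] <- count_window(tags, body, stranded = st)$count
  }
  tibble(gene_id = genes$gene_id, count = counts,
         rpkm = counts * 1e9 / (len * total_mapped))
}

#' Log-transform FPKM with the standard pseudocount
#'
#' `log10(fpkm + 1e-4)`; an FPKM of zero maps to exactly -4.
#'
#' @param fpkm Non-negative FPKM value(s).
#' @return `log10(fpkm + 1e-4)`.
#' @export
fpkm_log <- function(fpkm) {
  if (any(fpkm < 0, na.rm = TRUE)) abort("FPKM must be non-negative")
  log10(fpkm + 1e-4)
}
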