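#' Bin tags into a fixed-width count track
#'
#' @param tags Tag tibble (one chromosome).
#' @param bin_size Bin width in bp (> 0).
#' @param span Total span in bp covered by the track (defaults to the
#'   smallest multiple of `bin_size` covering the largest tag position).
#' @param offset Genomic coordinate of the left edge of bin 1.
#' @return A `binned_track` object: counts per half-open bin
#'   `[offset + i*bin, offset + (i+1)*bin)`.
#' @examples
#' bin_tags(tibble::tibble(chrom = "c", pos = c(0L, 199L, 200L),
#'                         strand = "+"), bin_size = 200)
#' @export
bin_tags <- function(tags, bin_size = 200, span = NULL, offset = 0) {
  if (bin_size <= 0) abort("bin_size must be positive")
  chrom <- if (nrow(tags)) tags$chrom[1] else "chrS"
  if (is.null(span)) {
    span <- if (nrow(tags) == 0) bin_size else
      (max(tags$pos) - offset) %/% bin_size * bin_size + bin_size
  }
  n_bins <- as.integer(ceiling(span / bin_size))
  idx <- (tags$pos - offset) %/% bin_size + 1L
  idx <- idx[idx >= 1L & idx <= n_bins]
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 offset = as.integer(offset), counts = as.integer(counts)),
            class = "binned_track")
}

#' @exportS3Method base::print
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %s: %d bins of %d bp from %d (%d tags)\n",
              x$chrom, length(x$counts), x$bin_size, x$offset,
              sum(x$counts)))
  invisible(x)
}

#' Segment a binned track into constant-rate blocks
#'
#' Computes the exact maximum-a-posteriori partition of the bin sequence
#' under Poisson emissions with a conjugate Gamma(`alpha`, `beta`) rate
#' prior (integrated out per block) and a geometric prior on block lengths
#' with change probability `p_change` per bin.  The dynamic program is
#' O(n * max_block_bins); with the default cap this is exact for any
#' realistic enriched-domain size.
#'
#' @param track A [bin_tags()] track.
#' @param p_change Per-bin probability of starting a new block (default
#'   0.01, i.e. an expected block length of 100 bins).
#' @param alpha,beta Gamma prior on the per-bin Poisson rate.
#' @param max_block_bins Cap on the dynamic-programming lookback.
#' @return A tibble of blocks: `start_bin`/`end_bin` (1-based, inclusive
#'   bin indices), genomic `start`/`end`, `n_bins`, `total` tag count and
#'   `post_mean_rate` (posterior mean tags per bin), with the attained log
#'   posterior as attribute `log_posterior`.
#' @export
segment_track <- function(track, p_change = 0.01, alpha = 1, beta = 1,
                          max_block_bins = 2000L) {
  stopifnot(inherits(track, "binned_track"))
  if (length(track$counts) == 0) abort("track is empty")
  res <- segment_dp_cpp(track$counts, alpha, beta, p_change,
                        as.integer(max_block_bins))
  out <- tibble(
    start_bin = res$start_bin + 1L,
    end_bin = res$end_bin,
    start = track$offset + res$start_bin * track$bin_size,
    end = track$offset + res$end_bin * track$bin_size,
    n_bins = res$end_bin - res$start_bin,
    total = vapply(seq_along(res$start_bin), function(i) {
      sum(track$counts[(res$start_bin[i] + 1L):res$end_bin[i]])
    }, numeric(1)),
    post_mean_rate = res$post_mean_rate)
  attr(out, "log_posterior") <- res$log_posterior
  out
}

#' Call regions enriched over a control track
#'
#' Segments the treatment track and emits blocks whose posterior mean rate
#' is at least `fold_threshold` times the depth-scaled local control rate;
#' adjacent qualifying blocks are merged.  Control counts are scaled by the
#' ratio of treatment to control totals; the local control rate is smoothed
#' with the same Gamma prior used for segmentation so empty control
#' stretches cannot produce infinite ratios.  An empty control falls back
#' to the global treatment background rate, with a warning.
#'
#' @param treatment,control Deduplicated tag tibbles.
#' @param bin_size Bin width in bp.
#' @param fold_threshold Minimum treatment/control rate ratio (default 2).
#' @param span Genomic span to analyze (defaults to covering both tag sets).
#' @param ... Passed to [segment_track()].
#' @return A tibble of disjoint, sorted enriched regions: `chrom`, `start`,
#'   `end`, `rate_ratio` (depth-weighted mean over merged blocks).
#' @export
call_enriched_regions <- function(treatment, control, bin_size = 200,
                                  fold_threshold = 2, span = NULL, ...) {
  if (is.null(span)) {
    mx <- max(c(treatment$pos, control$pos, 0))
    span <- (mx %/% bin_size + 1) * bin_size
  }
  tt <- bin_tags(treatment, bin_size, span = span)
  blocks <- segment_track(tt, ...)
  n_treat <- nrow(treatment)
  n_ctrl <- nrow(control)
  if (n_ctrl == 0) {
    warn("empty control: falling back to global treatment background rate")
    ctrl_rate <- rep(mean(tt$counts), nrow(blocks))
  } else {
    ct <- bin_tags(control, bin_size, span = span)
    sf <- n_treat / n_ctrl
    ctrl_rate <- vapply(seq_len(nrow(blocks)), function(i) {
      cnt <- sum(ct$counts[blocks$start_bin[i]:blocks$end_bin[i]])
      (cnt * sf + 1) / (blocks$n_bins[i] + 1)  # Gamma(1,1)-smoothed
    }, numeric(1))
  }
  ratio <- blocks$post_mean_rate / ctrl_rate
  keep <- ratio >= fold_threshold
  regions <- tibble(chrom = tt$chrom,
                    start = blocks$start[keep], end = blocks$end[keep],
                    rate_ratio = ratio[keep],
                    weight = blocks$n_bins[keep])
  merge_adjacent_regions(regions)
}

# Merge touching/overlapping regions; rate ratio becomes the
# length-weighted mean.  Idempotent.
merge_adjacent_regions <- function(regions) {
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(0), start = integer(0),
                  end = integer(0), rate_ratio = double(0)))
  }
  regions <- arrange(regions, .data$chrom, .data$start)
  if (!"weight" %in% names(regions)) {
    regions$weight <- regions$end - regions$start
  }
  grp <- cumsum(c(TRUE, regions$start[-1] > regions$end[-nrow(regions)] |
                    regions$chrom[-1] != regions$chrom[-nrow(regions)]))
  regions %>%
    mutate(grp = grp) %>%
    group_by(.data$grp) %>%
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end),
              rate_ratio = sum(.data$rate_ratio * .data$weight) /
                sum(.data$weight), .groups = "drop") %>%
    select("chrom", "start", "end", "rate_ratio")
}
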