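#' Configuration for the synthetic CTD-ChIP world
#'
#' Builds the fully-specified configuration object consumed by
#' [generate_genes()], [generate_tags()] and [generate_expression()].  The
#' generator plants a one-factor structural model on standardized log tag
#' masses: initiation-associated marks (S5p, S7p, 8WG16, K7ac and a latent
#' methylation factor read out by K7me1/K7me2) co-vary through a shared
#' per-gene activity factor, and the elongation mark S2p (measured in the 2 kb
#' window after the TES) is a linear function of S7p, K7ac, S5p and the
#' methylation factor with a *negative* methylation coefficient.  mRNA output
#' is coupled to S2p.  All downstream analyses (classification, ratio
#' tertiles, partial correlations, subset regression, LASSO) are expected to
#' recover this planted structure.
#'
#' Identical configurations produce byte-identical outputs: every random draw
#' is governed by `seed`.
#'
#' @param n_active,n_prcr,n_inactive Number of genes per planted class.
#'   Active genes carry the full structural model; polycomb-repressed (PRCr)
#'   genes carry S5p and the two repressive histone marks but no S7p, S2p or
#'   8WG16 signal; inactive genes carry background only and have FPKM 0.
#' @param gene_length_range Length range (bp) from which gene lengths are
#'   drawn uniformly.
#' @param intergenic_gap_range Range (bp) of gaps between consecutive genes;
#'   the lower bound must keep 2 kb promoter windows of neighbours disjoint.
#' @param chrom_length Chromosome length in bp, or `NULL` to size the
#'   chromosome to fit all genes plus 10 kb flanks.  An explicit value too
#'   small to place the requested genes is an error.
#' @param seed Integer seed controlling every draw.
#' @param sem_coefficients Named numeric vector with elements `a` (S7p to
#'   S2p), `b` (K7ac to S2p), `c` (S5p to S2p) and `d` (methylation to S2p).
#'   `a`, `b`, `c` must be positive and `d` negative.
#' @param noise_sd Residual standard deviation of the S2p equation.
#' @param activity_loading Loading of each promoter mark's standardized log
#'   mass on the shared activity factor (0 < loading < 1).
#' @param me_loadings Length-2 numeric: loadings of K7me1 and K7me2 on the
#'   latent methylation factor.  K7me1 is given the slightly larger loading
#'   so the two readouts are highly correlated but not exchangeable.
#' @param mass_log_sd Standard deviation applied to standardized log masses
#'   when they are exponentiated into expected tag weights.
#' @param depth_per_mark Expected total number of tags per simulated dataset.
#' @param background_rate Uniform background rate in tags per bp added to
#'   every mark (the mock dataset is background only).
#' @param profile_params Named list of spatial kernels, one per mark; see
#'   [default_profile_params()].  Unknown mark names are an error at tag
#'   generation time.
#'
#' @return A list of class `ctd_synth_config`.
#' @examples
#' cfg <- synthetic_config(n_active = 50, n_prcr = 10, n_inactive = 20, seed = 1)
#' genes <- generate_genes(cfg)
#' @export
synthetic_config <- function(n_active = 500,
                             n_prcr = 100,
                             n_inactive = 200,
                             gene_length_range = c(2000, 8000),
                             intergenic_gap_range = c(3000, 8000),
                             chrom_length = NULL,
                             seed = 1L,
                             sem_coefficients = c(a = 0.45, b = 0.35,
                                                  c = 0.12, d = -0.38),
                             noise_sd = 0.48,
                             activity_loading = 0.85,
                             me_loadings = c(K7me1 = 0.97, K7me2 = 0.93),
                             mass_log_sd = 0.5,
                             depth_per_mark = 2e5,
                             background_rate = 2e-3,
                             profile_params = default_profile_params()) {
  counts <- c(n_active = n_active, n_prcr = n_prcr, n_inactive = n_inactive)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("gene class counts must be non-negative integers")
  }
  if (length(gene_length_range) != 2 || diff(gene_length_range) < 0 ||
      gene_length_range[1] <= 0) {
    abort("gene_length_range must be an increasing positive pair")
  }
  if (intergenic_gap_range[1] < 2000) {
    abort("intergenic gaps below 2000 bp would overlap promoter windows")
  }
  stopifnot(is.numeric(seed), length(seed) == 1)
  req <- c("a", "b", "c", "d")
  if (!all(req %in% names(sem_coefficients))) {
    abort("sem_coefficients must name a, b, c and d")
  }
  if (sem_coefficients[["d"]] >= 0) {
    abort("the methylation path d must be negative")
  }
  if (any(sem_coefficients[c("a", "b", "c")] <= 0)) {
    abort("paths a, b and c must be positive")
  }
  stopifnot(noise_sd > 0, activity_loading > 0, activity_loading < 1,
            mass_log_sd > 0, depth_per_mark >= 0, background_rate >= 0)
  cfg <- structure(
    list(n_active = as.integer(n_active),
         n_prcr = as.integer(n_prcr),
         n_inactive = as.integer(n_inactive),
         gene_length_range = gene_length_range,
         intergenic_gap_range = intergenic_gap_range,
         chrom_length = chrom_length,
         seed = as.integer(seed),
         sem_coefficients = sem_coefficients,
         noise_sd = noise_sd,
         activity_loading = activity_loading,
         me_loadings = me_loadings,
         mass_log_sd = mass_log_sd,
         depth_per_mark = depth_per_mark,
         background_rate = background_rate,
         profile_params = profile_params),
    class = "ctd_synth_config")
  cfg
}

#' Default spatial kernels for each simulated mark
#'
#' Offsets are in transcription orientation relative to the TSS unless the
#' shape anchors elsewhere.  K7me1/K7me2 are sharp TSS kernels; K7ac extends
#' downstream of the TSS (up to roughly +500 bp); 8WG16 is bimodal with a
#' secondary peak 140 bp downstream of the main TSS peak; S5p and S7p are
#' intermediate TSS kernels; S2p is a gene-body component plus a dominant
#' post-TES component so that most of its mass falls in the 2 kb window after
#' the TES; the repressive histone marks are broad; mock is uniform
#' background only.
#'
#' @return Named list of kernel specifications.
#' @export
default_profile_params <- function() {
  list(
    K7me1    = list(shape = "gaussian", center = 0, spread = 80),
    K7me2    = list(shape = "gaussian", center = 0, spread = 80),
    K7ac     = list(shape = "gaussian", center = 250, spread = 250),
    `8WG16`  = list(shape = "bimodal", centers = c(0, 140), spread = 60,
                    weights = c(0.65, 0.35)),
    S5p      = list(shape = "gaussian", center = 0, spread = 150),
    S7p      = list(shape = "gaussian", center = 0, spread = 150),
    S2p      = list(shape = "body_tes", body_weight = 0.3,
                    tes_center = 500, tes_spread = 400),
    mock     = list(shape = "uniform"),
    H3K27me3 = list(shape = "gaussian", center = 0, spread = 800),
    H2Aub1   = list(shape = "gaussian", center = 0, spread = 800)
  )
}

#' @exportS3Method base::print
print.ctd_synth_config <- function(x, ...) {
  cat("<ctd_synth_config>\n")
  cat(sprintf("  genes: %d active, %d PRCr, %d inactive\n",
              x$n_active, x$n_prcr, x$n_inactive))
  co <- x$sem_coefficients
  cat(sprintf("  SEM: S2p = %.2f S7p + %.2f K7ac + %.2f S5p %+.2f K7me + noise(%.2f)\n",
              co[["a"]], co[["b"]], co[["c"]], co[["d"]], x$noise_sd))
  cat(sprintf("  depth/mark: %g tags, background %g tags/bp, seed %d\n",
              x$depth_per_mark, x$background_rate, x$seed))
  invisible(x)
}

# Serialize a config as a flat key=value file (one scalar per line).
#' Write a configuration as a flat key=value file
#' @param config A [synthetic_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- c(
    n_active = config$n_active, n_prcr = config$n_prcr,
    n_inactive = config$n_inactive,
    gene_length_min = config$gene_length_range[1],
    gene_length_max = config$gene_length_range[2],
    gap_min = config$intergenic_gap_range[1],
    gap_max = config$intergenic_gap_range[2],
    chrom_length = if (is.null(config$chrom_length)) NA else config$chrom_length,
    seed = config$seed,
    sem_a = config$sem_coefficients[["a"]],
    sem_b = config$sem_coefficients[["b"]],
    sem_c = config$sem_coefficients[["c"]],
    sem_d = config$sem_coefficients[["d"]],
    noise_sd = config$noise_sd,
    activity_loading = config$activity_loading,
    me_loading_K7me1 = config$me_loadings[["K7me1"]],
    me_loading_K7me2 = config$me_loadings[["K7me2"]],
    mass_log_sd = config$mass_log_sd,
    depth_per_mark = config$depth_per_mark,
    background_rate = config$background_rate)
  writeLines(paste0(names(flat), "=", vapply(flat, format, character(1))), path)
  invisible(path)
}
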