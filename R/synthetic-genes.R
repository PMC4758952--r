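#' Generate a toy gene annotation with planted classes
#'
#' Places `n_active + n_prcr + n_inactive` genes on a single chromosome
#' (`chrS`) in randomized class order, with intergenic gaps large enough that
#' 2 kb promoter windows of neighbouring genes never overlap.  Coordinates
#' are 0-based half-open; the TSS is `start` on the plus strand and
#' `end - 1` on the minus strand, and the TES is the opposite gene boundary.
#' Each active gene receives a latent activity score (standard normal) that
#' seeds the co-variation of all promoter marks; inactive genes have FPKM 0
#' by construction (FPKM itself is drawn by [generate_expression()]).
#'
#' @param config A [synthetic_config()] object.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`, `tes`, `true_class`, `activity`, `cpg`, plus a
#'   `chrom_length` attribute.
#' @examples
#' genes <- generate_genes(synthetic_config(n_active = 20, n_prcr = 5,
#'                                          n_inactive = 5, seed = 3))
#' table(genes$true_class)
#' @export
generate_genes <- function(config) {
  stopifnot(inherits(config, "ctd_synth_config"))
  n_total <- config$n_active + config$n_prcr + config$n_inactive
  if (n_total == 0) {
    out <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  tss = integer(), tes = integer(), true_class = character(),
                  activity = double(), cpg = double())
    attr(out, "chrom_length") <- config$chrom_length %||% 10000L
    return(out)
  }
  withr::with_seed(config$seed, {
    classes <- sample(rep(c("active", "PRCr", "inactive"),
                          times = c(config$n_active, config$n_prcr,
                                    config$n_inactive)))
    lens <- round(runif(n_total, config$gene_length_range[1],
                        config$gene_length_range[2]))
    gaps <- round(runif(n_total, config$intergenic_gap_range[1],
                        config$intergenic_gap_range[2]))
    starts <- 10000 + cumsum(c(0, (lens + gaps)[-n_total]))
    ends <- starts + lens
    needed <- ends[n_total] + 10000
    chrom_length <- config$chrom_length %||% needed
    if (chrom_length < needed) {
      abort(sprintf(
        "chrom_length %d cannot place %d genes (needs >= %d bp)",
        chrom_length, n_total, needed))
    }
    strand <- sample(c("+", "-"), n_total, replace = TRUE)
    activity <- ifelse(classes == "active", rnorm(n_total), 0)
    cpg <- exp(0.25 * activity + 0.3 * rnorm(n_total))
    out <- tibble(
      gene_id = sprintf("gene%04d", seq_len(n_total)),
      chrom = "chrS",
      start = as.integer(starts),
      end = as.integer(ends),
      strand = strand,
      tss = as.integer(ifelse(strand == "+", starts, ends - 1)),
      tes = as.integer(ifelse(strand == "+", ends, starts)),
      true_class = classes,
      activity = activity,
      cpg = cpg)
    attr(out, "chrom_length") <- as.integer(chrom_length)
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Latent standardized log masses for every gene x mark, a pure function of
# (genes, config): both generate_tags() and generate_expression() call this
# and obtain identical draws because the stream is re-seeded from the config.
#
# Active genes: one-factor model on the activity score for S5p, S7p, 8WG16,
# K7ac and the methylation factor M; K7me1/K7me2 are noisy readouts of M;
# S2p is the structural equation a*S7p + b*K7ac + c*S5p + d*M + noise.
# PRCr genes carry only S5p (poised polymerase) and the histone marks.
latent_masses <- function(genes, config) {
  n <- nrow(genes)
  marks <- c("S5p", "S7p", "8WG16", "K7ac", "K7me1", "K7me2", "S2p",
             "H3K27me3", "H2Aub1")
  z <- matrix(0, nrow = n, ncol = length(marks),
              dimnames = list(genes$gene_id, marks))
  m_factor <- numeric(n)
  if (n == 0) {
    return(list(z = tibble(gene_id = character()), me_factor = numeric(0)))
  }
  withr::with_seed(config$seed + 1L, {
    lam <- config$activity_loading
    res <- sqrt(1 - lam^2)
    act <- genes$true_class == "active"
    u <- genes$activity
    draw <- function() lam * u + res * rnorm(n)
    s5 <- draw(); s7 <- draw(); w8 <- draw(); ac <- draw(); m <- draw()
    l1 <- config$me_loadings[["K7me1"]]
    l2 <- config$me_loadings[["K7me2"]]
    me1 <- l1 * m + sqrt(1 - l1^2) * rnorm(n)
    me2 <- l2 * m + sqrt(1 - l2^2) * rnorm(n)
    co <- config$sem_coefficients
    s2 <- co[["a"]] * s7 + co[["b"]] * ac + co[["c"]] * s5 +
      co[["d"]] * m + config$noise_sd * rnorm(n)
    z[act, "S5p"] <- s5[act]
    z[act, "S7p"] <- s7[act]
    z[act, "8WG16"] <- w8[act]
    z[act, "K7ac"] <- ac[act]
    z[act, "K7me1"] <- me1[act]
    z[act, "K7me2"] <- me2[act]
    z[act, "S2p"] <- s2[act]
    m_factor[act] <- m[act]
    prc <- genes$true_class == "PRCr"
    if (any(prc)) {
      z[prc, "S5p"] <- rnorm(sum(prc), mean = -0.3)
      z[prc, "H3K27me3"] <- rnorm(sum(prc), mean = 0.2)
      z[prc, "H2Aub1"] <- rnorm(sum(prc), mean = 0.2)
    }
  })
  zt <- as_tibble(z)
  zt$gene_id <- genes$gene_id
  list(z = zt[, c("gene_id", marks)], me_factor = m_factor)
}

#' Latent standardized log masses of the synthetic world
#'
#' Exposes the per-gene latent variables that [generate_tags()] converts into
#' tag counts: standardized log masses for each mark plus the latent
#' methylation factor the structural equation acts on.  Useful for verifying
#' the planted correlation structure without sampling noise.
#'
#' @inheritParams generate_tags
#' @return A tibble of per-gene latent variables (column `me_factor` holds
#'   the methylation factor).
#' @export
latent_mark_masses <- function(genes, config) {
  lat <- latent_masses(genes, config)
  out <- lat$z
  out$me_factor <- lat$me_factor
  out$true_class <- genes$true_class
  out
}
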