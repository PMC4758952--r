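#' Generate ChIP tag sets for every simulated mark
#'
#' Converts the latent per-gene log masses of the planted structural model
#' into sequencing-like tag positions.  Per mark, a Poisson-distributed
#' number of signal tags (expectation `depth_per_mark` minus the expected
#' uniform background) is allocated to carrier genes with probability
#' proportional to `exp(mass_log_sd * z)`, and each tag's genomic position is
#' drawn from the mark's spatial kernel, oriented by gene strand.  A uniform
#' background (`background_rate` tags per bp) is added to every mark; the
#' mock dataset is uniform background only, at full depth.  Carriers are:
#' active genes for all CTD marks, active plus PRCr genes for S5p, and PRCr
#' genes for the repressive histone marks.
#'
#' @param genes Gene tibble from [generate_genes()].
#' @param config The same [synthetic_config()] used to generate `genes`.
#' @return Named list of tag tibbles (`chrom`, `pos`, `strand`), one per
#'   mark, with attributes `draws` (per-mark signal/background totals, the
#'   run log of the Poisson draws) and `chrom_length`.
#' @examples
#' cfg <- synthetic_config(n_active = 30, n_prcr = 5, n_inactive = 5,
#'                         depth_per_mark = 5000, seed = 2)
#' tags <- generate_tags(generate_genes(cfg), cfg)
#' vapply(tags, nrow, integer(1))
#' @export
generate_tags <- function(genes, config) {
  stopifnot(inherits(config, "ctd_synth_config"))
  marks <- c(CTD_MARKS, HISTONE_MARKS)
  unknown <- setdiff(marks, names(config$profile_params))
  if (length(unknown) > 0) {
    abort(paste0("no profile kernel for mark(s): ",
                 paste(unknown, collapse = ", ")))
  }
  chrom_length <- attr(genes, "chrom_length") %||% config$chrom_length %||% 10000L
  lat <- latent_masses(genes, config)
  z <- lat$z
  carriers <- list(
    K7me1 = "active", K7me2 = "active", K7ac = "active", `8WG16` = "active",
    S7p = "active", S2p = "active", S5p = c("active", "PRCr"),
    mock = character(0), H3K27me3 = "PRCr", H2Aub1 = "PRCr")
  out <- withr::with_seed(config$seed + 2L, {
    sets <- list()
    draws <- list()
    exp_bg <- config$background_rate * chrom_length
    for (mk in marks) {
      is_carrier <- genes$true_class %in% carriers[[mk]]
      if (mk == "mock") {
        n_sig <- 0L
        n_bg <- rpois(1, config$depth_per_mark)
      } else {
        n_sig <- rpois(1, max(config$depth_per_mark - exp_bg, 0))
        n_bg <- rpois(1, exp_bg)
      }
      pos_sig <- integer(0)
      if (n_sig > 0 && any(is_carrier)) {
        w <- ifelse(is_carrier, exp(config$mass_log_sd * z[[mk]]), 0)
        alloc <- as.integer(rmultinom(1, n_sig, w))
        gi <- rep(which(alloc > 0), alloc[alloc > 0])
        pos_sig <- sample_kernel_positions(
          config$profile_params[[mk]], genes[gi, ], chrom_length)
      } else {
        n_sig <- 0L
      }
      pos_bg <- if (n_bg > 0) {
        as.integer(floor(runif(n_bg, 0, chrom_length)))
      } else integer(0)
      pos <- c(pos_sig, pos_bg)
      sets[[mk]] <- tibble(
        chrom = rep("chrS", length(pos)),
        pos = pos,
        strand = if (length(pos)) sample(c("+", "-"), length(pos),
                                         replace = TRUE) else character(0))
      draws[[mk]] <- tibble(mark = mk, n_signal = length(pos_sig),
                            n_background = n_bg)
    }
    attr(sets, "draws") <- bind_rows(draws)
    sets
  })
  attr(out, "chrom_length") <- chrom_length
  attr(out, "latents") <- latent_mark_masses(genes, config)
  out
}

# Draw one genomic position per row of `genes` from a kernel specification.
# Offsets are in transcription orientation: multiplied by -1 on minus-strand
# genes before being added to the anchor.
sample_kernel_positions <- function(kernel, genes, chrom_length) {
  n <- nrow(genes)
  dir <- ifelse(genes$strand == "+", 1, -1)
  pos <- switch(
    kernel$shape,
    gaussian = genes$tss + dir * round(rnorm(n, kernel$center, kernel$spread)),
    bimodal = {
      comp <- sample(seq_along(kernel$centers), n, replace = TRUE,
                     prob = kernel$weights)
      genes$tss + dir * round(rnorm(n, kernel$centers[comp], kernel$spread))
    },
    body_tes = {
      in_body <- runif(n) < kernel$body_weight
      p <- genes$tes + dir * round(rnorm(n, kernel$tes_center,
                                         kernel$tes_spread))
      p[in_body] <- floor(runif(sum(in_body), genes$start[in_body],
                                genes$end[in_body]))
      p
    },
    uniform = floor(runif(n, 0, chrom_length)),
    abort(sprintf("unknown kernel shape '%s'", kernel$shape)))
  as.integer(pmin(pmax(pos, 0), chrom_length - 1))
}

#' Generate expression and perturbation-response tables
#'
#' Draws (i) per-gene FPKM coupled to the latent S2p elongation mass with
#' log-normal noise (inactive genes have FPKM exactly 0; PRCr genes have
#' negligible expression), (ii) a stranded GRO-seq-like tag set with sense
#' tags along gene bodies and a small antisense component just upstream of
#' the TSS, and (iii) a fold-change table emulating a histone-deacetylase-
#' inhibitor (TSA) microarray response in which genes with high planted
#' K7me2/K7ac ratios tend to be up-regulated.
#'
#' @inheritParams generate_tags
#' @return A list with elements `fpkm` (tibble `gene_id`, `fpkm`), `groseq`
#'   (stranded tag tibble) and `tsa` (tibble `gene_id`, `fold_change`,
#'   active genes only; fold change on the treated/control scale).
#' @export
generate_expression <- function(genes, config) {
  stopifnot(inherits(config, "ctd_synth_config"))
  chrom_length <- attr(genes, "chrom_length") %||% config$chrom_length %||% 10000L
  lat <- latent_masses(genes, config)
  z <- lat$z
  n <- nrow(genes)
  withr::with_seed(config$seed + 3L, {
    act <- genes$true_class == "active"
    fpkm <- numeric(n)
    mrna_z <- numeric(n)
    if (any(act)) {
      s2 <- z$S2p[act]
      s2 <- if (sd(s2) > 0) (s2 - mean(s2)) / sd(s2) else s2 * 0
      mz <- 0.8 * s2 + 0.6 * rnorm(sum(act))
      mrna_z[act] <- mz
      fpkm[act] <- exp(3 + 1.2 * mz)
    }
    prc <- genes$true_class == "PRCr"
    fpkm[prc] <- exp(-3 + 0.8 * rnorm(sum(prc)))
    fpkm_tbl <- tibble(gene_id = genes$gene_id, fpkm = fpkm)

    # GRO-seq: sense tags across gene bodies weighted by expression, plus a
    # 10% antisense component near the promoter.
    n_total <- rpois(1, config$depth_per_mark)
    w <- fpkm
    groseq <- tibble(chrom = character(0), pos = integer(0),
                     strand = character(0))
    if (n_total > 0 && sum(w) > 0) {
      n_anti <- rbinom(1, n_total, 0.1)
      n_sense <- n_total - n_anti
      alloc <- as.integer(rmultinom(1, n_sense, w))
      gi <- rep(seq_len(n), alloc)
      sense <- tibble(
        chrom = rep("chrS", length(gi)),
        pos = as.integer(floor(runif(length(gi), genes$start[gi],
                                     genes$end[gi]))),
        strand = genes$strand[gi])
      alloc_a <- as.integer(rmultinom(1, n_anti, w))
      ga <- rep(seq_len(n), alloc_a)
      dir <- ifelse(genes$strand[ga] == "+", 1, -1)
      anti <- tibble(
        chrom = rep("chrS", length(ga)),
        pos = as.integer(pmin(pmax(
          genes$tss[ga] - dir * abs(round(rnorm(length(ga), 150, 150))),
          0), chrom_length - 1)),
        strand = ifelse(genes$strand[ga] == "+", "-", "+"))
      groseq <- bind_rows(sense, anti)
    }

    # TSA response: fold change increases with the planted log K7me2/K7ac
    # ratio so the high-ratio tertile is enriched for >= 2-fold up-regulation.
    tsa <- tibble(gene_id = character(0), fold_change = double(0))
    if (any(act)) {
      lr <- z$K7me2[act] - z$K7ac[act]
      lr <- if (sd(lr) > 0) (lr - mean(lr)) / sd(lr) else lr * 0
      tsa <- tibble(
        gene_id = genes$gene_id[act],
        fold_change = 2^(0.9 * lr + rnorm(sum(act))))
    }
    list(fpkm = fpkm_tbl, groseq = groseq, tsa = tsa)
  })
}
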