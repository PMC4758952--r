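#' Run the full synthetic-to-association pipeline
#'
#' Orchestrates simulate, deduplicate, call peaks, classify, quantify,
#' ratio and associate as one seeded, logged run with plain-file handoff
#' (BED and TSV) between stages.  Given the same configuration the run is
#' byte-identical; a subset of `stages` can be re-run against the cached
#' files of an earlier run in the same `outdir`.
#'
#' @param config A [synthetic_config()] object.
#' @param outdir Output directory (created if needed).
#' @param stages Stages to execute, in order.  Later stages read their
#'   inputs from `outdir` when the producing stage is not part of this run.
#' @param bin_size Peak-calling bin size in bp.
#' @param fold_threshold Enrichment fold threshold.
#' @return Invisibly, a list with the in-memory results of the executed
#'   stages (`genes`, `tags`, `regions`, `status`, `classes`, `mark_table`,
#'   `ratios`, `assoc`).
#' @export
run_ctd_pipeline <- function(config = synthetic_config(),
                             outdir,
                             stages = c("simulate", "dedup", "peaks",
                                        "classify", "quantify", "ratio",
                                        "assoc"),
                             bin_size = 200, fold_threshold = 2) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("simulate", "dedup", "peaks", "classify", "quantify",
                  "ratio", "assoc")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  state <- new.env(parent = emptyenv())
  log_path <- file.path(outdir, "run_log.txt")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  if ("simulate" %in% stages) cat("", file = log_path)  # fresh log
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    log_line("stage %s: start (seed %d)", name, config$seed)
    tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    log_line("stage %s: done", name)
  }
  marks <- c(CTD_MARKS, HISTONE_MARKS)

  get_genes <- function() {
    if (is.null(state$genes)) {
      path <- file.path(outdir, "genes.tsv")
      g <- readr::read_tsv(path, show_col_types = FALSE)
      attr(g, "chrom_length") <- attr(g, "chrom_length") %||%
        max(g$end) + 10000L
      state$genes <- g
    }
    state$genes
  }
  get_tags <- function(dedup = TRUE) {
    slot <- if (dedup) "tags_dedup" else "tags"
    if (is.null(state[[slot]])) {
      sub <- if (dedup) "tags_dedup" else "tags"
      state[[slot]] <- setNames(lapply(marks, function(mk) {
        read_tag_bed(file.path(outdir, sub, paste0(mk, ".bed")))
      }), marks)
    }
    state[[slot]]
  }
  get_expr <- function() {
    if (is.null(state$fpkm)) {
      state$fpkm <- readr::read_tsv(file.path(outdir, "fpkm.tsv"),
                                    show_col_types = FALSE)
      state$tsa <- readr::read_tsv(file.path(outdir, "tsa_foldchange.tsv"),
                                   show_col_types = FALSE)
    }
    list(fpkm = state$fpkm, tsa = state$tsa)
  }
  get_regions <- function() {
    if (is.null(state$regions)) {
      state$regions <- setNames(lapply(marks[marks != "mock"], function(mk) {
        path <- file.path(outdir, "regions", paste0(mk, ".bed"))
        df <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                                  "name", "rate_ratio"),
                              show_col_types = FALSE)
        select(df, "chrom", "start", "end", "rate_ratio")
      }), marks[marks != "mock"])
    }
    state$regions
  }

  run_stage("simulate", function() {
    genes <- generate_genes(config)
    tags <- generate_tags(genes, config)
    expr <- generate_expression(genes, config)
    state$genes <- genes
    state$tags <- tags
    state$fpkm <- expr$fpkm
    state$tsa <- expr$tsa
    write_config(config, file.path(outdir, "config.txt"))
    readr::write_tsv(genes, file.path(outdir, "genes.tsv"))
    write_genes_bed(genes, file.path(outdir, "genes.bed"))
    dir.create(file.path(outdir, "tags"), showWarnings = FALSE)
    for (mk in names(tags)) {
      write_tag_bed(tags[[mk]], file.path(outdir, "tags",
                                          paste0(mk, ".bed")))
    }
    write_tag_bed(expr$groseq, file.path(outdir, "tags", "groseq.bed"))
    readr::write_tsv(expr$fpkm, file.path(outdir, "fpkm.tsv"))
    readr::write_tsv(expr$tsa, file.path(outdir, "tsa_foldchange.tsv"))
    draws <- attr(tags, "draws")
    readr::write_tsv(draws, file.path(outdir, "tag_draws.tsv"))
    log_line("simulate: %d genes, %d tag sets", nrow(genes), length(tags))
  })

  run_stage("dedup", function() {
    tags <- if (!is.null(state$tags)) state$tags else get_tags(dedup = FALSE)
    dir.create(file.path(outdir, "tags_dedup"), showWarnings = FALSE)
    dd <- list()
    thresholds <- list()
    for (mk in marks) {
      d <- deduplicate_tags(tags[[mk]])
      dd[[mk]] <- d
      thresholds[[mk]] <- tibble(mark = mk,
                                 threshold = dedup_threshold(d),
                                 total_before = nrow(tags[[mk]]),
                                 total_after = nrow(d))
      write_tag_bed(d, file.path(outdir, "tags_dedup", paste0(mk, ".bed")))
    }
    state$tags_dedup <- dd
    readr::write_tsv(bind_rows(thresholds),
                     file.path(outdir, "dedup_thresholds.tsv"))
  })

  run_stage("peaks", function() {
    tags <- get_tags()
    dir.create(file.path(outdir, "regions"), showWarnings = FALSE)
    regions <- list()
    for (mk in marks[marks != "mock"]) {
      regions[[mk]] <- call_enriched_regions(
        tags[[mk]], tags[["mock"]], bin_size = bin_size,
        fold_threshold = fold_threshold)
      write_regions_bed(regions[[mk]],
                        file.path(outdir, "regions", paste0(mk, ".bed")))
      log_line("peaks %s: %d regions", mk, nrow(regions[[mk]]))
    }
    state$regions <- regions
  })

  run_stage("classify", function() {
    genes <- get_genes()
    tags <- get_tags()
    regions <- get_regions()
    pw <- suppressWarnings(promoter_window(genes))
    tw <- suppressWarnings(tes_window(genes))
    status <- purrr::map_dfr(names(regions), function(mk) {
      win <- if (mk == "S2p") tw else pw
      counts <- count_window(tags[[mk]], win) %>%
        select("gene_id", "count")
      classify_promoters(genes, regions[[mk]], counts, mark = mk,
                         windows = win)
    })
    readr::write_tsv(status, file.path(outdir, "promoter_status.tsv"))
    fine <- bin_tags(tags[["8WG16"]], bin_size = 10,
                     span = attr(genes, "chrom_length") %||%
                       (max(genes$end) + 10000))
    offsets <- max_peak_offset(fine, genes)
    nonov <- nonoverlapping_promoters(genes)
    classes <- assign_gene_classes(status, get_expr()$fpkm,
                                   nonoverlapping = nonov,
                                   peak_offset = offsets)
    readr::write_tsv(classes, file.path(outdir, "gene_classes.tsv"))
    state$status <- status
    state$classes <- classes
    log_line("classify: %s",
             paste(capture_class_counts(classes), collapse = ", "))
  })

  run_stage("quantify", function() {
    genes <- get_genes()
    tags <- get_tags()
    mt <- build_mark_table(tags, genes, get_expr()$fpkm)
    readr::write_tsv(mt, file.path(outdir, "mark_table.tsv"))
    state$mark_table <- mt
  })

  run_stage("ratio", function() {
    genes <- get_genes()
    tags <- get_tags()
    if (is.null(state$classes)) {
      state$classes <- readr::read_tsv(file.path(outdir, "gene_classes.tsv"),
                                       show_col_types = FALSE)
    }
    pw <- suppressWarnings(promoter_window(genes))
    me <- count_window(tags[["K7me2"]], pw)$count
    ac <- count_window(tags[["K7ac"]], pw)$count
    ratios <- tibble(
      gene_id = genes$gene_id,
      ratio = k7_ratio(me, ac, nrow(tags[["K7me2"]]), nrow(tags[["K7ac"]])))
    active <- state$classes$gene_id[!is.na(state$classes$class) &
                                      state$classes$class == "active"]
    ratios <- mutate(ratios, quantile = NA_character_)
    act_idx <- ratios$gene_id %in% active
    if (sum(is.finite(ratios$ratio[act_idx])) >= 3) {
      ratios$quantile[act_idx] <-
        as.character(ratio_tertiles(ratios$ratio[act_idx]))
    }
    readr::write_tsv(ratios, file.path(outdir, "k7_ratios.tsv"))
    # between-tertile expression differences (log FPKM)
    fpkm <- get_expr()$fpkm
    lfp <- fpkm_log(fpkm$fpkm[match(ratios$gene_id, fpkm$gene_id)])
    qt <- ratios$quantile
    if (sum(!is.na(qt)) >= 6) {
      pairs <- list(c("low", "medium"), c("medium", "high"),
                    c("low", "high"))
      tests <- purrr::map_dfr(pairs, function(pr) {
        tibble(group_a = pr[1], group_b = pr[2],
               p_value = wilcoxon_rank_sum(lfp[qt %in% pr[1]],
                                           lfp[qt %in% pr[2]]))
      })
      readr::write_tsv(tests, file.path(outdir, "ratio_group_tests.tsv"))
      state$ratio_tests <- tests
    }
    tsa <- get_expr()$tsa
    result <- NULL
    if (sum(!is.na(ratios$quantile)) >= 6 && nrow(tsa) > 0) {
      result <- tsa_contingency(tsa, select(ratios, "gene_id", "quantile"))
      readr::write_tsv(tibble(
        high_up = result$table[1, 1], high_down = result$table[1, 2],
        low_up = result$table[2, 1], low_down = result$table[2, 2],
        odds_ratio = result$odds_ratio, p_two_sided = result$p_two_sided),
        file.path(outdir, "tsa_contingency.tsv"))
    }
    state$ratios <- ratios
    state$tsa_result <- result
  })

  run_stage("assoc", function() {
    if (is.null(state$mark_table)) {
      state$mark_table <- readr::read_tsv(file.path(outdir, "mark_table.tsv"),
                                          show_col_types = FALSE)
    }
    if (is.null(state$classes)) {
      state$classes <- readr::read_tsv(file.path(outdir, "gene_classes.tsv"),
                                       show_col_types = FALSE)
    }
    active <- state$classes$gene_id[!is.na(state$classes$class) &
                                      state$classes$class == "active"]
    mt <- standardize_mark_table(
      filter(state$mark_table, .data$gene_id %in% active))
    sp <- spearman_matrix(mt)
    readr::write_tsv(as_tibble(unclass(sp), rownames = "variable"),
                     file.path(outdir, "spearman_matrix.tsv"))
    partials <- bind_rows(
      partial_correlation(mt, "K7me2", "S2p", c("S5p")),
      partial_correlation(mt, "K7me2", "S2p", c("K7ac")),
      partial_correlation(mt, "K7me2", "S2p", c("S7p")),
      partial_correlation(mt, "K7me2", "S2p", c("S7p", "S5p", "K7ac")),
      partial_correlation(mt, "S7p", "S2p", c("K7ac")),
      partial_correlation(mt, "K7ac", "S2p", c("S7p")))
    readr::write_tsv(partials, file.path(outdir, "partial_correlations.tsv"))
    bs <- best_subset(mt)
    readr::write_tsv(glance(bs), file.path(outdir, "best_subset.tsv"))
    la <- lasso_1se(mt, seed = config$seed)
    readr::write_tsv(tidy(la), file.path(outdir, "lasso_coefficients.tsv"))
    state$assoc <- list(spearman = sp, partials = partials,
                        best_subset = bs, lasso = la)
    log_line("assoc: %d active genes in mark table", nrow(mt))
  })

  invisible(list(genes = state$genes, tags = state$tags_dedup %||% state$tags,
                 regions = state$regions, status = state$status,
                 classes = state$classes, mark_table = state$mark_table,
                 ratios = state$ratios, tsa = state$tsa_result,
                 assoc = state$assoc))
}

capture_class_counts <- function(classes) {
  tab <- table(classes$class, useNA = "ifany")
  paste0(names(tab), "=", as.integer(tab))
}
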