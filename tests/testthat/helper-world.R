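# A small synthetic world shared across tests, built once per session.
# 150 active / 50 PRCr / 100 inactive genes at desk-scale depth.
.world_cache <- new.env(parent = emptyenv())

test_world <- function() {
  if (is.null(.world_cache$world)) {
    cfg <- synthetic_config(n_active = 150, n_prcr = 50, n_inactive = 100,
                            depth_per_mark = 1e5, seed = 42)
    genes <- generate_genes(cfg)
    tags <- generate_tags(genes, cfg)
    expr <- generate_expression(genes, cfg)
    .world_cache$world <- list(config = cfg, genes = genes, tags = tags,
                               expr = expr)
  }
  .world_cache$world
}

# In-memory classification chain: dedup -> peaks -> positivity -> classes.
classify_world <- function(genes, tags, fpkm,
                           marks = c("S5p", "S7p", "S2p", "8WG16",
                                     "H3K27me3", "H2Aub1")) {
  dd <- lapply(tags[c(marks, "mock")], deduplicate_tags)
  pw <- suppressWarnings(promoter_window(genes))
  tw <- suppressWarnings(tes_window(genes))
  status <- purrr::map_dfr(marks, function(mk) {
    win <- if (mk == "S2p") tw else pw
    regions <- call_enriched_regions(dd[[mk]], dd[["mock"]])
    counts <- dplyr::select(count_window(dd[[mk]], win), gene_id, count)
    classify_promoters(genes, regions, counts, mark = mk, windows = win)
  })
  assign_gene_classes(status, fpkm,
                      nonoverlapping = nonoverlapping_promoters(genes))
}

# Balanced accuracy of planted active-vs-inactive recovery among genes
# receiving a definite (non-NA) call.
balanced_accuracy <- function(planted, called) {
  keep <- planted %in% c("active", "inactive") & !is.na(called)
  sens <- mean(called[keep & planted == "active"] == "active")
  spec <- mean(called[keep & planted == "inactive"] == "inactive")
  (sens + spec) / 2
}
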