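#' Read and write tag sets as 6-column BED
#'
#' Tags are stored as BED6 records of width 1 (`start = pos`,
#' `end = pos + 1`), the conventional representation of mapped-read 5'
#' positions.  Parsing and serialization go through `rtracklayer`.
#'
#' @param path BED file path.
#' @return `read_tag_bed()` returns a tag tibble (`chrom`, `pos`, `strand`).
#' @export
read_tag_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         pos = as.integer(GenomicRanges::start(gr)) - 1L,
         strand = as.character(GenomicRanges::strand(gr)))
}

#' @rdname read_tag_bed
#' @param tags Tag tibble.
#' @export
write_tag_bed <- function(tags, path) {
  # BED6 is plain TSV; written directly for speed, read back via rtracklayer
  df <- data.frame(chrom = tags$chrom, start = tags$pos,
                   end = tags$pos + 1L, name = "tag", score = 0L,
                   strand = ifelse(tags$strand %in% c("+", "-"),
                                   tags$strand, "."))
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write gene models as BED12 plus an attribute TSV
#'
#' @param genes Gene tibble from [generate_genes()].
#' @param bed_path,tsv_path Output paths for the BED12 annotation and the
#'   per-gene attribute table (class, activity, CpG).
#' @return `bed_path`, invisibly.
#' @export
write_genes_bed <- function(genes, bed_path, tsv_path = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    name = genes$gene_id,
    score = 0L)
  S4Vectors::mcols(gr)$thick <- IRanges::IRanges(start = genes$start + 1L,
                                                 end = genes$end)
  S4Vectors::mcols(gr)$blocks <- IRanges::IRangesList(
    lapply(genes$end - genes$start, function(w) IRanges::IRanges(1L, w)))
  rtracklayer::export(gr, bed_path, format = "BED")
  if (!is.null(tsv_path)) {
    readr::write_tsv(select(genes, -dplyr::any_of(c("chrom", "start", "end",
                                                    "strand"))), tsv_path)
  }
  invisible(bed_path)
}

#' Write enriched regions as BED5 with the rate ratio as score
#'
#' @param regions Region tibble from [call_enriched_regions()].
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom, start = regions$start,
                   end = regions$end,
                   name = sprintf("region%03d", seq_len(nrow(regions))),
                   score = round(regions$rate_ratio, 3))
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
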