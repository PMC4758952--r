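#' K7 methylation / acetylation ratio
#'
#' Per-gene quotient of depth-scaled promoter counts: both counts are
#' scaled per 10 million mapped tags of their respective dataset before
#' dividing.  The ratio is `NA` when the acetylation count is zero.
#'
#' @param me_count,ac_count Promoter tag counts for the methylation and
#'   acetylation datasets (vectors allowed).
#' @param me_total,ac_total Total non-duplicated mapped tags of each
#'   dataset.
#' @return Numeric ratio(s), `NA` where `ac_count == 0`.
#' @examples
#' k7_ratio(20, 10, 1e7, 2e7)  # 4
#' @export
k7_ratio <- function(me_count, ac_count, me_total, ac_total) {
  if (any(me_count < 0, na.rm = TRUE) || any(ac_count < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  ratio <- scale_per_10m(me_count, me_total) /
    scale_per_10m(ac_count, ac_total)
  ratio[!is.na(ac_count) & ac_count == 0] <- NA_real_
  ratio
}

#' Tertile labels for a ratio vector
#'
#' Ranks the finite ratios (ties broken by original order, making the split
#' stable) and partitions them into three near-equal groups labelled
#' `low`, `medium`, `high` via `group = ceiling(3 * rank / n)`; group sizes
#' differ by at most one (10 values split 3/3/4 from low to high).
#' Non-finite ratios get `NA`.  The labels are invariant
#' under any strictly increasing transform of the ratios.
#'
#' @param ratios Numeric vector.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
ratio_tertiles <- function(ratios) {
  ok <- is.finite(ratios)
  if (sum(ok) < 3) abort("need at least 3 finite ratios")
  r <- rank(ratios[ok], ties.method = "first")
  m <- sum(ok)
  grp <- ceiling(3 * r / m)
  out <- rep(NA_character_, length(ratios))
  out[ok] <- c("low", "medium", "high")[grp]
  factor(out, levels = c("low", "medium", "high"))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two groups of values with the exact null distribution when the
#' smaller group has at most 10 observations and there are no ties, and
#' otherwise with the normal approximation using tie-corrected variance and
#' continuity correction.  Two groups with entirely identical values give
#' p = 1.
#'
#' @param a,b Numeric vectors (non-empty).
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)  # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1) return(1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 10 && !ties
  res <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE))
  unname(res$p.value)
}

#' TSA-response contingency analysis of ratio tertiles
#'
#' Cross-tabulates high- versus low-ratio genes against up/down regulation
#' after a perturbation (up: fold change >= `min_fold`, down: fold change
#' <= `1/min_fold`; genes in between are excluded) and tests the 2x2 table
#' with a two-sided Fisher's exact test (probability-mass method).  The
#' odds ratio is the sample cross-product `(a*d)/(b*c)`; when a cell is
#' zero, 0.5 is added to every cell (Haldane correction) before forming the
#' cross-product.
#'
#' @param fold_changes Tibble `gene_id`, `fold_change` on the
#'   treated/control scale.
#' @param quantiles Tibble `gene_id`, `quantile` (factor from
#'   [ratio_tertiles()]), or a named factor.
#' @param min_fold Fold-change threshold (default 2).
#' @return An object of class `tsa_contingency`: list with `table` (2x2,
#'   rows high/low, columns up/down), `odds_ratio`, `p_two_sided`.
#' @export
tsa_contingency <- function(fold_changes, quantiles, min_fold = 2) {
  if (!is.data.frame(quantiles)) {
    quantiles <- tibble(gene_id = names(quantiles),
                        quantile = as.character(quantiles))
  }
  df <- dplyr::inner_join(fold_changes,
                          mutate(quantiles,
                                 quantile = as.character(.data$quantile)),
                          by = "gene_id")
  df <- filter(df, .data$quantile %in% c("high", "low"),
               .data$fold_change >= .env$min_fold |
                 .data$fold_change <= 1 / .env$min_fold)
  tab <- matrix(c(
    sum(df$quantile == "high" & df$fold_change >= min_fold),
    sum(df$quantile == "high" & df$fold_change <= 1 / min_fold),
    sum(df$quantile == "low" & df$fold_change >= min_fold),
    sum(df$quantile == "low" & df$fold_change <= 1 / min_fold)),
    nrow = 2, byrow = TRUE,
    dimnames = list(ratio = c("high", "low"), response = c("up", "down")))
  contingency_result(tab)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums all hypergeometric probabilities (at fixed
#' margins) that do not exceed the probability of the observed table — the
#' probability-mass convention.
#'
#' @param table 2x2 integer matrix.
#' @return An object of class `tsa_contingency`.
#' @export
contingency_result <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warn("empty margin: Fisher p undefined")
    p <- NA_real_
  } else {
    p <- fisher.test(table)$p.value
  }
  t2 <- table
  if (any(table == 0)) t2 <- table + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  structure(list(table = table, odds_ratio = unname(or), p_two_sided = p),
            class = "tsa_contingency")
}

#' @exportS3Method base::print
print.tsa_contingency <- function(x, ...) {
  cat("<tsa_contingency>\n")
  print(x$table)
  cat(sprintf("odds ratio %.3f, two-sided Fisher p = %.3g\n",
              x$odds_ratio, x$p_two_sided))
  invisible(x)
}
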