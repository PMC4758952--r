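#' Build the gene-by-variable mark table
#'
#' Assembles the matrix underlying all correlation and regression analyses:
#' depth-scaled promoter counts (2 kb around the TSS) for each promoter
#' mark, the depth-scaled S2p count in the 2 kb window after the TES,
#' log-transformed mRNA (FPKM with the 1e-4 pseudocount), the mock control
#' and CpG content.
#'
#' @param tag_sets Named list of (deduplicated) tag tibbles; must include
#'   the promoter marks in `promoter_marks` plus `"S2p"` and `"mock"`.
#' @param genes Gene tibble.
#' @param fpkm Tibble `gene_id`, `fpkm`.
#' @param promoter_marks Marks quantified at the promoter window.
#' @param half_width Promoter half-width (bp).
#' @param tes_length Post-TES window length (bp) for S2p.
#' @return A tibble, one row per gene: `gene_id`, one column per variable
#'   (`S2p` holding the TES-window signal, `mRNA` the log FPKM).
#' @export
build_mark_table <- function(tag_sets, genes, fpkm,
                             promoter_marks = c("K7me1", "K7me2", "K7ac",
                                                "8WG16", "S5p", "S7p",
                                                "mock"),
                             half_width = 1000, tes_length = 2000) {
  need <- union(promoter_marks, "S2p")
  missing_marks <- setdiff(need, names(tag_sets))
  if (length(missing_marks) > 0) {
    abort(paste0("missing tag set(s): ", paste(missing_marks, collapse = ", ")))
  }
  pw <- suppressWarnings(promoter_window(genes, half_width))
  tw <- suppressWarnings(tes_window(genes, tes_length))
  out <- tibble(gene_id = genes$gene_id)
  for (mk in promoter_marks) {
    cnt <- count_window(tag_sets[[mk]], pw)$count
    out[[mk]] <- scale_per_10m(cnt, nrow(tag_sets[[mk]]))
  }
  cnt <- count_window(tag_sets[["S2p"]], tw)$count
  out[["S2p"]] <- scale_per_10m(cnt, nrow(tag_sets[["S2p"]]))
  out[["mRNA"]] <- fpkm_log(fpkm$fpkm[match(genes$gene_id, fpkm$gene_id)])
  if ("cpg" %in% names(genes)) out[["CpG"]] <- genes$cpg
  out
}

#' Center and scale the numeric columns of a mark table
#'
#' @param table Mark table from [build_mark_table()].
#' @return The table with each numeric column standardized to mean 0 and
#'   sample standard deviation 1 (constant columns are left centered), and
#'   attribute `standardized = TRUE`.
#' @export
standardize_mark_table <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  out <- mutate(table, across(names(table)[num], function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) x - mean(x) else (x - mean(x)) / s
  }))
  attr(out, "standardized") <- TRUE
  out
}

mark_matrix <- function(table, vars = NULL) {
  num <- vapply(table, is.numeric, logical(1))
  m <- as.matrix(table[, num, drop = FALSE])
  if (!is.null(vars)) {
    missing_vars <- setdiff(vars, colnames(m))
    if (length(missing_vars) > 0) {
      abort(paste0("variable(s) not in table: ",
                   paste(missing_vars, collapse = ", ")))
    }
    m <- m[, vars, drop = FALSE]
  }
  m
}

#' Spearman correlation matrix ordered by correlation with mRNA
#'
#' Average-rank transforms each column, then computes Pearson correlations
#' on the ranks.  Rows and columns are ordered by increasing correlation
#' with `mRNA` when that variable is present.  Constant columns produce
#' `NA` entries and a warning.
#'
#' @param table Mark table.
#' @param vars Variables to include (default: every numeric column).
#' @return A symmetric correlation matrix of class `spearman_matrix`.
#' @export
spearman_matrix <- function(table, vars = NULL) {
  m <- mark_matrix(table, vars)
  if (nrow(m) < 3) abort("need at least 3 genes")
  const <- apply(m, 2, function(x) sd(x) == 0 || is.na(sd(x)))
  if (any(const)) warn(paste0("constant column(s): ",
                              paste(colnames(m)[const], collapse = ", ")))
  r <- apply(m, 2, rank)
  cm <- suppressWarnings(stats::cor(r))
  diag(cm) <- ifelse(const, NA_real_, 1)
  if ("mRNA" %in% colnames(cm)) {
    ord <- order(cm[, "mRNA"])
    cm <- cm[ord, ord]
  }
  structure(cm, class = c("spearman_matrix", "matrix", "array"))
}

#' Partial correlation given a conditioning set
#'
#' Computes the correlation between `x` and `y` after removing the linear
#' effect of the `given` variables, via the precision-matrix identity
#' `rho = -O[x,y] / sqrt(O[x,x] * O[y,y])` where `O` is the inverse of the
#' correlation matrix of `(x, y, given)`.  By default all columns are
#' average-rank transformed first, so the marginal case (`given` empty)
#' reproduces the Spearman coefficient; `method = "raw"` works on the
#' supplied values.  The p-value uses the t statistic
#' `rho * sqrt((n - |given| - 2) / (1 - rho^2))` with `n - |given| - 2`
#' degrees of freedom.
#'
#' @param table Mark table.
#' @param x,y Variable names.
#' @param given Character vector of conditioning variables (may be empty).
#' @param method `"rank"` (default) or `"raw"`.
#' @return A tibble: `x`, `y`, `given`, `estimate`, `statistic`, `p_value`,
#'   `n`.
#' @export
partial_correlation <- function(table, x, y, given = character(),
                                method = c("rank", "raw")) {
  method <- match.arg(method)
  vars <- c(x, y, given)
  m <- mark_matrix(table, vars)
  n <- nrow(m)
  if (n <= length(given) + 2) abort("too few observations")
  if (method == "rank") m <- apply(m, 2, rank)
  cm <- stats::cor(m)
  omega <- tryCatch(solve(cm), error = function(e) {
    abort(paste0("singular conditioning set among: ",
                 paste(vars, collapse = ", ")))
  })
  r <- -omega[x, y] / sqrt(omega[x, x] * omega[y, y])
  df <- n - length(given) - 2
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  tibble(x = x, y = y,
         given = paste(given, collapse = ","),
         estimate = unname(r), statistic = unname(tstat),
         p_value = unname(p), n = n)
}

#' Exhaustive best-subset regression
#'
#' Enumerates every predictor subset of size 1..`max_size`, fits ordinary
#' least squares on the standardized data and reports, per size, the
#' `top_k` models by adjusted R-squared, with coefficient signs,
#' per-coefficient t-test significance codes, adjusted R-squared, Mallow's
#' Cp (against the full model using all `predictors`) and AIC (Gaussian
#' log-likelihood including the constant term).
#'
#' @param table Mark table (standardize first with
#'   [standardize_mark_table()] for sign-comparable coefficients).
#' @param response Response variable (default `"S2p"`, the post-TES
#'   elongation signal).
#' @param predictors Candidate predictors.
#' @param max_size Largest subset size (default 5).
#' @param top_k Models reported per size (default 5).
#' @return An object of class `subset_models`: tibble `models` with one row
#'   per reported model (`size`, `rank`, `predictors`, `adj_r2`, `r2`,
#'   `cp`, `aic`, `coefficients` list-column).
#' @export
best_subset <- function(table, response = "S2p",
                        predictors = c("K7me1", "K7me2", "8WG16", "S5p",
                                       "S7p", "K7ac", "CpG"),
                        max_size = 5, top_k = 5) {
  m <- mark_matrix(table, c(response, predictors))
  n <- nrow(m)
  p_full <- length(predictors)
  if (n <= p_full + 1) abort("need n > number of predictors + 1")
  y <- m[, response]
  X <- m[, predictors, drop = FALSE]
  full <- stats::lm.fit(cbind(1, X), y)
  sigma2_full <- sum(full$residuals^2) / (n - p_full - 1)
  fit_one <- function(vars) {
    Xi <- cbind(`(Intercept)` = 1, X[, vars, drop = FALSE])
    fit <- stats::lm.fit(Xi, y)
    rss <- sum(fit$residuals^2)
    p <- length(vars)
    r2 <- 1 - rss / sum((y - mean(y))^2)
    adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
    cp <- rss / sigma2_full - n + 2 * (p + 1)
    aic <- n * log(2 * pi * rss / n) + n + 2 * (p + 2)
    # coefficient t tests
    XtXi <- chol2inv(chol(crossprod(Xi)))
    se <- sqrt(diag(XtXi) * rss / (n - p - 1))
    tval <- fit$coefficients / se
    pval <- 2 * pt(-abs(tval), n - p - 1)
    tibble(size = p, predictors = paste(vars, collapse = "+"),
           adj_r2 = adj, r2 = r2, cp = cp, aic = aic,
           coefficients = list(tibble(
             term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             std_error = unname(se), statistic = unname(tval),
             p_value = unname(pval),
             signif = signif_code(unname(pval)))))
  }
  models <- purrr::map_dfr(seq_len(min(max_size, p_full)), function(k) {
    subs <- combn(predictors, k, simplify = FALSE)
    fits <- purrr::map_dfr(subs, fit_one)
    fits <- arrange(fits, desc(.data$adj_r2))
    mutate(head(fits, top_k), rank = row_number())
  })
  structure(list(models = models, response = response, n = n,
                 predictors = predictors),
            class = "subset_models")
}

signif_code <- function(p) {
  dplyr::case_when(p <= 0.001 ~ "***", p <= 0.01 ~ "**",
                   p <= 0.05 ~ "*", TRUE ~ "n.s.")
}

#' @exportS3Method base::print
print.subset_models <- function(x, ...) {
  cat(sprintf("<subset_models> response %s, n = %d\n", x$response, x$n))
  best <- x$models %>% group_by(.data$size) %>%
    filter(.data$rank == 1) %>% ungroup()
  for (i in seq_len(nrow(best))) {
    cat(sprintf("  size %d: %-40s adjR2 %.3f  Cp %7.1f  AIC %.1f\n",
                best$size[i], best$predictors[i], best$adj_r2[i],
                best$cp[i], best$aic[i]))
  }
  invisible(x)
}

#' Cross-validated LASSO with the one-standard-error rule
#'
#' Fits the full L1 regularization path for the standardized response and
#' predictors, assigns genes to `nfolds` cross-validation folds using
#' `seed`, and selects the largest penalty whose cross-validated mean
#' squared error is within one standard error of the minimum (the 1-SE
#' rule), reporting the coefficients at that penalty.
#'
#' @param table Mark table (standardized recommended).
#' @param response Response variable.
#' @param predictors Candidate predictors, including the mock control
#'   (expected to be discarded by the selection).
#' @param nfolds Number of cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return An object of class `lasso_fit`: coefficients at the selected
#'   penalty, the penalty grid with CV error curve, `lambda_min`,
#'   `lambda_1se`.
#' @export
lasso_1se <- function(table, response = "S2p",
                      predictors = c("8WG16", "S5p", "S7p", "K7me1",
                                     "K7me2", "K7ac", "mock", "CpG"),
                      nfolds = 10, seed = 1L) {
  m <- mark_matrix(table, c(response, predictors))
  n <- nrow(m)
  if (n < nfolds) abort("need at least as many genes as folds")
  y <- m[, response]
  X <- m[, predictors, drop = FALSE]
  # keep >= 3 observations per fold so CV error bars are well defined
  nfolds <- max(3L, min(nfolds, n %/% 3L))
  foldid <- withr::with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  if (min(table(foldid)) == 0) abort("degenerate (empty) fold")
  cv <- glmnet::cv.glmnet(X, y, foldid = foldid, standardize = FALSE)
  co <- as.matrix(stats::coef(cv, s = "lambda.1se"))[, 1]
  structure(list(
    coefficients = tibble(term = names(co), estimate = unname(co)),
    lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
    cv_curve = tibble(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                      nonzero = cv$nzero),
    response = response, n = n, glmnet_fit = cv),
    class = "lasso_fit")
}

#' @exportS3Method base::print
print.lasso_fit <- function(x, ...) {
  nz <- filter(x$coefficients, .data$term != "(Intercept)",
               .data$estimate != 0)
  cat(sprintf("<lasso_fit> response %s, n = %d, lambda(1se) = %.4g\n",
              x$response, x$n, x$lambda_1se))
  cat(sprintf("  selected: %s\n",
              paste(sprintf("%s(%+.3f)", nz$term, nz$estimate),
                    collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the reported subset-regression models
#'
#' @param x A `subset_models` object.
#' @param ... Unused.
#' @return One row per coefficient of every reported model.
#' @export
tidy.subset_models <- function(x, ...) {
  x$models %>%
    select("size", "rank", "predictors", "coefficients") %>%
    tidyr::unnest("coefficients")
}

#' @rdname tidy.subset_models
#' @return `glance()`: one row per reported model with fit statistics.
#' @export
glance.subset_models <- function(x, ...) {
  select(x$models, "size", "rank", "predictors", "r2", "adj_r2", "cp",
         "aic")
}

#' Tidy a cross-validated LASSO fit
#'
#' @param x A `lasso_fit` object.
#' @param ... Unused.
#' @return `tidy()`: coefficients at the 1-SE penalty.
#' @export
tidy.lasso_fit <- function(x, ...) x$coefficients

#' @rdname tidy.lasso_fit
#' @export
glance.lasso_fit <- function(x, ...) {
  nz <- sum(x$coefficients$estimate != 0 &
              x$coefficients$term != "(Intercept)")
  tibble(lambda_min = x$lambda_min, lambda_1se = x$lambda_1se,
         n_selected = nz, n = x$n)
}
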