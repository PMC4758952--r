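sim_table <- function(n = 200, seed = 1) {
  # small correlated table with known structure for unit checks
  withr::with_seed(seed, {
    u <- rnorm(n)
    tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(n)),
      S5p = 0.8 * u + 0.6 * rnorm(n),
      S7p = 0.8 * u + 0.6 * rnorm(n),
      K7ac = 0.8 * u + 0.6 * rnorm(n),
      K7me2 = 0.8 * u + 0.6 * rnorm(n),
      mock = rnorm(n),
      S2p = 0.5 * u + 0.7 * rnorm(n),
      mRNA = 0.4 * u + 0.8 * rnorm(n))
  })
}

test_that("standardization yields mean-0, sample-sd-1 columns", {
  st <- standardize_mark_table(sim_table())
  for (v in c("S5p", "S2p", "mRNA")) {
    expect_lt(abs(mean(st[[v]])), 1e-10)
    expect_lt(abs(sd(st[[v]]) - 1), 1e-10)
  }
  expect_true(attr(st, "standardized"))
})

test_that("spearman_matrix is rank-based, symmetric and mRNA-ordered", {
  tb <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  sp <- spearman_matrix(tb)
  expect_equal(sp["x", "y"], 0.8)
  expect_equal(sp["x", "x"], 1)
  expect_equal(unclass(sp), t(unclass(sp)))
  # reversing one variable flips the sign
  tb$y <- -tb$y
  expect_equal(spearman_matrix(tb)["x", "y"], -0.8)
  # invariance under strictly monotone transforms
  big <- sim_table()
  sp1 <- spearman_matrix(big)
  big2 <- dplyr::mutate(big, S5p = exp(S5p), S2p = S2p^3)
  sp2 <- spearman_matrix(big2)
  expect_equal(unclass(sp1), unclass(sp2), tolerance = 1e-12)
  # ordering: last column has the highest correlation with mRNA
  cors <- sp1[, "mRNA"]
  expect_equal(colnames(sp1), names(sort(cors)))
  # constant columns give NA with a warning
  cc <- dplyr::mutate(tb, z = 1)
  expect_warning(spc <- spearman_matrix(cc), "constant")
  expect_true(is.na(spc["z", "x"]))
})

test_that("partial correlation reduces to the marginal case and matches oracles", {
  tb <- sim_table(n = 120, seed = 3)
  m <- as.matrix(tb[, -1])
  # empty conditioning set equals the Spearman coefficient
  p0 <- partial_correlation(tb, "K7me2", "S2p")
  expect_equal(p0$estimate, cor(tb$K7me2, tb$S2p, method = "spearman"),
               tolerance = 1e-12)
  # residual-regression oracle, rank and raw modes
  for (given in list("S5p", c("S5p", "S7p"), c("S5p", "S7p", "K7ac"))) {
    pr <- partial_correlation(tb, "K7me2", "S2p", given)
    expect_equal(pr$estimate,
                 oracle_partial_resid(m, "K7me2", "S2p", given),
                 tolerance = 1e-10)
    praw <- partial_correlation(tb, "K7me2", "S2p", given, method = "raw")
    expect_equal(praw$estimate,
                 oracle_partial_resid(m, "K7me2", "S2p", given,
                                      rank_first = FALSE),
                 tolerance = 1e-10)
  }
  # |given| = 1 matches the textbook recursive formula on raw values
  r_xy <- cor(m[, "K7me2"], m[, "S2p"])
  r_xz <- cor(m[, "K7me2"], m[, "S5p"])
  r_yz <- cor(m[, "S2p"], m[, "S5p"])
  expect_equal(partial_correlation(tb, "K7me2", "S2p", "S5p",
                                   method = "raw")$estimate,
               (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2)),
               tolerance = 1e-12)
  # the worked three-variable example: r_xy.z = 0.7782 from 0.9/0.8/0.72
  cm <- matrix(c(1, .9, .8, .9, 1, .72, .8, .72, 1), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  om <- solve(cm)
  expect_equal(-om["x", "y"] / sqrt(om["x", "x"] * om["y", "y"]),
               (0.9 - 0.8 * 0.72) / sqrt((1 - 0.64) * (1 - 0.72^2)),
               tolerance = 1e-12)
  # a collinear conditioning set errors informatively
  tb$dup <- tb$S5p
  expect_error(partial_correlation(tb, "K7me2", "S2p", c("S5p", "dup")),
               "singular")
})

test_that("best_subset ranks models by adjusted R2 with correct statistics", {
  tb <- standardize_mark_table(sim_table(n = 150, seed = 5))
  # response duplicated as a predictor: perfect size-1 fit
  tb$S2p_copy <- tb$S2p
  bs <- best_subset(tb, response = "S2p",
                    predictors = c("S2p_copy", "S5p", "S7p"), max_size = 2)
  top1 <- dplyr::filter(bs$models, size == 1, rank == 1)
  expect_equal(top1$predictors, "S2p_copy")
  expect_equal(top1$adj_r2, 1, tolerance = 1e-10)

  # adjusted R2 arithmetic: R2 = 0.5, n = 100, p = 2
  expect_equal(1 - (1 - 0.5) * 99 / 97, 0.4896907, tolerance = 1e-6)
  bs2 <- best_subset(tb, response = "S2p",
                     predictors = c("S5p", "S7p", "K7ac", "K7me2", "mock"),
                     max_size = 5)
  g <- glance(bs2)
  got <- dplyr::filter(g, size == 2, rank == 1)
  expect_equal(got$adj_r2, 1 - (1 - got$r2) * (150 - 1) / (150 - 2 - 1),
               tolerance = 1e-12)
  # the full model has Cp = p + 1 by construction
  full <- dplyr::filter(g, size == 5)
  expect_equal(full$cp, 6, tolerance = 1e-8)
  # AIC matches stats::AIC on the equivalent lm fit
  fit <- lm(S2p ~ S5p + S7p, data = tb)
  expect_equal(dplyr::filter(g, predictors == "S5p+S7p")$aic, AIC(fit),
               tolerance = 1e-8)
  # coefficient table carries signs and significance codes
  td <- tidy(bs2)
  expect_true(all(c("term", "estimate", "p_value", "signif") %in% names(td)))
})

test_that("best_subset recovers a planted sparse model", {
  # y = 0.6 S7p + 0.5 K7ac - 0.3 K7me1 + noise at R2 ~ 0.6
  wins2 <- 0; wins3 <- 0
  for (s in 1:20) {
    tb <- withr::with_seed(400 + s, {
      n <- 1500
      u <- rnorm(n)
      mk <- function() 0.7 * u + sqrt(1 - 0.49) * rnorm(n)
      t <- tibble::tibble(S7p = mk(), K7ac = mk(), K7me1 = mk(),
                          S5p = mk(), CpG = rnorm(n))
      t$y <- 0.6 * t$S7p + 0.5 * t$K7ac - 0.3 * t$K7me1 + 0.75 * rnorm(n)
      t
    })
    bs <- best_subset(standardize_mark_table(tb), response = "y",
                      predictors = c("S7p", "K7ac", "K7me1", "S5p", "CpG"),
                      max_size = 3, top_k = 1)
    b2 <- dplyr::filter(bs$models, size == 2, rank == 1)
    if (setequal(strsplit(b2$predictors, "\\+")[[1]],
                 c("S7p", "K7ac"))) wins2 <- wins2 + 1
    b3 <- dplyr::filter(bs$models, size == 3, rank == 1)
    co3 <- b3$coefficients[[1]]
    if ("K7me1" %in% co3$term &&
        co3$estimate[co3$term == "K7me1"] < 0) wins3 <- wins3 + 1
  }
  expect_gt(wins2, 10)
  expect_gt(wins3, 10)
})

test_that("the LASSO path shrinks to OLS at zero penalty and to null on noise", {
  # 5-observation toy: endpoint of the path equals least squares
  tb <- withr::with_seed(9, tibble::tibble(x1 = rnorm(5), x2 = rnorm(5)))
  tb$y <- 1.2 * tb$x1 - 0.4 * tb$x2 + 0.1 * rnorm(5)
  fit <- glmnet::glmnet(as.matrix(tb[, c("x1", "x2")]), tb$y,
                        lambda = c(1, 0.1, 0), standardize = FALSE,
                        thresh = 1e-14)
  ols <- coef(lm(y ~ x1 + x2, data = tb))
  expect_equal(as.numeric(coef(fit, s = 0)), as.numeric(ols),
               tolerance = 1e-6)

  # pure-noise response: the 1-SE model keeps no predictors
  tb2 <- withr::with_seed(10, {
    t <- tibble::tibble(gene_id = as.character(1:300))
    for (v in c("S5p", "S7p", "K7ac", "K7me2", "mock")) t[[v]] <- rnorm(300)
    t$S2p <- rnorm(300)
    t
  })
  la <- lasso_1se(standardize_mark_table(tb2), response = "S2p",
                  predictors = c("S5p", "S7p", "K7ac", "K7me2", "mock"),
                  seed = 2)
  co <- dplyr::filter(tidy(la), term != "(Intercept)")
  expect_true(all(co$estimate == 0))
  expect_equal(glance(la)$n_selected, 0)
})

test_that("lasso_1se fold assignment is seeded and reproducible", {
  tb <- standardize_mark_table(sim_table(n = 120, seed = 6))
  l1 <- lasso_1se(tb, response = "S2p",
                  predictors = c("S5p", "S7p", "K7ac", "K7me2", "mock"),
                  seed = 7)
  l2 <- lasso_1se(tb, response = "S2p",
                  predictors = c("S5p", "S7p", "K7ac", "K7me2", "mock"),
                  seed = 7)
  expect_identical(tidy(l1), tidy(l2))
  expect_error(lasso_1se(tb[1:5, ], response = "S2p",
                         predictors = c("S5p", "S7p"), nfolds = 10),
               "folds")
})
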