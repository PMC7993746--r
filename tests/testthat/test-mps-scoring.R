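# Weighted-sum scoring against the published 21-gene panel and the
# threshold stratification scheme.

score_matrix_for <- function(panel, fill = 0L) {
  m <- matrix(fill, nrow = nrow(panel), ncol = 3,
              dimnames = list(panel$symbol, c("P1", "P2", "P3")))
  m
}

test_that("mPS is the dot product of scores and published weights", {
  p <- panel_table2()
  zeros <- score_matrix_for(p, 0L)
  expect_equal(compute_mps(zeros, p)$mps, rep(0, 3))
  ones <- score_matrix_for(p, 1L)
  expect_equal(compute_mps(ones, p)$mps, rep(74.616, 3))
  only_ddah1 <- zeros
  only_ddah1["DDAH1", ] <- 1L
  expect_equal(compute_mps(only_ddah1, p)$mps, rep(3.580, 3))
  # random vectors match an independent dot product
  withr::with_seed(1, {
    for (i in 1:20) {
      s <- score_matrix_for(p, 0L)
      s[, 1] <- rbinom(nrow(p), 1, 0.5)
      expect_equal(compute_mps(s, p)$mps[1],
                   sum(s[p$symbol, 1] * p$weight))
    }
  })
})

test_that("missing panel genes and non-binary scores are rejected", {
  p <- panel_table2()
  m <- score_matrix_for(p)[-1, , drop = FALSE]
  expect_error(compute_mps(m, p), "DDAH1")
  m2 <- score_matrix_for(p); m2[1, 1] <- 2L
  expect_error(compute_mps(m2, p), "binary")
})

test_that("flipping one gene adds exactly its weight (additivity)", {
  p <- panel_table2()
  base <- score_matrix_for(p, 0L)
  m0 <- compute_mps(base, p)$mps[1]
  for (g in c("DDAH1", "UBE2C", "SIM2")) {
    flipped <- base
    flipped[g, 1] <- 1L
    expect_equal(compute_mps(flipped, p)$mps[1] - m0,
                 p$weight[p$symbol == g])
  }
})

test_that("pointwise score dominance implies mPS dominance", {
  p <- panel_table2()
  withr::with_seed(2, {
    for (i in 1:10) {
      lo <- rbinom(nrow(p), 1, 0.4)
      hi <- pmin(lo + rbinom(nrow(p), 1, 0.3), 1)
      m <- cbind(lo, hi)
      dimnames(m) <- list(p$symbol, c("lo", "hi"))
      r <- compute_mps(m, p)
      expect_gte(r$mps[2], r$mps[1])
    }
  })
})

test_that("stratification boundaries follow the published half-open bins", {
  res <- data.frame(sample_id = letters[1:4],
                    mps = c(21.99, 22, 29.99, 30))
  three <- stratify(res, stratification_scheme(c(22, 30)))
  expect_equal(as.character(three$stratum),
               c("low", "median", "median", "high"))
  two <- stratify(res, stratification_scheme(22))
  expect_equal(as.character(two$stratum), c("low", "high", "high", "high"))
})

test_that("strata partition every score exactly once", {
  withr::with_seed(3, res <- data.frame(sample_id = 1:200,
                                        mps = runif(200, 0, 75)))
  st <- stratify(res, stratification_scheme(c(22, 30)))
  expect_false(anyNA(st$stratum))
  expect_equal(sum(table(st$stratum)), 200L)
})

test_that("scaling weights by c > 0 scales mPS by c (with rescaled thresholds)", {
  p <- panel_table2()
  withr::with_seed(4, s <- matrix(rbinom(21 * 5, 1, 0.5), 21,
                                  dimnames = list(p$symbol,
                                                  sprintf("S%d", 1:5))))
  for (c_ in c(0.5, 3)) {
    p2 <- gene_panel(p$symbol, p$score_high, p$score_low, p$weight * c_)
    r1 <- stratify(compute_mps(s, p), stratification_scheme(c(22, 30)))
    r2 <- stratify(compute_mps(s, p2), stratification_scheme(c(22, 30) * c_))
    expect_equal(r2$mps, r1$mps * c_)
    expect_equal(r2$stratum, r1$stratum)
  }
})

test_that("scheme validation rejects bad thresholds and label counts", {
  expect_error(stratification_scheme(c(30, 22)), "ascending")
  expect_error(stratification_scheme(c(22, 30), c("a", "b")), "label")
})

test_that("scoring a cohort with its own medians matches construction scores", {
  co <- small_cohort(seed = 12, n_tumor = 80, n_genes = 30, n_prognostic = 5,
                     censor_rate = 0.3)
  scr <- screen_survival(co$expression, co$clinical, alpha = 1)
  genes <- scr$results$symbol[scr$results$scoreable][1:10]
  gs <- assign_gene_scores(co$expression, scr$results, genes)
  w <- setNames(runif(10, 3, 4.3), genes)
  panel <- build_panel(genes, gs$directions, w)
  construction_mps <- compute_mps(gs$scores, panel)
  scored <- score_cohort(co$expression, panel)
  expect_equal(scored$mps[match(construction_mps$sample_id,
                                scored$sample_id)],
               construction_mps$mps)
})

test_that("median reference transfers cutoffs across cohorts", {
  p <- gene_panel(c("A", "B"), c(1, 0), c(0, 1), c(2, 3))
  m <- matrix(c(1, 5, 9,
                1, 5, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  expr <- expression_matrix(m, rep("tumor", 3))
  ref <- median_reference(c(A = 0, B = 100), source = "external")
  r <- score_cohort(expr, p, medians = ref)
  # with cutoff 0 every A value is high (score 1); with cutoff 100 every B
  # value is low (score 1 since score_low = 1) => mps = 2 + 3
  expect_equal(r$mps, rep(5, 3))
  r_own <- score_cohort(expr, p)
  expect_false(all(r_own$mps == 5))
})

test_that("single-sample cohorts warn and take the all-low state", {
  p <- gene_panel(c("A", "B"), c(1, 0), c(0, 1), c(2, 3))
  m <- matrix(c(1, 2), ncol = 1, dimnames = list(c("A", "B"), "S1"))
  expr <- expression_matrix(m, "tumor")
  expect_warning(r <- score_cohort(expr, p), "single-sample")
  expect_equal(r$mps, 3)          # low state: A scores 0, B scores 1
})

test_that("missing panel genes: strict errors, permissive imputes, >20% always errors", {
  p <- panel_table2()
  withr::with_seed(5, m <- matrix(rnorm(20 * 10), 20,
                                  dimnames = list(p$symbol[1:20],
                                                  sprintf("S%d", 1:10))))
  expr <- expression_matrix(m, rep("tumor", 10))
  expect_error(score_cohort(expr, p, mode = "strict"), "SIM2")
  expect_message(r <- score_cohort(expr, p, mode = "permissive"), "SIM2")
  expect_equal(nrow(r), 10L)
  m2 <- m[1:15, , drop = FALSE]    # 6 of 21 missing > 20%
  expr2 <- expression_matrix(m2, rep("tumor", 10))
  expect_error(score_cohort(expr2, p, mode = "permissive"), "20%")
})

test_that("held-out strata from a planted panel separate survival", {
  co <- small_cohort(seed = 13, n_tumor = 300, n_genes = 40,
                     n_prognostic = 8, censor_rate = 0.3,
                     planted_log_hr = log(3.2))
  scr <- screen_survival(co$expression, co$clinical)
  genes <- intersect(co$truth$prognostic_genes, scr$hits$symbol)
  gs <- assign_gene_scores(co$expression, scr$results, genes)
  panel <- build_panel(genes, gs$directions,
                       setNames(rep(3.5, length(genes)), genes))
  held <- small_cohort(seed = 14, n_tumor = 300, n_genes = 40,
                       n_prognostic = 8, censor_rate = 0.3,
                       planted_log_hr = log(3.2))
  r <- score_cohort(held$expression, panel,
                    scheme = stratification_scheme(
                      sum(panel$weight) / 2, c("low", "high")))
  km <- km_logrank(held$clinical,
                   r$stratum[match(held$clinical$sample_id, r$sample_id)])
  expect_lt(km$p, 0.01)
})
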