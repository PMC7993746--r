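# KM/log-rank, Cox models, Harrell's C, nomogram and calibration.

test_that("identical groups give log-rank statistic 0 and p 1", {
  cl <- toy_clinical(time = rep(c(5, 10, 15, 20, 30), 2),
                     event = rep(c(1, 0, 1, 1, 0), 2))
  km <- km_logrank(cl, rep(c("a", "b"), each = 5))
  expect_equal(km$statistic, 0, tolerance = 1e-9)
  expect_equal(km$p, 1, tolerance = 1e-9)
  expect_error(km_logrank(cl, rep("a", 10)), "2 groups")
})

test_that("KM estimate is 1 before the first event and matches the empirical
          survival without censoring", {
  withr::with_seed(20, t <- sort(runif(40, 1, 100)))
  cl <- toy_clinical(time = t, event = rep(1, 40))
  km <- km_logrank(cl, rep(c("g1", "g2"), each = 20))
  c1 <- km$curves[["g1"]]
  expect_true(all(c1$surv <= 1))
  # empirical survival: after k-th ordered event, S = 1 - k/n
  t1 <- sort(t[1:20])
  expect_equal(c1$surv, 1 - seq_along(t1) / 20, tolerance = 1e-12)
})

test_that("log-rank separates exponential groups with rate ratio 2", {
  pvals <- vapply(1:10, function(s) {
    withr::with_seed(200 + s, {
      t <- c(rexp(200, 1), rexp(200, 2))
      cl <- toy_clinical(time = t, event = rep(1, 400))
      km_logrank(cl, rep(c("slow", "fast"), each = 200))$p
    })
  }, 0)
  expect_true(all(pvals < 0.05))
})

test_that("null binary covariate gives HR near 1, p near 1", {
  cl <- toy_clinical(time = rep(c(3, 7, 12, 18, 25, 31), 2),
                     event = rep(c(1, 1, 0, 1, 0, 1), 2))
  cl$x <- rep(c(0, 1), each = 6)
  fit <- cox_univariate(cl, "x")
  expect_equal(fit$table$hr, 1, tolerance = 1e-6)
  expect_gt(fit$table$p, 0.99)
  expect_equal(fit$n_used, 12L)
})

test_that("multivariate on a single covariate equals the univariate fit", {
  co <- small_cohort(seed = 21, n_tumor = 120, n_genes = 5, n_prognostic = 0,
                     n_de = 0)
  cl <- co$clinical
  uni <- cox_univariate(cl, "grade_group")
  multi <- cox_multivariate(cl, "grade_group")
  expect_equal(uni$table$beta, multi$table$beta, tolerance = 1e-8)
})

test_that("recoding the reference level negates beta exactly", {
  co <- small_cohort(seed = 22, n_tumor = 150, n_genes = 5, n_prognostic = 0,
                     n_de = 0)
  cl <- co$clinical
  cl$x <- as.integer(cl$grade_group == "G3&4")
  cl$x_flipped <- 1L - cl$x
  f1 <- cox_univariate(cl, "x")
  f2 <- cox_univariate(cl, "x_flipped")
  expect_equal(f1$table$beta, -f2$table$beta, tolerance = 1e-8)
  expect_equal(f1$table$hr, 1 / f2$table$hr, tolerance = 1e-8)
})

test_that("unknown covariate levels are dropped listwise with n_used reported", {
  co <- small_cohort(seed = 23, n_tumor = 200, n_genes = 5, n_prognostic = 0,
                     n_de = 0)
  fit <- cox_univariate(co$clinical, "m_status")
  expect_lt(fit$n_used, nrow(co$clinical))
  expect_equal(fit$n_used, sum(co$clinical$m_status %in% c("M0", "M1")))
})

test_that("separation is detected and reported", {
  cl <- toy_clinical(time = c(1, 2, 3, 4, 100, 110, 120, 130),
                     event = c(1, 1, 1, 1, 1, 1, 1, 1))
  cl$x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_error(cox_univariate(cl, "x"), "converge|separation")
})

test_that("cox screen applies the p < 0.05 carry-forward rule", {
  co <- small_cohort(seed = 24, n_tumor = 400, n_genes = 5, n_prognostic = 0,
                     n_de = 0)
  cl <- co$clinical
  # plant one strong predictor and one pure-noise column
  withr::with_seed(25, cl$noise <- rbinom(nrow(cl), 1, 0.5))
  risk <- rank(cl$os_time) <= nrow(cl) / 2
  cl$planted <- ifelse(risk, 1L,
                       withr::with_seed(26, rbinom(nrow(cl), 1, 0.2)))
  scr <- cox_screen(cl, c("planted", "noise"))
  expect_true("planted" %in% scr$selected)
  expect_false("noise" %in% scr$selected)
  expect_equal(scr$multivariate$table$variable, scr$selected)
})

test_that("concordance index honors its invariants", {
  withr::with_seed(27, {
    t <- sample(1:100, 50)
    cl <- toy_clinical(time = t, event = rep(1, 50))
  })
  perfect_risk <- -t                   # earlier failure = higher risk
  expect_equal(concordance_index(perfect_risk, cl), 1)
  expect_equal(concordance_index(-perfect_risk, cl), 0)
  expect_equal(concordance_index(t, cl, higher = "survival"), 1)
  expect_equal(concordance_index(rep(1, 50), cl), 0.5)
  # invariance to strictly monotone transforms
  withr::with_seed(28, s <- rnorm(50))
  expect_equal(concordance_index(s, cl),
               concordance_index(exp(3 * s) + 2, cl))
  expect_error(concordance_index(s, cl[1, , drop = FALSE][0, ]), "per sample")
  cl0 <- toy_clinical(time = c(5, 10), event = c(0, 0))
  expect_error(concordance_index(c(1, 2), cl0), "comparable")
})

test_that("hand-rolled concordance matches the survival package on censored data", {
  withr::with_seed(29, {
    n <- 120
    lp <- rnorm(n)
    t <- rexp(n, exp(lp)) + seq(0, 1e-4, length.out = n)  # break ties
    cens <- rexp(n, 0.5)
    cl <- toy_clinical(time = pmin(t, cens),
                       event = as.integer(t <= cens))
  })
  ours <- concordance_index(lp, cl, higher = "risk")
  ref <- survival::concordance(
    survival::Surv(cl$os_time, cl$os_event) ~ lp, reverse = TRUE)$concordance
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("random scores give concordance near one half", {
  co <- small_cohort(seed = 30, n_tumor = 500, n_genes = 5, n_prognostic = 0,
                     n_de = 0, censor_rate = 0.3)
  cs <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s,
                     concordance_index(rnorm(500), co$clinical))
  }, 0)
  expect_lt(abs(mean(cs) - 0.5), 0.03)
})

fit_nomogram_cohort <- function(seed = 31, n = 400) {
  co <- small_cohort(seed = seed, n_tumor = n, n_genes = 5,
                     n_prognostic = 0, n_de = 0, censor_rate = 0.3)
  cl <- co$clinical
  cl$age_bin <- as.integer(cl$age_group == "older")
  cl$stage_bin <- as.integer(cl$stage_group == "III&IV")
  cl
}

test_that("nomogram point scales normalize to 100 and round-trip the Cox model", {
  cl <- fit_nomogram_cohort()
  # plant hazard structure so the betas are non-trivial
  fit <- cox_multivariate(cl, c("age_group", "grade_group", "stage_group"))
  nom <- suppressMessages(build_nomogram(fit))
  expect_equal(max(nom$points$span), 100)
  expect_equal(nom$points$span[which.max(abs(nom$points$beta))], 100)
  # round trip: total points -> lp -> S(t) equals the direct prediction
  for (h in nom$horizons) {
    direct <- baseline_surv <- NULL
    s0 <- mpscore:::baseline_survival_at(fit$baseline, h)
    direct <- s0^exp(nom$predicted$lp)
    via_points <- nomogram_predict(nom, nom$predicted$total_points, h)
    expect_equal(via_points, direct, tolerance = 1e-6)
  }
  # a reference-profile sample (lp = 0) gets the baseline survival
  expect_equal(nomogram_predict(
    nom, (0 - nom$point_scale$lp_at_zero_points) /
      nom$point_scale$lp_per_point, nom$horizons[1]),
    mpscore:::baseline_survival_at(fit$baseline, nom$horizons[1]))
  expect_error(build_nomogram(
    structure(list(table = data.frame(beta = 0)), class = "mps_coxfit")),
    "zero")
})

test_that("calibration produces bins covering all samples; n_boot 0 is apparent only", {
  cl <- fit_nomogram_cohort(seed = 32, n = 500)
  fit <- cox_multivariate(cl, c("age_group", "stage_group", "grade_group"))
  nom <- suppressMessages(build_nomogram(fit))
  h <- 2 * 365.25
  cal0 <- calibration(nom, h, n_boot = 0)
  expect_equal(sum(cal0$n), fit$n_used)
  expect_identical(cal0$observed_corrected, cal0$observed)
  expect_true(all(cal0$predicted >= 0 & cal0$predicted <= 1))
  expect_true(all(cal0$observed >= 0 & cal0$observed <= 1))
  cal <- calibration(nom, h, n_boot = 25, seed = 2)
  expect_false(identical(cal$observed_corrected, cal$observed))
  expect_error(calibration(nom, 1e9, n_boot = 0), "beyond last observed")
})
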