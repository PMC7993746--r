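# Survival evaluation: Kaplan-Meier / log-rank by stratum, univariate ->
# multivariate Cox with the p < 0.05 carry-forward rule, Harrell's
# concordance index, and a points-based nomogram for 3-/5-year overall
# survival with bootstrap calibration.

#' Kaplan-Meier curves and log-rank test by group
#'
#' @param clinical An `mps_clinical` (or data frame with `os_time`,
#'   `os_event`).
#' @param groups Per-sample group labels (>= 2 distinct groups).
#' @return List: `curves` (per group: `time`, `surv`, `n_risk`),
#'   `statistic` (k-group log-rank chi-square), `df`, `p`.
#' @export
km_logrank <- function(clinical, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups for a log-rank test", call. = FALSE)
  if (sum(clinical$os_event) < 1L) stop("no events", call. = FALSE)
  s <- survival::Surv(clinical$os_time, clinical$os_event)
  fit <- survival::survfit(s ~ groups)
  sd <- survival::survdiff(s ~ groups)
  df <- nlevels(groups) - 1L
  strata_id <- rep(names(fit$strata), fit$strata)
  curves <- lapply(levels(groups), function(g) {
    sel <- strata_id == paste0("groups=", g)
    list(group = g, time = fit$time[sel], surv = fit$surv[sel],
         n_risk = fit$n.risk[sel])
  })
  names(curves) <- levels(groups)
  list(curves = curves, statistic = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

# Encode the standard dichotomous clinical covariates (plus any numeric or
# ready-made 0/1 column) into a complete-case 0/1 model matrix. Unknown /
# NX / MX levels become NA and are handled listwise by the caller.
encode_covariates <- function(clinical, variables) {
  cols <- lapply(variables, function(v) {
    if (!v %in% names(clinical))
      stop("unknown variable: ", v, call. = FALSE)
    col <- clinical[[v]]
    if (is.numeric(col)) {
      as.numeric(col)
    } else if (v %in% names(COVARIATE_CODING)) {
      coding <- COVARIATE_CODING[[v]]
      out <- ifelse(col == coding[["risk"]], 1,
                    ifelse(col == coding[["ref"]], 0, NA))
      as.numeric(out)
    } else if (is.factor(col) || is.character(col)) {
      lv <- sort(unique(as.character(col[!is.na(col)])))
      if (length(lv) != 2L)
        stop(sprintf("variable '%s' is not dichotomous (levels: %s)", v,
                     paste(lv, collapse = ", ")), call. = FALSE)
      as.numeric(as.character(col) == lv[2L])
    } else stop("cannot encode variable: ", v, call. = FALSE)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- variables
  m
}

cox_fit_core <- function(clinical, variables, type) {
  xm <- encode_covariates(clinical, variables)
  keep <- complete.cases(xm) & !is.na(clinical$os_time)
  n_used <- sum(keep)
  if (n_used < length(variables) + 2L)
    stop("too few complete cases (", n_used, ")", call. = FALSE)
  dat <- data.frame(os_time = clinical$os_time[keep],
                    os_event = clinical$os_event[keep],
                    xm[keep, , drop = FALSE], check.names = FALSE)
  f <- as.formula(paste("survival::Surv(os_time, os_event) ~",
                        paste(sprintf("`%s`", variables), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(f, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w)))
        stop("Cox fit failed to converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      suppressWarnings(survival::coxph(f, data = dat, ties = "efron"))
    })
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    stop("separation detected: |beta| diverges", call. = FALSE)
  tab <- data.frame(
    variable = variables,
    beta = unname(beta),
    hr = unname(exp(beta)),
    ci_low = unname(exp(beta - qnorm(0.975) * se)),
    ci_high = unname(exp(beta + qnorm(0.975) * se)),
    p = unname(2 * stats::pnorm(-abs(beta / se))),
    stringsAsFactors = FALSE)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(table = tab, type = type, n_used = n_used,
                 baseline = data.frame(time = bh$time,
                                       surv = exp(-bh$hazard)),
                 data = dat, fit = fit),
            class = "mps_coxfit")
}

#' Univariate and multivariate Cox proportional-hazards fits
#'
#' Covariates are the dichotomies used throughout (grade 3&4 vs 1&2, stage
#' III&IV vs I&II, M1 vs M0, ...; unknown levels dropped listwise, `n_used`
#' reported). Partial-likelihood fit with Efron tie handling, Wald CIs and
#' p-values, and the Breslow baseline survival of the reference profile.
#'
#' @param clinical An `mps_clinical` (possibly with extra 0/1 or
#'   dichotomous columns such as an mPS group).
#' @param variable,variables Column name(s) to model.
#' @return An `mps_coxfit`: `table` (beta, hr, ci_low, ci_high, p per
#'   variable), `type`, `n_used`, `baseline` (time, surv).
#' @export
cox_univariate <- function(clinical, variable) {
  cox_fit_core(clinical, variable, "univariate")
}

#' @rdname cox_univariate
#' @export
cox_multivariate <- function(clinical, variables) {
  cox_fit_core(clinical, variables, "multivariate")
}

#' @export
print.mps_coxfit <- function(x, ...) {
  cat(sprintf("<mps_coxfit> %s, n_used = %d\n", x$type, x$n_used))
  print(x$table, digits = 3)
  invisible(x)
}

#' Univariate screen with p < 0.05 carry-forward into a multivariate model
#'
#' Fits a univariate Cox model per variable; variables significant at
#' `alpha` are entered together into one multivariate model.
#'
#' @param clinical An `mps_clinical`.
#' @param variables Candidate variable names.
#' @param alpha Carry-forward level (default 0.05).
#' @return List: `univariate` (list of fits), `selected` (variable names),
#'   `multivariate` (fit, or NULL if nothing selected).
#' @export
cox_screen <- function(clinical, variables, alpha = 0.05) {
  uni <- lapply(variables, function(v) cox_univariate(clinical, v))
  names(uni) <- variables
  pvals <- vapply(uni, function(f) f$table$p[1L], 0)
  selected <- variables[pvals < alpha]
  multi <- if (length(selected)) cox_multivariate(clinical, selected) else NULL
  list(univariate = uni, selected = selected, multivariate = multi)
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs (the sample with the strictly earlier
#' observed time had an event) in which the predictions are concordant
#' with the outcome; prediction ties count 0.5. The orientation flag
#' declares whether a higher score means higher risk (earlier failure) or
#' higher survival.
#'
#' @param scores One numeric score per sample.
#' @param clinical An `mps_clinical` aligned with `scores`.
#' @param higher `"risk"` (default): higher score is expected to fail
#'   earlier; `"survival"`: higher score is expected to survive longer.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(scores, clinical,
                              higher = c("risk", "survival")) {
  higher <- match.arg(higher)
  if (length(scores) != nrow(clinical))
    stop("one score per sample required", call. = FALSE)
  if (higher == "survival") scores <- -scores
  t <- clinical$os_time; e <- clinical$os_event
  n <- length(t)
  conc <- 0; comp <- 0
  for (i in which(e == 1L)) {
    later <- t > t[i]               # comparable: i fails strictly first
    m <- sum(later)
    if (!m) next
    comp <- comp + m
    conc <- conc + sum(scores[i] > scores[later]) +
      0.5 * sum(scores[i] == scores[later])
  }
  if (comp == 0) stop("no comparable pairs", call. = FALSE)
  conc / comp
}

#' Build a points-based nomogram from a multivariate Cox fit
#'
#' Each variable's point span is `100 |beta_i| range_i / max_j(|beta_j|
#' range_j)` (range 1 for the 0/1 dichotomies), so the most influential
#' variable spans exactly 100 points. Total points map affinely back to
#' the Cox linear predictor, and predicted survival at the horizons is
#' `S0(t)^exp(lp)` with the Breslow baseline. Harrell's C on the fitting
#' cohort is attached.
#'
#' @param fit An `mps_coxfit` (multivariate, >= 1 variable).
#' @param horizons Prediction horizons in days (default 3 and 5 years).
#' @return List of class `mps_nomogram`: `points` (per variable x level),
#'   `point_scale` (lp per point, intercept), `baseline`, `horizons`,
#'   `predicted` (per sample: lp, total points, survival per horizon),
#'   `c_index`.
#' @export
build_nomogram <- function(fit, horizons = c(3, 5) * 365.25) {
  stopifnot(inherits(fit, "mps_coxfit"))
  beta <- fit$table$beta
  if (all(beta == 0)) stop("all coefficients are zero", call. = FALSE)
  vars <- fit$table$variable
  xm <- as.matrix(fit$data[, vars, drop = FALSE])
  rng <- apply(xm, 2L, function(c) diff(range(c)))
  rng[rng == 0] <- 1
  span <- abs(beta) * rng
  max_span <- max(span)
  points <- data.frame(variable = vars,
                       points_per_unit = 100 * abs(beta) * 1 / max_span,
                       span = 100 * span / max_span,
                       beta = beta, stringsAsFactors = FALSE)
  # per-sample: points_i(x) = 100 (beta_i x - min_level beta_i x) / max_span
  lo <- apply(xm, 2L, min); hi <- apply(xm, 2L, max)
  min_contrib <- pmin(beta * lo, beta * hi)
  lp <- as.numeric(xm %*% beta)
  total_points <- 100 * (lp - sum(min_contrib)) / max_span
  if (max(fit$baseline$time) < max(horizons))
    warning("horizon beyond last baseline time; using last value",
            call. = FALSE)
  s0 <- baseline_survival_at(fit$baseline, horizons)
  surv <- sapply(seq_along(horizons), function(j) s0[j]^exp(lp))
  surv <- matrix(surv, ncol = length(horizons))
  colnames(surv) <- paste0("s_", round(horizons))
  cidx <- concordance_index(lp, fit$data, higher = "risk")
  message(sprintf("nomogram C-index %.3f (>= 0.70 is conventionally a good fit)",
                  cidx))
  structure(list(points = points,
                 point_scale = list(lp_per_point = max_span / 100,
                                    lp_at_zero_points = sum(min_contrib)),
                 baseline = fit$baseline, horizons = horizons,
                 predicted = data.frame(lp = lp, total_points = total_points,
                                        surv, check.names = FALSE),
                 variables = vars, fit = fit, c_index = cidx),
            class = "mps_nomogram")
}

# Step-function lookup of baseline survival (right-continuous; 1 before
# the first event time).
baseline_survival_at <- function(baseline, times) {
  f <- stepfun(baseline$time, c(1, baseline$surv), right = FALSE)
  f(times)
}

#' Predict survival from a nomogram via total points
#'
#' Maps total points back to the linear predictor and evaluates
#' `S0(t)^exp(lp)` at a horizon; the round trip reproduces the direct Cox
#' prediction.
#'
#' @param nomogram An `mps_nomogram`.
#' @param total_points Numeric vector of total points.
#' @param horizon Horizon in days.
#' @return Predicted survival probabilities.
#' @export
nomogram_predict <- function(nomogram, total_points, horizon) {
  lp <- nomogram$point_scale$lp_at_zero_points +
    total_points * nomogram$point_scale$lp_per_point
  s0 <- baseline_survival_at(nomogram$baseline, horizon)
  s0^exp(lp)
}

#' Calibration of nomogram predictions at a horizon
#'
#' Samples are binned by predicted survival (tertiles by default); the
#' observed survival per bin is the Kaplan-Meier estimate at the horizon.
#' With `n_boot > 0` the Cox model is refit on bootstrap resamples and the
#' per-bin optimism of (observed - predicted) is subtracted from the
#' apparent observed values.
#'
#' @param nomogram An `mps_nomogram`.
#' @param horizon Horizon in days (must be within follow-up).
#' @param n_boot Bootstrap resamples (default 200; 0 = apparent curve only).
#' @param bins Number of predicted-risk bins (default 3).
#' @param seed Seed for the bootstrap.
#' @return Data frame (class `mps_calibration`): per bin mean `predicted`,
#'   apparent `observed`, `observed_corrected`, `n`, plus attributes
#'   `horizon` and `n_boot`.
#' @export
calibration <- function(nomogram, horizon, n_boot = 200, bins = 3,
                        seed = 1L) {
  stopifnot(inherits(nomogram, "mps_nomogram"))
  fit <- nomogram$fit
  if (horizon > max(fit$data$os_time))
    stop("horizon beyond last observed time", call. = FALSE)
  apparent <- calibration_bins(fit, horizon, bins)
  out <- apparent
  out$observed_corrected <- out$observed
  if (n_boot > 0) {
    optimism <- withr::with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(fit$data), replace = TRUE)
        boot_clin <- fit$data[idx, , drop = FALSE]
        boot_clin$sample_id <- seq_len(nrow(boot_clin))
        bf <- tryCatch(
          cox_fit_core(boot_clin, nomogram$variables, "multivariate"),
          error = function(e) NULL)
        if (is.null(bf)) return(rep(NA_real_, bins))
        on_boot <- calibration_bins(bf, horizon, bins)
        on_orig <- calibration_bins(bf, horizon, bins, newdata = fit$data)
        (on_boot$observed - on_boot$predicted) -
          (on_orig$observed - on_orig$predicted)
      }, numeric(bins))
      rowMeans(reps, na.rm = TRUE)
    })
    out$observed_corrected <- out$observed - optimism
  }
  attr(out, "horizon") <- horizon
  attr(out, "n_boot") <- n_boot
  class(out) <- c("mps_calibration", "data.frame")
  out
}

# Apparent calibration of a cox fit on its own (or new) data at `horizon`.
calibration_bins <- function(fit, horizon, bins, newdata = NULL) {
  dat <- if (is.null(newdata)) fit$data else newdata
  xm <- as.matrix(dat[, fit$table$variable, drop = FALSE])
  lp <- as.numeric(xm %*% fit$table$beta)
  pred <- baseline_survival_at(fit$baseline, horizon)^exp(lp)
  qs <- quantile(pred, probs = seq(0, 1, length.out = bins + 1L))
  qs[1L] <- -Inf; qs[length(qs)] <- Inf
  bin <- cut(pred, breaks = unique(qs), labels = FALSE, include.lowest = TRUE)
  res <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    km <- survival::survfit(survival::Surv(dat$os_time[sel],
                                           dat$os_event[sel]) ~ 1)
    obs <- if (length(km$time) == 0L || horizon < min(km$time)) 1
           else stepfun(km$time, c(1, km$surv), right = FALSE)(horizon)
    flagged <- sum(dat$os_time[sel] >= horizon) == 0 &&
      sum(dat$os_event[sel] & dat$os_time[sel] <= horizon) == 0
    data.frame(bin = b, predicted = mean(pred[sel]), observed = obs,
               n = sum(sel), flagged = flagged)
  })
  do.call(rbind, res)
}
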