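#' Specify a trend model
#'
#' Describes one repeated cross-sectional model: an outcome regressed on
#' survey wave (categorical, baseline reference) with optional race/ethnicity
#' adjustment, a school random intercept, cluster-robust standard errors, and
#' Bonferroni-corrected two-sided contrasts of each post-baseline wave against
#' baseline.
#'
#' @param outcome column name of the outcome (`"daily_consumer"` for the
#'   logistic family; `"total_kcal"` or a per-drink `kcal_<drink>` column for
#'   the linear family).
#' @param family `"logistic"` or `"linear"`; must match the outcome type.
#' @param baseline baseline wave label; default the first wave in sort order.
#' @param covariates adjustment covariates; default `"race_ethnicity"`,
#'   use `character(0)` for unadjusted (e.g. race-stratified) models.
#' @param alpha significance level for the Bonferroni-corrected contrasts.
#' @param conditional if `TRUE`, report prevalence conditional on a zero school
#'   random effect instead of the population-averaged default.
#' @param robust if `TRUE` (default) use school-cluster-robust standard errors
#'   built on per-school marginal-likelihood scores; otherwise model-based.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(outcome, family = c("logistic", "linear"),
                       baseline = NULL, covariates = "race_ethnicity",
                       alpha = 0.01, conditional = FALSE, robust = TRUE) {
  family <- match.arg(family)
  structure(list(outcome = outcome, family = family, baseline = baseline,
                 covariates = covariates, alpha = alpha,
                 conditional = conditional, robust = robust),
            class = "model_spec")
}

#' Exclude survey waves with low response rates
#'
#' @param data survey or scored data frame with a `wave` column.
#' @param response_rates named numeric vector (or data frame with `wave`,
#'   `response_rate`) giving each wave's response rate in `[0, 1]`.
#' @param min_rate waves with a rate strictly below this are dropped
#'   (default 0.5).
#' @return The filtered data; attribute `excluded_waves` lists what was
#'   dropped and why.
#' @export
exclude_low_response_waves <- function(data, response_rates, min_rate = 0.5) {
  if (is.data.frame(response_rates)) {
    response_rates <- stats::setNames(response_rates$response_rate,
                                      response_rates$wave)
  }
  waves <- unique(as.character(data$wave))
  miss <- setdiff(waves, names(response_rates))
  if (length(miss)) stop("no response rate for wave(s): ",
                         paste(miss, collapse = ", "))
  drop <- waves[response_rates[waves] < min_rate]
  out <- data[!(as.character(data$wave) %in% drop), , drop = FALSE]
  if (nrow(out) == 0) stop("all waves excluded at min_rate = ", min_rate)
  attr(out, "excluded_waves") <-
    data.frame(wave = drop, response_rate = unname(response_rates[drop]),
               stringsAsFactors = FALSE)
  out
}

#' Fit a wave-trend prevalence model (random-intercept logistic)
#'
#' Estimates the percent of students with a binary outcome (daily sugary-drink
#' consumption) in each wave from a logistic regression on wave (and optional
#' race adjustment) with a school random intercept. Wave estimates are
#' population-averaged: predicted probabilities, integrated over the random
#' intercept distribution, averaged over the analysis sample's covariate
#' distribution, on the percent scale. Each post-baseline wave is compared to
#' baseline with a two-sided Wald test on the wave coefficient using
#' cluster-robust standard errors, Bonferroni-corrected over the post-baseline
#' waves.
#'
#' @param data scored data frame with the outcome, `wave`, `school_id` and any
#'   covariate columns.
#' @param spec a [model_spec()] with `family = "logistic"`.
#' @return An `estimate_table` data frame: one row per wave with `estimate`
#'   (percent), `ci_low`, `ci_high`, `n`, `diff_vs_baseline`, `p_raw`,
#'   `p_bonferroni`, `significant`. Attributes carry the spec, the fitted
#'   variance components and convergence notes.
#' @export
fit_prevalence_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"), spec$family == "logistic")
  fit_trend_model(data, spec)
}

#' Fit a wave-trend calorie model (random-intercept linear)
#'
#' Linear analogue of [fit_prevalence_model()] for daily calories: wave
#' estimates are model-based wave means (kcal/day) at the analysis sample's
#' covariate composition, with cluster-robust standard errors and Bonferroni
#' contrasts versus baseline. Non-consumers enter as zeros.
#'
#' @inheritParams fit_prevalence_model
#' @param spec a [model_spec()] with `family = "linear"`.
#' @return An `estimate_table` data frame, estimates on the kcal/day scale.
#' @export
fit_calorie_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"), spec$family == "linear")
  fit_trend_model(data, spec)
}

fit_trend_model <- function(data, spec) {
  need <- c(spec$outcome, "wave", "school_id", spec$covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data is missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- data[need]
  names(df)[1] <- ".y"
  df$.y <- if (spec$family == "logistic") as.numeric(df$.y) else df$.y
  if (spec$family == "logistic" && !all(df$.y %in% c(0, 1))) {
    stop("logistic family requires a binary outcome")
  }

  # students with missing covariates are dropped from adjusted models, logged
  dropped <- 0L
  if (length(spec$covariates)) {
    cc <- stats::complete.cases(df[spec$covariates])
    dropped <- sum(!cc)
    df <- df[cc, , drop = FALSE]
  }
  waves <- sort(unique(as.character(df$wave)))
  if (length(waves) < 2) stop("need at least two waves to fit a trend model")
  baseline <- if (is.null(spec$baseline)) waves[1] else as.character(spec$baseline)
  if (!(baseline %in% waves)) stop("baseline wave '", baseline, "' not in data")
  df$wave <- stats::relevel(factor(df$wave, levels = waves), ref = baseline)
  df$school_id <- factor(df$school_id)
  for (v in spec$covariates) df[[v]] <- factor(df[[v]])

  rhs <- paste(c("wave", spec$covariates), collapse = " + ")
  fixed_formula <- stats::as.formula(paste(".y ~", rhs))
  n_schools <- nlevels(df$school_id)
  single_school <- n_schools < 2

  notes <- character(0)
  if (spec$family == "logistic") {
    if (single_school) {
      fit <- stats::glm(fixed_formula, family = stats::binomial(), data = df)
      beta <- stats::coef(fit); sigma <- 0
    } else {
      ff <- stats::as.formula(paste(".y ~", rhs, "+ (1 | school_id)"))
      # adaptive Gauss-Hermite for small samples; Laplace once clusters are
      # large enough for it to be accurate (and much faster)
      nagq <- if (nrow(df) <= 500) 25L else 1L
      fit <- withCallingHandlers(
        lme4::glmer(ff, data = df, family = stats::binomial(), nAGQ = nagq),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
        })
      beta <- lme4::fixef(fit)
      sigma <- attr(lme4::VarCorr(fit)$school_id, "stddev")[[1]]
    }
    if (any(abs(beta) > 15)) {
      stop("apparent separation: coefficient(s) diverging for ",
           paste(names(beta)[abs(beta) > 15], collapse = ", "))
    }
  } else {
    if (single_school) {
      fit <- stats::lm(fixed_formula, data = df)
      beta <- stats::coef(fit)
      sig_e <- summary(fit)$sigma; tau <- 0
    } else {
      ff <- stats::as.formula(paste(".y ~", rhs, "+ (1 | school_id)"))
      fit <- withCallingHandlers(
        lme4::lmer(ff, data = df, REML = FALSE),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
        })
      beta <- lme4::fixef(fit)
      tau <- attr(lme4::VarCorr(fit)$school_id, "stddev")[[1]]
      sig_e <- stats::sigma(fit)
    }
  }
  if (anyNA(beta)) stop("model is rank deficient; check the stratum cells")

  X <- stats::model.matrix(fixed_formula, df)
  stopifnot(identical(colnames(X), names(beta)))
  y <- df$.y
  cl <- df$school_id

  # parameter vector for the sandwich: variance components enter on the log
  # scale and are dropped when degenerate (boundary/single school)
  if (spec$family == "logistic") {
    has_sigma <- !single_school && sigma > 1e-6
    params <- if (has_sigma) c(beta, log(sigma)) else beta
    llfun <- if (has_sigma) {
      function(p) logit_cluster_loglik(p, X, y, cl)
    } else {
      function(p) logit_cluster_loglik(c(p, log(1e-12)), X, y, cl)
    }
  } else {
    has_sigma <- !single_school && tau > 1e-6
    params <- if (has_sigma) c(beta, log(sig_e), log(tau)) else c(beta, log(sig_e))
    llfun <- if (has_sigma) {
      function(p) linear_cluster_loglik(p, X, y, cl)
    } else {
      function(p) linear_cluster_loglik(c(p, log(1e-12)), X, y, cl)
    }
  }
  V <- if (spec$robust && !single_school) {
    cluster_robust_vcov(params, llfun)
  } else {
    model_vcov(fit, params, spec$family, single_school)
  }

  # wave estimates at the sample covariate composition
  k <- length(beta)
  wave_cols <- paste0("wave", setdiff(waves, baseline))
  est_fn <- function(p, w) {
    b <- p[seq_len(k)]
    Xw <- X
    Xw[, wave_cols] <- 0
    if (w != baseline) Xw[, paste0("wave", w)] <- 1
    eta <- drop(Xw %*% b)
    if (spec$family == "logistic") {
      s <- if (has_sigma) exp(p[k + 1]) else 0
      pr <- if (spec$conditional || s == 0) stats::plogis(eta)
            else pa_probability(eta, s)
      100 * mean(pr)
    } else {
      mean(eta)
    }
  }
  # clustered inference uses t quantiles with G-1 degrees of freedom (the
  # standard small-sample practice for cluster-robust errors); single-school
  # fits fall back to normal quantiles
  dfree <- if (single_school) Inf else n_schools - 1
  zq <- stats::qt(0.975, df = dfree)
  tab <- do.call(rbind, lapply(waves, function(w) {
    est <- est_fn(params, w)
    g <- numeric_jacobian(function(p) est_fn(p, w), params)
    se <- sqrt(drop(g %*% V %*% t(g)))
    if (spec$family == "logistic" && est > 0 && est < 100) {
      # Wald on the logit scale, transformed back to percent
      pr <- est / 100
      se_l <- (se / 100) / (pr * (1 - pr))
      lo <- 100 * stats::plogis(stats::qlogis(pr) - zq * se_l)
      hi <- 100 * stats::plogis(stats::qlogis(pr) + zq * se_l)
    } else {
      lo <- est - zq * se
      hi <- est + zq * se
    }
    data.frame(wave = w, n = sum(as.character(df$wave) == w),
               estimate = est, ci_low = lo, ci_high = hi,
               stringsAsFactors = FALSE)
  }))

  # Bonferroni contrasts vs baseline on the wave coefficients (link scale)
  m <- length(wave_cols)
  tab$diff_vs_baseline <- tab$estimate - tab$estimate[tab$wave == baseline]
  tab$p_raw <- NA_real_
  tab$p_bonferroni <- NA_real_
  for (w in setdiff(waves, baseline)) {
    j <- match(paste0("wave", w), names(beta))
    z <- beta[j] / sqrt(V[j, j])
    p <- 2 * stats::pt(-abs(z), df = dfree)
    tab$p_raw[tab$wave == w] <- p
    tab$p_bonferroni[tab$wave == w] <- min(1, m * p)
  }
  tab$significant <- !is.na(tab$p_bonferroni) & tab$p_bonferroni < spec$alpha

  structure(tab, class = c("estimate_table", "data.frame"),
            spec = spec, baseline = baseline, m_contrasts = m,
            sigma_school = if (spec$family == "logistic") sigma else tau,
            sigma_resid = if (spec$family == "linear") sig_e else NULL,
            n_dropped_missing_covariates = dropped,
            convergence_notes = notes)
}

model_vcov <- function(fit, params, family, single_school) {
  Vb <- as.matrix(stats::vcov(fit))
  V <- matrix(0, length(params), length(params))
  kb <- nrow(Vb)
  V[seq_len(kb), seq_len(kb)] <- Vb
  # variance-component uncertainty omitted in the model-based fallback
  V
}

#' Stratified trend analyses
#'
#' Fits the model of `spec` separately within strata defined by race/ethnicity,
#' retail-exposure group, or their crossing. Following the convention that
#' full-sample models adjust for race while race-stratified models do not,
#' race adjustment is removed automatically from any stratum conditioned on
#' race. Empty strata are reported and skipped.
#'
#' @param data scored data frame; needs `high_exposure` (see
#'   [join_exposure()]) when stratifying on exposure.
#' @param spec a [model_spec()].
#' @param by one of `"race"`, `"exposure"`, `c("race", "exposure")`.
#' @return Named list of `estimate_table`s (names like `"Black"`, `"high"`,
#'   `"Black:low"`); attribute `skipped` lists empty strata.
#' @export
stratified_analysis <- function(data, spec, by = "race") {
  by <- match.arg(by, c("race", "exposure"), several.ok = TRUE)
  if ("exposure" %in% by && !("high_exposure" %in% names(data))) {
    stop("data has no 'high_exposure' column; join an exposure map first ",
         "(see join_exposure)")
  }
  keys <- list()
  if ("race" %in% by) keys$race <- sort(unique(data$race_ethnicity))
  if ("exposure" %in% by) keys$exposure <- c("high", "low")
  grid <- expand.grid(keys, stringsAsFactors = FALSE)

  out <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(grid))) {
    sel <- rep(TRUE, nrow(data))
    label <- character(0)
    if (!is.null(grid$race)) {
      sel <- sel & data$race_ethnicity == grid$race[i]
      label <- c(label, grid$race[i])
    }
    if (!is.null(grid$exposure)) {
      sel <- sel & (data$high_exposure == (grid$exposure[i] == "high"))
      label <- c(label, grid$exposure[i])
    }
    label <- paste(label, collapse = ":")
    sub <- data[sel & !is.na(sel), , drop = FALSE]
    if (nrow(sub) == 0) { skipped <- c(skipped, label); next }
    sspec <- spec
    if (!is.null(grid$race)) {
      sspec$covariates <- setdiff(spec$covariates, "race_ethnicity")
    }
    out[[label]] <- tryCatch(fit_trend_model(sub, sspec), error = function(e) {
      skipped <<- c(skipped, paste0(label, " (", conditionMessage(e), ")"))
      NULL
    })
  }
  out <- Filter(Negate(is.null), out)
  attr(out, "skipped") <- skipped
  out
}

#' Join retail-exposure classifications onto a scored cohort
#'
#' @param scored scored data frame with `school_id`.
#' @param exposure an `exposure_map` from [classify_zones()].
#' @param membership data frame with `school_id`, `zone_id` (e.g. from
#'   [zone_membership()]).
#' @return `scored` with `zone_id` and logical `high_exposure` columns.
#' @export
join_exposure <- function(scored, exposure, membership) {
  m <- match(as.character(scored$school_id), as.character(membership$school_id))
  if (anyNA(m)) {
    stop("no zone membership for school(s): ",
         paste(unique(scored$school_id[is.na(m)]), collapse = ", "))
  }
  scored$zone_id <- membership$zone_id[m]
  e <- match(scored$zone_id, exposure$zone_id)
  if (anyNA(e)) {
    stop("no exposure classification for zone(s): ",
         paste(unique(scored$zone_id[is.na(e)]), collapse = ", "))
  }
  scored$high_exposure <- exposure$high_exposure[e]
  scored
}

#' Pooled high-vs-low exposure difference in daily consumption
#'
#' Welch two-sample t-test on the daily-consumer indicator between students in
#' high versus low exposure zones, pooled over the analysis waves.
#'
#' @param scored scored data frame with `daily_consumer` and `high_exposure`.
#' @return list with `diff_pp` (mean difference high - low, percentage
#'   points), `t`, `df`, `p`, and group means `mean_high`, `mean_low` (%).
#' @export
exposure_gap_ttest <- function(scored) {
  stopifnot(all(c("daily_consumer", "high_exposure") %in% names(scored)))
  hi <- as.numeric(scored$daily_consumer[scored$high_exposure])
  lo <- as.numeric(scored$daily_consumer[!scored$high_exposure])
  if (!length(hi) || !length(lo)) stop("one exposure group is empty")
  if (stats::var(hi) == 0 && stats::var(lo) == 0) {
    d <- 100 * (mean(hi) - mean(lo))
    return(list(diff_pp = d, t = if (d == 0) 0 else sign(d) * Inf,
                df = NA_real_, p = if (d == 0) 1 else 0,
                mean_high = 100 * mean(hi), mean_low = 100 * mean(lo)))
  }
  tt <- stats::t.test(hi, lo)
  list(diff_pp = 100 * (mean(hi) - mean(lo)),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_high = 100 * mean(hi), mean_low = 100 * mean(lo))
}

#' Chi-square test of race/ethnicity by exposure group
#'
#' Pearson chi-square (no continuity correction) on the race x high/low
#' exposure contingency table; with five race groups the test has 4 degrees of
#' freedom.
#'
#' @param data data frame with `race_ethnicity` and `high_exposure`.
#' @return list with `statistic`, `df`, `p` and the contingency `table`.
#' @export
race_zone_chisquare <- function(data) {
  tab <- table(data$race_ethnicity, data$high_exposure)
  if (nrow(tab) < 2 || ncol(tab) < 2 ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("race x exposure table has a zero or missing margin")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Sample-vs-population representativeness by race group
#'
#' Paired t-tests comparing, school by school, the share of each race group in
#' the analysed sample with its share in the full population of interest.
#'
#' @param sample_shares data frame: `school_id` plus one share column per race
#'   group.
#' @param population_shares data frame with the same shape.
#' @return data frame: `group`, `mean_diff` (sample - population), `t`, `df`,
#'   `p`.
#' @export
representativeness_test <- function(sample_shares, population_shares) {
  m <- match(sample_shares$school_id, population_shares$school_id)
  if (anyNA(m)) stop("population shares missing for some schools")
  if (nrow(sample_shares) < 2) stop("need at least two school pairs")
  groups <- setdiff(names(sample_shares), "school_id")
  do.call(rbind, lapply(groups, function(g) {
    d <- sample_shares[[g]] - population_shares[[g]][m]
    if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      return(data.frame(group = g, mean_diff = mean(d), t = t,
                        df = length(d) - 1,
                        p = if (mean(d) == 0) 1 else 0))
    }
    tt <- stats::t.test(d)
    data.frame(group = g, mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
}
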