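# Statistical layer: binomial mixed logistic model for diurnal arrivals,
# period-contrast and wind-assistance linear mixed models with
# Tukey-adjusted contrasts, the one-sample t test from summary statistics,
# the morning body-mass regression, and the fuel-fraction conversion.

new_model_result <- function(name, coefficients, ranef = NULL, n_obs = NA,
                             n_groups = NA, converged = TRUE, r2 = NULL,
                             contrasts = NULL, flags = character()) {
  structure(list(model = name, coefficients = coefficients, ranef = ranef,
                 n_obs = n_obs, n_groups = n_groups, converged = converged,
                 r2 = r2, contrasts = contrasts, flags = flags),
            class = "nx_model_result")
}

#' @export
print.nx_model_result <- function(x, ...) {
  cat("Model:", x$model, "\n")
  cat(sprintf("n = %s observations, %s groups; converged: %s\n",
              x$n_obs, x$n_groups, x$converged))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  if (!is.null(x$ranef)) {
    cat("Random effects:\n"); print(x$ranef, digits = 4, row.names = FALSE)
  }
  if (!is.null(x$contrasts)) {
    cat("Tukey-adjusted contrasts:\n")
    print(x$contrasts, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

coef_table <- function(m) {
  # uniform (term, estimate, se, statistic, p) table from a fitted model
  s <- if (inherits(m, "glmmTMB")) summary(m)$coefficients$cond else
    summary(m)$coefficients
  stat_col <- intersect(c("z value", "t value"), colnames(s))[1]
  p_col <- grep("^Pr", colnames(s), value = TRUE)
  data.frame(term = rownames(s), estimate = s[, "Estimate"],
             se = s[, "Std. Error"], statistic = s[, stat_col],
             p = if (length(p_col)) s[, p_col[1]] else NA_real_,
             row.names = NULL)
}

#' One-sample t test from summary statistics
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p-value.
#'
#' @param mean,sd,n sample summaries (`n >= 2`, `sd > 0`).
#' @param mu0 null value.
#' @return list `t`, `df`, `p`.
#' @export
#' @examples
#' one_sample_t(16.35, 5.19, 83, 10)  # t = 11.15, df = 82
one_sample_t <- function(mean, sd, n, mu0 = 0) {
  stopifnot(n >= 2, sd > 0)
  t <- (mean - mu0) / (sd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Fuel reserve as a fraction of lean mass
#'
#' @param mass_g observed body mass, g.
#' @param lean_mass_g population lean mass, g (mean mass of breeding birds
#'   carrying no fuel reserves).
#' @return `(mass - lean) / lean`.
#' @export
#' @examples
#' fuel_fraction(79.86)  # 0.12
fuel_fraction <- function(mass_g, lean_mass_g = 71.3) {
  if (any(mass_g <= 0) || lean_mass_g <= 0) stop("masses must be positive")
  (mass_g - lean_mass_g) / lean_mass_g
}

#' Morning body-mass regression
#'
#' Ordinary least squares of body mass on local trapping hour.
#'
#' @param trapping data frame `hour_local`, `mass_g` (at least 3 rows, hour
#'   variance > 0).
#' @return `nx_model_result` with the coefficient table and adjusted
#'   R-squared; the fitted `lm` is attached as attribute `fit`.
#' @export
fit_bodymass_ols <- function(trapping) {
  stopifnot(all(c("hour_local", "mass_g") %in% names(trapping)))
  if (nrow(trapping) < 3) stop("need at least 3 records")
  if (stats::var(trapping$hour_local) <= 0) stop("hour has no variance")
  m <- stats::lm(mass_g ~ hour_local, data = trapping)
  res <- new_model_result("bodymass_ols", coef_table(m),
                          n_obs = nrow(trapping),
                          r2 = list(adjusted = summary(m)$adj.r.squared))
  attr(res, "fit") <- m
  res
}

#' Mixed logistic model for diurnal arrivals
#'
#' `logit P(diurnal) = b0 + b1 owd_km + b2 v_g_ms + b3 completed_km +
#' u[individual]`, binomial family with an individual random intercept,
#' fitted by maximum likelihood (glmmTMB). Complete separation in the
#' response and non-convergence are flagged rather than silently reported.
#'
#' @param crossings data frame `owd_km`, `v_g_ms`, `completed_km`, `diurnal`
#'   (logical or 0/1), `individual`; at least two individuals.
#' @return `nx_model_result` (fitted model in attribute `fit`).
#' @export
fit_diurnal_glmm <- function(crossings) {
  need <- c("owd_km", "v_g_ms", "completed_km", "diurnal", "individual")
  stopifnot(all(need %in% names(crossings)))
  if (length(unique(crossings$individual)) < 2)
    stop("need at least two individuals for a random intercept")
  y <- as.integer(crossings$diurnal)
  flags <- character()
  if (length(unique(y)) < 2) {
    return(new_model_result("diurnal_glmm",
                            data.frame(term = character(), estimate = numeric(),
                                       se = numeric(), statistic = numeric(),
                                       p = numeric()),
                            n_obs = nrow(crossings),
                            n_groups = length(unique(crossings$individual)),
                            converged = FALSE,
                            flags = "complete separation: response is constant"))
  }
  m <- glmmTMB::glmmTMB(diurnal ~ owd_km + v_g_ms + completed_km + (1 | individual),
                        data = transform(crossings, diurnal = y),
                        family = stats::binomial())
  ct <- coef_table(m)
  conv <- isTRUE(m$fit$convergence == 0) && all(is.finite(ct$se))
  if (!conv) flags <- c(flags, "optimizer did not converge cleanly")
  # a boundary (zero-variance) random intercept makes the joint Hessian
  # singular without invalidating the fixed-effect estimates
  if (!isTRUE(m$sdr$pdHess))
    flags <- c(flags, "non-positive-definite joint Hessian (random-intercept variance at boundary)")
  if (isTRUE(any(ct$se > 50, na.rm = TRUE)))
    flags <- c(flags, "very large SEs: possible quasi-separation")
  vc <- glmmTMB::VarCorr(m)$cond$individual
  ranef <- data.frame(group = "individual", variance = as.numeric(vc[1, 1]),
                      sd = sqrt(as.numeric(vc[1, 1])))
  res <- new_model_result("diurnal_glmm", ct, ranef = ranef,
                          n_obs = nrow(crossings),
                          n_groups = length(unique(crossings$individual)),
                          converged = conv, flags = flags)
  attr(res, "fit") <- m
  res
}

emm_contrasts <- function(fit, spec) {
  em <- emmeans::emmeans(fit, spec)
  pc <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  names(pc)[names(pc) == "p.value"] <- "p"
  list(emmeans = as.data.frame(em), contrasts = pc)
}

#' Period-contrast linear mixed model on flight activity
#'
#' Mean flight activity per episode as the response, crossing period
#' (N1/D/N2) as a fixed factor, individual bird as a random intercept;
#' pairwise period differences with the Tukey adjustment on estimated
#' marginal means.
#'
#' @param periods data frame with `activity` (or `mean_activity`), `period`
#'   (levels among N1, D, N2) and `individual`.
#' @return `nx_model_result` with period estimates and Tukey-adjusted
#'   pairwise contrasts (fit attached as attribute `fit`).
#' @export
fit_period_lmm <- function(periods) {
  if (!"activity" %in% names(periods) && "mean_activity" %in% names(periods))
    periods$activity <- periods$mean_activity
  stopifnot(all(c("activity", "period", "individual") %in% names(periods)))
  if (!all(as.character(unique(periods$period)) %in% c("N1", "D", "N2")))
    stop("periods must be among N1, D, N2")
  periods$period <- factor(periods$period, levels = c("N1", "D", "N2"))
  periods$period <- droplevels(periods$period)
  if (length(unique(periods$individual)) < 2) {
    return(new_model_result("period_lmm",
                            data.frame(term = character(), estimate = numeric(),
                                       se = numeric(), statistic = numeric(),
                                       p = numeric()),
                            n_obs = nrow(periods), n_groups = 1,
                            converged = FALSE,
                            flags = "single individual: random intercept inestimable"))
  }
  m <- lmerTest::lmer(activity ~ period + (1 | individual), data = periods,
                  REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  ranef <- data.frame(group = vc$grp, variance = vc$vcov, sd = vc$sdcor)
  cc <- emm_contrasts(m, "period")
  res <- new_model_result("period_lmm", coef_table(m), ranef = ranef,
                          n_obs = nrow(periods),
                          n_groups = length(unique(periods$individual)),
                          converged = TRUE, contrasts = cc$contrasts)
  res$emmeans <- cc$emmeans
  attr(res, "fit") <- m
  res
}

#' Wind-assistance contrast model
#'
#' Derived (heading-compensated) ground speed as the response, altitude
#' condition (`surface`, `H1`, `H2`) as a fixed factor, track id as a random
#' intercept; Tukey-adjusted pairwise contrasts. Tracks missing any of the
#' three conditions are excluded with a warning.
#'
#' @param wind_summaries data frame `track`, `condition`, `groundspeed`.
#' @return `nx_model_result` with contrasts (fit in attribute `fit`).
#' @export
fit_wind_contrast_lmm <- function(wind_summaries) {
  stopifnot(all(c("track", "condition", "groundspeed") %in% names(wind_summaries)))
  wind_summaries$condition <- factor(wind_summaries$condition,
                                     levels = c("surface", "H1", "H2"))
  complete <- tapply(wind_summaries$condition, wind_summaries$track,
                     function(x) length(unique(x)) == 3)
  bad <- names(complete)[!complete]
  if (length(bad)) {
    warning("excluding track(s) missing a condition: ", paste(bad, collapse = ", "))
    wind_summaries <- wind_summaries[!wind_summaries$track %in% bad, ]
  }
  if (length(unique(wind_summaries$track)) < 2)
    stop("need at least two complete tracks")
  m <- lmerTest::lmer(groundspeed ~ condition + (1 | track), data = wind_summaries,
                  REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  cc <- emm_contrasts(m, "condition")
  res <- new_model_result("wind_contrast_lmm", coef_table(m),
                          ranef = data.frame(group = vc$grp, variance = vc$vcov,
                                             sd = vc$sdcor),
                          n_obs = nrow(wind_summaries),
                          n_groups = length(unique(wind_summaries$track)),
                          converged = TRUE, contrasts = cc$contrasts)
  res$emmeans <- cc$emmeans
  attr(res, "fit") <- m
  res
}
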