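#' PHQ-9 severity band
#'
#' Maps PHQ-9 total scores to the standard clinical severity categories:
#' minimal (0-4), mild (5-9), moderate (10-14), moderately severe (15-19),
#' severe (20-27). The five bands partition the 0-27 score range.
#'
#' @param phq Integer PHQ-9 score(s) in \[0, 27\].
#' @return A factor with levels minimal < mild < moderate <
#'   moderately severe < severe.
#' @export
severity_band <- function(phq) {
  if (any(is.na(phq)) || any(phq < 0 | phq > 27)) {
    stop("PHQ-9 scores must lie in [0, 27]")
  }
  cut(phq, breaks = c(-Inf, 4, 9, 14, 19, Inf),
      labels = c("minimal", "mild", "moderate", "moderately severe", "severe"),
      ordered_result = TRUE)
}

#' Percentile bootstrap CI for a mean
#'
#' @param values Nonempty numeric vector.
#' @param n_boot Number of bootstrap resamples.
#' @param alpha Two-sided error rate (0.05 gives a 95% interval).
#' @param seed Optional integer seed for reproducibility.
#' @return Named numeric vector `c(low, high)`, with the sample mean as
#'   attribute `"mean"`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 2000L, alpha = 0.05, seed = NULL) {
  if (length(values) == 0L) stop("cannot bootstrap an empty sample")
  stopifnot(alpha > 0, alpha < 1, n_boot >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- length(values)
  draws <- matrix(sample(values, n * n_boot, replace = TRUE), nrow = n_boot)
  means <- rowMeans(draws)
  ci <- unname(quantile(means, c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(c(low = ci[1], high = ci[2]), mean = mean(values))
}

#' Severity-band summary of linguistic markers
#'
#' Mean and percentile-bootstrap CI of each marker within each PHQ-9 severity
#' band (the descriptive cross-sectional analysis behind severity-profile
#' plots).
#'
#' @param scored Score table joined with PHQ (`phq9` column plus marker
#'   columns); empty documents are excluded.
#' @param markers Character vector of marker column names.
#' @param n_boot,alpha,seed Passed to [bootstrap_mean_ci()].
#' @return Tidy tibble: `marker`, `band`, `n`, `mean`, `ci_low`, `ci_high`.
#' @export
severity_band_summary <- function(scored, markers, n_boot = 2000L,
                                  alpha = 0.05, seed = 1L) {
  stopifnot("phq9" %in% names(scored), all(markers %in% names(scored)))
  if ("is_empty" %in% names(scored)) scored <- scored[!scored$is_empty, ]
  scored$band <- severity_band(scored$phq9)
  rows <- list()
  set.seed(seed)
  for (m in markers) {
    for (b in levels(scored$band)) {
      v <- scored[[m]][scored$band == b & !is.na(scored[[m]])]
      if (length(v) == 0L) next
      ci <- bootstrap_mean_ci(v, n_boot = n_boot, alpha = alpha)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker = m, band = b, n = length(v), mean = attr(ci, "mean"),
        ci_low = ci[["low"]], ci_high = ci[["high"]])
    }
  }
  dplyr::bind_rows(rows)
}

#' Fit a linear mixed model by maximum likelihood
#'
#' Fits `outcome ~ predictors` with a per-patient random intercept and,
#' optionally, a per-patient random slope on a time variable — the
#' random-intercept-and-slope form
#' `Y_ij = b0 + b1 X_ij + g0_i + g1_i X_ij + e_ij`. Estimation is by maximum
#' likelihood (not REML) so AIC is comparable across fixed-effect structures.
#' Singular fits and non-convergence are detected and flagged, not silently
#' accepted.
#'
#' @param data Long-format data with one row per observation.
#' @param outcome Outcome column name.
#' @param predictors Character vector of fixed-effect column names (may be
#'   empty for an intercept-only model).
#' @param group Grouping column for the random effects (patient id).
#' @param random_slope Column name to give a per-group random slope, or
#'   `NULL` for random intercept only.
#' @return An object of class `ba_lmm_fit`: `beta` (tibble of fixed effects
#'   with SEs), `varcomp` (random-effect variances/covariance and residual
#'   variance), `logLik`, `AIC`, `n_params`, `r2_marginal`, `r2_conditional`,
#'   `converged`, `singular`, `flags`, and the underlying `lme4` model.
#' @export
fit_lmm <- function(data, outcome, predictors = character(0),
                    group = "patient_id", random_slope = NULL) {
  stopifnot(is.data.frame(data), outcome %in% names(data), group %in% names(data))
  data <- data[stats::complete.cases(data[, c(outcome, predictors, group)]), ]
  if (length(unique(data[[group]])) < 2L) {
    stop("mixed model needs at least 2 groups (patients)")
  }
  flags <- character(0)
  # inestimable fixed effects: a predictor constant across all rows
  degenerate <- predictors[vapply(predictors, function(p) {
    v <- data[[p]]
    length(unique(v[!is.na(v)])) < 2L
  }, TRUE)]
  if (length(degenerate) > 0L) {
    flags <- c(flags, paste0("constant predictor dropped: ",
                             paste(degenerate, collapse = ", ")))
    predictors <- setdiff(predictors, degenerate)
  }
  bt <- function(x) paste0("`", x, "`")  # names like "long-term" need quoting
  fixed <- if (length(predictors) == 0L) "1" else paste(bt(predictors), collapse = " + ")
  rand <- if (is.null(random_slope)) {
    sprintf("(1 | %s)", bt(group))
  } else {
    sprintf("(1 + %s | %s)", bt(random_slope), bt(group))
  }
  fml <- as.formula(paste(bt(outcome), "~", fixed, "+", rand))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  # convergence = the optimizer's own status; lme4's post-hoc gradient checks
  # (which misfire on boundary/degenerate fits) are surfaced as flags
  converged <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0L
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) flags <- c(flags, "singular fit (a variance component is ~0)")
  checks <- unlist(fit@optinfo$conv$lme4$messages)
  if (length(checks) > 0L) flags <- c(flags, paste("lme4 check:", checks))
  if (!converged) flags <- c(flags, "optimizer did not converge")

  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  beta <- tibble::tibble(term = names(fe), estimate = unname(fe),
                         se = unname(se[names(fe)]))
  vc <- lme4::VarCorr(fit)
  vmat <- as.matrix(vc[[group]])
  varcomp <- list(
    var_intercept = unname(vmat[1, 1]),
    var_slope = if (nrow(vmat) > 1) unname(vmat[2, 2]) else NA_real_,
    cov_intercept_slope = if (nrow(vmat) > 1) unname(vmat[1, 2]) else NA_real_,
    var_residual = attr(vc, "sc")^2
  )
  ll <- as.numeric(logLik(fit))
  n_params <- attr(logLik(fit), "df")
  r2 <- r2_components(fit, group)
  structure(
    list(beta = beta, varcomp = varcomp, logLik = ll,
         AIC = 2 * n_params - 2 * ll, n_params = n_params,
         r2_marginal = r2[["marginal"]], r2_conditional = r2[["conditional"]],
         converged = converged, singular = singular, flags = flags,
         n_obs = nrow(data), n_groups = length(unique(data[[group]])),
         model = fit),
    class = "ba_lmm_fit"
  )
}

#' @export
print.ba_lmm_fit <- function(x, ...) {
  cat("<ba_lmm_fit> ML,", x$n_obs, "obs,", x$n_groups, "groups\n")
  print(as.data.frame(x$beta), row.names = FALSE)
  cat(sprintf("logLik %.2f  AIC %.2f  R2m %.3f  R2c %.3f%s\n",
              x$logLik, x$AIC, x$r2_marginal, x$r2_conditional,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = "; "), "]") else ""))
  invisible(x)
}

# Variance-partition R2 for a lmer fit: marginal = fixed-effect variance over
# total; conditional adds the random-effect variance to the numerator.
r2_components <- function(fit, group) {
  fe <- lme4::fixef(fit)
  X <- lme4::getME(fit, "X")
  var_fixed <- var(as.numeric(X %*% fe))
  vc <- lme4::VarCorr(fit)
  var_random <- sum(vapply(vc, function(m) sum(diag(as.matrix(m))), 1.0))
  var_resid <- attr(vc, "sc")^2
  total <- var_fixed + var_random + var_resid
  c(marginal = var_fixed / total,
    conditional = (var_fixed + var_random) / total)
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance-partition R-squared: the marginal form is the fixed-effect
#' variance over the total (fixed + random + residual); the conditional form
#' adds the random-effect variance to the numerator, i.e. the variance
#' explained by the model including the patient-level effects.
#'
#' @param fit A `ba_lmm_fit`.
#' @return Named numeric vector `c(marginal, conditional)`, both in \[0, 1\].
#' @export
r2_mixed <- function(fit) {
  stopifnot(inherits(fit, "ba_lmm_fit"))
  if (!fit$converged) stop("R-squared requested for a non-converged fit")
  c(marginal = fit$r2_marginal, conditional = fit$r2_conditional)
}

#' Marker-vs-PHQ mixed regression
#'
#' The per-unit association between one linguistic marker and the PHQ-9
#' score: fits `marker ~ phq9` with a per-patient random intercept, so the
#' slope is the average difference in the marker per unit difference in PHQ,
#' controlling for within-patient dependence.
#'
#' @param scored Score table joined with PHQ (`phq9` plus marker columns).
#' @param marker Marker column name.
#' @return A `ba_lmm_fit`; the `phq9` row of `$beta` is the per-PHQ-unit
#'   difference.
#' @export
marker_vs_phq <- function(scored, marker) {
  stopifnot(marker %in% names(scored), "phq9" %in% names(scored))
  if ("is_empty" %in% names(scored)) scored <- scored[!scored$is_empty, ]
  fit_lmm(scored, outcome = marker, predictors = "phq9")
}

# Predictor sets for the variable-subset model grid.
liwc_variable_sets <- function() {
  list(none = character(0),
       i = "i", we = "we", tone = "tone",
       `i+we+tone` = c("i", "we", "tone"),
       sadness = "sadness", health = "health", biology = "biology",
       `sadness+health+biology` = c("sadness", "health", "biology"),
       all_liwc = c("i", "we", "tone", "sadness", "health", "biology"))
}

ba_variable_sets <- function() {
  subs <- ba_subconstructs()
  sets <- c(list(none = character(0), overall = "activation"),
            stats::setNames(as.list(subs), subs),
            list(all_subconstructs = subs,
                 `all_subconstructs+overall` = c(subs, "activation")))
  sets
}

#' Enumerate the variable-subset model grid
#'
#' All combinations of (1) subsets of the established LIWC variables — each
#' of first-person singular, first-person plural, tone, and the three
#' together; each of sadness, health, biology, and the three together; all
#' six — and (2) subsets of the BA variables — the overall construct, each of
#' the 7 subconstructs, all 7, and all 7 plus the overall construct. With the
#' empty option on both axes (the empty-empty model excluded) this yields
#' 10 x 11 - 1 = 109 models, each with PHQ-9 as outcome and a per-patient
#' random intercept.
#'
#' @return A tibble with columns `model_id`, `liwc_set`, `ba_set` (labels)
#'   and `predictors` (list column of predictor names).
#' @export
enumerate_model_grid <- function() {
  liwc <- liwc_variable_sets()
  ba <- ba_variable_sets()
  grid <- tidyr::expand_grid(liwc_set = names(liwc), ba_set = names(ba))
  grid <- grid[!(grid$liwc_set == "none" & grid$ba_set == "none"), ]
  grid$predictors <- purrr::map2(grid$liwc_set, grid$ba_set,
                                 function(l, b) c(liwc[[l]], ba[[b]]))
  grid$model_id <- paste(grid$liwc_set, grid$ba_set, sep = " | ")
  grid[, c("model_id", "liwc_set", "ba_set", "predictors")]
}

#' Fit the full model grid
#'
#' Fits each model of [enumerate_model_grid()] to the scored data (PHQ-9
#' outcome, per-patient random intercept, ML) and reports variance explained
#' and AIC per model. Non-convergent models are recorded and the run
#' continues.
#'
#' @param scored Score table joined with PHQ: `patient_id`, `phq9`, and all
#'   marker columns named by the grid.
#' @param grid Optional grid tibble (defaults to [enumerate_model_grid()]).
#' @return A tibble with one row per model: `model_id`, `liwc_set`, `ba_set`,
#'   `r2_marginal`, `r2_conditional`, `aic`, `logLik`, `converged`,
#'   `singular`.
#' @export
fit_grid <- function(scored, grid = enumerate_model_grid()) {
  stopifnot("phq9" %in% names(scored))
  if ("is_empty" %in% names(scored)) scored <- scored[!scored$is_empty, ]
  needed <- unique(unlist(grid$predictors, use.names = FALSE))
  missing_cols <- setdiff(needed, names(scored))
  if (length(missing_cols) > 0L) {
    stop("scored table is missing marker column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rows <- purrr::pmap(grid, function(model_id, liwc_set, ba_set, predictors) {
    res <- tryCatch(
      fit_lmm(scored, outcome = "phq9", predictors = predictors),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble::tibble(model_id = model_id, liwc_set = liwc_set,
                            ba_set = ba_set, r2_marginal = NA_real_,
                            r2_conditional = NA_real_, aic = NA_real_,
                            logLik = NA_real_, converged = FALSE,
                            singular = NA))
    }
    tibble::tibble(model_id = model_id, liwc_set = liwc_set, ba_set = ba_set,
                   r2_marginal = res$r2_marginal,
                   r2_conditional = res$r2_conditional,
                   aic = res$AIC, logLik = res$logLik,
                   converged = res$converged, singular = res$singular)
  })
  dplyr::bind_rows(rows)
}

#' Reshape grid results into the BA-by-LIWC matrix
#'
#' Rows are BA variable subsets, columns LIWC subsets, cells the chosen
#' R-squared — the tabular form of the variance-explained heat map.
#'
#' @param grid_results Output of [fit_grid()].
#' @param value `"r2_conditional"` (default) or `"r2_marginal"` or `"aic"`.
#' @return A tibble with one row per BA set and one column per LIWC set.
#' @export
grid_matrix <- function(grid_results, value = "r2_conditional") {
  stopifnot(value %in% names(grid_results))
  tidyr::pivot_wider(
    grid_results[, c("ba_set", "liwc_set", value)],
    names_from = "liwc_set", values_from = dplyr::all_of(value)
  )
}

#' Per-group trajectory model
#'
#' The longitudinal trajectory fit for one patient group: marker (or PHQ)
#' against week with per-patient random intercept and slope,
#' `Y_ij = b0 + b1 week_ij + g0_i + g1_i week_ij + e_ij`, by ML.
#'
#' @param scored Weekly score table for one group: `patient_id`,
#'   `window_label` (week) or `week`, and the outcome column.
#' @param outcome Outcome column name (e.g. `"activation"` or `"phq9"`).
#' @return A `ba_lmm_fit`.
#' @export
fit_trajectory <- function(scored, outcome) {
  if (!"week" %in% names(scored) && "window_label" %in% names(scored)) {
    scored$week <- scored$window_label
  }
  stopifnot("week" %in% names(scored))
  if ("is_empty" %in% names(scored)) scored <- scored[!scored$is_empty, ]
  fit_lmm(scored, outcome = outcome, predictors = "week",
          random_slope = "week")
}

#' Compare weekly slopes between two group fits
#'
#' Two-sample Wald test on the fixed week slopes of two separately fitted
#' trajectory models (improving vs nonimproving):
#' `z = (b1_A - b1_B) / sqrt(se_A^2 + se_B^2)`, two-sided normal p-value,
#' plus per-group 95% Wald CIs for plotting.
#'
#' @param fit_a,fit_b `ba_lmm_fit` objects with a `week` fixed effect.
#' @param term Name of the slope term (default `"week"`).
#' @param level CI level for the per-group intervals.
#' @return A list: `difference`, `z`, `p`, and `groups` (tibble with
#'   estimate, se, ci_low, ci_high per fit).
#' @export
compare_group_slopes <- function(fit_a, fit_b, term = "week", level = 0.95) {
  get_slope <- function(fit) {
    stopifnot(inherits(fit, "ba_lmm_fit"))
    if (!fit$converged) stop("slope comparison requires converged fits")
    row <- fit$beta[fit$beta$term == term, ]
    if (nrow(row) != 1L) stop("fit has no term '", term, "'")
    if (is.na(row$se)) stop("missing standard error for term '", term, "'")
    row
  }
  a <- get_slope(fit_a); b <- get_slope(fit_b)
  diff <- a$estimate - b$estimate
  se <- sqrt(a$se^2 + b$se^2)
  z <- diff / se
  p <- 2 * pnorm(-abs(z))
  zc <- qnorm(1 - (1 - level) / 2)
  groups <- tibble::tibble(
    group = c("a", "b"),
    estimate = c(a$estimate, b$estimate),
    se = c(a$se, b$se),
    ci_low = c(a$estimate - zc * a$se, b$estimate - zc * b$se),
    ci_high = c(a$estimate + zc * a$se, b$estimate + zc * b$se)
  )
  list(difference = diff, z = z, p = p, groups = groups)
}
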