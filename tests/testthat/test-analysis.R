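test_that("severity bands match the PHQ-9 clinical cut points", {
  expect_equal(as.character(severity_band(c(4, 5, 14, 15, 20))),
               c("minimal", "mild", "moderate", "moderately severe", "severe"))
  expect_equal(as.character(severity_band(0)), "minimal")
  expect_equal(as.character(severity_band(27)), "severe")
  expect_error(severity_band(28), "\\[0, 27\\]")
  expect_error(severity_band(-1), "\\[0, 27\\]")
  # the five bands partition the score range: every score maps to one band
  bands <- severity_band(0:27)
  expect_false(any(is.na(bands)))
  expect_equal(nlevels(bands), 5L)
})

test_that("percentile bootstrap brackets the mean and handles degeneracy", {
  const <- bootstrap_mean_ci(rep(3.5, 20), n_boot = 200, seed = 1)
  expect_equal(unname(const[["low"]]), 3.5)
  expect_equal(unname(const[["high"]]), 3.5)
  set.seed(2)
  for (rep in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -5, 5))
    ci <- bootstrap_mean_ci(x, n_boot = 500)
    expect_lte(ci[["low"]], mean(x))
    expect_gte(ci[["high"]], mean(x))
  }
  expect_error(bootstrap_mean_ci(numeric(0)), "empty")
  # seed gives reproducible intervals
  x <- rnorm(30)
  expect_identical(bootstrap_mean_ci(x, 300, seed = 9),
                   bootstrap_mean_ci(x, 300, seed = 9))
})

test_that("severity-band summary is tidy and complete", {
  set.seed(4)
  scored <- tibble::tibble(
    patient_id = rep(paste0("p", 1:40), each = 2),
    phq9 = sample(0:27, 80, replace = TRUE),
    tone = runif(80, 20, 60)
  )
  out <- severity_band_summary(scored, "tone", n_boot = 200, seed = 5)
  expect_true(all(c("marker", "band", "n", "mean", "ci_low", "ci_high")
                  %in% names(out)))
  expect_true(all(out$ci_low <= out$mean & out$mean <= out$ci_high))
  expect_equal(sum(out$n), 80L)
})

test_that("mixed-model fit recovers a noise-free line exactly", {
  dat <- tidyr::expand_grid(patient_id = paste0("p", 1:12), x = 0:5)
  dat$y <- 2 + 3 * dat$x
  fit <- fit_lmm(dat, "y", "x")
  expect_equal(fit$beta$estimate[fit$beta$term == "(Intercept)"], 2,
               tolerance = 1e-6)
  expect_equal(fit$beta$estimate[fit$beta$term == "x"], 3, tolerance = 1e-6)
  # no variance left anywhere: both components collapse to ~0
  expect_lt(fit$varcomp$var_residual, 1e-8)
  expect_lt(fit$varcomp$var_intercept, 1e-8)
})

test_that("with zero random-effect variance the fit matches OLS", {
  set.seed(11)
  # balanced design, no patient-level effects in truth
  dat <- tidyr::expand_grid(patient_id = paste0("p", 1:30), x = 0:4)
  dat$y <- 1.5 - 0.4 * dat$x + rnorm(nrow(dat), 0, 0.3)
  fit <- fit_lmm(dat, "y", "x")
  ols <- lm(y ~ x, data = dat)
  expect_equal(fit$beta$estimate, unname(coef(ols)), tolerance = 1e-6)
  # with no random-effect variance, conditional R2 collapses to OLS R2
  # (up to the ML n vs OLS n-1 variance scaling)
  expect_equal(fit$r2_conditional, summary(ols)$r.squared, tolerance = 1e-2)
  expect_equal(fit$r2_marginal, fit$r2_conditional, tolerance = 1e-3)
})

test_that("fits report AIC identity, flags, and degenerate designs", {
  set.seed(12)
  dat <- tidyr::expand_grid(patient_id = paste0("p", 1:20), x = 0:4)
  dat$y <- 1 + 0.5 * dat$x + rnorm(nrow(dat), 0, 1) +
    rep(rnorm(20, 0, 0.8), each = 5)
  fit <- fit_lmm(dat, "y", "x")
  expect_equal(fit$AIC, 2 * fit$n_params - 2 * fit$logLik)
  expect_true(fit$converged)

  one <- dat[dat$patient_id == "p1", ]
  expect_error(fit_lmm(one, "y", "x"), "2 groups")

  dat$konst <- 7
  flagged <- fit_lmm(dat, "y", c("x", "konst"))
  expect_true(any(grepl("constant predictor", flagged$flags)))
  expect_false("konst" %in% flagged$beta$term)
})

test_that("R-squared components behave on perfect and nested fits", {
  dat <- tidyr::expand_grid(patient_id = paste0("p", 1:10), x = 0:5)
  dat$y <- 2 + 3 * dat$x
  fit <- fit_lmm(dat, "y", "x")
  r2 <- r2_mixed(fit)
  expect_equal(unname(r2[["marginal"]]), 1, tolerance = 1e-6)
  expect_equal(unname(r2[["conditional"]]), 1, tolerance = 1e-6)

  # adding a pure-noise predictor never lowers the ML log-likelihood
  set.seed(14)
  dat$y <- dat$y + rnorm(nrow(dat), 0, 1)
  dat$noise <- rnorm(nrow(dat))
  small <- fit_lmm(dat, "y", "x")
  big <- fit_lmm(dat, "y", c("x", "noise"))
  expect_gte(big$logLik, small$logLik - 1e-6)
})

test_that("the model grid enumerates exactly the 109 predictor subsets", {
  grid <- enumerate_model_grid()
  expect_equal(nrow(grid), 109L)
  expect_false(any(duplicated(grid$model_id)))
  expect_true(all(vapply(grid$predictors, length, 1L) >= 1L))
  # axes have the documented cardinalities (10 x 11 minus empty-empty)
  expect_equal(length(unique(grid$liwc_set)), 10L)
  expect_equal(length(unique(grid$ba_set)), 11L)
  expect_identical(grid, enumerate_model_grid())
  # the largest model carries all six LIWC variables plus all 8 BA columns
  biggest <- grid$predictors[[which(grid$liwc_set == "all_liwc" &
                                      grid$ba_set == "all_subconstructs+overall")]]
  expect_length(biggest, 14L)
})

test_that("grid fitting surfaces the truly predictive variable", {
  set.seed(15)
  n_pat <- 60
  scored <- tidyr::expand_grid(patient_id = paste0("p", seq_len(n_pat)),
                               obs = 1:4)
  n <- nrow(scored)
  scored$tone <- runif(n, 20, 80)
  # PHQ driven by tone only; everything else is noise
  scored$phq9 <- round(25 - 0.25 * scored$tone + rnorm(n, 0, 1) +
                         rep(rnorm(n_pat, 0, 1), each = 4))
  scored$phq9 <- pmin(pmax(scored$phq9, 0), 27)
  for (nm in c("i", "we", "sadness", "health", "biology", "activation",
               "satisfaction", "breadth", "decisions", "accomplishment",
               "long-term", "effort", "structure")) {
    scored[[nm]] <- runif(n, 0, 10)
  }
  grid <- enumerate_model_grid()
  keep <- grid[grid$liwc_set %in% c("tone", "i", "none") &
                 grid$ba_set %in% c("none", "overall", "all_subconstructs"), ]
  res <- fit_grid(scored, keep)
  expect_equal(nrow(res), nrow(keep))
  tone_r2 <- res$r2_marginal[res$liwc_set == "tone" & res$ba_set == "none"]
  junk_r2 <- res$r2_marginal[res$liwc_set == "i" & res$ba_set == "none"]
  expect_gt(tone_r2, junk_r2 + 0.2)
  # matrix reshape keeps one row per BA set
  mat <- grid_matrix(res)
  expect_equal(nrow(mat), length(unique(keep$ba_set)))
})

test_that("slope comparison is a two-sample Wald z with per-group CIs", {
  set.seed(16)
  dat <- tidyr::expand_grid(patient_id = paste0("p", 1:40), week = -3:11)
  dat$y <- 3 + 0.05 * dat$week + rep(rnorm(40, 0, 0.5), each = 15) +
    rnorm(nrow(dat), 0, 0.4)
  fit <- fit_trajectory(dat, "y")
  same <- compare_group_slopes(fit, fit)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  # CI half-width is the Wald 1.96-SE band
  hw <- (same$groups$ci_high - same$groups$ci_low) / 2
  expect_equal(hw, qnorm(0.975) * same$groups$se, tolerance = 1e-9)
})

test_that("marker-vs-PHQ regression recovers a known linkage", {
  set.seed(17)
  n_pat <- 150
  scored <- tidyr::expand_grid(patient_id = paste0("p", seq_len(n_pat)),
                               obs = 1:5)
  scored$phq9 <- sample(0:27, nrow(scored), replace = TRUE)
  scored$marker <- 5 - 0.1 * scored$phq9 +
    rep(rnorm(n_pat, 0, 0.5), each = 5) + rnorm(nrow(scored), 0, 0.3)
  fit <- marker_vs_phq(scored, "marker")
  b1 <- fit$beta[fit$beta$term == "phq9", ]
  expect_lt(abs(b1$estimate - (-0.1)), 3 * b1$se)

  scored$flat <- 12L
  flagged <- marker_vs_phq(dplyr::rename(scored, marker2 = marker,
                                         phq9_real = phq9, phq9 = flat),
                           "marker2")
  expect_true(any(grepl("constant predictor", flagged$flags)))
})
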