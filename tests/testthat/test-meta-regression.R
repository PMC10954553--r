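test_that("build_records centres and transforms as specified", {
  amt <- data.table(site = "s1", species = c("a", "b", "c"),
                    variant = "equilibrium",
                    aAME = c(1e-4, 2e-4, 0), rAME = c(0.0041, 0.01, 0),
                    var_log_rAME_plus1 = 1e-6, var_aAME = 1e-9, p = 0.5,
                    significant = FALSE, n_obs = 50, n_excluded = 0,
                    n_draws = 100, unstable = c(FALSE, TRUE, FALSE))
  meta <- data.table(site = "s1", absolute_latitude = 11.75)
  ab <- data.table(site = "s1", species = c("a", "b", "c"),
                   abundance = c(1, 100, 100))
  rec <- build_records(amt, meta, ab)
  expect_equal(nrow(rec), 2L)                    # unstable estimate excluded
  expect_equal(attr(rec, "n_excluded_unstable"), 1L)
  a <- rec[species == "a"]
  expect_equal(a$y, log(1.0041))
  expect_equal(a$tLatitude, 0)
  expect_equal(a$tAbundance, 0)
  expect_equal(rec[species == "c", tAbundance], log(100))
  expect_equal(rec[species == "c", y], 0)        # rAME = 0 -> y = 0
  # aAME route stays untransformed
  rec_a <- build_records(amt, meta, ab, measure = "aAME")
  expect_equal(rec_a[species == "a", y], 1e-4)
})

test_that("degenerate records give b0 = y with zero variance components", {
  rec <- data.table(site = rep(c("s1", "s2"), each = 3),
                    species = rep(c("a", "b", "c"), 2),
                    y = 0.004, v = 1e-6,
                    absolute_latitude = 10, abundance = 1,
                    tLatitude = 0, tAbundance = 0)
  fit <- fit_meta_regression(rec, ~ 1)
  expect_equal(unname(fit$b[1]), 0.004, tolerance = 1e-8)
  expect_lt(fit$sigma_r, 1e-4)
  expect_lt(fit$sigma_s, 1e-4)
})

test_that("REML fit matches the brute-force grid-search oracle on a toy", {
  # 2 sites x 3 species, hand-chosen values
  rec <- data.table(site = rep(c("s1", "s2"), each = 3),
                    species = rep(c("a", "b", "c"), 2),
                    y = c(0.010, 0.004, 0.007, 0.001, -0.002, 0.003),
                    v = c(1e-5, 2e-5, 5e-6, 1e-5, 4e-5, 2e-5),
                    tLatitude = 0, tAbundance = 0)
  fit <- fit_meta_regression(rec, ~ 1)
  X <- matrix(1, nrow(rec))
  # dense-path oracle: exhaustive grid over the two variance components
  grid <- exp(seq(log(1e-9), log(1e-3), length.out = 120))
  best <- Inf; best_par <- c(NA, NA)
  for (sr in grid) for (ss in grid) {
    cr <- reml_criterion(rec$y, X, rec$v, rec$site, sr, ss, dense = TRUE)$crit
    if (cr < best) { best <- cr; best_par <- c(sr, ss) }
  }
  # refine around the grid optimum
  ref <- optim(log(best_par), function(th)
    reml_criterion(rec$y, X, rec$v, rec$site, exp(th[1]), exp(th[2]),
                   dense = TRUE)$crit, method = "Nelder-Mead")
  expect_lt(abs(-0.5 * ref$value - fit$reml), 1e-4)
  oracle_b <- reml_criterion(rec$y, X, rec$v, rec$site,
                             exp(ref$par[1]), exp(ref$par[2]), dense = TRUE)$b
  expect_equal(unname(fit$b[1]), unname(oracle_b[1]), tolerance = 1e-4)
})

test_that("Woodbury and dense REML paths agree on random problems", {
  withr::with_seed(8, {
    for (i in 1:5) {
      n_sites <- sample(2:4, 1)
      rec <- simulate_records(n_sites, sample(3:6, 1), seed = i)
      X <- model.matrix(~ tLatitude, rec)
      sr <- runif(1, 0, 1e-4); ss <- runif(1, 0, 1e-4)
      a <- reml_criterion(rec$y, X, rec$v, rec$site, sr, ss)
      b <- reml_criterion(rec$y, X, rec$v, rec$site, sr, ss, dense = TRUE)
      expect_equal(a$crit, b$crit, tolerance = 1e-8)
      expect_equal(a$b, b$b, tolerance = 1e-8)
    }
  })
})

test_that("confidence intervals for the mean are calibrated", {
  b0 <- 0.004
  cover <- 0L
  n_rep <- 120L
  for (r in seq_len(n_rep)) {
    rec <- simulate_records(12, 25, b0 = b0, sigma_r = 0.002, sigma_s = 0.005,
                            v = 1e-5, seed = 5000 + r)
    fit <- fit_meta_regression(rec, ~ 1)
    cover <- cover + as.integer(fit$ci_low[1] <= b0 && b0 <= fit$ci_high[1])
  }
  expect_gte(cover / n_rep, 0.86)
  expect_lte(cover / n_rep, 1.00)
})

test_that("a record with exploded sampling variance loses all influence", {
  rec <- simulate_records(3, 8, seed = 77)
  fit_full <- fit_meta_regression(rec, ~ tLatitude)
  rec_inf <- copy(rec)
  rec_inf$v[1] <- rec_inf$v[1] * 1e12
  rec_inf$y[1] <- rec_inf$y[1] + 5     # wildly off, but infinitely uncertain
  fit_inf <- fit_meta_regression(rec_inf, ~ tLatitude)
  fit_drop <- fit_meta_regression(rec[-1], ~ tLatitude)
  # coefficients agree within a small fraction of their standard errors
  expect_true(all(abs(fit_inf$b - fit_drop$b) < 0.2 * fit_drop$se))
})

test_that("back-transform and recentring invariances hold", {
  rec <- simulate_records(4, 10, b0 = 0.005, seed = 42)
  fit <- fit_meta_regression(rec, ~ 1)
  expect_equal(predict_cndd_percent(fit, 11.75),
               100 * (exp(unname(fit$b[1])) - 1))

  fit_ab <- fit_meta_regression(rec, ~ tLatitude * tAbundance)
  refit <- inference_at(rec, ~ tLatitude * tAbundance,
                        center_latitude = 11.75, center_abundance = 1)
  expect_equal(unname(fit_ab$b), unname(refit$b), tolerance = 1e-5)

  # the prediction surface is invariant to recentring
  refit2 <- inference_at(rec, ~ tLatitude * tAbundance,
                         center_latitude = 30, center_abundance = 10)
  for (lat in c(5, 20, 45)) for (abund in c(1, 50)) {
    expect_equal(
      predict_cndd_percent(fit_ab, lat, abund),
      predict_cndd_percent(refit2, lat, abund, center_latitude = 30,
                           center_abundance = 10),
      tolerance = 1e-6)
  }
  expect_warning(predict_cndd_percent(fit, 80), "latitude range")
})

test_that("zero sampling variances reduce to the one-way random-effects ANOVA", {
  withr::with_seed(9, {
    y <- 0.004 + rnorm(40, 0, 0.003)
  })
  rec <- data.table(site = "s1", species = sprintf("sp%02d", 1:40), y = y,
                    v = 0, tLatitude = 0, tAbundance = 0)
  fit <- fit_meta_regression(rec, ~ 1, include_site = FALSE)
  expect_equal(unname(fit$b[1]), mean(y), tolerance = 1e-6)
  expect_equal(fit$sigma_s^2, var(y), tolerance = 1e-3)  # REML = sample variance
})

test_that("site summaries compute CV with the exclusion and threshold rules", {
  mk_site <- function(s, mean_y, n = 15, seed = 1) {
    withr::with_seed(seed, data.table(
      site = s, species = sprintf("%s_sp%02d", s, seq_len(n)),
      y = mean_y + rnorm(n, 0, abs(mean_y)), v = 1e-8,
      absolute_latitude = 10 + 10 * match(s, c("s1", "s2", "s3", "s4")),
      abundance = 1, tLatitude = 0, tAbundance = 0))
  }
  rec <- rbind(mk_site("s1", 0.004, seed = 1), mk_site("s2", 0.004, seed = 2),
               mk_site("s3", -0.004, seed = 3), mk_site("s4", 0.004, seed = 4),
               data.table(site = "s5", species = "only_one", y = 0.01, v = 1e-8,
                          absolute_latitude = 50, abundance = 1,
                          tLatitude = 0, tAbundance = 0))
  out <- site_summaries(rec)
  expect_false("s5" %in% out$summaries$site)          # below minimum size
  s3 <- out$summaries[site == "s3"]
  expect_false(s3$included_in_cv_analysis)            # negative mean CNDD
  s1 <- out$summaries[site == "s1"]
  expect_equal(s1$cv, s1$sd_y / s1$mean_y)
  # CV approx 1 here, so above the 0.4 coexistence threshold
  expect_true(s1$cv_above_threshold)
})

test_that("site abundance slopes are recentring-invariant and robust to tiny sites", {
  rec <- simulate_records(1, 20, seed = 11)
  rec[, y := y - 0.002 * tAbundance]  # inject a negative abundance slope
  sl <- site_abundance_models(rec)
  expect_equal(nrow(sl), 1L)
  expect_lt(sl$slope, 0)
  rec2 <- copy(rec)[, tAbundance := tAbundance - log(100)]
  expect_equal(site_abundance_models(rec2)$slope, sl$slope, tolerance = 1e-4)
  tiny <- rec[1:2]
  expect_equal(nrow(site_abundance_models(tiny)), 1L)  # wide CI, no crash
})

test_that("global interquantile summary back-transforms with monotone CIs", {
  rec <- data.table(site = rep(c("s1", "s2"), each = 4),
                    species = rep(letters[1:4], 2), y = log(1.05), v = 1e-5,
                    absolute_latitude = 10, abundance = 1,
                    tLatitude = 0, tAbundance = 0)
  out <- global_interquantile_summary(rec)
  expect_equal(out$percent, 5, tolerance = 1e-6)
  rec10 <- copy(rec)[, v := v * 10]
  out10 <- global_interquantile_summary(rec10)
  expect_gt(out10$ci_high - out10$ci_low, out$ci_high - out$ci_low)
})
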