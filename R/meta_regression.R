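#' Build meta-analytic records from an AME table
#'
#' One record per species-site estimate: the response is
#' `y = log(rAME + 1)` (normality-improving transform) with sampling
#' variance `v = var_log_rAME_plus1` from the simulation draws, or the
#' untransformed `aAME` with `var_aAME`. Latitude and log abundance are
#' centred so that main effects test rare tropical species: at 11.75 deg
#' absolute latitude and 1 tree/ha.
#'
#' @param ame_table Output table of [estimate_cndd()] (one variant).
#' @param site_metadata data.frame with `site`, `absolute_latitude`.
#' @param abundances data.frame with `site`, `species`, `abundance`
#'   (trees/ha; pooled groups carry the mean of member abundances).
#' @param center_latitude,center_abundance Centring constants.
#' @param measure `"rAME"` (log1p-transformed) or `"aAME"` (untransformed).
#' @return data.table of records: `site`, `species`, `y`, `v`,
#'   `absolute_latitude`, `abundance`, `tLatitude`, `tAbundance`; attribute
#'   `n_excluded_unstable`.
#' @export
build_records <- function(ame_table, site_metadata, abundances,
                          center_latitude = 11.75, center_abundance = 1,
                          measure = c("rAME", "aAME")) {
  measure <- match.arg(measure)
  amt <- as.data.table(ame_table)
  n_unstable <- sum(amt$unstable)
  amt <- amt[unstable == FALSE]
  amt <- merge(amt, as.data.table(site_metadata)[, .(site, absolute_latitude)],
               by = "site")
  amt <- merge(amt, as.data.table(abundances)[, .(site, species, abundance)],
               by = c("site", "species"))
  if (anyNA(amt$abundance)) stop("missing abundance for some species")
  out <- amt[, .(site, species,
                 y = if (measure == "rAME") log1p(rAME) else aAME,
                 v = if (measure == "rAME") var_log_rAME_plus1 else var_aAME,
                 absolute_latitude, abundance,
                 tLatitude = absolute_latitude - center_latitude,
                 tAbundance = log(abundance) - log(center_abundance))]
  out <- out[is.finite(y) & is.finite(v)]
  setattr(out, "n_excluded_unstable", n_unstable)
  setattr(out, "center_latitude", center_latitude)
  setattr(out, "center_abundance", center_abundance)
  out[]
}

#' REML criterion of the multilevel measurement-error model
#'
#' `-2` times the restricted log likelihood of
#' `y = X b + r_site + s_record + e` with `r ~ N(0, sigma_r2)` per site,
#' `s ~ N(0, sigma_s2)` per record and `e ~ N(0, v)` known. The default path
#' exploits the block-compound-symmetric structure (Woodbury identity per
#' site); `dense = TRUE` recomputes it by brute-force dense linear algebra
#' and exists as an independent cross-check.
#'
#' @param y,X,v Response, fixed-effect design matrix, known sampling
#'   variances.
#' @param site Site factor (or `NULL` for no site random effect).
#' @param sigma_r2,sigma_s2 Variance components (>= 0).
#' @param dense Use the dense reference path.
#' @return List with `crit` (-2 restricted log lik.), `b`, `vcov_b`.
#' @keywords internal
#' @export
reml_criterion <- function(y, X, v, site, sigma_r2, sigma_s2, dense = FALSE) {
  n <- length(y); p <- ncol(X)
  if (dense) {
    V <- diag(v + sigma_s2, n)
    if (!is.null(site)) {
      Z <- model.matrix(~ 0 + factor(site))
      V <- V + sigma_r2 * tcrossprod(Z)
    }
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    XtVy <- t(X) %*% Vi %*% y
    b <- solve(XtVX, XtVy)
    yPy <- as.numeric(t(y) %*% Vi %*% y - t(b) %*% XtVy)
    crit <- as.numeric(determinant(V)$modulus) +
      as.numeric(determinant(XtVX)$modulus) + yPy + (n - p) * log(2 * pi)
    return(list(crit = crit, b = drop(b), vcov_b = solve(XtVX)))
  }
  d <- v + sigma_s2
  A <- cbind(X, y)
  M <- matrix(0, p + 1, p + 1)
  logdet <- 0
  groups <- if (is.null(site)) list(seq_len(n)) else split(seq_len(n), site)
  for (idx in groups) {
    Ai <- A[idx, , drop = FALSE]
    di <- d[idx]
    AtDi <- crossprod(Ai, Ai / di)
    logdet <- logdet + sum(log(di))
    if (!is.null(site) && sigma_r2 > 0) {
      s1 <- colSums(Ai / di)
      denom <- 1 + sigma_r2 * sum(1 / di)
      AtDi <- AtDi - (sigma_r2 / denom) * tcrossprod(s1)
      logdet <- logdet + log(denom)
    }
    M <- M + AtDi
  }
  XtVX <- M[seq_len(p), seq_len(p), drop = FALSE]
  XtVy <- M[seq_len(p), p + 1]
  b <- solve(XtVX, XtVy)
  yPy <- M[p + 1, p + 1] - sum(b * XtVy)
  crit <- logdet + as.numeric(determinant(XtVX)$modulus) + yPy +
    (n - p) * log(2 * pi)
  list(crit = crit, b = drop(b), vcov_b = solve(XtVX))
}

#' Multilevel measurement-error meta-regression
#'
#' Fits `y_lm = b0 + f(predictors) + r_l + s_lm + e_lm` by REML: random site
#' intercepts (`sigma_r^2`), random species-in-site intercepts (`sigma_s^2`,
#' one record per species-site, so an extra latent variance per record), and
#' known per-record sampling variances `v_lm`. Variance components are
#' profiled on the log scale by bounded quasi-Newton with multiple starts;
#' fixed effects come from generalized least squares given the components,
#' with Wald z inference.
#'
#' @param records Output of [build_records()] (needs `y`, `v`, `site`).
#' @param fixed One-sided formula for the fixed effects (default `~ 1`).
#' @param include_site Include the site random intercept (default when more
#'   than one site is present; site-specific models use species only).
#' @return Object of class `meta_fit` with elements `b`, `se`, `z`, `p`,
#'   `ci_low`, `ci_high`, `vcov_b`, `sigma_r`, `sigma_s`, `reml`
#'   (restricted log likelihood), `n`, plus the inputs needed for
#'   diagnostics.
#' @export
fit_meta_regression <- function(records, fixed = ~ 1, include_site = NULL) {
  rec <- as.data.table(records)
  assert_that(all(rec$v >= 0), "sampling variances must be non-negative")
  X <- model.matrix(fixed, rec)
  y <- rec$y
  v <- rec$v
  n <- length(y)
  if (n < ncol(X)) stop("too few records (n = ", n, ") to estimate ",
                        ncol(X), " fixed effects")
  if (is.null(include_site)) include_site <- length(unique(rec$site)) > 1L
  site <- if (include_site) rec$site else NULL
  scale0 <- max(var(y), mean(v), 1e-10)
  obj <- function(th) {
    s2 <- exp(th)
    if (include_site)
      reml_criterion(y, X, v, site, s2[1], s2[2])$crit
    else
      reml_criterion(y, X, v, NULL, 0, s2[1])$crit
  }
  npar <- if (include_site) 2L else 1L
  starts <- list(rep(log(scale0), npar), rep(log(scale0) - 4, npar),
                 rep(log(scale0) + 2, npar))
  best <- NULL
  for (st in starts) {
    op <- tryCatch(
      optim(st, obj, method = "L-BFGS-B", lower = rep(-30, npar),
            upper = rep(log(scale0) + 12, npar),
            control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value - 1e-10)) best <- op
  }
  if (is.null(best)) stop("meta-regression REML optimization failed; ",
                          "n = ", n, ", p = ", ncol(X))
  # polish: derivative-free refinement catches flat-ridge stalls of L-BFGS-B
  pol <- tryCatch(
    if (npar == 1L) {
      o <- stats::optimize(obj, c(-30, log(scale0) + 12), tol = 1e-12)
      list(par = o$minimum, value = o$objective)
    } else {
      optim(best$par, obj, method = "Nelder-Mead",
            control = list(reltol = 1e-12, maxit = 500))
    },
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) best <- pol
  s2 <- exp(best$par)
  # boundary clean-up: components indistinguishable from zero are set to zero
  s2[s2 < 1e-12] <- 0
  sigma_r2 <- if (include_site) s2[1] else 0
  sigma_s2 <- if (include_site) s2[2] else s2[1]
  sol <- reml_criterion(y, X, v, site, sigma_r2, sigma_s2)
  b <- sol$b
  se <- sqrt(diag(sol$vcov_b))
  z <- b / se
  # Student-t reference with df = n - p: coincides with the normal for the
  # thousands of records of a production run, but keeps desk-scale CIs
  # calibrated when only a handful of species-site estimates are available
  df <- max(n - ncol(X), 1L)
  pv <- 2 * stats::pt(-abs(z), df)
  tcrit <- stats::qt(0.975, df)
  structure(list(b = setNames(b, colnames(X)), se = setNames(se, colnames(X)),
                 z = z, p = setNames(pv, colnames(X)), df = df,
                 ci_low = b - tcrit * se, ci_high = b + tcrit * se,
                 vcov_b = sol$vcov_b,
                 sigma_r = sqrt(sigma_r2), sigma_s = sqrt(sigma_s2),
                 reml = -0.5 * sol$crit, n = n, fixed = fixed,
                 include_site = include_site, X = X, y = y, v = v,
                 site = if (include_site) rec$site else rep("all", n),
                 records = rec, converged = best$convergence == 0),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("<meta_fit> n =", x$n, "| sigma_r =", format(x$sigma_r, digits = 3),
      "sigma_s =", format(x$sigma_s, digits = 3),
      "| REML =", format(x$reml, digits = 6), "\n")
  tab <- data.frame(beta = x$b, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p)
  print(format(tab, digits = 4))
  invisible(x)
}

# linear predictor from named meta-regression coefficients at centred
# covariates; accepts a meta_fit or a named coefficient vector
meta_linear_predictor <- function(coefs, latitude, abundance,
                                  center_latitude, center_abundance) {
  lp <- rep(unname(coefs["(Intercept)"]), length(latitude))
  tlat <- latitude - center_latitude
  if ("tLatitude" %in% names(coefs)) lp <- lp + coefs["tLatitude"] * tlat
  if (!is.null(abundance)) {
    tab <- log(abundance) - log(center_abundance)
    if ("tAbundance" %in% names(coefs)) lp <- lp + coefs["tAbundance"] * tab
    if ("tLatitude:tAbundance" %in% names(coefs))
      lp <- lp + coefs["tLatitude:tAbundance"] * tlat * tab
  }
  unname(lp)
}

#' Back-transformed CNDD prediction in percent
#'
#' Evaluates the meta-regression linear predictor at the requested absolute
#' latitude (and abundance, for abundance-mediated models) and
#' back-transforms from the `log(rAME + 1)` scale:
#' `100 * (exp(b0 + b1 x + ...) - 1)`, the relative change in annual
#' mortality probability in percent.
#'
#' @param object A `meta_fit`, or a named coefficient vector with names among
#'   `"(Intercept)"`, `"tLatitude"`, `"tAbundance"`,
#'   `"tLatitude:tAbundance"`.
#' @param latitude Absolute latitude in degrees.
#' @param abundance Trees per hectare (`NULL` for latitude-only models).
#' @param center_latitude,center_abundance Centring used when fitting.
#' @return Percent relative change in annual mortality probability.
#' @export
predict_cndd_percent <- function(object, latitude, abundance = NULL,
                                 center_latitude = 11.75, center_abundance = 1) {
  coefs <- if (inherits(object, "meta_fit")) object$b else object
  if (any(latitude < 0 | latitude > 66.5))
    warning("prediction outside the supported 0-66.5 degree latitude range")
  lp <- meta_linear_predictor(coefs, latitude, abundance,
                              center_latitude, center_abundance)
  100 * expm1(lp)
}

#' Refit with recentred covariates for local inference
#'
#' Coefficient tests in the centred parameterization refer to the centring
#' point; to test the main effects at another latitude/abundance the model
#' is refitted with covariates centred there (the fitted surface is
#' invariant to the recentring; only the meaning of the main effects moves).
#'
#' @param records Records from [build_records()] (must carry
#'   `absolute_latitude` and `abundance`).
#' @param fixed Fixed-effect formula.
#' @param center_latitude,center_abundance The new centring point.
#' @param include_site Passed to [fit_meta_regression()].
#' @return A `meta_fit` at the new centre.
#' @export
inference_at <- function(records, fixed, center_latitude = 11.75,
                         center_abundance = 1, include_site = NULL) {
  rec <- as.data.table(records)
  rec[, tLatitude := absolute_latitude - center_latitude]
  rec[, tAbundance := log(abundance) - log(center_abundance)]
  setattr(rec, "center_latitude", center_latitude)
  setattr(rec, "center_abundance", center_abundance)
  fit_meta_regression(rec, fixed, include_site = include_site)
}

#' Per-site CNDD summaries and the CV-latitude trend
#'
#' For each site with at least `min_records` species estimates, fits an
#' intercept-only meta-regression with a species random intercept: the
#' intercept is the site's mean CNDD on the transformed scale, the species
#' variance component its latent interspecific s.d. The coefficient of
#' variation `CV = sd/mean` is computed only for sites with positive mean
#' CNDD (positive density dependence is destabilizing regardless of species
#' differences), compared against the stable-coexistence threshold
#' `CV > 0.4`, and regressed on absolute latitude by OLS.
#'
#' @param records Records from [build_records()].
#' @param min_records Minimum estimates per site (default 2; smaller sites
#'   are skipped).
#' @param cv_threshold Threshold flagged in the output (default 0.4).
#' @return List with `summaries` (site, n, mean_y, sd_y, cv,
#'   included_in_cv_analysis, cv_above_threshold) and `cv_trend` (lm fit of
#'   CV on latitude, or `NULL`).
#' @export
site_summaries <- function(records, min_records = 2L, cv_threshold = 0.4) {
  rec <- as.data.table(records)
  rows <- list()
  for (s in unique(rec$site)) {
    sub <- rec[site == s]
    if (nrow(sub) < min_records) next
    fit <- tryCatch(fit_meta_regression(sub, ~ 1, include_site = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) next
    mean_y <- unname(fit$b[1]); sd_y <- fit$sigma_s
    cv <- if (mean_y > 0) sd_y / mean_y else NA_real_
    rows[[length(rows) + 1]] <- data.table(
      site = s, n = nrow(sub), absolute_latitude = sub$absolute_latitude[1],
      mean_y = mean_y, sd_y = sd_y, cv = cv,
      included_in_cv_analysis = mean_y > 0,
      cv_above_threshold = !is.na(cv) && cv > cv_threshold)
  }
  summaries <- rbindlist(rows)
  cv_trend <- NULL
  if (nrow(summaries) >= 3L && sum(summaries$included_in_cv_analysis) >= 3L)
    cv_trend <- lm(cv ~ absolute_latitude, data = summaries[included_in_cv_analysis == TRUE])
  list(summaries = summaries, cv_trend = cv_trend)
}

#' Per-site abundance slopes
#'
#' Independent per-site meta-regressions of CNDD on log abundance (species
#' random intercept): slope, Wald CI and p per site.
#'
#' @param records Records from [build_records()].
#' @param min_records Minimum estimates per site.
#' @return data.table: site, slope, ci_low, ci_high, p, n.
#' @export
site_abundance_models <- function(records, min_records = 2L) {
  rec <- as.data.table(records)
  rows <- list()
  for (s in unique(rec$site)) {
    sub <- rec[site == s]
    if (nrow(sub) < min_records) next
    fit <- tryCatch(fit_meta_regression(sub, ~ tAbundance, include_site = FALSE),
                    error = function(e) NULL)
    if (is.null(fit) || !"tAbundance" %in% names(fit$b)) next
    i <- which(names(fit$b) == "tAbundance")
    rows[[length(rows) + 1]] <- data.table(
      site = s, slope = unname(fit$b[i]), ci_low = fit$ci_low[i],
      ci_high = fit$ci_high[i], p = unname(fit$p[i]), n = fit$n)
  }
  rbindlist(rows)
}

#' Global mean of interquantile CNDD
#'
#' Intercept-only multilevel meta-regression (site and species-in-site
#' random intercepts) of the interquantile-variant estimates,
#' back-transformed to a percent change with a Wald 95% CI. The
#' interquantile perturbation differs per species, so this global mean is
#' not comparable across species — it summarizes how much conspecific
#' crowding matters for sapling mortality overall.
#'
#' @param records Records built from interquantile-variant estimates.
#' @return List with `percent`, `ci_low`, `ci_high`, `fit`.
#' @export
global_interquantile_summary <- function(records) {
  fit <- fit_meta_regression(records, ~ 1)
  list(percent = 100 * expm1(unname(fit$b[1])),
       ci_low = 100 * expm1(fit$ci_low[1]),
       ci_high = 100 * expm1(fit$ci_high[1]),
       fit = fit)
}
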