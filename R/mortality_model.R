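#' Species eligibility for an individual mortality model
#'
#' A species gets its own model when it has at least 20 alive and 20 dead
#' status observations, at least 4 unique conspecific density values, and an
#' observed conD range at least as wide as the marginal-effect perturbation
#' (so the counterfactual `conD + delta` does not extrapolate by more than
#' `delta`). Species failing any criterion are routed to the pooled rare
#' group matching their growth form.
#'
#' @param observations Observation table for one species-site (columns `Y`,
#'   `conD`).
#' @param delta Perturbation from [perturbation_delta()].
#' @param growth_form `"tree"`, `"shrub"` or `"unknown"` (unknown pools with
#'   trees).
#' @param min_each Minimum alive and dead counts (default 20).
#' @return List with counts, the boolean criteria and `decision` in
#'   `{"individual", "pooled_rare_tree", "pooled_rare_shrub"}`.
#' @export
assess_eligibility <- function(observations, delta, growth_form = "tree",
                               min_each = 20L) {
  obs <- as.data.table(observations)
  n_dead <- sum(obs$Y == 1)
  n_alive <- sum(obs$Y == 0)
  n_unique_conD <- length(unique(obs$conD))
  range_ok <- nrow(obs) > 0 && (max(obs$conD) - min(obs$conD)) >= delta
  individual <- n_alive >= min_each && n_dead >= min_each &&
    n_unique_conD >= 4L && range_ok
  list(n_alive = n_alive, n_dead = n_dead, n_unique_conD = n_unique_conD,
       range_covers_evaluation = range_ok,
       decision = if (individual) "individual"
                  else if (identical(growth_form, "shrub")) "pooled_rare_shrub"
                  else "pooled_rare_tree")
}

# smooth term for one predictor: thin-plate spline with k = 10, reduced to
# nvals - 2 when a predictor has fewer than 10 unique values; predictors
# with too few unique values for any spline basis enter linearly, constant
# predictors are dropped.
smooth_term <- function(name, vals, k = 10) {
  nv <- length(unique(vals))
  if (nv >= 10L) sprintf("s(%s, k = %d)", name, k)
  else if (nv >= 5L) sprintf("s(%s, k = %d)", name, max(3L, nv - 2L))
  else if (nv >= 2L) name
  else NA_character_
}

#' Fit a species-site mortality model
#'
#' Binomial GAM with complementary log-log link for the interval status
#' `Y` (1 = dead at follow-up): penalized thin-plate smooths of conspecific
#' density, total density and DBH, an interval-length offset `log(dt)`, and
#' a census random intercept when observations span more than one census
#' interval. Smoothing parameters (and the random-intercept variance) are
#' selected by REML. Non-convergence is flagged, never raised, because the
#' grid search and rare-species pooling consume the flags.
#'
#' @param observations Observation table with `Y`, `dt`, `conD`, `totD`,
#'   `dbh`, `j`.
#' @param k Basis dimension for the smooths (default 10).
#' @param sp Optional fixed smoothing-parameter vector passed to the
#'   underlying fit (REML selection when `NULL`); used mainly to verify the
#'   infinite-penalty limit against a parametric fit.
#' @return Object of class `mortality_fit`: the mgcv fit plus `coefficients`,
#'   `vcov` (unconditional when available), `vcov_unconditional` flag,
#'   `loglik`, `auc`, `sigma_u` (census random-intercept s.d., 0 when
#'   absent), `converged`, `n_obs`, `n_dead`.
#' @export
fit_mortality_model <- function(observations, k = 10, sp = NULL) {
  obs <- as.data.table(observations)
  assert_that(nrow(obs) > 0, "no observations")
  if (sum(obs$Y == 1) == 0L || sum(obs$Y == 0) == 0L)
    return(failed_fit(obs, reason = "degenerate outcome"))
  obs[, census_f := factor(j)]
  terms <- c(smooth_term("conD", obs$conD, k),
             smooth_term("totD", obs$totD, k),
             smooth_term("dbh", obs$dbh, k))
  terms <- terms[!is.na(terms)]
  multi_census <- nlevels(obs$census_f) > 1L
  if (multi_census) terms <- c(terms, 's(census_f, bs = "re")')
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- as.formula(paste("Y ~", rhs, "+ offset(log(dt))"))
  fit <- tryCatch(
    withCallingHandlers(
      mgcv::gam(form, family = stats::binomial(link = "cloglog"), data = obs,
                method = "REML", sp = sp),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(fit)) return(failed_fit(obs, reason = "optimizer failure"))
  beta <- coef(fit)
  conv <- isTRUE(fit$converged) && !anyNA(beta) && all(is.finite(beta))
  Vc <- tryCatch(vcov(fit, unconditional = TRUE), error = function(e) NULL)
  uncond <- !is.null(Vc) && all(is.finite(Vc))
  if (!uncond) Vc <- vcov(fit)
  if (any(!is.finite(Vc))) conv <- FALSE
  p_fit <- as.numeric(fitted(fit))
  sigma_u <- 0
  if (multi_census) {
    vc <- tryCatch(mgcv::gam.vcomp(fit, rescale = TRUE), error = function(e) NULL)
    if (!is.null(vc)) {
      rn <- rownames(vc) %||% names(vc)
      hit <- grep("census_f", rn)
      if (length(hit)) sigma_u <- unname(if (is.matrix(vc)) vc[hit[1], 1] else vc[hit[1]])
    }
  }
  structure(list(gam = fit, coefficients = beta, vcov = (Vc + t(Vc)) / 2,
                 vcov_unconditional = uncond,
                 loglik = as.numeric(logLik(fit)),
                 auc = auc_rank(obs$Y, p_fit),
                 sigma_u = sigma_u, converged = conv,
                 n_obs = nrow(obs), n_dead = sum(obs$Y == 1),
                 multi_census = multi_census,
                 census_levels = levels(obs$census_f)),
            class = "mortality_fit")
}

failed_fit <- function(obs, reason) {
  structure(list(gam = NULL, coefficients = NULL, vcov = NULL,
                 vcov_unconditional = FALSE, loglik = NA_real_, auc = NA_real_,
                 sigma_u = NA_real_, converged = FALSE, n_obs = nrow(obs),
                 n_dead = sum(obs$Y == 1), reason = reason,
                 multi_census = FALSE, census_levels = "1"),
            class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat("<mortality_fit>", if (x$converged) "converged" else "NOT converged",
      "| n =", x$n_obs, "deaths =", x$n_dead,
      "| logLik =", format(x$loglik, digits = 5),
      "| AUC =", format(x$auc, digits = 3), "\n")
  invisible(x)
}

#' Fit pooled rare-species group models
#'
#' Rare species (not individually eligible) are fitted jointly in one model
#' per growth form; the group fit is later combined with each member
#' species' own observations to obtain member-specific marginal effects.
#'
#' @param pooled_observations Observation table with a `group` column
#'   (`"pooled_rare_tree"` / `"pooled_rare_shrub"`).
#' @param k Basis dimension.
#' @return Named list of `mortality_fit` objects (possibly empty; empty
#'   groups are skipped with a warning).
#' @export
fit_rare_group_models <- function(pooled_observations, k = 10) {
  obs <- as.data.table(pooled_observations)
  fits <- list()
  for (g in c("pooled_rare_tree", "pooled_rare_shrub")) {
    sub <- obs[group == g]
    if (nrow(sub) == 0L) {
      warning("empty rare group skipped: ", g)
      next
    }
    fits[[g]] <- fit_mortality_model(sub, k = k)
  }
  fits
}

# linear-predictor matrix with random-intercept columns zeroed (prediction
# at the population mean of the census effect)
lp_matrix <- function(fit, newdata) {
  nd <- as.data.table(newdata)
  if (!"dt" %in% names(nd)) nd[, dt := 1]
  nd[, census_f := factor(fit$census_levels[1], levels = fit$census_levels)]
  Xp <- predict(fit$gam, newdata = nd, type = "lpmatrix")
  for (sm in fit$gam$smooth) {
    if (inherits(sm, "random.effect"))
      Xp[, sm$first.para:sm$last.para] <- 0
  }
  Xp
}

#' Predict mortality probability
#'
#' Inverse cloglog link `p = 1 - exp(-exp(eta + log(dt)))` with the census
#' random intercept at its population mean (0).
#'
#' @param fit A convergent `mortality_fit`.
#' @param newdata data.frame with `conD`, `totD`, `dbh`.
#' @param delta_t Interval length in years (default 1).
#' @param coefficients Optional replacement coefficient vector (e.g. one
#'   simulation draw).
#' @return Probabilities in (0, 1).
#' @export
predict_mortality <- function(fit, newdata, delta_t = 1, coefficients = NULL) {
  assert_that(isTRUE(fit$converged), "fit did not converge")
  Xp <- lp_matrix(fit, newdata)
  beta <- coefficients %||% fit$coefficients
  cloglog_inv(as.numeric(Xp %*% beta), delta_t)
}

#' Simulate coefficient vectors from a fitted model
#'
#' Draws from the multivariate normal with the fitted coefficients as mean
#' and the unconditional covariance matrix (including smoothing-parameter
#' uncertainty when available). A covariance matrix that is not positive
#' semidefinite is repaired by clamping negative eigenvalues to zero, with a
#' warning.
#'
#' @param fit A convergent `mortality_fit`.
#' @param n_draws Number of draws (default 500).
#' @param seed Integer seed.
#' @return `n_draws x p` matrix of coefficient vectors.
#' @export
draw_coefficients <- function(fit, n_draws = 500, seed = 1) {
  assert_that(isTRUE(fit$converged), "fit did not converge")
  V <- fit$vcov
  eg <- eigen(V, symmetric = TRUE)
  if (any(eg$values < -1e-8 * max(abs(eg$values), 1))) {
    warning("covariance repaired to nearest positive semidefinite matrix")
  }
  lam <- pmax(eg$values, 0)
  with_seed(seed, {
    z <- matrix(rnorm(n_draws * length(lam)), n_draws)
    sweep(z %*% (t(eg$vectors) * sqrt(lam)), 2, fit$coefficients, `+`)
  })
}

#' Randomized quantile residuals
#'
#' Probability-integral-transform residuals for the Bernoulli outcome: for
#' `Y = 0` a uniform draw on `(0, 1 - p)`, for `Y = 1` on `(1 - p, 1)`,
#' where `p` is the fitted mortality probability (including the census
#' effect and the interval offset). Uniform on (0,1) under the fitted model.
#'
#' @param fit A convergent `mortality_fit`.
#' @param observations The observations the model was fitted to.
#' @param seed Integer seed.
#' @return Numeric vector of residuals in (0, 1).
#' @export
model_residual_quantiles <- function(fit, observations, seed = 1) {
  assert_that(isTRUE(fit$converged), "fit did not converge")
  obs <- as.data.table(observations)
  p <- as.numeric(fitted(fit$gam))
  with_seed(seed, {
    u <- runif(nrow(obs))
    ifelse(obs$Y == 0, u * (1 - p), (1 - p) + u * p)
  })
}
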