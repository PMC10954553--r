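P_FLOOR <- 1e-12

# baseline / perturbed covariate tables for one AME variant; confounders
# (totD, DBH) stay at observed values, dt is fixed at one year, and the
# added neighbor increments conD only (totD held constant: the estimand is
# stabilizing CNDD, i.e. the conspecific effect net of the total-density
# effect)
ame_covariates <- function(observations, variant, delta) {
  obs <- as.data.table(observations)
  base <- obs[, .(conD, totD, dbh, dt = 1)]
  if (variant == "equilibrium") {
    pert <- copy(base)[, conD := conD + delta]
  } else if (variant == "invasion") {
    base[, conD := 0]
    pert <- copy(base)[, conD := delta]
  } else if (variant == "interquantile") {
    q <- quantile(obs$conD, c(0.25, 0.75), type = 7, names = FALSE)
    base[, conD := q[1]]
    pert <- copy(base)[, conD := q[2]]
  } else stop("unknown AME variant: ", variant)
  list(base = base, pert = pert)
}

#' Per-observation marginal effects of a conspecific-density perturbation
#'
#' For each observation, evaluates the fitted annual mortality probability at
#' the observed covariates (`p`) and after adding the conspecific
#' perturbation (`p'`), with total density, DBH and census held at observed
#' values, the census random effect at its population mean, and the interval
#' length fixed at one year. Returns `aME = p' - p` and `rME = p'/p - 1`;
#' observations whose baseline probability falls below a 1e-12 floor have
#' undefined `rME` and are flagged.
#'
#' @param fit Convergent `mortality_fit`.
#' @param observations Observation table (`conD`, `totD`, `dbh`).
#' @param delta Perturbation from [perturbation_delta()].
#' @param variant `"equilibrium"` (observed conD), `"invasion"` (conD set to
#'   0) or `"interquantile"` (Q1 to Q3 of the species' observed conD).
#' @param coefficients Optional coefficient vector overriding the point
#'   estimates.
#' @return data.table with `aME`, `rME` (NA where undefined) and `usable`.
#' @export
observation_effects <- function(fit, observations, delta,
                                variant = "equilibrium", coefficients = NULL) {
  cov <- ame_covariates(observations, variant, delta)
  p0 <- predict_mortality(fit, cov$base, delta_t = 1, coefficients = coefficients)
  p1 <- predict_mortality(fit, cov$pert, delta_t = 1, coefficients = coefficients)
  usable <- p0 >= P_FLOOR
  data.table(aME = p1 - p0, rME = ifelse(usable, p1 / p0 - 1, NA_real_),
             usable = usable)
}

#' Average marginal effect (point estimates)
#'
#' Averages per-observation effects over all observations of the species
#' (equal weights across censuses): `aAME = mean(aME)`,
#' `rAME = mean(rME)` over usable observations.
#'
#' @inheritParams observation_effects
#' @return List with `aAME`, `rAME`, `n_obs`, `n_excluded`.
#' @export
average_marginal_effect <- function(fit, observations, delta,
                                    variant = "equilibrium") {
  me <- observation_effects(fit, observations, delta, variant)
  if (!any(me$usable)) stop("no usable observations for the average marginal effect")
  list(aAME = mean(me$aME), rAME = mean(me$rME[me$usable]),
       n_obs = nrow(me), n_excluded = sum(!me$usable))
}

#' Average marginal effect with simulation-based uncertainty
#'
#' Completes the point estimates with sampling variances and significance by
#' recomputing the AMEs under `n_draws` coefficient vectors simulated from
#' the fitted model's multivariate normal ([draw_coefficients()]). The
#' variance of `log(rAME + 1)` across draws is the sampling variance carried
#' into the meta-regression (`aAME` analogous, untransformed). The two-sided
#' p-value is `2 * min(share of draws <= 0, share >= 0)`, floored at
#' `2 / n_draws`; significance is tested at `alpha = 0.05`. The estimate is
#' flagged unstable when more than 10% of draws contain an undefined
#' relative effect.
#'
#' @inheritParams observation_effects
#' @param n_draws Number of coefficient draws (default 500).
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @return One-row data.table: `variant`, `aAME`, `rAME`,
#'   `var_log_rAME_plus1`, `var_aAME`, `p`, `significant`, `n_obs`,
#'   `n_excluded`, `n_draws`, `unstable`.
#' @export
ame_uncertainty <- function(fit, observations, delta, variant = "equilibrium",
                            n_draws = 500, seed = 1, alpha = 0.05) {
  point <- average_marginal_effect(fit, observations, delta, variant)
  cov <- ame_covariates(observations, variant, delta)
  Xb <- lp_matrix(fit, cov$base)
  Xp <- lp_matrix(fit, cov$pert)
  B <- t(draw_coefficients(fit, n_draws = n_draws, seed = seed))  # p x m
  p0 <- cloglog_inv(Xb %*% B, 1)  # n x m
  p1 <- cloglog_inv(Xp %*% B, 1)
  ok <- p0 >= P_FLOOR
  aAME_d <- colMeans(p1 - p0)
  r <- (p1 / p0 - 1)
  r[!ok] <- NA
  rAME_d <- colMeans(r, na.rm = TRUE)
  rAME_d[colSums(ok) == 0] <- NA
  draw_bad <- colSums(!ok) > 0
  defined <- !is.na(rAME_d)
  p_val <- max(2 / n_draws,
               2 * min(mean(rAME_d[defined] <= 0), mean(rAME_d[defined] >= 0)))
  p_val <- min(p_val, 1)
  data.table(variant = variant, aAME = point$aAME, rAME = point$rAME,
             var_log_rAME_plus1 = var(log1p(rAME_d[defined])),
             var_aAME = var(aAME_d),
             p = p_val, significant = p_val < alpha,
             n_obs = point$n_obs, n_excluded = point$n_excluded,
             n_draws = n_draws, unstable = mean(draw_bad) > 0.10)
}

#' Species-site CNDD estimates for a whole dataset
#'
#' Runs the estimation stage end to end for one canonical observation table
#' with densities attached: species eligibility, individual fits, pooled
#' rare-group fits per growth form, and AMEs (with uncertainty) per species
#' and variant. Member species of a pooled group get the group coefficients
#' combined with their own covariate distribution.
#'
#' @param observations Canonical observation table with `conD`/`totD`
#'   attached; edge-excluded rows are dropped here.
#' @param config The [density_config()] used (defines the perturbation).
#' @param growth_forms Named character vector, species -> growth form
#'   (missing species default to `"tree"`).
#' @param variants AME variants to compute.
#' @param pooled_level `"group"` (default): each rare group contributes one
#'   estimate per site, computed from the group fit and the group's pooled
#'   observations — the unit that enters the meta-regression ("species or
#'   species groups"). `"member"`: one estimate per member species (group
#'   coefficients, that species' own covariate distribution).
#' @param n_draws,seed,k As elsewhere.
#' @return List with `ame` (table: site, species, variant, aAME, rAME,
#'   var_log_rAME_plus1, var_aAME, p, significant, n_obs, n_excluded,
#'   n_draws, unstable, pooled), `fits` (named list of mortality fits),
#'   `eligibility` (per-species decisions), `members` (site, group, species
#'   composition of the rare groups).
#' @export
estimate_cndd <- function(observations, config = density_config(),
                          growth_forms = character(),
                          variants = c("equilibrium", "invasion", "interquantile"),
                          pooled_level = c("group", "member"),
                          n_draws = 500, seed = 1, k = 10) {
  pooled_level <- match.arg(pooled_level)
  obs <- as.data.table(observations)[edge_excluded == FALSE]
  delta <- perturbation_delta(config)
  keys <- unique(obs[, .(site, species)])
  elig <- vector("list", nrow(keys))
  fits <- list()
  ame_rows <- list()
  members <- list()
  for (s in unique(keys$site)) {
    sobs <- obs[site == s]
    sp_all <- unique(sobs$species)
    decisions <- character(length(sp_all))
    names(decisions) <- sp_all
    for (sp in sp_all) {
      gf <- if (sp %in% names(growth_forms)) growth_forms[[sp]] else "tree"
      e <- assess_eligibility(sobs[species == sp], delta, growth_form = gf)
      decisions[sp] <- e$decision
      elig[[length(elig) + 1]] <- c(list(site = s, species = sp), e)
    }
    # individual fits; non-convergent species fall back to the pooled group
    for (sp in sp_all[decisions == "individual"]) {
      fit <- fit_mortality_model(sobs[species == sp], k = k)
      if (fit$converged) {
        fits[[paste(s, sp, sep = "::")]] <- fit
      } else {
        gf <- if (sp %in% names(growth_forms)) growth_forms[[sp]] else "tree"
        decisions[sp] <- if (identical(gf, "shrub")) "pooled_rare_shrub" else "pooled_rare_tree"
      }
    }
    pooled <- sobs[species %in% sp_all[decisions != "individual"]]
    if (nrow(pooled)) {
      pooled[, group := decisions[species]]
      gfits <- suppressWarnings(fit_rare_group_models(pooled, k = k))
      for (g in names(gfits)) fits[[paste(s, g, sep = "::")]] <- gfits[[g]]
      members[[length(members) + 1]] <-
        unique(pooled[, .(site = s, group, species)])
    }
    # estimation units: individual species, plus rare groups or their members
    units <- lapply(sp_all[decisions == "individual"], function(sp)
      list(label = sp, fit_key = paste(s, sp, sep = "::"),
           obs = sobs[species == sp], pooled = FALSE))
    if (nrow(pooled)) {
      if (pooled_level == "group") {
        for (g in unique(pooled$group))
          units[[length(units) + 1]] <- list(
            label = g, fit_key = paste(s, g, sep = "::"),
            obs = pooled[group == g], pooled = TRUE)
      } else {
        for (sp in unique(pooled$species))
          units[[length(units) + 1]] <- list(
            label = sp, fit_key = paste(s, decisions[sp], sep = "::"),
            obs = sobs[species == sp], pooled = TRUE)
      }
    }
    for (u in units) {
      fit <- fits[[u$fit_key]]
      if (is.null(fit) || !isTRUE(fit$converged)) next
      for (v in variants) {
        row <- tryCatch(
          ame_uncertainty(fit, u$obs, delta, variant = v, n_draws = n_draws,
                          seed = split_seed(seed, s, u$label, v)),
          error = function(e) NULL)
        if (is.null(row)) next
        ame_rows[[length(ame_rows) + 1]] <-
          cbind(data.table(site = s, species = u$label, pooled = u$pooled), row)
      }
    }
  }
  list(ame = rbindlist(ame_rows),
       fits = fits,
       eligibility = rbindlist(lapply(elig, as.data.table)),
       members = rbindlist(members))
}
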