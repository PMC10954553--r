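#' Distance-decay kernel specification
#'
#' Two kernel families are supported for down-weighting neighbor influence
#' with distance `d` (metres):
#' * `exponential`: \eqn{f(d) = e^{-d/\mu}}
#' * `exponential_normal`: \eqn{f(d) = e^{-d^2/\mu^2}}
#'
#' Both satisfy `f(0) = 1` and decrease strictly with distance; `mu` sets how
#' far neighborhood effects extend.
#'
#' @param kind `"exponential"` or `"exponential_normal"`.
#' @param mu Decay range in metres (> 0).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("exponential", "exponential_normal"), mu) {
  kind <- match.arg(kind)
  assert_that(is.numeric(mu) && length(mu) == 1 && mu > 0, "mu must be a single positive number")
  structure(list(kind = kind, mu = mu), class = "kernel_spec")
}

#' Evaluate a decay kernel
#'
#' @param spec A [kernel_spec()].
#' @param d Non-negative distances in metres.
#' @return Weights in (0, 1].
#' @export
kernel_weight <- function(spec, d) {
  assert_that(inherits(spec, "kernel_spec"), "spec must be a kernel_spec")
  if (any(d < 0)) stop("distances must be non-negative")
  switch(spec$kind,
    exponential = exp(-d / spec$mu),
    exponential_normal = exp(-d^2 / spec$mu^2)
  )
}

#' Neighborhood density configuration
#'
#' Bundles the local-density estimator (`N` = weighted neighbor count, `BA` =
#' weighted basal area in cm^2), one decay kernel for conspecific and one for
#' total density (same family, possibly different ranges), and the search
#' radius. The default is the configuration selected by grid search on the
#' multi-site data this workflow targets: basal area with exponential decay,
#' `mu = 3` m (conspecific) and `17` m (total), radius 30 m.
#'
#' @param estimator `"BA"` or `"N"`.
#' @param kind Kernel family, shared by both kernels.
#' @param mu_con,mu_tot Decay ranges (m) for conspecific and total density.
#' @param radius Neighborhood search radius in metres.
#' @return An object of class `density_config`.
#' @export
density_config <- function(estimator = c("BA", "N"),
                           kind = c("exponential", "exponential_normal"),
                           mu_con = 3, mu_tot = 17, radius = 30) {
  estimator <- match.arg(estimator)
  kind <- match.arg(kind)
  assert_that(radius > 0, "radius must be positive")
  structure(list(
    estimator = estimator,
    kernel_con = kernel_spec(kind, mu_con),
    kernel_tot = kernel_spec(kind, mu_tot),
    radius = radius
  ), class = "density_config")
}

config_hash <- function(config) {
  with(config, sprintf("%s_%s_%g_%g_%g", estimator, kernel_con$kind,
                       kernel_con$mu, kernel_tot$mu, radius))
}

#' Conspecific-density perturbation used for marginal effects
#'
#' The perturbation adds one conspecific neighbor with DBH = 2 cm at 1 m
#' distance: its weighted contribution is `kernel_con(1 m)` times `pi` cm^2
#' (basal area of a 2 cm stem) for the BA estimator, or times 1 for the N
#' estimator.
#'
#' @param config A [density_config()].
#' @return The increment added to `conD` (cm^2 for BA, dimensionless for N).
#' @export
perturbation_delta <- function(config) {
  w <- kernel_weight(config$kernel_con, 1)
  if (config$estimator == "BA") w * basal_area(2) else w
}

# Map species codes (any type) to integer ids shared by focals and neighbors
species_codes <- function(f, n) {
  lev <- unique(c(as.character(f), as.character(n)))
  list(f = match(as.character(f), lev), n = match(as.character(n), lev))
}

#' Kernel-weighted neighborhood densities
#'
#' Computes, for each focal observation, the kernel-weighted conspecific
#' (`conD`) and total (`totD`) density from the pool of trees alive at the
#' census preceding the interval. Neighbors of all sizes within `radius`
#' contribute; a tree is never its own neighbor (matched by `tree_id`).
#' `conD` uses the conspecific kernel, `totD` the total-density kernel.
#'
#' @param observations data.frame/data.table of focal observations with
#'   columns `x`, `y`, `species`, `tree_id`.
#' @param neighbors data.frame/data.table of live trees at the preceding
#'   census with columns `x`, `y`, `dbh`, `species`, `tree_id`.
#' @param config A [density_config()].
#' @return A data.table with columns `conD`, `totD` (row order matches
#'   `observations`).
#' @export
compute_densities <- function(observations, neighbors, config) {
  obs <- as.data.table(observations)
  nb <- as.data.table(neighbors)
  if (nrow(obs) == 0L) return(data.table(conD = numeric(), totD = numeric()))
  sp <- species_codes(obs$species, nb$species)
  ids <- species_codes(obs$tree_id, nb$tree_id)  # reuse for id matching
  m <- cpp_densities(
    as.numeric(obs$x), as.numeric(obs$y), sp$f, ids$f,
    as.numeric(nb$x), as.numeric(nb$y), as.numeric(nb$dbh), sp$n, ids$n,
    config$radius, if (config$kernel_con$kind == "exponential") 0L else 1L,
    config$kernel_con$mu, config$kernel_tot$mu,
    if (config$estimator == "BA") 1L else 0L
  )
  as.data.table(m)
}

#' Brute-force density oracle
#'
#' Pairwise O(n^2) reference implementation of [compute_densities()] used to
#' validate the spatial-index version; results must agree to numerical
#' round-off, not merely approximately.
#'
#' @inheritParams compute_densities
#' @return As [compute_densities()].
#' @export
compute_densities_brute <- function(observations, neighbors, config) {
  obs <- as.data.table(observations)
  nb <- as.data.table(neighbors)
  conD <- totD <- numeric(nrow(obs))
  contrib <- if (config$estimator == "BA") basal_area(nb$dbh) else rep(1, nrow(nb))
  for (i in seq_len(nrow(obs))) {
    d <- sqrt((nb$x - obs$x[i])^2 + (nb$y - obs$y[i])^2)
    keep <- d <= config$radius & nb$tree_id != obs$tree_id[i]
    if (!any(keep)) next
    wc <- kernel_weight(config$kernel_con, d[keep])
    wt <- kernel_weight(config$kernel_tot, d[keep])
    totD[i] <- sum(wt * contrib[keep])
    cons <- nb$species[keep] == obs$species[i]
    conD[i] <- sum((wc * contrib[keep])[cons])
  }
  data.table(conD = conD, totD = totD)
}

#' Attach neighborhood densities to a canonical observation table
#'
#' For every (site, census interval) the neighbor pool is the set of trees
#' alive at the interval's starting census; densities are computed for all
#' focal observations of that interval and attached as `conD`/`totD` columns.
#'
#' @param observations Canonical observation table (see [build_observations()])
#'   with columns `site`, `j`, `x`, `y`, `species`, `tree_id`.
#' @param trees Tree table with columns `site`, `census_index`, `tree_id`,
#'   `species`, `x`, `y`, `dbh`, `status` (`"alive"`/`"dead"`).
#' @param config A [density_config()].
#' @return Copy of `observations` with `conD` and `totD` columns.
#' @export
attach_densities <- function(observations, trees, config) {
  obs <- as.data.table(observations)
  trees <- as.data.table(trees)
  obs[, `:=`(conD = NA_real_, totD = NA_real_)]
  for (s in unique(obs$site)) {
    for (jj in unique(obs[site == s, j])) {
      idx <- which(obs$site == s & obs$j == jj)
      pool <- trees[site == s & census_index == jj & status == "alive"]
      if (nrow(pool) == 0L) stop("no live trees at the preceding census for site ", s, ", interval ", jj)
      dens <- compute_densities(obs[idx], pool, config)
      obs[idx, `:=`(conD = dens$conD, totD = dens$totD)]
    }
  }
  obs[]
}

#' Joint grid search for the density definition
#'
#' Evaluates candidate local-density definitions — estimator in \{N, BA\},
#' kernel family in \{exponential, exponential-normal\}, and decay ranges
#' `mu_con`, `mu_tot` on a grid (default 1 to 25 m in 2 m steps) — by
#' refitting all species-site mortality models per cell and summing their log
#' likelihoods over the fixed set of species whose models converge in every
#' cell. Mean AUC across that species set is reported alongside.
#'
#' @param observations Canonical observation table (without densities).
#' @param trees Tree table as in [attach_densities()].
#' @param mu_grid Candidate decay ranges in metres.
#' @param mu_grid_con,mu_grid_tot Separate grids for the conspecific and
#'   total-density axes (default: `mu_grid` for both; reduced searches pin
#'   each axis around a region of interest).
#' @param estimators,kinds Candidate estimators and kernel families.
#' @param radius Search radius (m).
#' @param model_settings List passed through to [fit_mortality_model()]
#'   (e.g. `k`).
#' @param min_obs Minimum alive and dead observations for a species to enter
#'   the search (the eligibility pieces that do not depend on the kernel).
#' @return List with `table` (one row per cell: estimator, kind, mu_con,
#'   mu_tot, sumLL, meanAUC, n_species), `selected` (the argmax
#'   [density_config()]), and `species` (the convergent-everywhere set).
#' @export
grid_search_mu <- function(observations, trees,
                           mu_grid = seq(1, 25, by = 2),
                           mu_grid_con = mu_grid, mu_grid_tot = mu_grid,
                           estimators = c("N", "BA"),
                           kinds = c("exponential", "exponential_normal"),
                           radius = 30, model_settings = list(),
                           min_obs = 20L) {
  obs <- as.data.table(observations)
  obs <- obs[edge_excluded == FALSE]
  counts <- obs[, .(n_dead = sum(Y == 1), n_alive = sum(Y == 0)), by = .(site, species)]
  cand <- counts[n_dead >= min_obs & n_alive >= min_obs, paste(site, species, sep = "::")]
  if (length(cand) == 0L) stop("no species with enough observations for the grid search")

  cells <- CJ(estimator = estimators, kind = kinds, mu_con = mu_grid_con,
              mu_tot = mu_grid_tot)
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cfg <- density_config(cells$estimator[ci], cells$kind[ci],
                          cells$mu_con[ci], cells$mu_tot[ci], radius)
    dobs <- attach_densities(obs, trees, cfg)
    ll <- auc <- setNames(rep(NA_real_, length(cand)), cand)
    for (key in cand) {
      parts <- strsplit(key, "::", fixed = TRUE)[[1]]
      sub <- dobs[site == parts[1] & species == parts[2]]
      fit <- try(do.call(fit_mortality_model, c(list(observations = sub), model_settings)), silent = TRUE)
      if (!inherits(fit, "try-error") && fit$converged) {
        ll[key] <- fit$loglik
        auc[key] <- fit$auc
      }
    }
    res[[ci]] <- list(ll = ll, auc = auc)
  }
  ok <- Reduce(`&`, lapply(res, function(r) !is.na(r$ll)))
  if (!any(ok)) stop("no species converged in every grid cell; failures: ",
                     paste(cand[!ok], collapse = ", "))
  tab <- copy(cells)
  tab[, sumLL := vapply(res, function(r) sum(r$ll[ok]), numeric(1))]
  tab[, meanAUC := vapply(res, function(r) mean(r$auc[ok], na.rm = TRUE), numeric(1))]
  tab[, n_species := sum(ok)]
  best <- which.max(tab$sumLL)
  selected <- density_config(tab$estimator[best], tab$kind[best],
                             tab$mu_con[best], tab$mu_tot[best], radius)
  list(table = tab[], selected = selected, species = cand[ok])
}

#' Species-specific decay-range optima and pattern audit
#'
#' For each species, profiles the model log likelihood over `mu_con` (at the
#' selected family, estimator and `mu_tot`), keeps species with a distinct
#' interior optimum (strict interior argmax whose LL exceeds both grid ends
#' by at least `drop` units), and tests the retained optima for correlation
#' with absolute latitude and log abundance.
#'
#' @param observations Canonical observation table.
#' @param trees Tree table.
#' @param selected A [density_config()] fixing family, estimator and `mu_tot`.
#' @param mu_grid Profile grid for `mu_con`.
#' @param site_metadata data.frame with `site`, `absolute_latitude`.
#' @param abundances data.frame with `site`, `species`, `abundance`.
#' @param drop Required LL drop to both grid ends (default 2).
#' @param min_obs As in [grid_search_mu()].
#' @return List with `optima` (per-species table) and `tests` (correlation
#'   test results, `NULL` when fewer than 3 distinct optima).
#' @export
audit_mu_by_species <- function(observations, trees, selected,
                                mu_grid = seq(1, 25, by = 2),
                                site_metadata = NULL, abundances = NULL,
                                drop = 2, min_obs = 20L) {
  obs <- as.data.table(observations)[edge_excluded == FALSE]
  counts <- obs[, .(n_dead = sum(Y == 1), n_alive = sum(Y == 0)), by = .(site, species)]
  cand <- counts[n_dead >= min_obs & n_alive >= min_obs]
  prof <- matrix(NA_real_, nrow(cand), length(mu_grid))
  for (g in seq_along(mu_grid)) {
    cfg <- density_config(selected$estimator, selected$kernel_con$kind,
                          mu_grid[g], selected$kernel_tot$mu, selected$radius)
    dobs <- attach_densities(obs, trees, cfg)
    for (r in seq_len(nrow(cand))) {
      sub <- dobs[site == cand$site[r] & species == cand$species[r]]
      fit <- try(fit_mortality_model(sub), silent = TRUE)
      if (!inherits(fit, "try-error") && fit$converged) prof[r, g] <- fit$loglik
    }
  }
  out <- cand[, .(site, species)]
  out[, mu_opt := NA_real_][, distinct := FALSE]
  for (r in seq_len(nrow(out))) {
    p <- prof[r, ]
    if (anyNA(p)) next
    i <- which.max(p)
    out$mu_opt[r] <- mu_grid[i]
    out$distinct[r] <- i > 1 && i < length(p) &&
      (p[i] - p[1]) >= drop && (p[i] - p[length(p)]) >= drop
  }
  keep <- out[distinct == TRUE]
  tests <- NULL
  if (!is.null(site_metadata) && !is.null(abundances) && nrow(keep) >= 3L) {
    keep <- merge(keep, as.data.table(site_metadata)[, .(site, absolute_latitude)], by = "site")
    keep <- merge(keep, as.data.table(abundances), by = c("site", "species"))
    tests <- list(
      latitude = cor.test(keep$mu_opt, keep$absolute_latitude),
      abundance = cor.test(keep$mu_opt, log(keep$abundance))
    )
  }
  list(optima = out[], tests = tests)
}
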