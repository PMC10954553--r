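#' Community configuration for the synthetic forest generator
#'
#' Describes one site's initial census: a log-series species abundance
#' distribution (Fisher's alpha), within-species spatial clustering from a
#' Thomas process (Poisson parents, isotropic Gaussian offspring), and a
#' truncated lognormal stem-size distribution. Defaults emulate a mid-sized
#' mapped forest plot: 9 ha, ~20,000 stems >= 1 cm DBH (about 2,200/ha),
#' 40 species, most stems in the sapling range.
#'
#' @param n_species Number of species.
#' @param fisher_alpha Log-series diversity parameter; together with
#'   `n_species` it sets the expected community size
#'   `N = alpha * (exp(S / alpha) - 1)`.
#' @param width,height Plot dimensions in metres.
#' @param cluster_rate Thomas-process parent intensity (parents per ha).
#' @param cluster_sd Gaussian offspring dispersion (m); very large values
#'   approach complete spatial randomness.
#' @param dbh_meanlog,dbh_sdlog Lognormal DBH parameters (cm scale).
#' @param dbh_max Upper truncation of DBH (cm); lower truncation is 1 cm.
#' @return Object of class `community_config`.
#' @export
community_config <- function(n_species = 40, fisher_alpha = 4.8,
                             width = 300, height = 300,
                             cluster_rate = 2, cluster_sd = 10,
                             dbh_meanlog = log(2.5), dbh_sdlog = 0.6,
                             dbh_max = 80) {
  assert_that(n_species >= 1 && fisher_alpha > 0 && cluster_rate > 0 && cluster_sd > 0,
              "all rates must be positive")
  structure(as.list(environment()), class = "community_config")
}

# draw counts from a log-series distribution with parameter x in (0,1)
r_logseries <- function(n, x, nmax = 1e6) {
  k <- seq_len(nmax)
  pmf <- x^k / k
  cdf <- cumsum(pmf) / sum(pmf)
  findInterval(runif(n), cdf) + 1L
}

#' Sample an initial synthetic census
#'
#' Species abundances are drawn i.i.d. from the log-series distribution
#' implied by `fisher_alpha` and `n_species`; locations come from a
#' per-species Thomas cluster process; DBHs are i.i.d. truncated lognormal.
#' Deterministic given `seed`.
#'
#' @param config A [community_config()].
#' @param seed Integer seed.
#' @param site Site name stored in the output.
#' @return Stem/tree table: `site`, `census_index` (= 1), `tree_id`,
#'   `species`, `x`, `y`, `dbh`, `status` (= "alive"), `date` (= 0).
#' @export
sample_community <- function(config, seed, site = "synthetic") {
  with_seed(seed, {
    S <- config$n_species
    alpha <- config$fisher_alpha
    N_exp <- alpha * (exp(S / alpha) - 1)
    if (N_exp < 1) stop("infeasible community: expected zero stems")
    xpar <- N_exp / (N_exp + alpha)
    counts <- r_logseries(S, xpar)
    area_ha <- config$width * config$height / 1e4
    rows <- vector("list", S)
    for (m in seq_len(S)) {
      n <- counts[m]
      n_par <- max(1L, rpois(1, config$cluster_rate * area_ha))
      px <- runif(n_par, 0, config$width)
      py <- runif(n_par, 0, config$height)
      parent <- sample.int(n_par, n, replace = TRUE)
      x <- px[parent] + rnorm(n, 0, config$cluster_sd)
      y <- py[parent] + rnorm(n, 0, config$cluster_sd)
      # resample out-of-bounds offspring (no toroidal wrap); fall back to
      # uniform placement after repeated failure
      for (it in 1:100) {
        out <- x < 0 | x > config$width | y < 0 | y > config$height
        if (!any(out)) break
        pj <- sample.int(n_par, sum(out), replace = TRUE)
        x[out] <- px[pj] + rnorm(sum(out), 0, config$cluster_sd)
        y[out] <- py[pj] + rnorm(sum(out), 0, config$cluster_sd)
      }
      out <- x < 0 | x > config$width | y < 0 | y > config$height
      x[out] <- runif(sum(out), 0, config$width)
      y[out] <- runif(sum(out), 0, config$height)
      u <- runif(n, plnorm(1, config$dbh_meanlog, config$dbh_sdlog),
                 plnorm(config$dbh_max, config$dbh_meanlog, config$dbh_sdlog))
      dbh <- qlnorm(u, config$dbh_meanlog, config$dbh_sdlog)
      sp <- sprintf("sp%02d", m)
      rows[[m]] <- data.table(site = site, census_index = 1L,
                              tree_id = sprintf("%s_%s_%06d", site, sp, seq_len(n)),
                              species = sp, x = x, y = y, dbh = dbh,
                              status = "alive", date = 0)
    }
    rbindlist(rows)
  })
}

#' Ground-truth mortality generator
#'
#' Mortality of every tree follows a discrete-time survival model with
#' complementary log-log link and *linear* terms on the link scale:
#' `cloglog(p) = beta0 + beta_con * conD + beta_tot * totD + beta_dbh * DBH
#' + log(dt)`, with densities computed under `config`. Linear truth gives
#' the downstream smooth fits a known closed-form target.
#'
#' @param baseline_mortality Annual mortality probability at zero covariates
#'   (scalar or per-species named vector).
#' @param beta_con True conspecific coefficient (per unit of `conD`; >= 0 for
#'   CNDD); scalar or per-species named vector.
#' @param beta_tot,beta_dbh Total-density and DBH coefficients.
#' @param config [density_config()] used to generate densities.
#' @param growth_rate Deterministic annual DBH increment of survivors (cm/yr),
#'   scalar or per-species.
#' @return Object of class `mortality_generator`.
#' @export
mortality_generator <- function(baseline_mortality = 0.02, beta_con = 0,
                                beta_tot = 1e-4, beta_dbh = -0.05,
                                config = density_config(),
                                growth_rate = 0.15) {
  assert_that(all(baseline_mortality > 0 & baseline_mortality < 1),
              "baseline annual mortality must be in (0,1)")
  structure(list(beta0 = log(-log(1 - baseline_mortality)),
                 beta_con = beta_con, beta_tot = beta_tot, beta_dbh = beta_dbh,
                 config = config, growth_rate = growth_rate),
            class = "mortality_generator")
}

per_species <- function(param, species) {
  if (is.null(names(param))) rep(param, length(species))
  else {
    v <- param[species]
    if (anyNA(v)) stop("missing per-species parameter for: ",
                       paste(unique(species[is.na(v)]), collapse = ", "))
    unname(v)
  }
}

generator_eta <- function(generator, species, conD, totD, dbh) {
  per_species(generator$beta0, species) +
    per_species(generator$beta_con, species) * conD +
    per_species(generator$beta_tot, species) * totD +
    per_species(generator$beta_dbh, species) * dbh
}

#' Advance a synthetic census by one interval
#'
#' Kernel densities are computed for every live tree from the current census;
#' each tree dies with `p = 1 - exp(-exp(eta + log(dt)))`; survivors grow by
#' the generator's deterministic increment. Deterministic given `seed`.
#'
#' @param census Tree table for one census (one site).
#' @param generator A [mortality_generator()].
#' @param delta_t Interval length in years.
#' @param seed Integer seed.
#' @return Tree table at the next census (`census_index + 1`); dead trees are
#'   carried with status `"dead"`.
#' @export
simulate_census_interval <- function(census, generator, delta_t, seed) {
  census <- as.data.table(census)
  live <- census[status == "alive"]
  dens <- compute_densities(live, live, generator$config)
  eta <- generator_eta(generator, live$species, dens$conD, dens$totD, live$dbh)
  p <- cloglog_inv(eta, delta_t)
  if (any(!is.finite(p))) {
    warning("non-finite mortality probabilities clamped")
    p[!is.finite(p)] <- 1 - 1e-12
  }
  died <- with_seed(seed, rbinom(nrow(live), 1L, p) == 1L)
  nxt <- copy(live)
  nxt[, status := ifelse(died, "dead", "alive")]
  nxt[status == "alive",
      dbh := dbh + per_species(generator$growth_rate, species) * delta_t]
  nxt[, `:=`(census_index = census_index + 1L, date = date + delta_t)]
  nxt[]
}

#' Closed-form ground-truth relative marginal effect
#'
#' Under the generating (linear cloglog) model, the true rAME of a species is
#' the average over its observed covariates of
#' `p(conD + delta) / p(conD) - 1` at `dt = 1`. Serves as the oracle for
#' parameter-recovery tests.
#'
#' @param generator A [mortality_generator()].
#' @param observations Observation/covariate table with columns `species`,
#'   `conD`, `totD`, `dbh`.
#' @param species Species code.
#' @param delta Conspecific-density perturbation (defaults to the generator
#'   config's [perturbation_delta()]).
#' @return List with `rAME` and `aAME`.
#' @export
true_rAME <- function(generator, observations, species, delta = NULL) {
  obs <- as.data.table(observations)
  sp_query <- species
  sub <- obs[species %in% sp_query]
  if (nrow(sub) == 0L) stop("species not present: ", species)
  if (is.null(delta)) delta <- perturbation_delta(generator$config)
  eta0 <- generator_eta(generator, sub$species, sub$conD, sub$totD, sub$dbh)
  eta1 <- generator_eta(generator, sub$species, sub$conD + delta, sub$totD, sub$dbh)
  p0 <- cloglog_inv(eta0, 1); p1 <- cloglog_inv(eta1, 1)
  list(rAME = mean(p1 / p0 - 1), aAME = mean(p1 - p0))
}

#' Scenario specification for multi-site ensembles
#'
#' Defines the ground truth of a latitudinal experiment: site latitudes, a
#' linear trend of mean true rAME with latitude (centred at 11.75 deg), an
#' interspecific spread of true effects and a target correlation between
#' log abundance and the conspecific coefficient.
#'
#' @param n_sites Number of sites.
#' @param latitudes Absolute site latitudes (recycled / defaulted to an even
#'   spread 5..50 deg).
#' @param mean_rAME Mean true rAME at the centring latitude (relative change
#'   per added conspecific neighbor; 0.05 default sits inside the range
#'   observed across real species).
#' @param rAME_slope Change in mean true rAME per degree latitude.
#' @param sd_rAME Interspecific s.d. of true rAME.
#' @param abundance_correlation Target correlation between log abundance and
#'   the species' conspecific coefficient (negative = stronger CNDD when rare).
#' @param n_censuses Number of censuses (>= 2).
#' @param delta_t Census interval (years).
#' @param community A [community_config()] shared by sites.
#' @param density A [density_config()] used by the generator.
#' @param baseline_mortality,beta_tot,beta_dbh Generator nuisance parameters.
#' @param seed Master seed; sites and censuses derive child seeds from it.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_sites = 2, latitudes = NULL,
                          mean_rAME = 0.05, rAME_slope = 0, sd_rAME = 0,
                          abundance_correlation = 0,
                          n_censuses = 2, delta_t = 5,
                          community = community_config(),
                          density = density_config(),
                          baseline_mortality = 0.02,
                          beta_tot = 1e-4, beta_dbh = -0.05,
                          seed = 1) {
  if (is.null(latitudes))
    latitudes <- if (n_sites == 1) 11.75 else seq(5, 50, length.out = n_sites)
  assert_that(length(latitudes) == n_sites, "need one latitude per site")
  structure(as.list(environment()), class = "scenario_spec")
}

#' Generate a multi-site ensemble with known truth
#'
#' For each site, draws a community, builds per-species true conspecific
#' coefficients whose implied rAMEs follow the scenario's latitude trend and
#' abundance correlation (via `beta_con = log(1 + rAME_target) / delta`,
#' exact when baseline mortality is small), simulates the censuses, and
#' stores the truth for recovery tests.
#'
#' @param scenario A [scenario_spec()].
#' @return List of per-site lists with elements `plot` ([plot_metadata()]),
#'   `trees` (all censuses stacked), `generator`, `truth` (per-species
#'   data.table: species, abundance, beta_con, rAME_target), plus attribute
#'   `scenario`.
#' @export
make_latitudinal_ensemble <- function(scenario) {
  delta <- perturbation_delta(scenario$density)
  sites <- vector("list", scenario$n_sites)
  for (l in seq_len(scenario$n_sites)) {
    site_name <- sprintf("site%02d", l)
    lat <- scenario$latitudes[l]
    census1 <- sample_community(scenario$community,
                                split_seed(scenario$seed, "site", l, "community"),
                                site = site_name)
    ab <- census1[dbh >= 1, .N, by = species]
    mean_target <- scenario$mean_rAME + scenario$rAME_slope * (lat - 11.75)
    z <- as.numeric(scale(log(ab$N)))
    if (length(z) == 1L || anyNA(z)) z <- rep(0, nrow(ab))
    r <- scenario$abundance_correlation
    noise <- with_seed(split_seed(scenario$seed, "site", l, "species_effects"),
                       rnorm(nrow(ab)))
    target <- mean_target + scenario$sd_rAME * (r * z + sqrt(max(0, 1 - r^2)) * noise)
    target <- pmax(target, -0.9)
    beta_con <- setNames(log1p(target) / delta, ab$species)
    gen <- mortality_generator(
      baseline_mortality = scenario$baseline_mortality,
      beta_con = beta_con, beta_tot = scenario$beta_tot,
      beta_dbh = scenario$beta_dbh, config = scenario$density)
    censuses <- list(census1)
    for (jj in seq_len(scenario$n_censuses - 1L)) {
      censuses[[jj + 1L]] <- simulate_census_interval(
        censuses[[jj]], gen, scenario$delta_t,
        split_seed(scenario$seed, "site", l, "census", jj))
    }
    trees <- rbindlist(censuses)
    plot <- plot_metadata(site_name, scenario$community$width,
                          scenario$community$height, lat,
                          census_dates = (seq_len(scenario$n_censuses) - 1) * scenario$delta_t)
    area_ha <- plot$area_ha
    truth <- data.table(site = site_name, species = ab$species,
                        abundance = ab$N / area_ha,
                        beta_con = unname(beta_con), rAME_target = target)
    sites[[l]] <- list(plot = plot, trees = trees, generator = gen, truth = truth)
  }
  attr(sites, "scenario") <- scenario
  sites
}

#' Write scenario ground truth to JSON
#'
#' @param ensemble Result of [make_latitudinal_ensemble()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(ensemble, path) {
  scen <- attr(ensemble, "scenario")
  out <- list(
    scenario = scen[!vapply(scen, is.object, logical(1))],
    sites = lapply(ensemble, function(s) list(
      site = s$plot$site_name, latitude = s$plot$absolute_latitude,
      truth = s$truth))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
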