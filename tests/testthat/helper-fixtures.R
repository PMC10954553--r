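library(data.table)

# small canonical observation table with linear-cloglog mortality, used by
# model-level tests; covariates are continuous so the fit uses full smooths
make_linear_obs <- function(n = 2000, beta0 = log(-log(0.98)), beta_con = 0.02,
                            beta_tot = 1e-4, beta_dbh = -0.05, dt = 5,
                            seed = 1, j = 1L) {
  withr::with_seed(seed, {
    conD <- rexp(n, 1 / 5)
    totD <- 1000 + 800 * runif(n)
    dbh <- pmin(9.9, 1 + rexp(n, 1 / 2))
    eta <- beta0 + beta_con * conD + beta_tot * totD + beta_dbh * dbh
    p <- 1 - exp(-exp(eta + log(dt)))
    data.table(site = "s1", tree_id = sprintf("t%06d", seq_len(n)),
               species = "spA", j = j, Y = rbinom(n, 1, p), dt = dt,
               dbh = dbh, x = runif(n, 0, 100), y = runif(n, 0, 100),
               edge_excluded = FALSE, conD = conD, totD = totD)
  })
}

# random point pattern for density tests
make_point_census <- function(n = 500, width = 100, height = 100,
                              n_species = 5, seed = 1) {
  withr::with_seed(seed, {
    data.table(site = "s1", census_index = 1L,
               tree_id = sprintf("t%05d", seq_len(n)),
               species = sample(sprintf("sp%02d", seq_len(n_species)), n, TRUE),
               x = runif(n, 0, width), y = runif(n, 0, height),
               dbh = 1 + rexp(n, 1 / 3), status = "alive", date = 0)
  })
}

# shared small 2-site ensemble with densities attached (built once per file)
small_ensemble_cache <- new.env(parent = emptyenv())
small_ensemble <- function() {
  if (is.null(small_ensemble_cache$data)) {
    scen <- scenario_spec(n_sites = 2, mean_rAME = 0.08, seed = 99,
                          community = community_config(n_species = 12,
                                                       fisher_alpha = 2.2,
                                                       width = 220, height = 220))
    ens <- make_latitudinal_ensemble(scen)
    trees <- rbindlist(lapply(ens, `[[`, "trees"))
    obs <- rbindlist(lapply(ens, function(s) build_observations(s$trees, s$plot)))
    obs <- attach_densities(obs, trees, density_config())
    smeta <- rbindlist(lapply(ens, function(s)
      data.table(site = s$plot$site_name,
                 absolute_latitude = s$plot$absolute_latitude)))
    ab <- rbindlist(lapply(ens, function(s) s$truth[, .(site, species, abundance)]))
    small_ensemble_cache$data <- list(scen = scen, ens = ens, trees = trees,
                                      obs = obs, site_metadata = smeta,
                                      abundances = ab)
  }
  small_ensemble_cache$data
}

# meta-analytic records simulated from the multilevel model itself
simulate_records <- function(n_sites, n_species, b0 = 0.004, sigma_r = 0.002,
                             sigma_s = 0.005, v = 1e-5, seed = 1) {
  withr::with_seed(seed, {
    r <- rnorm(n_sites, 0, sigma_r)
    rec <- CJ(site = sprintf("s%02d", seq_len(n_sites)),
              species = sprintf("sp%03d", seq_len(n_species)))
    rec[, v := v]
    rec[, y := b0 + r[as.integer(factor(site))] + rnorm(.N, 0, sigma_s) +
          rnorm(.N, 0, sqrt(v))]
    rec[, absolute_latitude := 10 + 2 * as.integer(factor(site))]
    rec[, abundance := exp(runif(.N, 0, 5))]
    rec[, tLatitude := absolute_latitude - 11.75]
    rec[, tAbundance := log(abundance)]
    rec[]
  })
}
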