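test_that("sample_community is deterministic and respects the configuration", {
  cfg <- community_config(n_species = 8, fisher_alpha = 2, width = 120, height = 120)
  a <- sample_community(cfg, seed = 4)
  b <- sample_community(cfg, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, sample_community(cfg, seed = 5)))
  expect_true(all(a$x >= 0 & a$x <= 120 & a$y >= 0 & a$y <= 120))
  expect_true(all(a$dbh >= 1 & a$dbh <= cfg$dbh_max))

  one <- sample_community(community_config(n_species = 1, fisher_alpha = 2), seed = 1)
  expect_equal(unique(one$species), "sp01")
})

test_that("huge cluster_sd approaches complete spatial randomness (Clark-Evans)", {
  cfg <- community_config(n_species = 3, fisher_alpha = 1.2, width = 200,
                          height = 200, cluster_sd = 1e6)
  cen <- sample_community(cfg, seed = 21)
  # Clark-Evans index: observed mean nearest-neighbor distance over the
  # CSR expectation 1/(2 sqrt(lambda))
  nn <- vapply(seq_len(nrow(cen)), function(i) {
    d <- sqrt((cen$x - cen$x[i])^2 + (cen$y - cen$y[i])^2)
    min(d[-i])
  }, numeric(1))
  lambda <- nrow(cen) / (200 * 200)
  ce <- mean(nn) * 2 * sqrt(lambda)
  expect_gt(ce, 0.9)
  expect_lt(ce, 1.1)
  # and strong clustering gives a clearly smaller index
  cl <- sample_community(community_config(n_species = 3, fisher_alpha = 1.2,
                                          width = 200, height = 200,
                                          cluster_rate = 0.5, cluster_sd = 3),
                         seed = 21)
  nn_cl <- vapply(seq_len(nrow(cl)), function(i) {
    d <- sqrt((cl$x - cl$x[i])^2 + (cl$y - cl$y[i])^2)
    min(d[-i])
  }, numeric(1))
  ce_cl <- mean(nn_cl) * 2 * sqrt(nrow(cl) / (200 * 200))
  expect_lt(ce_cl, ce)
})

test_that("log-series draws match the log-series pmf (chi-square GOF)", {
  x <- 0.98
  draws <- withr::with_seed(31, cnddtools:::r_logseries(5000, x))
  kmax <- 30L
  obs_counts <- tabulate(pmin(draws, kmax + 1L), nbins = kmax + 1L)
  k <- seq_len(kmax)
  pmf <- x^k / k / -log(1 - x)
  probs <- c(pmf, 1 - sum(pmf))
  gof <- suppressWarnings(chisq.test(obs_counts, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulate_census_interval reproduces binomial mortality expectations", {
  n <- 10000
  cen <- data.table(site = "s", census_index = 1L,
                    tree_id = sprintf("t%05d", 1:n), species = "sp01",
                    x = runif(n, 0, 600), y = runif(n, 0, 600),
                    dbh = 2, status = "alive", date = 0)
  gen <- mortality_generator(baseline_mortality = 0.02, beta_con = 0,
                             beta_tot = 0, beta_dbh = 0)
  nxt <- simulate_census_interval(cen, gen, delta_t = 1, seed = 8)
  deaths <- sum(nxt$status == "dead")
  expect_lt(abs(deaths - 200), 3 * sqrt(10000 * 0.02 * 0.98))
  expect_equal(nxt$census_index, rep(2L, n))

  # dt = 0: no deaths, no growth of the clock
  none <- simulate_census_interval(cen, gen, delta_t = 0, seed = 8)
  expect_equal(sum(none$status == "dead"), 0L)

  # determinism
  expect_identical(nxt, simulate_census_interval(cen, gen, delta_t = 1, seed = 8))
})

test_that("positive conspecific coefficient raises conD among the dying", {
  cfg <- community_config(n_species = 5, fisher_alpha = 0.9, width = 150,
                          height = 150, cluster_sd = 6)
  diff_sum <- 0
  for (s in 1:3) {
    cen <- sample_community(cfg, seed = s)
    gen <- mortality_generator(baseline_mortality = 0.05, beta_con = 0.05,
                               beta_tot = 0, beta_dbh = 0)
    dens <- compute_densities(cen, cen, gen$config)
    nxt <- simulate_census_interval(cen, gen, delta_t = 5, seed = s + 100)
    died <- nxt$status == "dead"
    expect_gte(sum(died), 5)
    diff_sum <- diff_sum + mean(dens$conD[died]) - mean(dens$conD[!died])
  }
  expect_gt(diff_sum, 0)
})

test_that("true_rAME matches hand computation and is monotone in beta_con", {
  obs <- data.table(species = "sp01", conD = 2, totD = 100, dbh = 3)
  gen0 <- mortality_generator(beta_con = 0)
  expect_equal(true_rAME(gen0, obs, "sp01")$rAME, 0)
  gen <- mortality_generator(baseline_mortality = 0.02, beta_con = 0.03,
                             beta_tot = 1e-4, beta_dbh = -0.05)
  delta <- perturbation_delta(gen$config)
  eta0 <- log(-log(0.98)) + 0.03 * 2 + 1e-4 * 100 - 0.05 * 3
  p0 <- 1 - exp(-exp(eta0))
  p1 <- 1 - exp(-exp(eta0 + 0.03 * delta))
  tr <- true_rAME(gen, obs, "sp01")
  expect_equal(tr$rAME, p1 / p0 - 1, tolerance = 1e-12)
  expect_equal(tr$aAME, p1 - p0, tolerance = 1e-12)
  gen2 <- mortality_generator(baseline_mortality = 0.02, beta_con = 0.06,
                              beta_tot = 1e-4, beta_dbh = -0.05)
  expect_gt(true_rAME(gen2, obs, "sp01")$rAME, tr$rAME)
  expect_error(true_rAME(gen, obs, "nope"), "not present")
})

test_that("latitudinal ensembles store exact truths with the requested structure", {
  # zero slope: stored targets are constant across sites by construction
  scen0 <- scenario_spec(n_sites = 3, mean_rAME = 0.05, rAME_slope = 0,
                         sd_rAME = 0, n_censuses = 2, seed = 12,
                         community = community_config(n_species = 6,
                                                      fisher_alpha = 1.5,
                                                      width = 100, height = 100))
  ens0 <- make_latitudinal_ensemble(scen0)
  truths <- rbindlist(lapply(ens0, `[[`, "truth"))
  expect_equal(unique(truths$rAME_target), 0.05)
  expect_equal(length(ens0), 3L)

  # abundance correlation close to the target at many species
  scen_r <- scenario_spec(n_sites = 1, mean_rAME = 0.05, sd_rAME = 0.02,
                          abundance_correlation = -0.5, seed = 13,
                          community = community_config(n_species = 150,
                                                       fisher_alpha = 25,
                                                       width = 150, height = 150))
  ens_r <- make_latitudinal_ensemble(scen_r)
  tr <- ens_r[[1]]$truth
  r_emp <- cor(log(tr$abundance), tr$beta_con)
  expect_lt(abs(r_emp - (-0.5)), 0.2)

  # single-site ensemble works and is reproducible
  one <- make_latitudinal_ensemble(scenario_spec(n_sites = 1, seed = 5,
    community = community_config(n_species = 4, fisher_alpha = 1.2,
                                 width = 80, height = 80)))
  one2 <- make_latitudinal_ensemble(scenario_spec(n_sites = 1, seed = 5,
    community = community_config(n_species = 4, fisher_alpha = 1.2,
                                 width = 80, height = 80)))
  expect_identical(one[[1]]$trees, one2[[1]]$trees)
})

test_that("ground truth JSON export round-trips the scenario", {
  f <- withr::local_tempfile(fileext = ".json")
  ens <- make_latitudinal_ensemble(scenario_spec(n_sites = 1, seed = 5,
    community = community_config(n_species = 3, fisher_alpha = 1.2,
                                 width = 60, height = 60)))
  write_ground_truth(ens, f)
  got <- jsonlite::fromJSON(f)
  expect_equal(got$scenario$seed, 5)
  expect_equal(got$sites$site, "site01")
})
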