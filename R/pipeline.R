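#' Reference global meta-regression coefficients
#'
#' Fixed-effect coefficients of the two published global meta-regressions of
#' stabilizing CNDD across 23 mapped forest plots (response:
#' `log(rAME + 1)`; covariates centred at 11.75 deg absolute latitude and
#' 1 tree/ha): the `"average"` model (latitude only) and the `"abundance"`
#' model (latitude, log abundance and their interaction). Shipped as a
#' worked-example input for [predict_cndd_percent()].
#'
#' @param model `"average"` or `"abundance"`.
#' @return Named coefficient vector.
#' @export
reference_meta_coefficients <- function(model = c("average", "abundance")) {
  model <- match.arg(model)
  path <- system.file("extdata", "global_meta_coefficients.csv",
                      package = "cnddtools", mustWork = TRUE)
  tab <- fread(path)
  wanted <- model
  sub <- tab[tab[["model"]] == wanted]
  setNames(sub$beta, sub$term)
}

pipeline_defaults <- function() {
  list(
    seed = 1,
    output_dir = NULL,
    scenario = list(n_sites = 2, n_censuses = 2, delta_t = 5,
                    mean_rAME = 0.05, rAME_slope = 0, sd_rAME = 0,
                    abundance_correlation = 0,
                    n_species = 40, fisher_alpha = 4.8,
                    width = 300, height = 300),
    input = NULL,  # alternatively: list of per-site census CSV paths + metadata
    density = list(estimator = "BA", kind = "exponential",
                   mu_con = 3, mu_tot = 17, radius = 30,
                   grid_search = FALSE, mu_grid = seq(1, 25, by = 2)),
    model = list(k = 10, n_draws = 500),
    meta = list(center_latitude = 11.75, center_abundance = 1,
                alpha = 0.05, cook_threshold = 0.005),
    edge_buffer = 30,
    stages = list(robustness = FALSE, interquantile = TRUE)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML or JSON document (or takes a list), checks keys and types
#' against the schema, and injects defaults (`k = 10`, `n_draws = 500`,
#' decay grid 1 to 25 m in 2 m steps, 30 m radius, centring at 11.75 deg
#' and 1 tree/ha, `alpha = 0.05`, Cook's threshold 0.005). Unknown keys and
#' type mismatches are collected and reported together.
#'
#' @param config Path to a YAML/JSON file, or a (possibly partial) list; an
#'   empty document yields the full default configuration.
#' @return Normalized configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (grepl("^\\s*\\{", txt)) jsonlite::fromJSON(txt, simplifyVector = TRUE)
    else if (requireNamespace("yaml", quietly = TRUE)) yaml::yaml.load(txt)
    else jsonlite::fromJSON(txt, simplifyVector = TRUE)
    if (is.null(config)) config <- list()
  }
  defaults <- pipeline_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) errors <- c(errors, paste("unknown keys:", paste(unknown, collapse = ", ")))
  for (sect in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[sect]]) && !is.null(config[[sect]])) {
      if (!is.list(config[[sect]])) {
        errors <- c(errors, paste0("'", sect, "' must be a list"))
        next
      }
      bad <- setdiff(names(config[[sect]]), names(defaults[[sect]]))
      if (length(bad) && sect != "input" && sect != "scenario")
        errors <- c(errors, paste0("unknown keys in '", sect, "': ",
                                   paste(bad, collapse = ", ")))
    }
  }
  merged <- modifyList(defaults, config)
  if (merged$density$radius <= 0) errors <- c(errors, "density radius must be positive")
  if (merged$model$n_draws < 2) errors <- c(errors, "n_draws must be >= 2")
  if (any(merged$density$mu_grid <= 0)) errors <- c(errors, "mu grid values must be positive")
  if (length(errors)) stop("invalid configuration:\n  ",
                           paste(errors, collapse = "\n  "), call. = FALSE)
  structure(merged, class = "pipeline_config")
}

# stable content hash of an R object (FNV-1a over its serialization)
object_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261 %% 2147483647
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full CNDD estimation pipeline
#'
#' Executes simulate/ingest, neighborhood densities (optionally the grid
#' search), mortality fits, AMEs, meta-regressions, and optional robustness
#' checks, from one validated configuration. When `output_dir` is set, all
#' stage outputs are written as CSV/JSON together with a run manifest.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @return Results list: `observations`, `ame`, `records`, `meta_average`,
#'   `meta_abundance`, `site_summaries`, `site_abundance`, `interquantile`,
#'   `truth` (synthetic runs), `robustness` (optional), `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  config <- validate_config(unclass(config))
  t0 <- proc.time()[3]
  manifest <- list(config_hash = object_hash(unclass(config)),
                   package_version = as.character(utils::packageVersion("cnddtools")),
                   stages = list())
  tick <- function(stage) {
    manifest$stages[[stage]] <<- round(proc.time()[3] - t0, 2)
  }

  # --- data stage: synthetic scenario or ingest ---
  if (is.null(config$input)) {
    sc <- config$scenario
    scen <- scenario_spec(
      n_sites = sc$n_sites %||% 2,
      latitudes = sc$latitudes,
      mean_rAME = sc$mean_rAME %||% 0.05,
      rAME_slope = sc$rAME_slope %||% 0,
      sd_rAME = sc$sd_rAME %||% 0,
      abundance_correlation = sc$abundance_correlation %||% 0,
      n_censuses = sc$n_censuses %||% 2,
      delta_t = sc$delta_t %||% 5,
      community = community_config(
        n_species = sc$n_species %||% 40,
        fisher_alpha = sc$fisher_alpha %||% 4.8,
        width = sc$width %||% 300, height = sc$height %||% 300),
      density = do.call(density_config, config$density[c("estimator", "kind",
                                                         "mu_con", "mu_tot", "radius")]),
      seed = config$seed)
    ensemble <- make_latitudinal_ensemble(scen)
    trees <- rbindlist(lapply(ensemble, `[[`, "trees"))
    plots <- lapply(ensemble, `[[`, "plot")
    truth <- rbindlist(lapply(ensemble, `[[`, "truth"))
  } else {
    stop("file-based ingestion: read censuses with read_census_tables() and ",
         "pass the canonical tables to the stage functions directly")
  }
  names(plots) <- vapply(plots, `[[`, "", "site_name")
  site_metadata <- rbindlist(lapply(plots, function(p)
    data.table(site = p$site_name, absolute_latitude = p$absolute_latitude)))
  obs <- rbindlist(lapply(plots, function(p)
    build_observations(trees[site == p$site_name], p, buffer_m = config$edge_buffer)))
  tick("data")

  # --- densities (and optional grid search) ---
  dcfg <- do.call(density_config, config$density[c("estimator", "kind",
                                                   "mu_con", "mu_tot", "radius")])
  grid <- NULL
  if (isTRUE(config$density$grid_search)) {
    grid <- grid_search_mu(obs, trees, mu_grid = config$density$mu_grid,
                           radius = config$density$radius,
                           model_settings = list(k = config$model$k))
    dcfg <- grid$selected
  }
  obs <- attach_densities(obs, trees, dcfg)
  tick("densities")

  # --- growth forms & abundances ---
  gf <- vapply(split(trees, trees$species), classify_growth_form, "")
  ab_rows <- list()
  for (p in plots) {
    a <- compute_abundance(trees[site == p$site_name], p, census = 1)
    ab_rows[[p$site_name]] <- data.table(site = p$site_name,
                                         species = names(a), abundance = unname(a))
  }
  abundances <- rbindlist(ab_rows)

  # --- mortality fits + AMEs ---
  variants <- c("equilibrium", "invasion",
                if (isTRUE(config$stages$interquantile)) "interquantile")
  est <- estimate_cndd(obs, config = dcfg, growth_forms = gf,
                       variants = variants,
                       n_draws = config$model$n_draws,
                       seed = split_seed(config$seed, "ame"), k = config$model$k)
  # pooled groups: abundance is the mean of member species' abundances
  if (nrow(est$members)) {
    grp_ab <- merge(est$members, abundances, by = c("site", "species"))[
      , .(abundance = group_abundance(abundance)), by = .(site, group)]
    abundances <- rbind(abundances,
                        grp_ab[, .(site, species = group, abundance)])
  }
  tick("ame")

  # --- meta-regressions ---
  rec <- build_records(est$ame[variant == "equilibrium"], site_metadata, abundances,
                       center_latitude = config$meta$center_latitude,
                       center_abundance = config$meta$center_abundance)
  if (nrow(rec) < 2L)
    stop("no usable CNDD estimates: the dataset is too small for any ",
         "species or group model to converge")
  multi_site <- length(unique(rec$site)) > 1L
  meta_a <- fit_meta_regression(rec, if (multi_site) ~ tLatitude else ~ 1)
  meta_b <- if (multi_site)
    fit_meta_regression(rec, ~ tLatitude * tAbundance) else NULL
  sites_out <- site_summaries(rec)
  site_ab <- site_abundance_models(rec)
  iq <- NULL
  if (isTRUE(config$stages$interquantile) &&
      nrow(est$ame[variant == "interquantile"])) {
    rec_iq <- build_records(est$ame[variant == "interquantile"], site_metadata,
                            abundances)
    iq <- tryCatch(global_interquantile_summary(rec_iq), error = function(e) NULL)
  }
  tick("meta")

  # --- robustness (optional) ---
  rob <- NULL
  if (isTRUE(config$stages$robustness)) {
    infl <- influence_filter(if (multi_site) meta_b else meta_a,
                             threshold = config$meta$cook_threshold)
    obs_by_fit <- lapply(names(est$fits), function(key) {
      parts <- strsplit(key, "::", fixed = TRUE)[[1]]
      if (grepl("^pooled", parts[2])) obs[site == parts[1]][0]
      else obs[site == parts[1] & species == parts[2] & edge_excluded == FALSE]
    })
    names(obs_by_fit) <- names(est$fits)
    scr <- spatial_autocorrelation_screen(est$fits, obs_by_fit,
                                          seed = split_seed(config$seed, "screen"),
                                          n_perm = 199)
    rob <- list(influence = infl, spatial = scr)
    tick("robustness")
  }

  results <- list(config = config, observations = obs, trees = trees,
                  site_metadata = site_metadata, abundances = abundances,
                  density_config = dcfg, grid = grid,
                  ame = est$ame, eligibility = est$eligibility, fits = est$fits,
                  records = rec, meta_average = meta_a, meta_abundance = meta_b,
                  site_summaries = sites_out, site_abundance = site_ab,
                  interquantile = iq, truth = truth, robustness = rob,
                  manifest = manifest)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    write_observations(obs, file.path(od, "observations.csv"))
    fwrite(est$ame, file.path(od, "ame.csv"))
    fwrite(meta_coef_table(results), file.path(od, "meta_coefficients.csv"))
    fwrite(sites_out$summaries, file.path(od, "site_summaries.csv"))
    if (!is.null(grid)) fwrite(grid$table, file.path(od, "grid_search.csv"))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE)
    writeLines(make_report(results), file.path(od, "report.md"))
  }
  results
}

meta_coef_table <- function(results) {
  one <- function(fit, label) {
    if (is.null(fit)) return(NULL)
    data.table(model = label, term = names(fit$b), beta = unname(fit$b),
               ci_low = fit$ci_low, ci_high = fit$ci_high, p = unname(fit$p),
               sigma_r = fit$sigma_r, sigma_s = fit$sigma_s)
  }
  rbindlist(list(one(results$meta_average, "average"),
                 one(results$meta_abundance, "abundance")))
}

#' Human-readable pipeline report
#'
#' Markdown summary of a [run_pipeline()] result: the two global
#' meta-regression coefficient tables, back-transformed predictions,
#' per-site abundance slopes, the CV table, and a robustness synopsis.
#' Skipped stages are marked as such. Deterministic given the results.
#'
#' @param results A [run_pipeline()] result.
#' @return Character vector of markdown lines.
#' @export
make_report <- function(results) {
  fmt <- function(x, d = 4) formatC(x, digits = d, format = "g")
  lines <- c("# CNDD pipeline report", "",
             paste0("Config hash: ", results$manifest$config_hash), "")
  coefs <- meta_coef_table(results)
  if (nrow(coefs)) {
    lines <- c(lines, "## Global meta-regressions", "",
               "| model | term | beta | 95% CI | p | sigma_r | sigma_s |",
               "|---|---|---|---|---|---|---|",
               coefs[, sprintf("| %s | %s | %s | %s, %s | %s | %s | %s |",
                               model, term, fmt(beta), fmt(ci_low), fmt(ci_high),
                               fmt(p, 2), fmt(sigma_r), fmt(sigma_s))], "")
    cl <- attr(results$records, "center_latitude") %||% 11.75
    pr <- predict_cndd_percent(results$meta_average, cl, center_latitude = cl)
    lines <- c(lines, sprintf(
      "Back-transformed mean CNDD at the centring latitude: %s%% relative increase in annual mortality per added conspecific neighbor.",
      fmt(pr, 3)), "")
  }
  if (!is.null(results$site_abundance) && nrow(results$site_abundance)) {
    lines <- c(lines, "## Per-site abundance slopes", "",
               "| site | slope | 95% CI | p |", "|---|---|---|---|",
               results$site_abundance[, sprintf("| %s | %s | %s, %s | %s |",
                                                site, fmt(slope), fmt(ci_low),
                                                fmt(ci_high), fmt(p, 2))], "")
  } else lines <- c(lines, "## Per-site abundance slopes", "", "_skipped_", "")
  ss <- results$site_summaries$summaries
  if (!is.null(ss) && nrow(ss)) {
    lines <- c(lines, "## Interspecific variation (per site)", "",
               "| site | mean | s.d. | CV | CV > 0.4 |", "|---|---|---|---|---|",
               ss[, sprintf("| %s | %s | %s | %s | %s |", site, fmt(mean_y),
                            fmt(sd_y), fmt(cv), cv_above_threshold)], "")
  }
  if (!is.null(results$interquantile)) {
    iq <- results$interquantile
    lines <- c(lines, sprintf(
      "Global interquantile CNDD: %s%% (95%% CI %s to %s%%).",
      fmt(iq$percent, 3), fmt(iq$ci_low, 3), fmt(iq$ci_high, 3)), "")
  }
  if (!is.null(results$robustness)) {
    rb <- results$robustness
    lines <- c(lines, "## Robustness", "",
               sprintf("- influence filter removed %d of %d records",
                       length(rb$influence$removed), length(rb$influence$distances)),
               if (nrow(rb$spatial))
                 sprintf("- spatial screening flagged %s of %d models",
                         fmt(attr(rb$spatial, "flagged_share") * nrow(rb$spatial), 0),
                         nrow(rb$spatial))
               else "- spatial screening: no testable models", "")
  } else lines <- c(lines, "## Robustness", "", "_skipped_", "")
  lines
}
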