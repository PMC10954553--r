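#' Within-species randomization of the observation table
#'
#' Permutes one column within each species-site group, leaving everything
#' else untouched: `"status_within_species"` shuffles the outcome `Y`
#' (removes any mortality-predictor relationship but keeps species-level
#' mortality rates), `"conD_within_species"` shuffles conspecific density
#' (removes the density-mortality relationship but keeps the
#' confounder-mortality relationships). Deterministic given `seed`;
#' within-group multisets are preserved exactly.
#'
#' @param observations Canonical observation table (with densities for the
#'   conD mode).
#' @param mode `"status_within_species"` or `"conD_within_species"`.
#' @param seed Integer seed.
#' @return Randomized copy of the table.
#' @export
randomize_dataset <- function(observations,
                              mode = c("status_within_species", "conD_within_species"),
                              seed = 1) {
  mode <- match.arg(mode)
  obs <- copy(as.data.table(observations))
  col <- if (mode == "status_within_species") "Y" else "conD"
  with_seed(seed, {
    obs[, (col) := { v <- get(col); if (.N > 1L) sample(v) else v },
        by = .(site, species)]
  })
  obs[]
}

#' Rerun the estimation pipeline on randomized data
#'
#' Runs mortality models, AMEs and the global meta-regressions on a
#' randomized observation table; used to verify that the pipeline reports
#' near-zero CNDD and no latitude/abundance patterns when the signal has
#' been destroyed.
#'
#' @param observations Observation table with densities attached.
#' @param spec List with `mode`, `seed` and optionally `n_replicates`.
#' @param site_metadata,abundances As in [build_records()].
#' @param config,n_draws,k As in [estimate_cndd()].
#' @param fixed Fixed-effect formula for the meta-regression.
#' @return data.table with one row per replicate: intercept and predictor
#'   coefficients with CIs from the refitted meta-regression.
#' @export
null_pipeline_check <- function(observations, spec, site_metadata, abundances,
                                config = density_config(), n_draws = 200,
                                k = 10, fixed = ~ tLatitude) {
  n_rep <- spec$n_replicates %||% 1L
  rows <- list()
  for (r in seq_len(n_rep)) {
    rnd <- randomize_dataset(observations, spec$mode,
                             seed = split_seed(spec$seed, "randomize", r))
    est <- estimate_cndd(rnd, config = config,
                         variants = "equilibrium", n_draws = n_draws,
                         seed = split_seed(spec$seed, "ame", r), k = k)
    ab <- as.data.table(abundances)
    if (nrow(est$members)) {
      grp <- merge(est$members, ab, by = c("site", "species"))[
        , .(abundance = group_abundance(abundance)), by = .(site, group)]
      ab <- rbind(ab[, .(site, species, abundance)],
                  grp[, .(site, species = group, abundance)])
    }
    rec <- build_records(est$ame, site_metadata, ab)
    fit <- fit_meta_regression(rec, fixed)
    rows[[r]] <- data.table(replicate = r, term = names(fit$b), beta = unname(fit$b),
                            ci_low = fit$ci_low, ci_high = fit$ci_high,
                            p = unname(fit$p))
  }
  rbindlist(rows)
}

#' Cook's distances and influence filtering for a meta-regression
#'
#' Leave-one-out Cook's distance per record, computed on the fixed effects
#' with variance components held at their full-data estimates (the fast
#' approximation): `D_i = (b - b_(-i))' X'V^-1X (b - b_(-i))`. Records above
#' the threshold are removed and the model refitted on the remainder.
#'
#' @param fit A `meta_fit`.
#' @param threshold Cook's distance cutoff (default 0.005).
#' @return List with `distances` (per-record), `removed` (indices),
#'   `records` (reduced table) and `refit` (`meta_fit` on the remainder, or
#'   the original fit when nothing is removed).
#' @export
influence_filter <- function(fit, threshold = 0.005) {
  y <- fit$y; X <- fit$X; v <- fit$v
  site <- if (fit$include_site) fit$site else NULL
  s_r2 <- fit$sigma_r^2; s_s2 <- fit$sigma_s^2
  full <- reml_criterion(y, X, v, site, s_r2, s_s2)
  XtVX <- solve(full$vcov_b)
  n <- length(y)
  d <- numeric(n)
  for (i in seq_len(n)) {
    loo <- reml_criterion(y[-i], X[-i, , drop = FALSE], v[-i],
                          if (is.null(site)) NULL else site[-i], s_r2, s_s2)
    db <- full$b - loo$b
    d[i] <- as.numeric(t(db) %*% XtVX %*% db)
  }
  removed <- which(d > threshold)
  reduced <- fit$records[setdiff(seq_len(n), removed)]
  refit <- if (length(removed))
    tryCatch(fit_meta_regression(reduced, fit$fixed, include_site = fit$include_site),
             error = function(e) {
               warning("refit on the reduced dataset failed: ", conditionMessage(e))
               NULL
             })
  else fit
  list(distances = d, removed = removed, records = reduced, refit = refit)
}

# Moran's I with inverse-distance weights for neighbors within `radius`
morans_i <- function(z, x, y, radius = 30) {
  n <- length(z)
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  d <- sqrt(dx^2 + dy^2)
  W <- ifelse(d > 0 & d <= radius, 1 / pmax(d, 0.5), 0)
  diag(W) <- 0
  s0 <- sum(W)
  if (s0 == 0) return(NA_real_)
  zc <- z - mean(z)
  denom <- sum(zc^2)
  if (denom == 0) return(NA_real_)
  (n / s0) * as.numeric(t(zc) %*% W %*% zc) / denom
}

#' Spatial autocorrelation screening of mortality models
#'
#' Tests each fitted species-site model for residual spatial
#' autocorrelation: randomized quantile residuals, Moran's I with
#' inverse-distance weights among observations within 30 m, a permutation
#' p-value (999 permutations), and a Holm adjustment across all models.
#' Models with fewer than `min_obs` observations or degenerate residuals are
#' skipped with a warning.
#'
#' @param fits Named list of `mortality_fit` objects (keys `site::species`).
#' @param observations_by_fit Named list of matching observation tables
#'   (with `x`, `y`, `Y`).
#' @param seed Integer seed.
#' @param n_perm Number of permutations (default 999).
#' @param min_obs Minimum observations per model (default 10).
#' @param alpha Significance level for the flags.
#' @return data.table: model, n, moran_i, p_raw, p_holm, flagged; plus
#'   attribute `flagged_share`.
#' @export
spatial_autocorrelation_screen <- function(fits, observations_by_fit, seed = 1,
                                           n_perm = 999, min_obs = 10L,
                                           alpha = 0.05) {
  rows <- list()
  for (key in names(fits)) {
    fit <- fits[[key]]
    obs <- as.data.table(observations_by_fit[[key]])
    if (is.null(fit) || !isTRUE(fit$converged) || nrow(obs) < min_obs) next
    res <- model_residual_quantiles(fit, obs, seed = split_seed(seed, key, "resid"))
    if (var(res) == 0) {
      warning("degenerate residuals, model skipped: ", key)
      next
    }
    i_obs <- morans_i(res, obs$x, obs$y)
    if (is.na(i_obs)) next
    i_perm <- with_seed(split_seed(seed, key, "perm"), {
      vapply(seq_len(n_perm), function(b) morans_i(sample(res), obs$x, obs$y),
             numeric(1))
    })
    p_raw <- (1 + sum(abs(i_perm) >= abs(i_obs))) / (n_perm + 1)
    rows[[length(rows) + 1]] <- data.table(model = key, n = nrow(obs),
                                           moran_i = i_obs, p_raw = p_raw)
  }
  out <- rbindlist(rows)
  if (nrow(out)) {
    out[, p_holm := p.adjust(p_raw, method = "holm")]
    out[, flagged := p_holm < alpha]
    setattr(out, "flagged_share", mean(out$flagged))
  }
  out[]
}

#' Species-site life-history covariates
#'
#' Proxies for life history strategy used in confounder models, all
#' standardized within site (mean 0, s.d. 1):
#' * growth: `log(median annual DBH increment + 1)` of surviving stems;
#' * survival: logit of mean annual survival from an intercept-only cloglog
#'   fit (`1 - p` at `dt = 1`);
#' * stature: log 90th-percentile DBH over all individuals;
#' * two trade-off axes from principal-component rotations: axis 1 from
#'   (growth, survival), axis 2 from (stature, recruitment proxy), where the
#'   recruitment proxy is the per-abundance influx of new individuals (the
#'   standardized stature alone when influx is not computable). The axes
#'   approximate published demographic trade-off constructions.
#'
#' @param trees Tree table across censuses for one or more sites.
#' @param observations Canonical observation table (supplies the survival
#'   model inputs per species-site).
#' @return data.table: site, species, growth, survival, stature,
#'   recruitment, axis_growth_survival, axis_stature_recruitment (all
#'   standardized within site; NA where not computable).
#' @export
compute_life_history <- function(trees, observations) {
  trees <- as.data.table(trees)
  obs <- as.data.table(observations)
  rows <- list()
  for (s in unique(trees$site)) {
    tr <- trees[site == s]
    setorder(tr, tree_id, census_index)
    # annual DBH increments of stems alive in consecutive censuses
    inc <- tr[, {
      if (.N > 1 && any(status == "alive")) {
        dd <- diff(dbh); ddt <- diff(date)
        ok <- status[-1] == "alive" & ddt > 0
        list(increment = dd[ok] / ddt[ok], species = species[-1][ok])
      } else list(increment = numeric(0), species = character(0))
    }, by = tree_id]
    for (sp in unique(tr$species)) {
      sp_inc <- inc[species == sp, increment]
      growth <- if (length(sp_inc)) log1p(median(sp_inc)) else NA_real_
      sp_obs <- obs[site == s & species == sp]
      survival <- NA_real_
      if (nrow(sp_obs) > 0) {
        f0 <- tryCatch(fit_mortality_model(sp_obs[, .(Y, dt, conD = 0, totD = 0,
                                                      dbh = 0, j)]),
                       error = function(e) NULL)
        if (!is.null(f0) && f0$converged) {
          p1 <- cloglog_inv(unname(f0$coefficients[1]), 1)
          survival <- qlogis(min(max(1 - p1, 1e-12), 1 - 1e-12))
        }
      }
      dall <- tr[species == sp, dbh]
      stature <- if (length(dall)) log(quantile(dall, 0.9, names = FALSE)) else NA_real_
      # recruitment proxy: new individuals per census per unit abundance
      ids1 <- unique(tr[species == sp & census_index == 1, tree_id])
      recr <- NA_real_
      if (max(tr$census_index) > 1) {
        new_ids <- unique(tr[species == sp & census_index > 1 &
                               !(tree_id %in% ids1), tree_id])
        recr <- length(new_ids) / max(1L, length(ids1))
      }
      rows[[length(rows) + 1]] <- data.table(site = s, species = sp,
                                             growth = growth, survival = survival,
                                             stature = stature, recruitment = recr)
    }
  }
  out <- rbindlist(rows)
  std <- function(x) {
    if (sum(is.finite(x)) < 2 || sd(x, na.rm = TRUE) == 0) return(rep(NA_real_, length(x)))
    (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  }
  out[, `:=`(growth = std(growth), survival = std(survival),
             stature = std(stature), recruitment = std(recruitment)), by = site]
  pc1 <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    res <- rep(NA_real_, length(a))
    if (sum(ok) >= 3) {
      p <- prcomp(cbind(a[ok], b[ok]), center = FALSE, scale. = FALSE)
      sc <- p$x[, 1]
      if (cor(sc, a[ok]) < 0) sc <- -sc  # orient along the first input
      res[ok] <- sc
    } else res[ok] <- a[ok]
    res
  }
  out[, axis_growth_survival := pc1(growth, survival), by = site]
  out[, axis_stature_recruitment := {
    if (all(!is.finite(recruitment))) stature else pc1(stature, recruitment)
  }, by = site]
  out[]
}

#' Life-history confounder meta-regressions
#'
#' Refits the abundance-mediated meta-regression with life-history
#' covariates added (main effects of the pair plus their interaction) and
#' reports whether the abundance main effect keeps its sign and
#' significance. Zero-variance covariates are dropped with a warning;
#' near-collinear designs warn.
#'
#' @param records Records from [build_records()].
#' @param covariates Output of [compute_life_history()].
#' @param which `"rates"` = (growth, survival), `"axes"` = the two trade-off
#'   axes.
#' @param base_fixed Base fixed-effect formula.
#' @return List with `fit`, `abundance_term` (beta, p), `dropped`
#'   (covariates removed), `n_excluded` (records lacking covariates).
#' @export
confounder_meta_models <- function(records, covariates,
                                   which = c("rates", "axes"),
                                   base_fixed = ~ tLatitude * tAbundance) {
  which <- match.arg(which)
  pair <- if (which == "rates") c("growth", "survival")
          else c("axis_growth_survival", "axis_stature_recruitment")
  rec <- merge(as.data.table(records), as.data.table(covariates),
               by = c("site", "species"))
  keep <- Reduce(`&`, lapply(pair, function(cn) is.finite(rec[[cn]])))
  n_excluded <- sum(!keep)
  rec <- rec[keep]
  dropped <- character()
  for (cn in pair) if (var(rec[[cn]]) == 0) {
    warning("zero-variance covariate dropped: ", cn)
    dropped <- c(dropped, cn)
  }
  use <- setdiff(pair, dropped)
  add <- if (length(use) == 2) paste(use[1], "*", use[2])
         else if (length(use) == 1) use else NULL
  make_formula <- function(extra) {
    if (is.null(extra)) base_fixed
    else as.formula(paste("~", deparse(base_fixed[[2]]), "+", extra))
  }
  fixed <- make_formula(add)
  X <- model.matrix(fixed, rec)
  if (qr(X)$rank < ncol(X) || kappa(crossprod(X)) > 1e8) {
    victim <- use[length(use)]
    warning("near-collinear confounder design; dropping ", victim)
    dropped <- c(dropped, victim)
    use <- setdiff(use, victim)
    fixed <- make_formula(if (length(use) == 2) paste(use[1], "*", use[2])
                          else if (length(use) == 1) use else NULL)
  }
  fit <- fit_meta_regression(rec, fixed)
  ab <- which(names(fit$b) == "tAbundance")
  list(fit = fit,
       abundance_term = if (length(ab)) list(beta = unname(fit$b[ab]),
                                             p = unname(fit$p[ab])) else NULL,
       dropped = dropped, n_excluded = n_excluded)
}
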