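#' Plot metadata
#'
#' @param site_name Site identifier.
#' @param width,height Plot dimensions in metres (origin at a plot corner,
#'   coordinates continuous metres).
#' @param absolute_latitude Distance to the equator in degrees (>= 0).
#' @param census_dates Strictly increasing decimal years, one per census.
#' @param stems_as_individuals If `TRUE` every stem is treated as an
#'   individual (used when stem-to-tree links are unavailable) and
#'   [consolidate_stems()] is skipped.
#' @return An object of class `plot_metadata`.
#' @export
plot_metadata <- function(site_name, width, height, absolute_latitude,
                          census_dates, stems_as_individuals = FALSE) {
  assert_that(width > 0 && height > 0, "plot dimensions must be positive")
  assert_that(absolute_latitude >= 0, "absolute latitude must be >= 0")
  assert_that(all(diff(census_dates) > 0), "census dates must be strictly increasing")
  structure(list(site_name = site_name, width = width, height = height,
                 absolute_latitude = absolute_latitude,
                 census_dates = census_dates,
                 area_ha = width * height / 1e4,
                 stems_as_individuals = stems_as_individuals),
            class = "plot_metadata")
}

default_schema <- function() {
  list(
    columns = list(tree_id = "tree_id", stem_id = "stem_id", species = "species",
                   x = "x", y = "y", dbh = "dbh", status = "status", date = "date"),
    status_codes = list(alive = "alive", dead = "dead", missing = "missing"),
    on_unknown_status = "drop"  # or "fail"
  )
}

#' Read stem-level census tables
#'
#' Reads one delimited table per census into the canonical stem schema.
#' Column names and status codes are remapped through `schema`; rows with
#' missing coordinates, species, status or measurement date are dropped and
#' counted.
#'
#' @param paths Character vector of file paths, one per census (ordered).
#' @param schema List with `columns` (canonical name -> file column),
#'   `status_codes` (alive/dead/missing -> file codes) and
#'   `on_unknown_status` (`"drop"` or `"fail"`). Defaults cover the canonical
#'   dialect written by [write_census()].
#' @return List with `censuses` (list of data.tables with columns `tree_id`,
#'   `stem_id`, `species`, `x`, `y`, `dbh`, `status`, `census_index`, `date`)
#'   and `dropped` (per-census counts of removed rows).
#' @export
read_census_tables <- function(paths, schema = default_schema()) {
  schema <- modifyList(default_schema(), schema)
  cols <- schema$columns
  censuses <- vector("list", length(paths))
  dropped <- integer(length(paths))
  for (i in seq_along(paths)) {
    dt <- tryCatch(fread(paths[i]), error = function(e)
      stop("unparseable census file ", paths[i], ": ", conditionMessage(e), call. = FALSE))
    if (nrow(dt) == 0L) {
      warning("empty census file: ", paths[i])
      censuses[[i]] <- data.table(tree_id = character(), stem_id = character(),
                                  species = character(), x = numeric(), y = numeric(),
                                  dbh = numeric(), status = character(),
                                  census_index = integer(), date = numeric())
      next
    }
    for (cn in names(cols))
      if (!cols[[cn]] %in% names(dt) && cn != "stem_id" && cn != "date")
        stop("column '", cols[[cn]], "' missing in ", paths[i])
    out <- data.table(
      tree_id = as.character(dt[[cols$tree_id]]),
      stem_id = if (cols$stem_id %in% names(dt)) as.character(dt[[cols$stem_id]]) else as.character(dt[[cols$tree_id]]),
      species = as.character(dt[[cols$species]]),
      x = as.numeric(dt[[cols$x]]),
      y = as.numeric(dt[[cols$y]]),
      dbh = as.numeric(dt[[cols$dbh]]),
      status_raw = as.character(dt[[cols$status]]),
      date = if (cols$date %in% names(dt)) as.numeric(dt[[cols$date]]) else NA_real_
    )
    # status remapping
    code_map <- unlist(schema$status_codes)
    out[, status := names(code_map)[match(status_raw, code_map)]]
    unknown <- !is.na(out$status_raw) & is.na(out$status)
    if (any(unknown)) {
      if (identical(schema$on_unknown_status, "fail"))
        stop("unknown status codes in ", paths[i], ": ",
             paste(unique(out$status_raw[unknown]), collapse = ", "))
      out[unknown, status := NA_character_]
    }
    keep <- !is.na(out$x) & !is.na(out$y) & !is.na(out$species) & out$species != "" &
      !is.na(out$status) & (!(cols$date %in% names(dt)) | !is.na(out$date))
    dropped[i] <- sum(!keep)
    out <- out[keep][, status_raw := NULL]
    out[, census_index := i]
    censuses[[i]] <- out[]
  }
  list(censuses = censuses, dropped = dropped)
}

#' Consolidate multi-stem trees into tree records
#'
#' A multi-stem individual is alive if at least one stem is alive; its
#' DBH equivalent derives from the summed basal area of live stems (all
#' stems when none is alive), i.e. `sqrt(sum(dbh^2))`; coordinates are those
#' of the main stem, taken as the largest-DBH living stem (largest overall
#' when all are dead). Skipped (identity) when
#' `plot$stems_as_individuals` is `TRUE`.
#'
#' @param stems data.table of stem records for one census (columns as from
#'   [read_census_tables()]).
#' @param plot A [plot_metadata()].
#' @return data.table with one row per tree: `tree_id`, `species`, `x`, `y`,
#'   `dbh` (DBH equivalent, cm), `status`, `census_index`, `date`.
#' @export
consolidate_stems <- function(stems, plot) {
  stems <- as.data.table(stems)
  if (nrow(stems) == 0L) stop("no stems to consolidate")
  if (isTRUE(plot$stems_as_individuals)) {
    out <- copy(stems)[, tree_id := stem_id]
    return(out[, .(tree_id, species, x, y, dbh, status, census_index, date)])
  }
  stems[, .(
    species = species[which.max(dbh)],
    x = { live <- status == "alive"; i <- if (any(live)) which(live)[which.max(dbh[live])] else which.max(dbh); x[i] },
    y = { live <- status == "alive"; i <- if (any(live)) which(live)[which.max(dbh[live])] else which.max(dbh); y[i] },
    dbh = { live <- status == "alive"
            d <- if (any(live)) dbh[live] else dbh
            sqrt(sum(d^2)) },
    status = if (any(status == "alive")) "alive" else if (any(status == "dead")) "dead" else "missing",
    date = median(date),
    census_index = census_index[1]
  ), by = tree_id]
}

#' Clean per-tree status histories
#'
#' Applies the plausibility corrections: a tree recorded dead but found
#' alive in any later census is set back to alive for the intervening
#' censuses ("resurrection" correction), and species or coordinates that
#' conflict across censuses are replaced by the most recent recorded value.
#' Alive records are never converted to dead.
#'
#' @param trees data.table of tree records across censuses (`tree_id`,
#'   `species`, `x`, `y`, `dbh`, `status`, `census_index`, `date`).
#' @return Corrected data.table, same shape.
#' @export
clean_statuses <- function(trees) {
  trees <- as.data.table(trees)
  setorder(trees, tree_id, census_index)
  trees[, status := {
    s <- status
    alive_idx <- which(s == "alive")
    if (length(alive_idx)) {
      last_alive <- max(alive_idx)
      s[seq_len(last_alive)][s[seq_len(last_alive)] == "dead"] <- "alive"
    }
    s
  }, by = tree_id]
  trees[, species := species[.N], by = tree_id]
  trees[, `:=`(x = x[.N], y = y[.N]), by = tree_id]
  trees[]
}

#' Build focal sapling observations
#'
#' One observation per living focal sapling (1 cm <= DBH < 10 cm, non-fern,
#' non-palm) per consecutive census pair with known follow-up status.
#' `Y = 1` when the tree is dead at the follow-up census. The interval
#' length `dt` uses per-tree measurement dates when available and the
#' census-level dates otherwise. `edge_excluded` flags focal trees within
#' `buffer_m` of any plot boundary; they are retained in the table (they
#' still act as neighbors) but dropped from modelling.
#'
#' @param trees Cleaned tree table across censuses.
#' @param plot A [plot_metadata()].
#' @param buffer_m Edge buffer in metres (default 30).
#' @param fern_palm Character vector of species codes to exclude as ferns or
#'   palms.
#' @return Canonical observation data.table: `site`, `tree_id`, `species`,
#'   `j` (interval index = starting census), `Y`, `dt` (years), `dbh`, `x`,
#'   `y`, `edge_excluded`.
#' @export
build_observations <- function(trees, plot, buffer_m = 30, fern_palm = character()) {
  trees <- as.data.table(trees)
  n_cen <- length(plot$census_dates)
  if (n_cen < 2L) stop("at least two censuses are required")
  obs_list <- vector("list", n_cen - 1L)
  for (jj in seq_len(n_cen - 1L)) {
    start <- trees[census_index == jj & status == "alive" & dbh >= 1 & dbh < 10 &
                     !(species %in% fern_palm)]
    nxt <- trees[census_index == jj + 1L & status %in% c("alive", "dead"),
                 .(tree_id, status_next = status, date_next = date)]
    m <- merge(start, nxt, by = "tree_id")
    if (nrow(m) == 0L) next
    m[, dt := date_next - date]
    m[is.na(dt), dt := plot$census_dates[jj + 1L] - plot$census_dates[jj]]
    bad <- m$dt <= 0
    if (any(bad)) {
      warning(sum(bad), " observations with non-positive interval length dropped")
      m <- m[!bad]
    }
    m[, edge_excluded := x < buffer_m | y < buffer_m |
        x > plot$width - buffer_m | y > plot$height - buffer_m]
    obs_list[[jj]] <- m[, .(site = plot$site_name, tree_id, species, j = jj,
                            Y = as.integer(status_next == "dead"), dt, dbh, x, y,
                            edge_excluded)]
  }
  out <- rbindlist(obs_list)
  if (nrow(out) == 0L) return(data.table(site = character(), tree_id = character(),
    species = character(), j = integer(), Y = integer(), dt = numeric(),
    dbh = numeric(), x = numeric(), y = numeric(), edge_excluded = logical()))
  out[]
}

#' Classify species growth form
#'
#' Per census, the mean DBH of the six largest individuals of the species
#' (all individuals when fewer than six) is taken; the species is a tree
#' when the maximum of these per-census means exceeds 10 cm (strictly),
#' otherwise a shrub. With no measured individuals the growth form is
#' unknown.
#'
#' @param species_trees Tree records of one species across all censuses
#'   (columns `dbh`, `census_index`).
#' @return `"tree"`, `"shrub"` or `"unknown"`.
#' @export
classify_growth_form <- function(species_trees) {
  st <- as.data.table(species_trees)
  st <- st[!is.na(dbh)]
  if (nrow(st) == 0L) return("unknown")
  means <- st[, .(m = mean(sort(dbh, decreasing = TRUE)[seq_len(min(6L, .N))])),
              by = census_index]$m
  if (max(means) > 10) "tree" else "shrub"
}

#' Species abundance in trees per hectare
#'
#' Number of living individuals with DBH >= 1 cm on the entire plot at the
#' given census, divided by plot area (ha). For a pooled rare-species group
#' pass the member species' abundances to [group_abundance()].
#'
#' @param trees Tree table (one site).
#' @param plot A [plot_metadata()].
#' @param census Census index.
#' @param species Optional species code; all species when `NULL`.
#' @return Trees per hectare (named vector by species when `species = NULL`).
#' @export
compute_abundance <- function(trees, plot, census, species = NULL) {
  assert_that(plot$area_ha > 0, "plot area must be positive")
  trees <- as.data.table(trees)
  pool <- trees[census_index == census & status == "alive" & dbh >= 1]
  if (!is.null(species)) {
    sp_query <- species
    return(sum(pool$species %in% sp_query) / plot$area_ha)
  }
  counts <- pool[, .N, by = species]
  setNames(counts$N / plot$area_ha, counts$species)
}

#' Abundance of a pooled rare-species group
#'
#' The mean of the member species' abundances.
#'
#' @param member_abundances Numeric vector of per-species abundances
#'   (trees/ha).
#' @return Group abundance in trees/ha.
#' @export
group_abundance <- function(member_abundances) mean(member_abundances)

#' Write / read the canonical observation table
#'
#' Fixed canonical columns; round-trips exactly.
#' @param observations Canonical observation table.
#' @param path CSV path.
#' @return `read_observations()` returns the data.table.
#' @export
write_observations <- function(observations, path) {
  fwrite(as.data.table(observations)[, .(site, tree_id, species, j, Y, dt, dbh,
                                         x, y, edge_excluded)], path)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  dt <- fread(path, colClasses = list(character = c("site", "tree_id", "species")))
  dt[, `:=`(j = as.integer(j), Y = as.integer(Y), edge_excluded = as.logical(edge_excluded))]
  dt[]
}

#' Write a census table in the canonical dialect
#'
#' @param census data.table of stem records.
#' @param path CSV path.
#' @export
write_census <- function(census, path) {
  fwrite(as.data.table(census), path)
  invisible(path)
}
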