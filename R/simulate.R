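#' Specify one aggregation site for simulation
#'
#' @param site site code.
#' @param pop_size number of individuals resident at the site (>= 1).
#' @param annual_sighting_prob probability that an individual present at the
#'   site is photo-identified at least once in a given year.
#' @param sex_mix length-3 numeric, proportions of (male, female,
#'   indeterminate), summing to 1.
#' @param flank_probs length-3 numeric, probabilities that a sighting's
#'   photographs cover (both flanks, left only, right only), summing to 1.
#' @return an object of class `site_spec`.
#' @export
site_spec <- function(site, pop_size, annual_sighting_prob,
                      sex_mix = c(male = 0.5, female = 0.2, indeterminate = 0.3),
                      flank_probs = c(both = 0.6, left = 0.25, right = 0.15)) {
  stopifnot(pop_size >= 1,
            annual_sighting_prob >= 0, annual_sighting_prob <= 1,
            length(sex_mix) == 3, length(flank_probs) == 3,
            all(sex_mix >= 0), all(flank_probs >= 0))
  if (abs(sum(sex_mix) - 1) > 1e-9) stop("sex_mix must sum to 1")
  if (abs(sum(flank_probs) - 1) > 1e-9) stop("flank_probs must sum to 1")
  structure(list(site = site, pop_size = as.integer(pop_size),
                 annual_sighting_prob = annual_sighting_prob,
                 sex_mix = sex_mix, flank_probs = flank_probs),
            class = "site_spec")
}

#' Configure a synthetic multi-site world
#'
#' @param sites list of [site_spec()] objects.
#' @param years inclusive year range `c(first, last)`.
#' @param migration square numeric matrix (source sites in rows, sink sites in
#'   columns, dimnames = site codes) of per-year migration rates, each the
#'   proportion of the source population relocating permanently to the sink
#'   that year. Row sums must not exceed 1. `NULL` means no migration.
#' @param seed RNG seed used by [simulate_world()].
#' @param fixed_migrants if `TRUE`, exactly `round(rate * pop)` individuals
#'   migrate each year; if `FALSE` (default) the count is binomially drawn.
#' @return an object of class `world_config`.
#' @export
world_config <- function(sites, years, migration = NULL, seed = 1L,
                         fixed_migrants = FALSE) {
  stopifnot(length(sites) >= 1, length(years) == 2, years[2] >= years[1])
  codes <- vapply(sites, function(s) s$site, character(1))
  if (anyDuplicated(codes)) stop("duplicate site codes")
  if (!is.null(migration)) {
    if (!is.matrix(migration) || any(migration < 0) || any(migration > 1)) {
      stop("migration must be a matrix of rates in [0, 1]")
    }
    if (is.null(dimnames(migration)) ||
        !all(rownames(migration) %in% codes) ||
        !all(colnames(migration) %in% codes)) {
      stop("migration matrix dimnames must be site codes")
    }
    if (any(rowSums(migration) > 1 + 1e-12)) {
      stop("migration row sums must not exceed 1")
    }
    diag_rates <- migration[intersect(rownames(migration), colnames(migration)),
                            intersect(rownames(migration), colnames(migration))]
    if (is.matrix(diag_rates) && any(diag(diag_rates) > 0)) {
      stop("self-migration rates must be zero")
    }
  }
  structure(list(sites = sites, years = as.integer(years),
                 migration = migration, seed = as.integer(seed),
                 fixed_migrants = isTRUE(fixed_migrants)),
            class = "world_config")
}

#' Simulate a multi-site sighting catalogue with known ground truth
#'
#' Generates closed per-site populations linked only by migration. Each
#' simulated year, every individual present at a site is photo-identified
#' with that site's `annual_sighting_prob` (a sighted individual gets one
#' record with a uniformly drawn day-of-year and flank coverage drawn from
#' `flank_probs`); after the sighting season, migrants relocate permanently
#' from each source to each sink according to the migration matrix. Sex is a
#' fixed per-individual attribute drawn once from the home site's `sex_mix`.
#'
#' The simulation is deterministic given `config$seed`.
#'
#' @param config a [world_config()].
#' @return a list with elements
#'   \describe{
#'     \item{records}{a `sighting_catalogue` of all simulated encounters.}
#'     \item{truth}{a list with `home_site` (named character vector per
#'       individual), `events` (data frame of migration events:
#'       `individual_id`, `year`, `from`, `to`) and `sighted` (data frame of
#'       per-site-year true numbers of individuals identified).}
#'   }
#' @export
simulate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  sites <- config$sites
  codes <- vapply(sites, function(s) s$site, character(1))
  names(sites) <- codes

  ids <- unlist(lapply(sites, function(s) {
    sprintf("%s-%04d", s$site, seq_len(s$pop_size))
  }), use.names = FALSE)
  home <- rep(codes, vapply(sites, function(s) s$pop_size, integer(1)))
  names(home) <- ids
  loc <- home
  sex <- unlist(lapply(sites, function(s) {
    sample(c("male", "female", "indeterminate"), s$pop_size,
           replace = TRUE, prob = s$sex_mix)
  }), use.names = FALSE)
  names(sex) <- ids

  rec <- list()
  events <- list()
  sighted <- list()
  years <- seq(config$years[1], config$years[2])

  for (year in years) {
    # sighting season
    for (code in codes) {
      present <- names(loc)[loc == code]
      if (length(present) == 0L) next
      s <- sites[[code]]
      seen <- present[stats::runif(length(present)) < s$annual_sighting_prob]
      sighted[[length(sighted) + 1L]] <-
        data.frame(site = code, year = year, n_sighted = length(seen))
      if (length(seen) == 0L) next
      day <- sample.int(365L, length(seen), replace = TRUE) - 1L
      fl <- sample(c("LR", "L", "R"), length(seen), replace = TRUE,
                   prob = s$flank_probs)
      rec[[length(rec) + 1L]] <- data.frame(
        individual_id = seen,
        site = code,
        date = as.Date(sprintf("%d-01-01", year)) + day,
        sex = unname(sex[seen]),
        flanks = fl,
        stringsAsFactors = FALSE
      )
    }
    # end-of-season relocation
    mig <- config$migration
    if (!is.null(mig)) {
      moves <- list()
      for (src in rownames(mig)) {
        pool <- names(loc)[loc == src]
        n_pool <- length(pool)
        for (snk in colnames(mig)) {
          rate <- mig[src, snk]
          if (rate == 0 || src == snk) next
          n_mig <- if (config$fixed_migrants) {
            as.integer(round(rate * n_pool))
          } else {
            stats::rbinom(1L, n_pool, rate)
          }
          if (n_mig > length(pool)) {
            stop(sprintf("infeasible migration: %d migrants from %s (pool %d)",
                         n_mig, src, length(pool)))
          }
          if (n_mig == 0L) next
          movers <- sample(pool, n_mig)
          pool <- setdiff(pool, movers)
          moves[[length(moves) + 1L]] <- data.frame(
            individual_id = movers, year = year, from = src, to = snk,
            stringsAsFactors = FALSE)
        }
      }
      if (length(moves) > 0L) {
        mv <- do.call(rbind, moves)
        loc[mv$individual_id] <- mv$to
        events[[length(events) + 1L]] <- mv
      }
    }
  }

  records <- if (length(rec) > 0L) do.call(rbind, rec) else {
    data.frame(individual_id = character(0), site = character(0),
               date = as.Date(character(0)), sex = character(0),
               flanks = character(0), stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  class(records) <- c("sighting_catalogue", "data.frame")

  ev <- if (length(events) > 0L) do.call(rbind, events) else {
    data.frame(individual_id = character(0), year = integer(0),
               from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(ev) <- NULL
  list(records = records,
       truth = list(home_site = home, events = ev,
                    sighted = do.call(rbind, sighted)))
}

#' Split identities the way single-flank matching would
#'
#' Emulates the double-counting failure mode that the dual LB/RB analysis
#' protocol guards against: without a both-flank photograph linking the two
#' sides, an individual photographed left-only on some occasions and
#' right-only on others is indistinguishable from two different animals.
#' This function rewrites IDs accordingly: for any individual with no
#' both-flank (`LR`) record, its left-only records get the suffix `#L` and
#' its right-only records `#R`; individuals with at least one `LR` record
#' keep a single ID.
#'
#' @param records a `sighting_catalogue` with true identities.
#' @return the catalogue with flank-split identities.
#' @export
naive_split_ids <- function(records) {
  has_both <- tapply(records$flanks == "LR", records$individual_id, any)
  linked <- names(has_both)[has_both]
  split_needed <- !(records$individual_id %in% linked)
  out <- records
  out$individual_id[split_needed] <- paste0(
    records$individual_id[split_needed], "#",
    ifelse(records$flanks[split_needed] == "L", "L", "R"))
  out
}

#' Read a world configuration from YAML
#'
#' The file carries `years: [first, last]`, `seed`, an optional
#' `fixed_migrants` flag, a `sites:` list (each with `site`, `pop_size`,
#' `annual_sighting_prob` and optional `sex_mix`, `flank_probs`) and an
#' optional `migration:` list of `{from, to, rate}` entries.
#'
#' @param path YAML file path.
#' @return a [world_config()].
#' @export
read_world_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sites) || is.null(cfg$years)) {
    stop("world config must declare 'sites' and 'years'")
  }
  sites <- lapply(cfg$sites, function(s) {
    args <- list(site = s$site, pop_size = s$pop_size,
                 annual_sighting_prob = s$annual_sighting_prob)
    if (!is.null(s$sex_mix)) args$sex_mix <- unlist(s$sex_mix)
    if (!is.null(s$flank_probs)) args$flank_probs <- unlist(s$flank_probs)
    do.call(site_spec, args)
  })
  codes <- vapply(sites, function(s) s$site, character(1))
  migration <- NULL
  if (!is.null(cfg$migration)) {
    migration <- matrix(0, length(codes), length(codes),
                        dimnames = list(codes, codes))
    for (m in cfg$migration) migration[m$from, m$to] <- m$rate
  }
  world_config(sites, years = unlist(cfg$years), migration = migration,
               seed = if (is.null(cfg$seed)) 1L else cfg$seed,
               fixed_migrants = isTRUE(cfg$fixed_migrants))
}
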