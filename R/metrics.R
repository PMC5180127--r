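#' Per-site-year counts of unique, new and resighted individuals
#'
#' An individual counts once per site-year no matter how many encounters it
#' had. A "resight" is an individual already recorded at the same site in a
#' previous sampled year; consequently a site's first sampled year has zero
#' resights and `n_unique = n_new + n_resight` always.
#'
#' @param view a `sighting_catalogue` or `flank_catalogue`.
#' @param year_range optional `c(first, last)` calendar years; records outside
#'   are dropped before counting (and "first ever" is assessed within the
#'   restricted range, matching a design balanced to that window).
#' @return data frame with columns `site`, `year`, `n_unique`, `n_new`,
#'   `n_resight`, one row per sampled site-year.
#' @export
site_year_summaries <- function(view, year_range = NULL) {
  if (nrow(view) == 0L) stop("empty catalogue")
  yr <- as.integer(format(as.Date(view$date), "%Y"))
  if (!is.null(year_range)) {
    if (length(year_range) != 2 || year_range[2] < year_range[1]) {
      stop("year_range must be c(first, last) with first <= last")
    }
    keep <- yr >= year_range[1] & yr <= year_range[2]
    view <- view[keep, , drop = FALSE]
    yr <- yr[keep]
    if (nrow(view) == 0L) stop("no records inside year_range")
  }
  key <- paste(view$site, view$individual_id, sep = "\r")
  first_year <- tapply(yr, key, min)
  seen <- unique(data.frame(site = view$site, id = view$individual_id,
                            year = yr, key = key, stringsAsFactors = FALSE))
  seen$n_unique <- 1L
  seen$n_new <- as.integer(seen$year == first_year[seen$key])
  agg <- stats::aggregate(cbind(n_unique, n_new) ~ site + year,
                          data = seen, FUN = sum)
  agg$n_resight <- agg$n_unique - agg$n_new
  agg <- agg[order(agg$site, agg$year), ]
  rownames(agg) <- NULL
  agg
}

#' Yearly proportion of resighted individuals
#'
#' For each site the first sampled year is removed (no resight is possible
#' there) and the proportion `n_resight / n_unique` is reported for the
#' remaining years. Sites sampled in a single year are dropped with a warning.
#'
#' @param summaries output of [site_year_summaries()].
#' @return data frame `site`, `year`, `n_unique`, `n_resight`,
#'   `prop_resight`.
#' @export
proportion_resighted_per_year <- function(summaries) {
  out <- lapply(split(summaries, summaries$site), function(d) {
    if (nrow(d) < 2L) {
      warning("site ", d$site[1], " sampled in a single year; excluded")
      return(NULL)
    }
    d <- d[order(d$year), ]
    d <- d[-1L, , drop = FALSE]  # first sampled year: resights impossible
    data.frame(site = d$site, year = d$year, n_unique = d$n_unique,
               n_resight = d$n_resight,
               prop_resight = d$n_resight / d$n_unique)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Distribution of the number of years individuals were observed
#'
#' Counts, per site and over a six-consecutive-year window, how many distinct
#' years each individual was recorded, then tabulates individuals by that
#' count. With `pool_top = TRUE` the 5- and 6-year categories are merged into
#' `"5-6"` (done to keep expected contingency-table counts large enough for a
#' chi-square test).
#'
#' @param view a `sighting_catalogue`.
#' @param windows named list (or two-column matrix with site rownames) giving
#'   each site's window as `c(first, last)`; each window must span exactly six
#'   years and lie inside the site's sampled years.
#' @param pool_top merge the top two categories (default `TRUE`).
#' @return an integer matrix, sites in rows, years-observed categories in
#'   columns (`1,2,3,4,5-6` pooled, else `1..6`). Row sums equal the number
#'   of unique individuals seen at the site within its window.
#' @export
years_observed_distribution <- function(view, windows, pool_top = TRUE) {
  if (is.matrix(windows)) {
    windows <- stats::setNames(
      lapply(seq_len(nrow(windows)), function(i) windows[i, ]),
      rownames(windows))
  }
  yr <- as.integer(format(as.Date(view$date), "%Y"))
  cats <- if (pool_top) c("1", "2", "3", "4", "5-6") else as.character(1:6)
  out <- matrix(0L, nrow = length(windows), ncol = length(cats),
                dimnames = list(names(windows), cats))
  for (site in names(windows)) {
    w <- windows[[site]]
    if (w[2] - w[1] != 5L) {
      stop("window for ", site, " must span exactly six consecutive years")
    }
    site_years <- sort(unique(yr[view$site == site]))
    if (length(site_years) == 0L || w[1] < min(site_years) || w[2] > max(site_years)) {
      stop("window ", w[1], "-", w[2], " outside sampled years for site ", site)
    }
    keep <- view$site == site & yr >= w[1] & yr <= w[2]
    if (!any(keep)) next
    n_years <- tapply(yr[keep], view$individual_id[keep],
                      function(y) length(unique(y)))
    idx <- if (pool_top) pmin(n_years, 5L) else n_years
    tab <- tabulate(idx, nbins = length(cats))
    out[site, ] <- tab
  }
  out
}

#' Mean number of years individuals were observed, per site
#'
#' Over the entire study period, each unique individual contributes its count
#' of distinct years with at least one record at the site; the per-site mean
#' and its standard error are returned.
#'
#' @param view a `sighting_catalogue`.
#' @return data frame `site`, `n_individuals`, `mean_years`, `se`.
#' @export
mean_years_observed <- function(view) {
  if (nrow(view) == 0L) stop("empty catalogue")
  yr <- as.integer(format(as.Date(view$date), "%Y"))
  out <- lapply(split(seq_len(nrow(view)), view$site), function(i) {
    n_years <- tapply(yr[i], view$individual_id[i],
                      function(y) length(unique(y)))
    n <- length(n_years)
    data.frame(site = view$site[i[1]], n_individuals = n,
               mean_years = mean(n_years),
               se = if (n > 1) stats::sd(n_years) / sqrt(n) else 0)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Longest run of consecutive years an individual was seen at a site
#'
#' @param view a `sighting_catalogue`.
#' @return data frame `individual_id`, `site`, `max_run` (longest streak of
#'   consecutive calendar years with at least one record of that individual
#'   at that site).
#' @export
max_consecutive_years <- function(view) {
  yr <- as.integer(format(as.Date(view$date), "%Y"))
  key <- paste(view$individual_id, view$site, sep = "\r")
  runs <- tapply(yr, key, function(y) {
    y <- sort(unique(y))
    max(tapply(y, cumsum(c(1L, diff(y) != 1L)), length))
  })
  parts <- do.call(rbind, strsplit(names(runs), "\r", fixed = TRUE))
  out <- data.frame(individual_id = parts[, 1], site = parts[, 2],
                    max_run = as.integer(runs), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$individual_id, out$site), ]
}

#' Individuals recorded at more than one site
#'
#' Lists, for every individual with records at two or more sites, each
#' between-site leg of its itinerary (consecutive records at different
#' sites, in date order) with elapsed days and, when a between-site distance
#' is supplied, the implied minimum straight-line travel speed.
#'
#' @param view a `sighting_catalogue`.
#' @param distances optional data frame `from`, `to`, `km` of straight-line
#'   distances (symmetric: either direction matches).
#' @return data frame `individual_id`, `from_site`, `to_site`, `from_date`,
#'   `to_date`, `days`, `km`, `km_per_day` (the latter two `NA` when no
#'   distance is supplied); zero rows when no individual crossed sites.
#' @export
cross_site_matches <- function(view, distances = NULL) {
  empty <- data.frame(individual_id = character(0), from_site = character(0),
                      to_site = character(0), from_date = as.Date(character(0)),
                      to_date = as.Date(character(0)), days = numeric(0),
                      km = numeric(0), km_per_day = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(view) == 0L) return(empty)
  n_sites <- tapply(view$site, view$individual_id,
                    function(s) length(unique(s)))
  movers <- names(n_sites)[n_sites >= 2L]
  if (length(movers) == 0L) return(empty)
  lookup_km <- function(a, b) {
    if (is.null(distances)) return(NA_real_)
    hit <- (distances$from == a & distances$to == b) |
           (distances$from == b & distances$to == a)
    if (any(hit)) distances$km[which(hit)[1]] else NA_real_
  }
  legs <- lapply(movers, function(id) {
    d <- view[view$individual_id == id, , drop = FALSE]
    d <- d[order(d$date), ]
    jump <- which(d$site[-1] != d$site[-nrow(d)])
    do.call(rbind, lapply(jump, function(i) {
      days <- as.numeric(d$date[i + 1] - d$date[i])
      km <- lookup_km(d$site[i], d$site[i + 1])
      data.frame(individual_id = id, from_site = d$site[i],
                 to_site = d$site[i + 1], from_date = d$date[i],
                 to_date = d$date[i + 1], days = days, km = km,
                 km_per_day = if (!is.na(km) && days > 0)
                   min_travel_speed(km, days) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, legs)
  rownames(out) <- NULL
  out
}

#' Minimum travel speed implied by a between-site resight
#'
#' The straight-line distance divided by the elapsed days is a lower bound on
#' the animal's average swimming speed (any real track is at least as long as
#' the straight line). Report rounded to one decimal.
#'
#' @param distance_km straight-line distance in km, > 0.
#' @param days elapsed days between the two sightings, > 0.
#' @return speed in km per day.
#' @examples
#' min_travel_speed(3000, 221)  # 13.6 km/day
#' @export
min_travel_speed <- function(distance_km, days) {
  if (any(distance_km <= 0) || any(days <= 0)) {
    stop("distance and days must be positive")
  }
  distance_km / days
}

#' Per-site sex composition of unique individuals
#'
#' Sex is treated as fixed per individual: the first (by date)
#' non-indeterminate value among an individual's records at the site is
#' used; records disagreeing on a determinate sex are reported via a
#' warning and resolved to the earliest determinate value.
#'
#' @param view a `sighting_catalogue`.
#' @return data frame `site`, `n_individuals`, `male`, `female`,
#'   `indeterminate` (proportions summing to 1 per site).
#' @export
sex_composition <- function(view) {
  if (nrow(view) == 0L) {
    warning("empty catalogue: no sex composition to report")
    return(data.frame(site = character(0), n_individuals = integer(0),
                      male = numeric(0), female = numeric(0),
                      indeterminate = numeric(0)))
  }
  view <- view[order(view$date), ]
  key <- paste(view$site, view$individual_id, sep = "\r")
  resolve <- function(sx) {
    det <- sx[sx != "indeterminate"]
    if (length(det) == 0L) return("indeterminate")
    if (length(unique(det)) > 1L) {
      warning("conflicting determinate sex records; using earliest")
    }
    det[1]
  }
  sex <- tapply(view$sex, key, resolve)
  site <- vapply(strsplit(names(sex), "\r", fixed = TRUE), `[`, character(1), 1)
  out <- lapply(split(unname(sex), site), function(sx) {
    n <- length(sx)
    data.frame(n_individuals = n,
               male = mean(sx == "male"),
               female = mean(sx == "female"),
               indeterminate = mean(sx == "indeterminate"))
  })
  res <- cbind(data.frame(site = names(out), stringsAsFactors = FALSE),
               do.call(rbind, out))
  rownames(res) <- NULL
  res
}
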