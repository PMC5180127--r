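#' Read a sighting catalogue from CSV
#'
#' A sighting catalogue records one row per photo-identified encounter of an
#' individual animal at an aggregation site. The canonical format is a CSV
#' with header `individual_id, site, date, sex, flanks`, where `date` is an
#' ISO calendar date (`YYYY-MM-DD`), `sex` is one of `male`, `female` or
#' `indeterminate`, and `flanks` encodes which flanks were photographed:
#' `"L"` (left only), `"R"` (right only) or `"LR"` (both).
#'
#' Rows that fail validation (unparseable date, site outside `site_set`,
#' unknown sex or flank code, empty individual id, date outside
#' `study_window`) are skipped with a warning reporting how many rows were
#' dropped and why; a missing column is a fatal error.
#'
#' @param path path to a CSV file.
#' @param site_set optional character vector of admissible site codes; when
#'   supplied, rows at other sites are skipped.
#' @param study_window optional length-2 integer vector of calendar years
#'   `c(first, last)`; rows dated outside it are skipped.
#' @return a `sighting_catalogue`: a data frame with columns `individual_id`
#'   (character), `site` (character), `date` (`Date`), `sex` (character) and
#'   `flanks` (character), one row per encounter. The number of skipped rows
#'   is attached as attribute `n_skipped`.
#' @seealso [write_catalogue()], [build_flank_views()]
#' @export
read_catalogue <- function(path, site_set = NULL, study_window = NULL) {
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  required <- c("individual_id", "site", "date", "sex", "flanks")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("catalogue is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  raw <- raw[required]
  dates <- as.Date(raw$date, format = "%Y-%m-%d")

  reasons <- character(0)
  bad <- rep(FALSE, nrow(raw))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    if (any(cond & !bad)) {
      reasons <<- c(reasons, sprintf("%d row(s): %s", sum(cond & !bad), why))
    }
    bad <<- bad | cond
  }
  flag(is.na(dates), "unparseable date")
  flag(!nzchar(raw$individual_id), "empty individual_id")
  flag(!(raw$sex %in% c("male", "female", "indeterminate")), "unknown sex code")
  flag(!(raw$flanks %in% c("L", "R", "LR")), "unknown flank code")
  if (!is.null(site_set)) {
    flag(!(raw$site %in% site_set), "site not in declared site set")
  }
  if (!is.null(study_window)) {
    yr <- as.integer(format(dates, "%Y"))
    flag(yr < study_window[1] | yr > study_window[2],
         "date outside study window")
  }

  if (any(bad)) {
    warning(sprintf("skipped %d of %d rows (%s)", sum(bad), nrow(raw),
                    paste(reasons, collapse = "; ")))
  }
  out <- data.frame(individual_id = raw$individual_id[!bad],
                    site = raw$site[!bad],
                    date = dates[!bad],
                    sex = raw$sex[!bad],
                    flanks = raw$flanks[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(bad)
  class(out) <- c("sighting_catalogue", "data.frame")
  out
}

#' Write a sighting catalogue to CSV
#'
#' Inverse of [read_catalogue()]: emits the canonical five-column header and
#' ISO dates, UTF-8 encoded, so that a written catalogue reads back to the
#' identical record multiset.
#'
#' @param records a `sighting_catalogue` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(records, path) {
  stopifnot(all(c("individual_id", "site", "date", "sex", "flanks")
                %in% names(records)))
  out <- data.frame(individual_id = records$individual_id,
                    site = records$site,
                    date = format(as.Date(records$date), "%Y-%m-%d"),
                    sex = records$sex,
                    flanks = records$flanks)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Build left- and right-flank catalogue views
#'
#' Spot patterns differ between the two flanks of a shark, so an individual
#' photographed only on the left on one occasion and only on the right on
#' another cannot be linked without a both-flank photo. All analyses are
#' therefore run twice: on the LB view (records whose photos include the left
#' flank, i.e. flank codes `L` or `LR`) and on the RB view (`R` or `LR`).
#' A both-flank record appears in both views.
#'
#' @param records a `sighting_catalogue`.
#' @return a list with elements `LB` and `RB`, each a `flank_catalogue`
#'   (a `sighting_catalogue` with attributes `side` and `site_counts`, the
#'   per-site number of unique individuals in the view).
#' @export
build_flank_views <- function(records) {
  if (nrow(records) == 0L) stop("empty catalogue: no records to split")
  mk <- function(keep, side) {
    v <- records[keep, , drop = FALSE]
    if (nrow(v) == 0L) {
      warning(side, " view is empty")
      counts <- integer(0)
    } else {
      counts <- vapply(split(v$individual_id, v$site),
                       function(id) length(unique(id)), integer(1))
    }
    rownames(v) <- NULL
    attr(v, "side") <- side
    attr(v, "site_counts") <- counts
    class(v) <- c("flank_catalogue", "sighting_catalogue", "data.frame")
    v
  }
  list(LB = mk(records$flanks %in% c("L", "LR"), "LB"),
       RB = mk(records$flanks %in% c("R", "LR"), "RB"))
}

#' Average two population point estimates
#'
#' Some sites have two published abundance estimates (e.g. one from
#' researcher-collected and one from publicly contributed photographs); the
#' arithmetic mean of the two is used as the working point estimate. Rounding
#' to whole individuals happens only at the reporting layer.
#'
#' @param est_a,est_b positive population estimates (individuals).
#' @return their arithmetic mean.
#' @examples
#' population_point_estimate(77, 98.5)   # 87.75, reported as 88
#' population_point_estimate(320, 440)   # 380
#' @export
population_point_estimate <- function(est_a, est_b) {
  if (any(c(est_a, est_b) <= 0)) stop("population estimates must be positive")
  (est_a + est_b) / 2
}

#' Derive a standard error from a 95% confidence interval
#'
#' Assumes a symmetric normal interval: `se = (ci_high - ci_low) / (2 * z)`
#' with `z = qnorm(0.975)`. This is how published mark-recapture population
#' estimates, reported only as a point estimate with a 95% CI, are converted
#' to the mean/SE pair the Monte Carlo power simulation samples from.
#'
#' @param ci_low,ci_high interval bounds (individuals), `ci_high > ci_low`.
#' @return the implied standard error (individuals).
#' @export
derive_se_from_ci <- function(ci_low, ci_high) {
  if (any(ci_high <= ci_low)) stop("degenerate interval: ci_high must exceed ci_low")
  (ci_high - ci_low) / (2 * stats::qnorm(0.975))
}

#' Construct a population estimate
#'
#' Bundles a site's abundance point estimate with its 95% CI and the implied
#' standard error, the form consumed by [migration_power()].
#'
#' @param site site code.
#' @param ci_low,ci_high 95% CI bounds (individuals).
#' @param mean point estimate; defaults to the interval midpoint (equivalently
#'   the average of two point estimates when the "interval" is really a pair
#'   of published estimates).
#' @param se standard error; defaults to [derive_se_from_ci()] on the bounds.
#'   Override when the interval is known not to be a normal 95% CI.
#' @return an object of class `population_estimate`.
#' @export
population_estimate <- function(site, ci_low, ci_high,
                                mean = (ci_low + ci_high) / 2,
                                se = derive_se_from_ci(ci_low, ci_high)) {
  if (!(ci_low <= mean && mean <= ci_high)) {
    stop("population estimate must satisfy ci_low <= mean <= ci_high")
  }
  if (se <= 0) stop("se must be positive")
  structure(list(site = site, mean = mean, ci_low = ci_low,
                 ci_high = ci_high, se = se),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("Population estimate for %s: %.1f (95%% CI %.1f-%.1f, se %.2f)\n",
              x$site, x$mean, x$ci_low, x$ci_high, x$se))
  invisible(x)
}

#' Indian Ocean whale-shark aggregation inputs
#'
#' Published per-site inputs for the power analysis: average yearly number of
#' photo-identified individuals and mark-recapture population estimates with
#' 95% CIs. Mozambique has a yearly identification count but no published
#' population estimate (`NA`); any analysis using it as a population must be
#' given an explicit user-supplied estimate.
#'
#' @return a data frame with columns `site`, `n_per_year`, `p_mean`,
#'   `ci_low`, `ci_high`.
#' @export
indian_ocean_sites <- function() {
  data.frame(
    site = c("ningaloo", "maldives", "seychelles", "mozambique"),
    n_per_year = c(104, 28, 59, 77),
    p_mean = c(380, 87.75, 513, NA),
    ci_low = c(320, 77, 469, NA),
    ci_high = c(440, 98.5, 557, NA),
    stringsAsFactors = FALSE
  )
}

#' Per-site-year summary writer
#'
#' Writes any of the package's tidy result tables as a TSV with a `#`-prefixed
#' provenance header (package version and, when given, the RNG seed).
#'
#' @param df a data frame.
#' @param path output path.
#' @param seed optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("resight"))
  cat(sprintf("# resight %s%s\n", ver,
              if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed))),
      file = con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
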