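# One-way permutational ANOVA on Euclidean distances.
#
# The pseudo-F is computed from the distance-matrix partition
#   SS_total = sum_{i<j} d_ij^2 / n,   SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g,
# which for univariate data and Euclidean distance is algebraically identical
# to the classical one-way ANOVA decomposition (that identity is exploited as
# a test oracle, not assumed here). The null distribution comes from
# unrestricted permutation of the raw observations across groups.

.pseudo_f_from_d2 <- function(d2, g) {
  n <- length(g)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in unique(g)) {
    i <- which(g == lev)
    ss_within <- ss_within + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  ss_between <- ss_total - ss_within
  k <- length(unique(g))
  df_b <- k - 1L
  df_w <- n - k
  list(f = (ss_between / df_b) / (ss_within / df_w), df = c(df_b, df_w))
}

#' One-way permutational ANOVA (Euclidean distance, unrestricted permutation)
#'
#' Tests for a difference in location among groups of univariate
#' observations using a pseudo-F computed from the Euclidean distance
#' matrix and a permutation null obtained by unrestricted reshuffling of the
#' raw observations across groups. The p-value uses the add-one convention
#' `p = (b + 1) / (n_perm + 1)`, where `b` counts permuted pseudo-F values at
#' least as large as the observed one, so a sampled permutation p-value is
#' never exactly zero.
#'
#' With `exhaustive = TRUE` (two groups only) all distinct reassignments of
#' observations to group sizes are enumerated and the p-value is exact:
#' `p = (#{F_perm >= F_obs}) / #assignments` (the identity assignment is one
#' of them, so p > 0 and no add-one is needed).
#'
#' @param x numeric observations, or a list of per-group numeric vectors
#'   (in which case `g` is ignored).
#' @param g group labels, same length as `x`.
#' @param n_perm number of random permutations (default 999).
#' @param seed optional RNG seed for the permutation draw.
#' @param exhaustive enumerate all assignments (two groups only).
#' @return an object of class `perm_anova`: `pseudo_F`, `df_between`,
#'   `df_within`, `p_perm`, `n_perm`, `seed`, `exhaustive`.
#' @examples
#' set.seed(1)
#' perm_anova_oneway(list(a = rnorm(9), b = rnorm(9, 2), c = rnorm(9)))
#' @export
perm_anova_oneway <- function(x, g = NULL, n_perm = 999, seed = NULL,
                              exhaustive = FALSE) {
  if (is.list(x)) {
    g <- rep(names(x) %||% seq_along(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  g <- as.character(g)
  stopifnot(length(x) == length(g))
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes < 2L)) stop("every group needs at least two observations")

  d2 <- outer(x, x, "-")^2
  if (sum(d2) == 0) {
    warning("zero total variance: pseudo-F undefined, p set to 1")
    return(structure(list(pseudo_F = NA_real_,
                          df_between = length(sizes) - 1L,
                          df_within = length(x) - length(sizes),
                          p_perm = 1, n_perm = 0L, seed = seed,
                          exhaustive = FALSE),
                     class = "perm_anova"))
  }
  obs <- .pseudo_f_from_d2(d2, g)

  if (exhaustive) {
    if (length(sizes) != 2L) {
      stop("exhaustive enumeration is implemented for two groups only")
    }
    n <- length(x)
    n1 <- sizes[[1]]
    combos <- utils::combn(n, n1)
    fs <- apply(combos, 2, function(i) {
      gg <- rep(names(sizes)[2], n)
      gg[i] <- names(sizes)[1]
      .pseudo_f_from_d2(d2, gg)$f
    })
    p <- mean(fs >= obs$f - 1e-12)
    n_used <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    fs <- replicate(n_perm, .pseudo_f_from_d2(d2, sample(g))$f)
    p <- (sum(fs >= obs$f - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(pseudo_F = obs$f, df_between = obs$df[1],
                 df_within = obs$df[2], p_perm = p, n_perm = n_used,
                 seed = seed, exhaustive = exhaustive),
            class = "perm_anova")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("Permutational one-way ANOVA (Euclidean distance)\n"))
  cat(sprintf("  pseudo-F(%d, %d) = %.4g, p = %.4g (%s, %d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$p_perm,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}

#' Pairwise two-group permutation tests
#'
#' Post-hoc companion to [perm_anova_oneway()]: for each requested pair of
#' groups, a two-group permutation test on the Euclidean-distance pseudo-F
#' (the square of the pseudo-t). No multiplicity correction is applied by
#' default; set `p_adjust = "holm"` to adjust.
#'
#' @param x numeric observations, or a list of per-group vectors.
#' @param g group labels (ignored when `x` is a list).
#' @param pairs optional two-column character matrix of group pairs; defaults
#'   to all pairs.
#' @param n_perm permutations per pair.
#' @param seed optional RNG seed.
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @param exhaustive enumerate all assignments per pair.
#' @return data frame `group1`, `group2`, `pseudo_F`, `p`.
#' @export
pairwise_perm_tests <- function(x, g = NULL, pairs = NULL, n_perm = 999,
                                seed = NULL, p_adjust = "none",
                                exhaustive = FALSE) {
  if (is.list(x)) {
    g <- rep(names(x) %||% seq_along(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  g <- as.character(g)
  levs <- unique(g)
  if (is.null(pairs)) pairs <- t(utils::combn(levs, 2))
  if (!is.null(seed)) set.seed(seed)
  res <- apply(pairs, 1, function(pr) {
    keep <- g %in% pr
    if (length(unique(g[keep])) != 2L) {
      stop("pair (", pr[1], ", ", pr[2], ") missing a group")
    }
    fit <- perm_anova_oneway(x[keep], g[keep], n_perm = n_perm,
                             exhaustive = exhaustive)
    c(fit$pseudo_F, fit$p_perm)
  })
  out <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                    pseudo_F = res[1, ], p = stats::p.adjust(res[2, ],
                                                             method = p_adjust),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chi-square contingency test on years-returned distributions
#'
#' Compares sites on the distribution of the number of years individuals
#' returned. With `pool_rule = TRUE` the top two year-categories (e.g. 5 and
#' 6 years) are merged before testing, a pooling applied so that more than
#' 80% of cells have expected counts above five; `assumption_ok` reports
#' whether that rule is met after pooling. The statistic is the Pearson
#' chi-square without continuity correction.
#'
#' @param table nonnegative integer matrix, sites in rows, years-returned
#'   categories in columns (e.g. from [years_observed_distribution()] with
#'   `pool_top = FALSE` when `pool_rule = TRUE` here, or already pooled).
#' @param pool_rule merge the last two columns before testing.
#' @return object of class `chisq_return_years`: `chi2`, `df`, `p`, `pooled`,
#'   `expected_table`, `assumption_ok`, `observed`.
#' @export
chisq_return_years <- function(table, pool_rule = TRUE) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain nonnegative integer counts")
  }
  if (pool_rule && ncol(tab) >= 3L) {
    nc <- ncol(tab)
    pooled_col <- tab[, nc - 1L] + tab[, nc]
    lab <- paste(colnames(tab)[nc - 1L], colnames(tab)[nc], sep = "-")
    tab <- cbind(tab[, seq_len(nc - 2L), drop = FALSE], pooled_col)
    colnames(tab)[ncol(tab)] <- lab
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has an empty row or column")
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need at least 2 rows and 2 columns after pooling")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, pooled = isTRUE(pool_rule),
                 expected_table = ct$expected,
                 assumption_ok = mean(ct$expected > 5) > 0.8,
                 observed = tab),
            class = "chisq_return_years")
}

#' @export
print.chisq_return_years <- function(x, ...) {
  cat(sprintf("Pearson chi-square on years-returned table (%dx%d%s)\n",
              nrow(x$observed), ncol(x$observed),
              if (x$pooled) ", top categories pooled" else ""))
  cat(sprintf("  chi2(%d) = %.4g, p = %.4g; expected-count rule %s\n",
              x$df, x$chi2, x$p,
              if (x$assumption_ok) "met" else "NOT met"))
  invisible(x)
}

#' Upper-tail chi-square critical value
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha upper-tail probability in (0, 1).
#' @return the value exceeded with probability `alpha` under chi-square(df).
#' @examples
#' chi2_critical(12, 0.001)  # 32.91
#' @export
chi2_critical <- function(df, alpha) {
  if (any(df < 1) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("need df >= 1 and 0 < alpha < 1")
  }
  stats::qchisq(alpha, df, lower.tail = FALSE)
}

#' Choose which flank view's result to report
#'
#' Every analysis is run on both the LB and RB catalogue views. When the two
#' results fall in the same significance category at `alpha`, the LB result
#' is reported (the left-flank view typically has the larger sample); when
#' they disagree, both are returned flagged for manual review.
#'
#' @param result_LB,result_RB results carrying a p-value (`p_perm` or `p`
#'   element) computed on the same design from the two views.
#' @param alpha significance level defining the categories (default 0.05).
#' @return a list of class `side_selection`: `concordant`, `chosen` (the LB
#'   result when concordant, else `NULL`), `side`, and both inputs.
#' @export
report_side_selection <- function(result_LB, result_RB, alpha = 0.05) {
  pval <- function(r) r$p_perm %||% r$p %||% stop("result carries no p-value")
  sig <- c(LB = pval(result_LB) <= alpha, RB = pval(result_RB) <= alpha)
  concordant <- sig[["LB"]] == sig[["RB"]]
  structure(list(concordant = concordant,
                 chosen = if (concordant) result_LB else NULL,
                 side = if (concordant) "LB" else "discordant",
                 LB = result_LB, RB = result_RB, alpha = alpha),
            class = "side_selection")
}

#' @export
print.side_selection <- function(x, ...) {
  if (x$concordant) {
    cat("LB and RB views agree at alpha =", x$alpha,
        "-> reporting LB result:\n")
    print(x$chosen)
  } else {
    cat("LB and RB views DISAGREE at alpha =", x$alpha,
        "-> both returned for manual review\n")
  }
  invisible(x)
}
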