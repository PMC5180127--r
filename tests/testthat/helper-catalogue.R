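# Build a sighting catalogue in code from parallel vectors.
make_catalogue <- function(id, site, date, sex = "indeterminate",
                           flanks = "LR") {
  out <- data.frame(individual_id = id, site = site, date = as.Date(date),
                    sex = sex, flanks = flanks, stringsAsFactors = FALSE)
  class(out) <- c("sighting_catalogue", "data.frame")
  out
}

# A two-site toy catalogue used across metric tests:
# at site A, shark a1 is seen in 2005 and 2006, a2 only in 2006.
toy_two_year <- function() {
  make_catalogue(
    id = c("a1", "a1", "a2"),
    site = "A",
    date = c("2005-06-01", "2006-06-15", "2006-07-01"))
}

# Classical one-way ANOVA F, the independent oracle for the distance-based
# pseudo-F (computed from group means, not from the distance partition).
anova_f <- function(x, g) {
  g <- factor(g)
  summary(stats::aov(x ~ g))[[1]]$`F value`[1]
}
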