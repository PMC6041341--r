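#' F-index: a species' gene count relative to the family average
#'
#' For an orthogroup (gene family) g with counts \eqn{n_{g,s}} across species,
#' let \eqn{\bar x_g} be the arithmetic mean count over *all* species in the
#' table (the focal species included). The F-index of species s in family g is
#'
#' \deqn{F_{g,s} = n_{g,s} / (n_{g,s} + \bar x_g).}
#'
#' F lies in `[0, 1)`: it is 0 when the species has no member and the family
#' is non-empty, exactly 0.5 when the species' count equals the family
#' average, below 0.5 when the count is smaller than the average and above
#' 0.5 when larger. `f_ratio()` is the scoring kernel; supplying a different
#' kernel to [f_index_table()] changes the statistic everywhere at once.
#'
#' @param n Non-negative gene count(s).
#' @param xbar Positive family mean count(s).
#' @return `f_ratio()`: numeric in `[0, 1)`.
#' @export
f_ratio <- function(n, xbar) {
  if (any(xbar <= 0)) abort("family mean must be positive (all-zero families have no F-index)")
  n / (n + xbar)
}

#' @rdname f_ratio
#' @param counts Gene-count tibble (see [read_gene_counts()]).
#' @param orthogroup Orthogroup id (single string).
#' @param species Species id (single string).
#' @return `f_index()`: a single F value.
#' @examples
#' m <- tibble::tibble(orthogroup = "OG1", spA = 2L, spB = 2L, spC = 2L)
#' f_index(m, "OG1", "spA") # 0.5: count equals the family mean
#' @export
f_index <- function(counts, orthogroup, species) {
  validate_gene_counts(counts)
  check_species(counts, species)
  row <- match(orthogroup, counts[[1]])
  if (is.na(row)) abort(sprintf("unknown orthogroup id: %s", orthogroup))
  m <- count_matrix(counts)
  xbar <- mean(m[row, ])
  if (xbar <= 0) abort(sprintf("orthogroup %s has no members in any species; its F-index is undefined", orthogroup))
  f_ratio(m[row, species], xbar)
}

#' F-index table over many families and species
#'
#' @param counts Gene-count tibble.
#' @param orthogroups Orthogroup ids to score (default: all rows). All-zero
#'   orthogroups are rejected rather than silently scored.
#' @param species Species ids to score (default: all species columns). The
#'   family mean is always taken over *all* species columns, regardless of
#'   which species are scored.
#' @param f_fun Scoring kernel `f(n, xbar)`; defaults to [f_ratio()].
#' @return A long tibble with columns `orthogroup`, `species`, `n`
#'   (the count), `family_mean` and `f`.
#' @export
f_index_table <- function(counts, orthogroups = NULL, species = NULL, f_fun = f_ratio) {
  validate_gene_counts(counts)
  m <- count_matrix(counts)
  orthogroups <- if (is.null(orthogroups)) counts[[1]] else as_orthogroup_ids(orthogroups)
  rows <- match(orthogroups, counts[[1]])
  if (anyNA(rows)) {
    abort(sprintf("unknown orthogroup id(s): %s",
                  paste(utils::head(orthogroups[is.na(rows)], 5), collapse = ", ")))
  }
  species <- species %||% species_cols(counts)
  check_species(counts, species)
  xbar <- rowMeans(m)[rows]
  if (any(xbar <= 0)) {
    abort(sprintf("all-zero orthogroup(s) have no F-index: %s",
                  paste(utils::head(orthogroups[xbar <= 0], 5), collapse = ", ")))
  }
  tidyr::expand_grid(orthogroup = orthogroups, species = species) |>
    dplyr::mutate(
      n = as.vector(m[cbind(match(.data$orthogroup, counts[[1]]), match(.data$species, colnames(m)))]),
      family_mean = xbar[match(.data$orthogroup, orthogroups)],
      f = f_fun(.data$n, .data$family_mean)
    )
}

#' Tukey summary of a species' F-index distribution
#'
#' Summarises the F-indices of one species over a conserved set of
#' orthogroups in the form used for a Tukey boxplot: quartiles (linear
#' interpolation, the classical "type 7" rule), mean, whiskers at the most
#' extreme data within 1.5 interquartile ranges of the nearer quartile, and
#' outliers beyond the whiskers. `fraction_below_half` is the fraction of
#' families whose count in this species is strictly below the family mean
#' (equivalently, F strictly below 0.5).
#'
#' @param counts Gene-count tibble.
#' @param conserved Conserved set (tibble from [conserved_orthogroups()] or
#'   character vector of orthogroup ids); must be non-empty.
#' @param species Species id to summarise.
#' @inheritParams f_index_table
#' @return A `tukey_summary` object: a list with `species`, `n`, `q1`,
#'   `median`, `q3`, `mean`, `whisker_low`, `whisker_high`, `outliers`,
#'   `fraction_below_half` and the raw `values`. [tidy()] returns the
#'   statistics as a one-row tibble; [autoplot()] draws the boxplot.
#' @export
f_summary <- function(counts, conserved, species, f_fun = f_ratio) {
  ids <- as_orthogroup_ids(conserved)
  if (length(ids) == 0) abort("conserved set is empty")
  tab <- f_index_table(counts, orthogroups = ids, species = species, f_fun = f_fun)
  x <- tab$f
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  structure(
    list(
      species = species,
      n = length(x),
      q1 = q[1], median = q[2], q3 = q[3],
      mean = mean(x),
      whisker_low = min(x[x >= lo_fence]),
      whisker_high = max(x[x <= hi_fence]),
      outliers = x[x < lo_fence | x > hi_fence],
      fraction_below_half = mean(tab$n < tab$family_mean),
      values = x
    ),
    class = "tukey_summary"
  )
}

#' @export
print.tukey_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "F-index summary for %s over %d families\n",
      "  quartiles: %.3f / %.3f / %.3f   mean: %.3f\n",
      "  whiskers: [%.3f, %.3f]   outliers: %d\n",
      "  families below the all-species average: %.1f%%\n"
    ),
    x$species, x$n, x$q1, x$median, x$q3, x$mean,
    x$whisker_low, x$whisker_high, length(x$outliers),
    100 * x$fraction_below_half
  ))
  invisible(x)
}

#' @rdname f_summary
#' @param x A `tukey_summary`.
#' @param ... Unused.
#' @export
tidy.tukey_summary <- function(x, ...) {
  tibble(
    species = x$species, n = x$n,
    q1 = x$q1, median = x$median, q3 = x$q3, mean = x$mean,
    whisker_low = x$whisker_low, whisker_high = x$whisker_high,
    n_outliers = length(x$outliers),
    fraction_below_half = x$fraction_below_half
  )
}
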