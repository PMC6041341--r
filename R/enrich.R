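#' Hypergeometric gene-set enrichment
#'
#' Tests each annotation term for over-representation in a query gene set
#' drawn from a universe, with the upper-tail hypergeometric probability
#' \eqn{P(X \ge k)} where k is the number of query genes carrying the term,
#' K the number of universe genes carrying it, n the query size and N the
#' universe size. Benjamini-Hochberg q-values are computed across the tested
#' terms; terms with no query hit (k = 0) are dropped before adjustment.
#'
#' @param query Character vector of query gene ids; must be a subset of
#'   `universe`.
#' @param universe Character vector of background gene ids.
#' @param annotation Tibble with columns `term`, `gene` (one row per
#'   annotation); genes outside the universe are ignored.
#' @return A tibble sorted by `p_value` with columns `term`, `k`, `K`, `n`,
#'   `N`, `p_value`, `q_value`.
#' @examples
#' ann <- tibble::tibble(term = "T1", gene = paste0("g", 1:5))
#' enrich(paste0("g", 1:5), paste0("g", 1:10), ann)
#' @export
enrich <- function(query, universe, annotation) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0) abort("query gene set is empty")
  if (length(universe) == 0) abort("universe gene set is empty")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    abort(sprintf("query gene(s) not in universe: %s",
                  paste(utils::head(outside, 5), collapse = ", ")))
  }
  stopifnot(is.data.frame(annotation), all(c("term", "gene") %in% names(annotation)))

  ann <- annotation |>
    dplyr::distinct(.data$term, .data$gene) |>
    dplyr::filter(.data$gene %in% universe)
  if (nrow(ann) == 0) {
    return(tibble(term = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(),
                  p_value = double(), q_value = double()))
  }
  N <- length(universe)
  n <- length(query)
  ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      k = sum(.data$gene %in% query),
      K = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$k > 0) |>
    dplyr::mutate(
      n = n,
      N = N,
      p_value = phyper(.data$k - 1L, .data$K, N - .data$K, n, lower.tail = FALSE),
      q_value = p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::arrange(.data$p_value, .data$term)
}
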