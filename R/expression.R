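#' Read a gene-by-tissue expression matrix
#'
#' Tab-separated: header row of tissue ids, first column of gene ids, cells
#' holding non-negative TPM-like values.
#'
#' @param path Path to a TSV file.
#' @return A tibble whose first column is `gene` and whose remaining columns
#'   are tissues (numeric).
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort(sprintf("'%s' is not an expression table: need genes plus at least one tissue column", path))
  }
  names(raw)[1] <- "gene"
  if (anyDuplicated(raw$gene)) {
    abort(sprintf("duplicated gene id(s) in '%s'", path))
  }
  if (anyDuplicated(names(raw))) {
    abort(sprintf("duplicated tissue column(s) in '%s'", path))
  }
  for (col in names(raw)[-1]) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | vals < 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "parse error in '%s' at line %d: cell '%s' in column '%s' is not a non-negative number",
        path, bad[1] + 1L, raw[[col]][bad[1]], col
      ))
    }
    raw[[col]] <- vals
  }
  raw
}

validate_expression <- function(expr) {
  if (!is.data.frame(expr) || ncol(expr) < 2) {
    abort("expression table must have a gene column plus tissue columns")
  }
  if (anyDuplicated(expr[[1]])) abort("gene ids must be unique")
  m <- as.matrix(expr[-1])
  if (!is.numeric(m) || anyNA(m) || any(m < 0)) {
    abort("expression values must be non-negative numbers")
  }
  invisible(expr)
}

tissue_cols <- function(expr) names(expr)[-1]

#' Principally expressed tissues (PETs)
#'
#' A tissue t is a *principally expressed tissue* of gene g when the gene's
#' expression in t is at least `fold_threshold` times the mean of its
#' expression over all the *other* tissues. With the default
#' `fold_threshold = 2` this encodes "at least one-fold greater than the
#' average of the other tissues"; setting it to 1 gives the weaker "at least
#' as high as the average" reading. Genes with zero expression everywhere
#' have no PET. A gene may have several PETs.
#'
#' @param expr Expression tibble (see [read_expression()]); must have at
#'   least two tissues.
#' @param fold_threshold Positive fold threshold (default 2).
#' @param genes Optional subset of gene ids to classify (default: all).
#' @return A long tibble with one row per (gene, PET tissue): columns `gene`,
#'   `tissue`, `value` and `other_mean`. Genes with an empty PET set have no
#'   rows. The classified gene set is attached as attribute `genes`.
#' @export
principal_tissues <- function(expr, fold_threshold = 2, genes = NULL) {
  validate_expression(expr)
  if (ncol(expr) < 3) abort("PET classification needs at least two tissues")
  if (!is.numeric(fold_threshold) || fold_threshold <= 0) {
    abort("fold_threshold must be a positive number")
  }
  if (!is.null(genes)) {
    miss <- setdiff(genes, expr[[1]])
    if (length(miss) > 0) abort(sprintf("unknown gene id(s): %s", paste(utils::head(miss, 5), collapse = ", ")))
    expr <- expr[match(genes, expr[[1]]), ]
  }
  m <- as.matrix(expr[-1])
  rownames(m) <- expr[[1]]
  k <- ncol(m)
  other_mean <- (rowSums(m) - m) / (k - 1)
  is_pet <- (m >= fold_threshold * other_mean) & (rowSums(m) > 0)
  idx <- which(is_pet, arr.ind = TRUE)
  out <- tibble(
    gene = rownames(m)[idx[, 1]],
    tissue = colnames(m)[idx[, 2]],
    value = m[idx],
    other_mean = other_mean[idx]
  ) |>
    dplyr::arrange(match(.data$gene, rownames(m)), match(.data$tissue, colnames(m)))
  attr(out, "genes") <- rownames(m)
  attr(out, "fold_threshold") <- fold_threshold
  out
}

#' Principally expressed genes (PEGs) of a focal tissue set
#'
#' A gene is a *principally expressed gene* of the focal tissues (for
#' instance prehaustoria plus haustoria) when its mean expression over the
#' focal tissues is at least `fold_threshold` times its mean expression over
#' all the remaining tissues.
#'
#' @inheritParams principal_tissues
#' @param focal_tissues Non-empty proper subset of the tissue columns.
#' @return A tibble with one row per gene: `gene`, `focal_mean`,
#'   `other_mean`, `is_peg`. Filter on `is_peg` for the PEG set.
#' @export
principal_genes <- function(expr, focal_tissues, fold_threshold = 2) {
  validate_expression(expr)
  if (!is.numeric(fold_threshold) || fold_threshold <= 0) {
    abort("fold_threshold must be a positive number")
  }
  tissues <- tissue_cols(expr)
  miss <- setdiff(focal_tissues, tissues)
  if (length(miss) > 0) abort(sprintf("unknown tissue id(s): %s", paste(miss, collapse = ", ")))
  if (length(focal_tissues) == 0) abort("focal tissue set is empty")
  if (length(focal_tissues) >= length(tissues)) {
    abort("focal tissues must be a proper subset: no other tissues left to compare against")
  }
  other <- setdiff(tissues, focal_tissues)
  fm <- rowMeans(as.matrix(expr[focal_tissues]))
  om <- rowMeans(as.matrix(expr[other]))
  tibble(
    gene = expr[[1]],
    focal_mean = fm,
    other_mean = om,
    is_peg = (fm >= fold_threshold * om) & (fm + om > 0)
  )
}

#' Read a two-column orthogroup-to-proxy-gene map
#'
#' @param path TSV with columns orthogroup id, proxy gene id (header
#'   optional: a first line whose second field does not look like data is
#'   treated as a header only if it matches `orthogroup`/`gene` names).
#' @return Tibble with columns `orthogroup`, `gene`.
#' @export
read_ortholog_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                         col_names = c("orthogroup", "gene"), skip = 0)
  if (nrow(raw) > 0 && tolower(raw$orthogroup[1]) %in% c("orthogroup", "og") ) {
    raw <- raw[-1, ]
  }
  if (nrow(raw) == 0) abort(sprintf("'%s' contains no orthogroup-gene pairs", path))
  raw
}

#' Tabulate the PET classes of lost orthogroups in a proxy species
#'
#' Links lost orthogroups to genes of a proxy (autotrophic) species, looks up
#' those genes' principally expressed tissues, collapses tissues into the
#' classes leaves / roots / flowers / other, and counts how many lost
#' orthogroups have at least one PET in each class. An orthogroup with PETs
#' in several classes contributes to each of them. Two percentages are
#' reported, because the normalisation can be read two ways: `pct_of_class`
#' divides by the number of *all* mapped orthogroups (lost or not) with a PET
#' in that class, and `pct_of_lost` divides by the number of lost orthogroups
#' tabulated.
#'
#' @param lost Character vector of lost orthogroup ids (or a `loss_report`).
#' @param ortholog_map Tibble with columns `orthogroup`, `gene` linking
#'   orthogroups to proxy-species genes (possibly one-to-many).
#' @param pets PET assignments for the proxy species, from
#'   [principal_tissues()] run on the proxy expression matrix.
#' @param tissue_classes Tibble with columns `tissue`, `class` covering every
#'   tissue of the proxy matrix; classes beyond leaves/roots/flowers are
#'   reported under their own labels (conventionally "other").
#' @return A `pet_tabulation` object: list with `classes` (tibble of `class`,
#'   `n_lost`, `n_all`, `pct_of_class`, `pct_of_lost`), `n_lost_total`,
#'   `n_unmapped` (lost orthogroups with no map entry) and `n_no_pet` (mapped
#'   but with no PET in any tissue). [tidy()] returns the class tibble.
#' @export
tabulate_lost_pets <- function(lost, ortholog_map, pets, tissue_classes) {
  if (inherits(lost, "loss_report")) lost <- lost$lost
  lost <- unique(as.character(lost))
  stopifnot(is.data.frame(ortholog_map), all(c("orthogroup", "gene") %in% names(ortholog_map)))
  stopifnot(is.data.frame(tissue_classes), all(c("tissue", "class") %in% names(tissue_classes)))
  uncovered <- setdiff(unique(pets$tissue), tissue_classes$tissue)
  if (length(uncovered) > 0) {
    abort(sprintf("tissue class map does not cover: %s", paste(uncovered, collapse = ", ")))
  }
  class_levels <- unique(tissue_classes$class)

  og_classes <- ortholog_map |>
    dplyr::inner_join(pets, by = "gene", relationship = "many-to-many") |>
    dplyr::inner_join(tissue_classes, by = "tissue") |>
    dplyr::distinct(.data$orthogroup, .data$class)

  n_all <- og_classes |> dplyr::count(.data$class, name = "n_all")
  n_lost <- og_classes |>
    dplyr::filter(.data$orthogroup %in% lost) |>
    dplyr::count(.data$class, name = "n_lost")

  classes <- tibble(class = class_levels) |>
    dplyr::left_join(n_lost, by = "class") |>
    dplyr::left_join(n_all, by = "class") |>
    dplyr::mutate(
      n_lost = dplyr::coalesce(.data$n_lost, 0L),
      n_all = dplyr::coalesce(.data$n_all, 0L),
      pct_of_class = ifelse(.data$n_all > 0, 100 * .data$n_lost / .data$n_all, NA_real_),
      pct_of_lost = if (length(lost) > 0) 100 * .data$n_lost / length(lost) else NA_real_
    )

  mapped <- intersect(lost, ortholog_map$orthogroup)
  with_pet <- intersect(lost, og_classes$orthogroup)
  structure(
    list(
      classes = classes,
      n_lost_total = length(lost),
      n_unmapped = length(setdiff(lost, mapped)),
      n_no_pet = length(setdiff(mapped, with_pet))
    ),
    class = "pet_tabulation"
  )
}

#' @export
print.pet_tabulation <- function(x, ...) {
  cat(sprintf("PET tabulation of %d lost orthogroups (%d unmapped, %d without any PET)\n",
              x$n_lost_total, x$n_unmapped, x$n_no_pet))
  print(x$classes)
  invisible(x)
}

#' @rdname tabulate_lost_pets
#' @param x A `pet_tabulation`.
#' @param ... Unused.
#' @export
tidy.pet_tabulation <- function(x, ...) x$classes

#' @rdname tabulate_lost_pets
#' @export
glance.pet_tabulation <- function(x, ...) {
  tibble(
    n_lost_total = x$n_lost_total,
    n_unmapped = x$n_unmapped,
    n_no_pet = x$n_no_pet,
    n_classified = x$n_lost_total - x$n_unmapped - x$n_no_pet
  )
}
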