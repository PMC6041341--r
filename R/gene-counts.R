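#' Read an orthogroup-by-species gene-count table
#'
#' Reads a tab-separated table in the OrthoFinder `Orthogroups.GeneCount.tsv`
#' dialect: a header row naming the species, a first column of orthogroup
#' identifiers, and one non-negative integer gene count per cell. A trailing
#' `Total` column, if present, is kept but ignored by every downstream
#' computation (see [species_cols()]).
#'
#' @param path Path to a TSV file.
#' @return A tibble whose first column (`orthogroup`) holds the orthogroup
#'   identifiers and whose remaining columns hold integer gene counts, one
#'   column per species, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Orthogroup\tspA\tspB", "OG1\t1\t2", "OG2\t0\t3"), tf)
#' read_gene_counts(tf)
#' @export
read_gene_counts <- function(path) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort(sprintf("'%s' is not a gene-count table: need a header row plus at least one orthogroup row and one species column", path))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("parse error in '%s' at line %d: %s", path, prob$row[1] + 1L, prob$expected[1]))
  }
  names(raw)[1] <- "orthogroup"
  ids <- raw$orthogroup
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicated orthogroup id(s) in '%s': %s", path, paste(dup, collapse = ", ")))
  }
  dup_sp <- unique(names(raw)[duplicated(names(raw))])
  if (length(dup_sp) > 0) {
    abort(sprintf("duplicated species column(s) in '%s': %s", path, paste(dup_sp, collapse = ", ")))
  }
  for (col in names(raw)[-1]) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | vals < 0 | vals != floor(vals))
    if (length(bad) > 0) {
      abort(sprintf(
        "parse error in '%s' at line %d: cell '%s' in column '%s' is not a non-negative integer",
        path, bad[1] + 1L, raw[[col]][bad[1]], col
      ))
    }
    raw[[col]] <- as.integer(vals)
  }
  raw
}

validate_gene_counts <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    abort("gene-count table must have an orthogroup column plus species columns")
  }
  ids <- counts[[1]]
  if (anyDuplicated(ids)) abort("orthogroup ids must be unique")
  m <- count_matrix(counts)
  if (anyNA(m) || any(m < 0) || any(m != floor(m))) {
    abort("gene counts must be non-negative integers")
  }
  invisible(counts)
}

#' Identify conserved orthogroups
#'
#' An orthogroup is *conserved* when it has at least one member in the
#' reference species and at least one member in `min_present` or more of the
#' panel species. Counts in any other species (for instance the parasite
#' targets whose losses are to be called) play no role in this rule.
#'
#' @param counts Gene-count tibble from [read_gene_counts()].
#' @param reference Reference species id (a column of `counts`).
#' @param panel Character vector of panel species ids.
#' @param min_present Minimum number of panel species in which the orthogroup
#'   must be present (default 5, i.e. five of a six-species autotroph panel).
#' @return A tibble with columns `orthogroup`, `ref_count` and
#'   `n_panel_present`, one row per conserved orthogroup, in input order.
#'   The rule parameters are attached as attributes `reference`, `panel` and
#'   `min_present`.
#' @export
conserved_orthogroups <- function(counts, reference, panel, min_present = 5L) {
  validate_gene_counts(counts)
  check_species(counts, reference, "reference species")
  check_species(counts, panel, "panel species")
  if (reference %in% panel) abort("the reference species cannot also be in the panel")
  min_present <- as.integer(min_present)
  if (min_present < 0 || min_present > length(panel)) {
    abort(sprintf("min_present must be between 0 and the panel size (%d)", length(panel)))
  }
  m <- count_matrix(counts, c(reference, panel))
  n_panel <- rowSums(m[, panel, drop = FALSE] >= 1)
  keep <- m[, reference] >= 1 & n_panel >= min_present
  out <- tibble(
    orthogroup = counts[[1]][keep],
    ref_count = as.integer(m[keep, reference]),
    n_panel_present = as.integer(n_panel[keep])
  )
  attr(out, "reference") <- reference
  attr(out, "panel") <- panel
  attr(out, "min_present") <- min_present
  out
}

#' Call gene losses in a target species
#'
#' A conserved orthogroup is *lost* in the target species when the target has
#' zero members in it.
#'
#' @param counts Gene-count tibble.
#' @param conserved Conserved set: the tibble from [conserved_orthogroups()]
#'   or a character vector of orthogroup ids (each must be a row of `counts`).
#' @param target Target species id.
#' @return A `loss_report` object: a list with elements `target`,
#'   `lost` (character vector of lost orthogroup ids), `conserved` (the full
#'   conserved id vector), `n_conserved`, `n_lost` and `loss_fraction`.
#'   Use [tidy()] for a per-orthogroup tibble and [glance()] for a one-row
#'   summary.
#' @export
call_losses <- function(counts, conserved, target) {
  validate_gene_counts(counts)
  check_species(counts, target, "target species")
  ids <- as_orthogroup_ids(conserved)
  unknown <- setdiff(ids, counts[[1]])
  if (length(unknown) > 0) {
    abort(sprintf("conserved set references unknown orthogroup(s): %s",
                  paste(utils::head(unknown, 5), collapse = ", ")))
  }
  if (length(ids) == 0) abort("conserved set is empty")
  cnt <- setNames(count_matrix(counts, target)[, 1], counts[[1]])[ids]
  lost <- ids[cnt == 0]
  structure(
    list(
      target = target,
      lost = lost,
      conserved = ids,
      n_conserved = length(ids),
      n_lost = length(lost),
      loss_fraction = length(lost) / length(ids)
    ),
    class = "loss_report"
  )
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(
    "Loss report for %s: %d of %d conserved orthogroups lost (%.1f%%)\n",
    x$target, x$n_lost, x$n_conserved, 100 * x$loss_fraction
  ))
  invisible(x)
}

#' @rdname call_losses
#' @param x A `loss_report`.
#' @param ... Unused.
#' @export
tidy.loss_report <- function(x, ...) {
  tibble(
    orthogroup = x$conserved,
    target = x$target,
    lost = x$conserved %in% x$lost
  )
}

#' @rdname call_losses
#' @export
glance.loss_report <- function(x, ...) {
  tibble(
    target = x$target,
    n_conserved = x$n_conserved,
    n_lost = x$n_lost,
    loss_fraction = x$loss_fraction
  )
}

#' Partition losses of two target species
#'
#' Splits the lost orthogroups of two targets (called against the same
#' conserved set) into jointly lost and species-specific sets.
#'
#' @param loss_a,loss_b `loss_report` objects from [call_losses()], derived
#'   from the same conserved set.
#' @return A `loss_partition` object with elements `joint`, `specific_a`,
#'   `specific_b` (character vectors), `target_a`, `target_b` and
#'   `n_conserved`. [tidy()] gives an orthogroup/status tibble, [glance()]
#'   the three counts.
#' @export
partition_losses <- function(loss_a, loss_b) {
  stopifnot(inherits(loss_a, "loss_report"), inherits(loss_b, "loss_report"))
  if (!setequal(loss_a$conserved, loss_b$conserved)) {
    abort("loss reports were derived from different conserved sets")
  }
  joint <- intersect(loss_a$lost, loss_b$lost)
  structure(
    list(
      joint = joint,
      specific_a = setdiff(loss_a$lost, joint),
      specific_b = setdiff(loss_b$lost, joint),
      target_a = loss_a$target,
      target_b = loss_b$target,
      n_conserved = loss_a$n_conserved
    ),
    class = "loss_partition"
  )
}

#' @export
print.loss_partition <- function(x, ...) {
  cat(sprintf(
    "Loss partition (%s vs %s): %d joint, %d specific to %s, %d specific to %s\n",
    x$target_a, x$target_b, length(x$joint),
    length(x$specific_a), x$target_a, length(x$specific_b), x$target_b
  ))
  invisible(x)
}

#' @rdname partition_losses
#' @param x A `loss_partition`.
#' @param ... Unused.
#' @export
tidy.loss_partition <- function(x, ...) {
  tibble(
    orthogroup = c(x$joint, x$specific_a, x$specific_b),
    status = rep(c("joint", "specific_a", "specific_b"),
                 c(length(x$joint), length(x$specific_a), length(x$specific_b)))
  )
}

#' @rdname partition_losses
#' @export
glance.loss_partition <- function(x, ...) {
  tibble(
    target_a = x$target_a,
    target_b = x$target_b,
    n_joint = length(x$joint),
    n_specific_a = length(x$specific_a),
    n_specific_b = length(x$specific_b),
    n_lost_union = length(x$joint) + length(x$specific_a) + length(x$specific_b)
  )
}
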