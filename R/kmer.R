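#' Read a k-mer depth histogram
#'
#' Two-column whitespace-separated text in the jellyfish/KMC `histo` dialect:
#' depth (positive integer, strictly ascending) and the number of distinct
#' k-mers observed at that depth.
#'
#' @param path Path to the histogram file.
#' @return Tibble with integer columns `depth` and `count` (count stored as
#'   double to accommodate billions of k-mers).
#' @export
read_kmer_histogram <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("'%s' is empty", path))
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) != 2)) {
    abort(sprintf("parse error in '%s' at line %d: expected two columns",
                  path, which(lengths(parts) != 2)[1]))
  }
  depth <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  count <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  bad <- which(is.na(depth) | is.na(count) | depth < 1 | depth != floor(depth) |
                 count < 0 | count != floor(count))
  if (length(bad) > 0) {
    abort(sprintf("parse error in '%s' at line %d: depth must be a positive integer and count a non-negative integer",
                  path, bad[1]))
  }
  if (is.unsorted(depth, strictly = TRUE)) {
    abort(sprintf("'%s': depths must be unique and sorted ascending", path))
  }
  validate_kmer_histogram(tibble(depth = as.integer(depth), count = count))
}

validate_kmer_histogram <- function(h) {
  stopifnot(is.data.frame(h), all(c("depth", "count") %in% names(h)))
  if (nrow(h) == 0) abort("k-mer histogram is empty")
  if (any(h$depth < 1) || is.unsorted(h$depth, strictly = TRUE)) {
    abort("histogram depths must be positive, unique and ascending")
  }
  if (any(h$count < 0)) abort("histogram counts must be non-negative")
  h
}

#' Locate the error valley and coverage peak of a k-mer histogram
#'
#' Sequencing errors pile up distinct low-depth k-mers, so the depth-count
#' curve falls from depth 1, bottoms out, then rises into the coverage peak.
#' The error threshold is taken as the first local minimum (the histogram
#' must first descend, then rise); the peak is the most frequent depth above
#' the threshold, with ties broken toward the smaller depth.
#'
#' @param h Histogram tibble (see [read_kmer_histogram()]); at least 3 bins.
#' @return List with `error_threshold` and `peak_depth`.
#' @export
find_peak <- function(h) {
  h <- validate_kmer_histogram(h)
  if (nrow(h) < 3) abort("need at least 3 histogram bins to locate a valley and a peak")
  cnt <- h$count
  n <- length(cnt)
  # require an initial descent: a histogram rising from depth 1 has no error valley
  descent <- which(diff(cnt) < 0)
  rise <- which(diff(cnt) > 0)
  if (length(descent) == 0 || length(rise) == 0 || min(rise) < min(descent)) {
    abort("no error valley found (histogram is not descend-then-rise); supply error_threshold manually")
  }
  valley <- min(rise[rise >= min(descent)]) # last bin of the descending limb
  above <- which(h$depth > h$depth[valley])
  if (length(above) == 0) abort("no bins above the error threshold")
  peak <- above[which.max(cnt[above])]
  list(error_threshold = h$depth[valley], peak_depth = h$depth[peak])
}

#' Genome-size and repeat-content estimate from a k-mer histogram
#'
#' Implements the classical k-mer survey quotient: with K the total number
#' of k-mer observations above the error threshold (sum of depth x count)
#' and D the coverage-peak depth, the genome size is `G = K / D`. The repeat
#' fraction is the share of K carried by depths at or above
#' `repeat_multiplier x D` (k-mers observed well above single-copy coverage).
#' The unfiltered quotient (all depths included) is also reported as
#' `genome_size_naive`.
#'
#' @param h Histogram tibble.
#' @param error_threshold Depth at or below which k-mers are treated as
#'   sequencing errors; default: detected by [find_peak()].
#' @param peak_depth Single-copy coverage depth; default: detected.
#' @param repeat_multiplier Multiple of the peak depth above which k-mer mass
#'   counts as repetitive (default 2). With repeats of copy number c the
#'   repeat k-mer mass sits near `c x D`, so a multiplier between 1 and c
#'   (e.g. 1.5 for two-copy repeats) separates the two bumps cleanly.
#' @return A `survey_estimate` object: list with `error_threshold`,
#'   `peak_depth`, `kmer_count` (K), `genome_size`, `genome_size_naive`,
#'   `repeat_fraction`, `repeat_multiplier` and the input `histogram`.
#'   [tidy()]/[glance()] return the estimates as a one-row tibble;
#'   [autoplot()] draws the histogram with the detected valley and peak.
#' @export
estimate_genome_size <- function(h, error_threshold = NULL, peak_depth = NULL,
                                 repeat_multiplier = 2) {
  h <- validate_kmer_histogram(h)
  if (is.null(error_threshold)) {
    fp <- find_peak(h)
    error_threshold <- fp$error_threshold
    peak_depth <- peak_depth %||% fp$peak_depth
  }
  if (is.null(peak_depth)) {
    above <- which(h$depth > error_threshold)
    if (length(above) == 0) abort("no bins above the error threshold")
    peak_depth <- h$depth[above[which.max(h$count[above])]]
  }
  if (peak_depth <= error_threshold) abort("peak_depth must exceed error_threshold")
  if (repeat_multiplier <= 1) abort("repeat_multiplier must exceed 1")
  mass <- h$depth * h$count
  keep <- h$depth > error_threshold
  K <- sum(mass[keep])
  if (K == 0) abort("no k-mer mass above the error threshold")
  repeat_mass <- sum(mass[keep & h$depth >= repeat_multiplier * peak_depth])
  structure(
    list(
      error_threshold = error_threshold,
      peak_depth = peak_depth,
      kmer_count = K,
      genome_size = K / peak_depth,
      genome_size_naive = sum(mass) / peak_depth,
      repeat_fraction = repeat_mass / K,
      repeat_multiplier = repeat_multiplier,
      histogram = h
    ),
    class = "survey_estimate"
  )
}

#' @export
print.survey_estimate <- function(x, ...) {
  cat(sprintf(
    paste0(
      "k-mer genome survey\n",
      "  error threshold: depth <= %d   coverage peak: %d\n",
      "  k-mer count above threshold: %.0f\n",
      "  genome size: %.2f Mb (naive, unfiltered: %.2f Mb)\n",
      "  repeat fraction (depth >= %.1f x peak): %.2f%%\n"
    ),
    x$error_threshold, x$peak_depth, x$kmer_count,
    x$genome_size / 1e6, x$genome_size_naive / 1e6,
    x$repeat_multiplier, 100 * x$repeat_fraction
  ))
  invisible(x)
}

#' @rdname estimate_genome_size
#' @param x A `survey_estimate`.
#' @param ... Unused.
#' @export
tidy.survey_estimate <- function(x, ...) {
  tibble(
    error_threshold = x$error_threshold,
    peak_depth = x$peak_depth,
    kmer_count = x$kmer_count,
    genome_size = x$genome_size,
    genome_size_naive = x$genome_size_naive,
    repeat_fraction = x$repeat_fraction,
    repeat_multiplier = x$repeat_multiplier
  )
}

#' @rdname estimate_genome_size
#' @export
glance.survey_estimate <- function(x, ...) tidy(x)
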