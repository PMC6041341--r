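#' Plot an F-index Tukey summary
#'
#' Horizontal Tukey boxplot of one species' F-index distribution: box at the
#' quartiles, band at the median, cross at the mean, whiskers at the most
#' extreme data within 1.5 IQR, outliers as dots, and a dashed guide at
#' F = 0.5 (count equal to the family average).
#'
#' @param object A `tukey_summary` from [f_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tukey_summary <- function(object, ...) {
  box <- tibble(
    species = object$species,
    q1 = object$q1, median = object$median, q3 = object$q3,
    whisker_low = object$whisker_low, whisker_high = object$whisker_high,
    mean = object$mean
  )
  out <- tibble(species = object$species,
                f = if (length(object$outliers)) object$outliers else double())
  ggplot2::ggplot(box, ggplot2::aes(y = .data$species)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(xmin = .data$whisker_low, xlower = .data$q1,
                   xmiddle = .data$median, xupper = .data$q3,
                   xmax = .data$whisker_high),
      stat = "identity", orientation = "y", width = 0.5
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$mean), shape = 4, size = 3) +
    ggplot2::geom_point(data = out, ggplot2::aes(x = .data$f), alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "F-index", y = NULL)
}

#' Plot a loss partition
#'
#' Bar chart of jointly lost and species-specific lost orthogroup counts.
#'
#' @param object A `loss_partition` from [partition_losses()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loss_partition <- function(object, ...) {
  df <- tibble(
    set = factor(
      c("joint", object$target_a, object$target_b),
      levels = c("joint", object$target_a, object$target_b)
    ),
    n = c(length(object$joint), length(object$specific_a), length(object$specific_b))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "lost orthogroups",
                  title = "Joint and species-specific gene losses")
}

#' Plot a k-mer genome survey
#'
#' Depth-count curve of the k-mer histogram with the detected error
#' threshold (dotted), coverage peak (dashed) and repeat cutoff (dot-dash).
#'
#' @param object A `survey_estimate` from [estimate_genome_size()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survey_estimate <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$depth, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$error_threshold, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$peak_depth, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$repeat_multiplier * object$peak_depth,
                        linetype = "dotdash") +
    ggplot2::scale_y_continuous(trans = "log10") +
    ggplot2::labs(
      x = "k-mer depth", y = "distinct k-mers",
      title = sprintf("Genome size %.2f Mb, repeat fraction %.1f%%",
                      object$genome_size / 1e6, 100 * object$repeat_fraction)
    )
}

#' Plot a lost-orthogroup PET tabulation
#'
#' @param object A `pet_tabulation` from [tabulate_lost_pets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pet_tabulation <- function(object, ...) {
  ggplot2::ggplot(object$classes,
                  ggplot2::aes(x = .data$class, y = .data$n_lost)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", .data$pct_of_class)),
                       vjust = -0.3, na.rm = TRUE) +
    ggplot2::labs(x = "PET tissue class", y = "lost orthogroups")
}
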