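#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram geom_point
#'   labs theme_minimal scale_y_log10
#' @export
ggplot2::autoplot

#' Plot the cluster-size distribution of a nonredundant database
#'
#' @param object An `nr_db`.
#' @param ... Unused.
#' @return A ggplot: histogram of cluster sizes (identical-sequence counts)
#'   on a log count scale.
#' @method autoplot nr_db
#' @export
autoplot.nr_db <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$n_members)) +
    geom_histogram(bins = 30, fill = "grey30") +
    scale_y_log10() +
    labs(x = "identical members per representative",
         y = "clusters (log scale)",
         title = "Panallelome compaction") +
    theme_minimal()
}

#' Plot variant observation counts against identity to the reference
#'
#' @param object A `variant_set`.
#' @param ... Unused.
#' @return A ggplot of observations (cluster size) versus global percent
#'   identity for each retained allelic variant.
#' @method autoplot variant_set
#' @export
autoplot.variant_set <- function(object, ...) {
  d <- tidy(object)
  if (!"global_identity" %in% names(d)) {
    abort("variant set carries no alignment statistics to plot")
  }
  ggplot(d, aes(x = .data$global_identity, y = .data$observations)) +
    geom_point(alpha = 0.7) +
    labs(x = "global identity to reference (%)",
         y = "observations (identical sequences)",
         title = paste0("Allelic variants of ", object$reference$id)) +
    theme_minimal()
}

#' Plot per-variant coverage achieved by the minimum peptide list
#'
#' @param object A `selection_state` after [greedy_select()].
#' @param ... Unused.
#' @return A ggplot: covering-peptide count per variant, coloured by
#'   whether the coverage target was reached.
#' @method autoplot selection_state
#' @export
autoplot.selection_state <- function(object, ...) {
  d <- tibble(variant_id = names(object$coverage),
              coverage = as.integer(object$coverage),
              reached = object$coverage >= object$target)
  ggplot(d, aes(x = stats::reorder(.data$variant_id, .data$coverage),
                y = .data$coverage, fill = .data$reached)) +
    geom_col() +
    labs(x = "allelic variant", y = "covering peptides",
         fill = paste0(">= target (", object$target, ")"),
         title = "Coverage by the minimum peptide list") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
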