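#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_histogram
#'   geom_vline labs theme_minimal
NULL

#' Plot a spacer spectrum
#'
#' Bar chart of the number of regions containing a same-orientation double
#' motif at each spacer length.
#'
#' @param object A `spacer_spectrum` (see [spacer_spectrum()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spacer_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$spacer, y = .data$n_regions_with_pair)) +
    geom_col(fill = "steelblue") +
    labs(x = "Spacer (bp)", y = "Regions with double motif",
         title = "Double-motif spacer spectrum",
         subtitle = paste0(attr(object, "n_regions"), " regions scanned")) +
    theme_minimal()
}

#' Plot a summit-centred meta-profile
#'
#' @param object A `meta_profile` (see [metaprofile()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$offset, y = .data$mean_density)) +
    geom_line(colour = "firebrick") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    labs(x = "Offset from summit (bp)", y = "Mean density (RPM)",
         title = "Summit meta-profile") +
    theme_minimal()
}

#' Plot a conservation profile
#'
#' @param object A `conservation_profile` (see [conservation_profile()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$offset, y = .data$mean_score)) +
    geom_line(colour = "darkgreen") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    labs(x = "Offset from summit (bp)", y = "Mean score",
         title = "Summit-aligned score profile") +
    theme_minimal()
}

#' Plot the holdout AUC distribution
#'
#' Histogram of per-iteration AUCs with the mean marked.
#'
#' @param object An `nb_cv` (see [iterated_holdout()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_cv <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$auc)) +
    geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = object$mean_auc, colour = "firebrick") +
    labs(x = "AUC", y = "Iterations",
         title = "Iterated-holdout AUC distribution",
         subtitle = paste0("mean AUC = ", signif(object$mean_auc, 3))) +
    theme_minimal()
}

#' @export
ggplot2::autoplot
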