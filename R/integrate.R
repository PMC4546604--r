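#' Differential-expression gene selection
#'
#' Applies the knockdown DE rule across four pairwise comparisons of
#' knockdown vs control samples: a gene is selected iff (i) all four adjusted
#' p-values are at or below `p_threshold`, (ii) all four changes share one
#' direction, and (iii) at least one comparison reaches `major_fold` with the
#' remaining three reaching `minor_fold`. Fold changes are linear magnitudes
#' (> 0), with down-regulation expressed as the control/knockdown ratio.
#'
#' @param stats Long-format tibble with columns `gene_id`, `comparison`,
#'   `fold_change` (linear, > 0), `padj`, `direction` (`"down"`/`"up"`);
#'   exactly four comparisons per gene.
#' @param p_threshold Adjusted p-value cut (default `1e-5`).
#' @param major_fold Fold required in at least one comparison (default 2).
#' @param minor_fold Fold required in the other three (default 1.2).
#' @return A tibble with `gene_id`, `de_status` (`"down"`/`"up"`) for the
#'   selected genes.
#' @export
de_filter <- function(stats, p_threshold = 1e-5, major_fold = 2,
                      minor_fold = 1.2) {
  need <- c("gene_id", "comparison", "fold_change", "padj", "direction")
  missing <- setdiff(need, names(stats))
  if (length(missing) > 0) {
    abort(paste0("`stats` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(stats$fold_change <= 0)) abort("Fold changes must be positive.")
  if (!all(stats$direction %in% c("down", "up"))) {
    abort("`direction` must be 'down' or 'up'.")
  }
  counts <- table(stats$gene_id)
  if (any(counts != 4)) {
    abort(paste0("Every gene needs exactly 4 comparisons; offending gene(s): ",
                 paste(utils::head(names(counts)[counts != 4], 5), collapse = ", ")))
  }
  stats |>
    group_by(.data$gene_id) |>
    summarise(
      all_p = all(.data$padj <= p_threshold),
      one_dir = length(unique(.data$direction)) == 1,
      fold_rule = {
        f <- sort(.data$fold_change, decreasing = TRUE)
        f[1] >= major_fold && all(f[-1] >= minor_fold)
      },
      de_status = .data$direction[1],
      .groups = "drop"
    ) |>
    filter(.data$all_p, .data$one_dir, .data$fold_rule) |>
    select("gene_id", "de_status")
}

#' Differential-binding region selection
#'
#' Selects differentially bound regions with the triple threshold: adjusted
#' p-value at or below `p_threshold`, fold enrichment of at least
#' `fold_threshold`, and enrichment in the reference sample strictly below
#' `max_reference_density` normalised reads per kilobase.
#'
#' @param stats Tibble with columns `region_id`, `padj`, `fold`,
#'   `reference_density`.
#' @param p_threshold Adjusted p-value cut (default `1e-5`).
#' @param fold_threshold Minimum between-sample fold enrichment (default 2).
#' @param max_reference_density Reference-sample density bound (default 100).
#' @return The selected rows of `stats`.
#' @export
diffbind_filter <- function(stats, p_threshold = 1e-5, fold_threshold = 2,
                            max_reference_density = 100) {
  need <- c("region_id", "padj", "fold", "reference_density")
  missing <- setdiff(need, names(stats))
  if (length(missing) > 0) {
    abort(paste0("`stats` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  stats |>
    filter(.data$padj <= p_threshold,
           .data$fold >= fold_threshold,
           .data$reference_density < max_reference_density)
}

#' Intersect DE genes with peak target assignments
#'
#' Combines a DE gene selection with nearest-TSS peak assignments into a
#' per-gene target table recording whether each DE gene carries a peak — the
#' "down-regulated genes with a binding-site assignment" intersection that
#' defines the direct-target signature.
#'
#' @param de Output of [de_filter()] (columns `gene_id`, `de_status`).
#' @param assignments Output of [nearest_tss_assign()].
#' @return A `target_table` tibble with `gene_id`, `de_status`, `has_peak`;
#'   summary counts are available via [summary()] or
#'   [target_summary()].
#' @export
intersect_targets <- function(de, assignments) {
  peak_genes <- assigned_genes(assignments)
  all_genes <- sort(unique(c(de$gene_id, peak_genes)))
  status <- setNames(rep("none", length(all_genes)), all_genes)
  status[de$gene_id] <- de$de_status
  out <- tibble(
    gene_id = all_genes,
    de_status = unname(status),
    has_peak = all_genes %in% peak_genes
  )
  new_grammar_tbl(out, "target_table")
}

#' Summary counts for a target table
#'
#' @param x A `target_table` from [intersect_targets()].
#' @return A one-row tibble: `n_down`, `n_down_with_peak`,
#'   `fraction_down_with_peak` (NA when there are no down genes), `n_up`,
#'   `n_up_with_peak`, `fraction_up_with_peak`.
#' @export
target_summary <- function(x) {
  cnt <- function(status) {
    sel <- x$de_status == status
    n <- sum(sel)
    k <- sum(sel & x$has_peak)
    c(n = n, k = k, frac = if (n == 0) NA_real_ else k / n)
  }
  d <- cnt("down"); u <- cnt("up")
  tibble(
    n_down = d[["n"]], n_down_with_peak = d[["k"]],
    fraction_down_with_peak = d[["frac"]],
    n_up = u[["n"]], n_up_with_peak = u[["k"]],
    fraction_up_with_peak = u[["frac"]]
  )
}

#' @export
summary.target_table <- function(object, ...) {
  target_summary(object)
}
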