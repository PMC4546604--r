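#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n distinct pull across rename count
#' @importFrom stats phyper rnorm runif var sd cor median setNames rbinom
NULL

# Internal coordinate convention: 0-based, half-open [start, end).
# Summits are absolute 0-based positions satisfying start <= summit < end.

peak_cols <- c("chrom", "start", "end", "peak_id", "summit", "score")

assert_peaks <- function(peaks, require_sample = FALSE) {
  if (!is.data.frame(peaks)) {
    abort("`peaks` must be a data frame of peak records.")
  }
  missing <- setdiff(peak_cols, names(peaks))
  if (length(missing) > 0) {
    abort(paste0("`peaks` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (require_sample && !"sample" %in% names(peaks)) {
    abort("`peaks` must carry a `sample` column.")
  }
  bad <- which(!(peaks$start < peaks$end))
  if (length(bad) > 0) {
    abort(paste0("Invalid interval (start >= end) at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(peaks$summit < peaks$start | peaks$summit >= peaks$end)
  if (length(bad) > 0) {
    abort(paste0("Summit outside [start, end) at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(peaks$score < 0, na.rm = TRUE)) abort("Peak scores must be nonnegative.")
  invisible(peaks)
}

assert_chrom_sizes <- function(sizes) {
  if (!is.data.frame(sizes) || !all(c("chrom", "size") %in% names(sizes))) {
    abort("`chrom_sizes` must be a data frame with columns chrom, size.")
  }
  if (anyDuplicated(sizes$chrom) > 0) abort("Duplicate chromosome names in `chrom_sizes`.")
  if (any(sizes$size <= 0)) abort("Chromosome sizes must be positive.")
  invisible(sizes)
}

chrom_size_lookup <- function(sizes) {
  setNames(as.numeric(sizes$size), sizes$chrom)
}

# Run `expr` under a fixed RNG seed when `seed` is given, leaving the global
# RNG state untouched; without a seed the global stream is used as-is.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(as.integer(seed), expr)
}

new_grammar_tbl <- function(x, class, ...) {
  out <- as_tibble(x)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, class(out))
  out
}
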