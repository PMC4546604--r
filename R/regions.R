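#' Summit-centred windows
#'
#' Replaces each peak's interval with a fixed-width window centred on its
#' summit, the frame on which motif statistics are computed (151 bp, the
#' average ChIP fragment length, by default). Windows are clipped at
#' chromosome bounds when `chrom_sizes` is supplied and the `clipped` column
#' reports which rows were truncated.
#'
#' @param peaks A peak tibble (see [read_peaks()]).
#' @param width Odd window width in bp.
#' @param chrom_sizes Optional chromosome-sizes tibble for bounds clipping.
#' @return The peak tibble with `start`/`end` replaced by the window and a
#'   logical `clipped` column.
#' @examples
#' pk <- tibble::tibble(chrom = "chr1", start = 900, end = 1100,
#'                      peak_id = "p1", summit = 1000, score = 1)
#' summit_window(pk, 151)
#' @export
summit_window <- function(peaks, width = 151, chrom_sizes = NULL) {
  assert_peaks(peaks)
  if (length(width) != 1 || width <= 0 || width %% 2 == 0) {
    abort("`width` must be a single positive odd integer.")
  }
  half <- (width - 1) / 2
  out <- peaks
  out$start <- peaks$summit - half
  out$end <- peaks$summit + half + 1
  lo <- pmax(out$start, 0)
  hi <- out$end
  if (!is.null(chrom_sizes)) {
    assert_chrom_sizes(chrom_sizes)
    lens <- chrom_size_lookup(chrom_sizes)
    missing <- setdiff(unique(out$chrom), names(lens))
    if (length(missing) > 0) {
      abort(paste0("Chromosome(s) absent from `chrom_sizes`: ",
                   paste(missing, collapse = ", ")))
    }
    hi <- pmin(out$end, lens[out$chrom])
  }
  out$clipped <- lo != out$start | hi != out$end
  out$start <- lo
  out$end <- unname(hi)
  out
}

intervals_to_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1, end = x$end)  # to 1-based closed
}

#' Which query intervals overlap a reference set
#'
#' @param query,reference Data frames with `chrom`, `start`, `end` columns
#'   (0-based half-open).
#' @param min_overlap Minimum intersection in bp for a query to count as
#'   overlapping (default 1).
#' @return A logical vector, one element per query row.
#' @export
interval_overlaps <- function(query, reference, min_overlap = 1) {
  hits <- logical(nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    ri <- which(reference$chrom == chr)
    if (length(ri) == 0) next
    ov <- IRanges::overlapsAny(
      intervals_to_iranges(query[qi, , drop = FALSE]),
      intervals_to_iranges(reference[ri, , drop = FALSE]),
      minoverlap = min_overlap
    )
    hits[qi] <- ov
  }
  hits
}

#' Fraction of query regions overlapping a reference set
#'
#' The statistic behind "X% of peaks overlap" comparisons between samples
#' (e.g. TEAD1 vs YAP1 peak sets, or peak sets vs H3K27ac regions). A query
#' region counts as overlapping if it intersects at least `min_overlap` bp of
#' any reference region.
#'
#' @inheritParams interval_overlaps
#' @return A list with `fraction` (scalar in \[0, 1\]) and `overlaps`
#'   (per-query logical vector).
#' @export
overlap_fraction <- function(query, reference, min_overlap = 1) {
  if (nrow(query) == 0) abort("`query` must be non-empty: fraction undefined.")
  if (nrow(reference) == 0) abort("`reference` must be non-empty.")
  ov <- interval_overlaps(query, reference, min_overlap = min_overlap)
  list(fraction = mean(ov), overlaps = ov)
}

#' Chromosome-shuffled control regions
#'
#' Builds the null region set used for enrichment tests: each peak is
#' relocated to a uniformly random position on its own chromosome, preserving
#' its width. Shuffled regions may overlap each other and the original
#' locations are not excluded. The summit is placed at the relocated
#' interval's centre.
#'
#' @param peaks A peak tibble.
#' @param chrom_sizes Chromosome-sizes tibble covering all peak chromosomes.
#' @param seed Optional integer seed for reproducible placement.
#' @return A peak tibble of the same dimensions; `peak_id`s get a
#'   `"_shuf"` suffix.
#' @export
shuffle_regions <- function(peaks, chrom_sizes, seed = NULL) {
  assert_peaks(peaks)
  assert_chrom_sizes(chrom_sizes)
  lens <- chrom_size_lookup(chrom_sizes)
  missing <- setdiff(unique(peaks$chrom), names(lens))
  if (length(missing) > 0) {
    abort(paste0("Chromosome(s) absent from `chrom_sizes`: ",
                 paste(missing, collapse = ", ")))
  }
  widths <- peaks$end - peaks$start
  if (any(widths > lens[peaks$chrom])) {
    abort("A peak is wider than its chromosome; cannot shuffle.")
  }
  with_optional_seed(seed, {
    # uniform integer start in [0, L - width]
    new_start <- floor(runif(nrow(peaks)) * (lens[peaks$chrom] - widths + 1))
    new_start <- pmin(new_start, lens[peaks$chrom] - widths)  # guard runif()==1
    out <- peaks
    out$start <- unname(new_start)
    out$end <- unname(new_start + widths)
    out$summit <- unname(new_start + floor(widths / 2))
    out$peak_id <- paste0(peaks$peak_id, "_shuf")
    out
  })
}

#' Assign peaks to their nearest gene TSS
#'
#' Links each peak to the gene whose transcription start site is closest to
#' the peak summit on the same chromosome — the standard heuristic for
#' attributing distal enhancer peaks to target genes. Distance is signed:
#' summit minus TSS on the forward strand, negated for minus-strand genes, so
#' negative always means upstream of the gene. Peaks within
#' `proximal_threshold` bp (absolute) are classed `proximal`, the rest
#' `distal`. Ties are broken by smallest absolute distance, then
#' lexicographically smallest `gene_id`.
#'
#' @param peaks A peak tibble.
#' @param tss A TSS tibble (see [read_tss()]).
#' @param proximal_threshold Proximal/distal cut in bp (default 2000).
#' @return A tibble with `peak_id`, `gene_id`, `distance`, `proximity_class`.
#'   Peaks with no same-chromosome TSS get `NA` gene and class `"unassigned"`.
#' @seealso [assigned_genes()] for the deduplicated target-gene list.
#' @export
nearest_tss_assign <- function(peaks, tss, proximal_threshold = 2000) {
  assert_peaks(peaks)
  if (nrow(tss) == 0) abort("`tss` must be non-empty.")
  out <- vector("list", nrow(peaks))
  tss_by_chr <- split(tss, tss$chrom)
  for (i in seq_len(nrow(peaks))) {
    cand <- tss_by_chr[[peaks$chrom[i]]]
    if (is.null(cand) || nrow(cand) == 0) {
      out[[i]] <- tibble(peak_id = peaks$peak_id[i], gene_id = NA_character_,
                         distance = NA_real_, proximity_class = "unassigned")
      next
    }
    d_abs <- abs(peaks$summit[i] - cand$tss)
    best <- which(d_abs == min(d_abs))
    if (length(best) > 1) best <- best[order(cand$gene_id[best])][1]
    signed <- peaks$summit[i] - cand$tss[best]
    if (cand$strand[best] == "-") signed <- -signed
    out[[i]] <- tibble(
      peak_id = peaks$peak_id[i],
      gene_id = cand$gene_id[best],
      distance = signed,
      proximity_class = if (abs(signed) <= proximal_threshold) "proximal" else "distal"
    )
  }
  bind_rows(out)
}

#' Distinct target genes from peak assignments
#'
#' @param assignments Output of [nearest_tss_assign()].
#' @return Sorted character vector of unique assigned gene ids.
#' @export
assigned_genes <- function(assignments) {
  sort(unique(assignments$gene_id[!is.na(assignments$gene_id)]))
}

#' Classify peaks by genomic feature
#'
#' Assigns each peak a single genomic class by summit position with priority
#' promoter > 5'UTR > exon > intron > intergenic, so that class fractions are
#' mutually exclusive. `promoter` records conventionally cover the 2 kb
#' upstream of gene TSSs (see [read_feature_annotation()]).
#'
#' @param peaks A peak tibble.
#' @param annotation Feature annotation tibble (`chrom`, `start`, `end`,
#'   `class`).
#' @return The peak tibble with a `feature_class` column.
#' @seealso [feature_fractions()] for the per-class summary.
#' @export
classify_features <- function(peaks, annotation) {
  assert_peaks(peaks)
  bad <- setdiff(unique(annotation$class), feature_classes)
  if (length(bad) > 0) {
    abort(paste0("Unknown feature class(es): ", paste(bad, collapse = ", ")))
  }
  cls <- rep("intergenic", nrow(peaks))
  summit_iv <- tibble(chrom = peaks$chrom, start = peaks$summit,
                      end = peaks$summit + 1)
  for (fc in rev(feature_classes)) {  # low- to high-priority; later writes win
    ref <- annotation[annotation$class == fc, , drop = FALSE]
    if (nrow(ref) == 0) next
    hit <- interval_overlaps(summit_iv, ref)
    cls[hit] <- fc
  }
  out <- peaks
  out$feature_class <- cls
  out
}

#' Per-class peak fractions
#'
#' @param classified Output of [classify_features()].
#' @return A tibble with `feature_class`, `n`, `fraction` over the fixed class
#'   set (promoter, five_prime_utr, exon, intron, intergenic); fractions sum
#'   to 1.
#' @export
feature_fractions <- function(classified) {
  all_classes <- c(feature_classes, "intergenic")
  counts <- table(factor(classified$feature_class, levels = all_classes))
  tibble(
    feature_class = all_classes,
    n = as.integer(counts),
    fraction = as.integer(counts) / nrow(classified)
  )
}
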