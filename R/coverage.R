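#' Read mapped-read positions from a BED-like table
#'
#' The core coverage functions work from a position table: one row per mapped
#' read with its chromosome, 5' end and strand. BED6 input uses `chromStart`
#' as the 5' end for `+` reads and `chromEnd - 1` for `-` reads.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return A tibble with `chrom`, `five_prime` (0-based), `strand`,
#'   `read_length`.
#' @export
read_reads_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 6) abort("Expected BED6 with a strand column.")
  start <- as.numeric(raw[[2]])
  end <- as.numeric(raw[[3]])
  strand <- raw[[6]]
  if (!all(strand %in% c("+", "-"))) abort("Read strand must be '+' or '-'.")
  tibble(
    chrom = raw[[1]],
    five_prime = ifelse(strand == "+", start, end - 1),
    strand = strand,
    read_length = end - start
  )
}

#' Read mapped-read positions from a SAM file
#'
#' Minimal single-end SAM adapter: parses mapped records' position, strand
#' (FLAG bit 0x10) and sequence length. Header lines and unmapped records
#' (FLAG bit 0x4 or `*` reference) are skipped.
#'
#' @param path SAM text file.
#' @return A tibble as in [read_reads_bed()].
#' @export
read_reads_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), five_prime = numeric(),
                  strand = character(), read_length = numeric()))
  }
  fields <- strsplit(lines, "\t")
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  rname <- vapply(fields, `[`, "", 3)
  pos <- vapply(fields, function(f) as.numeric(f[4]), numeric(1))
  len <- vapply(fields, function(f) nchar(f[10]), numeric(1))
  keep <- bitwAnd(flag, 4L) == 0L & rname != "*"
  minus <- bitwAnd(flag[keep], 16L) != 0L
  start0 <- pos[keep] - 1  # SAM POS is 1-based leftmost
  tibble(
    chrom = rname[keep],
    five_prime = ifelse(minus, start0 + len[keep] - 1, start0),
    strand = ifelse(minus, "-", "+"),
    read_length = len[keep]
  )
}

#' Strand-aware read extension and pileup
#'
#' Extends each read to the average fragment length from its 5' end in the
#' read direction (a `+` read at p covers `[p, p + extension)`; a `-` read
#' covers `(p - extension, p]`) and accumulates a per-base density track
#' normalised to reads per million: each read adds `1e6 / library_size` to
#' every base it covers. Extensions are clipped at chromosome ends and the
#' number of clipped reads is recorded.
#'
#' @param reads Read tibble (see [read_reads_bed()]).
#' @param chrom_sizes Chromosome-sizes tibble.
#' @param extension Fragment extension length in bp (default 150).
#' @param library_size Total mapped reads for normalisation; defaults to
#'   `nrow(reads)`.
#' @return A `density_track`: list with `density` (named list of per-base
#'   numeric vectors), `extension`, `library_size`, `n_reads`, `n_clipped`.
#' @export
extend_and_pile <- function(reads, chrom_sizes, extension = 150,
                            library_size = nrow(reads)) {
  assert_chrom_sizes(chrom_sizes)
  if (library_size <= 0) abort("`library_size` must be positive.")
  if (nrow(reads) > 0 && extension < max(reads$read_length)) {
    abort("`extension` must be at least the read length.")
  }
  missing <- setdiff(unique(reads$chrom), chrom_sizes$chrom)
  if (length(missing) > 0) {
    abort(paste0("Chromosome(s) absent from `chrom_sizes`: ",
                 paste(missing, collapse = ", ")))
  }
  w <- 1e6 / library_size
  lens <- chrom_size_lookup(chrom_sizes)
  density <- lapply(lens, function(L) numeric(L))
  n_clipped <- 0L
  if (nrow(reads) > 0) {
    frag_start <- ifelse(reads$strand == "+", reads$five_prime,
                         reads$five_prime - extension + 1)
    frag_end <- frag_start + extension  # half-open
    for (chr in unique(reads$chrom)) {
      sel <- reads$chrom == chr
      L <- lens[[chr]]
      s <- pmax(frag_start[sel], 0)
      e <- pmin(frag_end[sel], L)
      n_clipped <- n_clipped + sum(frag_start[sel] < 0 | frag_end[sel] > L)
      keep <- s < e
      # difference-array accumulation, then cumulative sum
      diff_vec <- numeric(L + 1)
      add_s <- tabulate(s[keep] + 1, nbins = L + 1)
      add_e <- tabulate(e[keep] + 1, nbins = L + 1)
      diff_vec <- (add_s - add_e) * w
      density[[chr]] <- cumsum(diff_vec)[seq_len(L)]
    }
  }
  if (n_clipped > 0) warn(paste0(n_clipped, " read extension(s) clipped at chromosome ends."))
  structure(
    list(density = density, extension = extension, library_size = library_size,
         n_reads = nrow(reads), n_clipped = n_clipped),
    class = "density_track"
  )
}

#' @export
print.density_track <- function(x, ...) {
  cat("<density_track> ", x$n_reads, " reads extended to ", x$extension,
      " bp over ", length(x$density), " chromosome(s); reads-per-million ",
      "normalisation (library size ", x$library_size, ")\n", sep = "")
  invisible(x)
}

#' Mean density per region
#'
#' Arithmetic mean of the per-base density over each region's bases — the
#' per-region statistic used for between-sample correlation.
#'
#' @param track A `density_track` from [extend_and_pile()].
#' @param regions A peak tibble.
#' @return A tibble with `peak_id`, `mean_density`, ordered as `regions`.
#' @export
region_mean_density <- function(track, regions) {
  assert_peaks(regions)
  missing <- setdiff(unique(regions$chrom), names(track$density))
  if (length(missing) > 0) {
    abort(paste0("Chromosome(s) absent from track: ",
                 paste(missing, collapse = ", ")))
  }
  md <- vapply(seq_len(nrow(regions)), function(i) {
    v <- track$density[[regions$chrom[i]]]
    mean(v[(regions$start[i] + 1):regions$end[i]])
  }, numeric(1))
  tibble(peak_id = regions$peak_id, mean_density = md)
}

#' Pearson correlation between two samples' region densities
#'
#' @param a,b Numeric vectors of per-region mean densities on the same region
#'   set (e.g. `mean_density` columns from [region_mean_density()]).
#' @return The Pearson product-moment correlation coefficient.
#' @export
sample_correlation <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 3) abort("Need at least 3 regions for a correlation.")
  if (var(a) == 0 || var(b) == 0) abort("Zero variance: correlation undefined.")
  cor(a, b, method = "pearson")
}

#' Summit-centred meta-profile
#'
#' Mean density at each offset in `-flank..flank` relative to peak summits,
#' averaged over all peaks; the aggregate "ChIP enrichment centred on peak
#' summit" view. Offsets falling outside a chromosome are excluded from that
#' peak's contribution.
#'
#' @param track A `density_track`.
#' @param peaks A peak tibble.
#' @param flank Flank in bp (default 1000).
#' @return A `meta_profile` tibble with `offset`, `mean_density`, `n`.
#' @export
metaprofile <- function(track, peaks, flank = 1000) {
  assert_peaks(peaks)
  if (flank <= 0) abort("`flank` must be positive.")
  offsets <- -flank:flank
  total <- numeric(length(offsets))
  n_cov <- integer(length(offsets))
  for (i in seq_len(nrow(peaks))) {
    v <- track$density[[peaks$chrom[i]]]
    if (is.null(v)) next
    pos <- peaks$summit[i] + offsets  # 0-based positions
    ok <- pos >= 0 & pos < length(v)
    total[ok] <- total[ok] + v[pos[ok] + 1]
    n_cov <- n_cov + ok
  }
  new_grammar_tbl(
    tibble(offset = offsets,
           mean_density = ifelse(n_cov > 0, total / pmax(n_cov, 1), 0),
           n = n_cov),
    "meta_profile",
    n_regions = nrow(peaks)
  )
}

#' Write a density track as bedGraph
#'
#' Runs of equal density are merged into intervals; zero-density runs are
#' omitted.
#'
#' @param track A `density_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$density)) {
    v <- track$density[[chr]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(chr, starts[keep], ends[keep], signif(r$values[keep], 8),
                     sep = "\t"), con)
  }
  invisible(path)
}
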