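#' Read a peak table
#'
#' Reads ChIP-seq peak calls into the tidy peak representation used across the
#' package: one row per peak with columns `chrom`, `start`, `end` (0-based,
#' half-open), `peak_id`, `summit` (absolute 0-based position), `score`, and
#' `sample`.
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`"summit_table"`}{Tab-separated `chrom, start, end, name, summit,
#'     score` with 0-based half-open coordinates and a 0-based summit.}
#'   \item{`"peakzilla"`}{The same six columns but 1-based inclusive, as
#'     emitted by the peakzilla caller; coordinates and summits are shifted to
#'     the internal 0-based convention on read.}
#'   \item{`"bed"`}{BED with at least 3 columns (name and score optional);
#'     the summit is set to the interval midpoint since BED carries none.}
#' }
#'
#' @param path Path to a tab-separated peak file (no header).
#' @param dialect One of `"summit_table"`, `"peakzilla"`, `"bed"`.
#' @param sample Sample label attached to every peak (e.g. `"YAP1_SF268"`).
#' @return A tibble of peaks; input row order is preserved.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("chr1\t100\t300\tpk1\t200\t5", tf)
#' read_peaks(tf, sample = "demo")
#' @export
read_peaks <- function(path, dialect = c("summit_table", "peakzilla", "bed"),
                       sample = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("Peak file not found: ", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#",
                           colClasses = "character", quote = "")
  need <- if (dialect == "bed") 3L else 6L
  if (ncol(raw) < need) {
    abort(paste0("Expected at least ", need, " columns for dialect '",
                 dialect, "', found ", ncol(raw), "."))
  }
  parse_int <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(paste0("Malformed ", what, " at line ", bad[1], ": '", x[bad[1]], "'"))
    }
    v
  }
  if (dialect == "bed") {
    start <- parse_int(raw[[2]], "start")
    end <- parse_int(raw[[3]], "end")
    peaks <- tibble(
      chrom = raw[[1]], start = start, end = end,
      peak_id = if (ncol(raw) >= 4) raw[[4]] else paste0("peak_", seq_len(nrow(raw))),
      summit = floor((start + end) / 2),
      score = if (ncol(raw) >= 5) parse_int(raw[[5]], "score") else 0,
      sample = sample
    )
  } else {
    off <- if (dialect == "peakzilla") 1L else 0L
    peaks <- tibble(
      chrom = raw[[1]],
      start = parse_int(raw[[2]], "start") - off,
      end = parse_int(raw[[3]], "end"),    # 1-based inclusive end == 0-based exclusive
      peak_id = raw[[4]],
      summit = parse_int(raw[[5]], "summit") - off,
      score = parse_int(raw[[6]], "score"),
      sample = sample
    )
  }
  assert_peaks(peaks)
  peaks
}

#' Write peaks as a summit table
#'
#' Inverse of [read_peaks()] for the `"summit_table"` dialect; a subsequent
#' read reproduces the records exactly.
#'
#' @param peaks A peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  assert_peaks(peaks)
  utils::write.table(
    peaks[, peak_cols],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read chromosome sizes
#'
#' @param path Two-column tab-separated file: chromosome name, length in bp.
#' @return A tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric"))
  sizes <- tibble(chrom = raw[[1]], size = raw[[2]])
  assert_chrom_sizes(sizes)
  sizes
}

#' Read transcription start sites
#'
#' @param path Tab-separated file with columns gene_id, chrom, tss, strand
#'   (no header). The TSS position is taken as given (0-based).
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "character", "numeric", "character"))
  tss <- tibble(gene_id = raw[[1]], chrom = raw[[2]], tss = raw[[3]], strand = raw[[4]])
  if (!all(tss$strand %in% c("+", "-"))) abort("TSS strand must be '+' or '-'.")
  tss
}

feature_classes <- c("promoter", "five_prime_utr", "exon", "intron")

#' Read a genomic feature annotation
#'
#' Loads interval/class pairs used by [classify_features()]. The native format
#' is a four-column TSV (`chrom`, `start`, `end`, `class` with 0-based
#' half-open intervals); a GTF subset can be read through rtracklayer, mapping
#' `five_prime_utr`/`exon`/`intron` feature types directly and deriving
#' `promoter` records from the 2 kb upstream of `transcript` (or `gene`)
#' features.
#'
#' @param path Annotation file.
#' @param format `"tsv"` or `"gtf"`.
#' @param promoter_width Width in bp of the upstream promoter window derived
#'   from GTF transcripts (default 2000).
#' @return A tibble with columns `chrom`, `start`, `end`, `class`.
#' @export
read_feature_annotation <- function(path, format = c("tsv", "gtf"),
                                    promoter_width = 2000) {
  format <- match.arg(format)
  if (format == "tsv") {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = c("character", "numeric", "numeric", "character"))
    ann <- tibble(chrom = raw[[1]], start = raw[[2]], end = raw[[3]], class = raw[[4]])
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("Reading GTF annotations requires the rtracklayer package.")
    }
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    feat <- tibble(chrom = as.character(df$seqnames),
                   start = df$start - 1, end = df$end,
                   strand = as.character(df$strand), type = as.character(df$type))
    direct <- feat |>
      filter(.data$type %in% feature_classes) |>
      select("chrom", "start", "end", class = "type")
    tx <- feat |> filter(.data$type %in% c("transcript", "gene"))
    prom <- tibble(
      chrom = tx$chrom,
      start = ifelse(tx$strand == "-", tx$end, pmax(0, tx$start - promoter_width)),
      end = ifelse(tx$strand == "-", tx$end + promoter_width, tx$start),
      class = "promoter"
    ) |> filter(.data$start < .data$end)
    ann <- bind_rows(prom, direct)
  }
  bad <- setdiff(unique(ann$class), feature_classes)
  if (length(bad) > 0) {
    abort(paste0("Unknown feature class(es): ", paste(bad, collapse = ", ")))
  }
  if (any(ann$start >= ann$end)) abort("Invalid annotation interval (start >= end).")
  ann
}
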