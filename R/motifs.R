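#' Reverse complement of a DNA string
#'
#' @param x Character vector of sequences over A, C, G, T, N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

assert_dna <- function(sequence) {
  if (length(sequence) != 1 || !is.character(sequence)) {
    abort("`sequence` must be a single string.")
  }
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) {
    abort("Sequence contains characters outside {A, C, G, T, N}.")
  }
  s
}

# Mismatch counts of `consensus` against every offset of `seq_str`
# (both plain uppercase strings); returns integer vector over 0-based offsets.
mismatch_counts <- function(seq_str, consensus) {
  k <- nchar(consensus)
  L <- nchar(seq_str)
  n_off <- L - k + 1
  if (n_off <= 0) return(integer(0))
  offs <- seq_len(n_off)  # 1-based start positions
  mism <- integer(n_off)
  cons <- strsplit(consensus, "")[[1]]
  for (j in seq_len(k)) {
    mism <- mism + (substring(seq_str, offs + j - 1, offs + j - 1) != cons[j])
  }
  mism
}

#' Scan a sequence for a consensus motif with mismatches
#'
#' Finds all occurrences of a short consensus (default `CATTCC`, the TEAD
#' binding motif) on both strands, tolerating up to `max_mismatch`
#' substitutions. A minus-strand match means the reverse complement of the
#' consensus (`GGAATG` for TEAD) occurs at that offset of the given sequence.
#' `N` bases never match any consensus base. A site matching on both strands
#' yields two rows.
#'
#' @param sequence A single DNA string (A/C/G/T/N, case-insensitive).
#' @param consensus Consensus motif, length >= 4, over A/C/G/T.
#' @param max_mismatch Maximum substitutions allowed (default 1); must be
#'   smaller than the consensus length.
#' @return A tibble with `offset` (0-based match start within `sequence`),
#'   `strand` (`"+"`/`"-"`), `n_mismatch`, sorted by offset then strand.
#' @examples
#' scan_consensus("TTCATTCCAA", max_mismatch = 0)
#' scan_consensus("GGAATGTT", max_mismatch = 0)  # minus-strand hit
#' @export
scan_consensus <- function(sequence, consensus = "CATTCC", max_mismatch = 1) {
  s <- assert_dna(sequence)
  consensus <- toupper(consensus)
  if (nchar(consensus) < 4 || grepl("[^ACGT]", consensus)) {
    abort("`consensus` must be a string of length >= 4 over A/C/G/T.")
  }
  if (max_mismatch < 0 || max_mismatch >= nchar(consensus)) {
    abort("`max_mismatch` must satisfy 0 <= max_mismatch < nchar(consensus).")
  }
  fwd <- mismatch_counts(s, consensus)
  rev_ <- mismatch_counts(s, revcomp(consensus))
  hits_f <- which(fwd <= max_mismatch)
  hits_r <- which(rev_ <= max_mismatch)
  out <- tibble(
    offset = c(hits_f, hits_r) - 1L,
    strand = c(rep("+", length(hits_f)), rep("-", length(hits_r))),
    n_mismatch = c(fwd[hits_f], rev_[hits_r])
  )
  out[order(out$offset, out$strand), ]
}

#' Same-orientation motif pairs within a region
#'
#' Enumerates all ordered pairs of motif matches on the same strand whose
#' spacer — the gap in bp between the end of the first occurrence and the
#' start of the second, in plus-strand coordinates — lies in
#' `[0, max_spacer]`. Overlapping occurrences (negative gap) never pair, and
#' opposite-strand matches are excluded: the homotypic "double motif" of
#' interest is two sites in the same orientation. All qualifying pairs are
#' reported, not only adjacent ones.
#'
#' @param matches Match tibble from [scan_consensus()].
#' @param motif_len Motif length in bp.
#' @param max_spacer Maximum spacer in bp (default 30).
#' @return A tibble with `first_offset`, `second_offset`, `strand`, `spacer`.
#' @export
find_motif_pairs <- function(matches, motif_len, max_spacer = 30) {
  if (max_spacer < 0) abort("`max_spacer` must be >= 0.")
  empty <- tibble(first_offset = integer(), second_offset = integer(),
                  strand = character(), spacer = integer())
  if (nrow(matches) < 2) return(empty)
  m <- matches[order(matches$offset), ]
  idx <- which(outer(m$offset, m$offset, function(a, b) b - (a + motif_len)) >= 0 &
                 outer(m$offset, m$offset, function(a, b) b - (a + motif_len)) <= max_spacer &
                 outer(m$strand, m$strand, "=="),
               arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  out <- tibble(
    first_offset = m$offset[idx[, 1]],
    second_offset = m$offset[idx[, 2]],
    strand = m$strand[idx[, 1]],
    spacer = m$offset[idx[, 2]] - (m$offset[idx[, 1]] + motif_len)
  )
  out[order(out$first_offset, out$second_offset, out$strand), ]
}

#' Spacer spectrum of double motifs across regions
#'
#' For each spacer length 0..`max_spacer`, counts how many regions contain at
#' least one same-orientation double motif with exactly that spacer. A region
#' can count toward several spacer values. This is the observable behind the
#' "double motif with a 3 bp spacer" signal at TEAD-bound sites.
#'
#' @param regions Character vector of region sequences (e.g. 151 bp summit
#'   windows).
#' @param consensus,max_mismatch Consensus query, as in [scan_consensus()].
#' @param max_spacer Maximum spacer length surveyed (default 30).
#' @return A `spacer_spectrum` tibble with `spacer` (0..max_spacer) and
#'   `n_regions_with_pair`; the total region count is in
#'   `attr(, "n_regions")`.
#' @export
spacer_spectrum <- function(regions, consensus = "CATTCC", max_mismatch = 1,
                            max_spacer = 30) {
  if (max_spacer < 0) abort("`max_spacer` must be >= 0.")
  k <- nchar(consensus)
  counts <- integer(max_spacer + 1)
  for (s in regions) {
    m <- scan_consensus(s, consensus, max_mismatch)
    pr <- find_motif_pairs(m, k, max_spacer)
    if (nrow(pr) > 0) {
      sp <- unique(pr$spacer)
      counts[sp + 1] <- counts[sp + 1] + 1L
    }
  }
  new_grammar_tbl(
    tibble(spacer = 0:max_spacer, n_regions_with_pair = counts),
    "spacer_spectrum",
    n_regions = length(regions)
  )
}

#' Extract summit-window sequences from a genome
#'
#' @param peaks A peak tibble.
#' @param genome Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param width Odd window width in bp (default 151); windows are clipped at
#'   chromosome ends.
#' @return Character vector of uppercase window sequences, named by peak id.
#' @export
peak_window_sequences <- function(peaks, genome, width = 151) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing) > 0) {
    abort(paste0("Chromosome(s) absent from genome: ",
                 paste(missing, collapse = ", ")))
  }
  sizes <- tibble(chrom = names(genome), size = nchar(genome))
  win <- summit_window(peaks, width = width, chrom_sizes = sizes)
  seqs <- toupper(substring(genome[win$chrom], win$start + 1, win$end))
  setNames(seqs, peaks$peak_id)
}

#' Read a FASTA file
#'
#' @param path FASTA file (multi-record, line wrapping allowed).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  setNames(toupper(as.character(x)), nm)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
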