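# Small in-code fixtures shared across test files.

toy_peaks <- function(chrom = "chr1", starts = c(100, 500), width = 100,
                      sample = "toy") {
  tibble::tibble(
    chrom = chrom, start = starts, end = starts + width,
    peak_id = paste0("pk", seq_along(starts)),
    summit = starts + floor(width / 2),
    score = seq_along(starts),
    sample = sample
  )
}

toy_sizes <- function(chrom = "chr1", size = 1e4) {
  tibble::tibble(chrom = chrom, size = size)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Independent naive scanner: exact substring occurrences of the consensus
# and its reverse complement, via fixed-string matching.
naive_exact_scan <- function(seq, consensus) {
  rc <- peakgrammar::revcomp(consensus)
  find_all <- function(pat) {
    hits <- integer(0)
    from <- 1
    repeat {
      i <- regexpr(pat, substring(seq, from), fixed = TRUE)
      if (i == -1) break
      hits <- c(hits, from + i - 2)  # 0-based offset
      from <- from + i
    }
    hits
  }
  f <- find_all(consensus)
  r <- find_all(rc)
  out <- data.frame(
    offset = c(f, r),
    strand = c(rep("+", length(f)), rep("-", length(r))),
    stringsAsFactors = FALSE
  )
  out[order(out$offset, out$strand), , drop = FALSE]
}

# Exhaustive all-pairs double-motif oracle on one sequence.
naive_pair_spacers <- function(seq, consensus, max_mismatch, max_spacer) {
  m <- peakgrammar::scan_consensus(seq, consensus, max_mismatch)
  k <- nchar(consensus)
  sp <- integer(0)
  if (nrow(m) >= 2) {
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(nrow(m))) {
        gap <- m$offset[j] - (m$offset[i] + k)
        if (m$strand[i] == m$strand[j] && gap >= 0 && gap <= max_spacer) {
          sp <- c(sp, gap)
        }
      }
    }
  }
  sort(unique(sp))
}

# Exact upper-tail hypergeometric by direct enumeration over the support.
enum_hypergeom_upper <- function(x, n, X, N) {
  supp <- max(0, n - (N - X)):min(n, X)
  probs <- choose(X, supp) * choose(N - X, n - supp) / choose(N, n)
  sum(probs[supp >= x])
}
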