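#' Default synthetic chromosome sizes
#'
#' Two 10-Mb chromosomes: large enough that 2,500 non-overlapping 151-bp
#' windows occupy under 2% of the genome, so chromosome-shuffled control
#' regions rarely strike a planted peak window.
#'
#' @return A chromosome-sizes tibble.
#' @export
default_sim_chrom_sizes <- function() {
  tibble(chrom = c("chr1", "chr2"), size = c(1e7, 1e7))
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# P(a consensus of length k matches at one offset, either strand) under
# i.i.d. background with the given GC content.
offset_match_prob <- function(consensus, gc) {
  p <- base_probs(gc)
  hit <- function(m) prod(p[strsplit(m, "")[[1]]])
  hit(consensus) + hit(revcomp(consensus))
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = base_probs(gc))
}

#' Synthetic genome with motif-planted peaks
#'
#' Generates chromosome sequences of i.i.d. background bases, places
#' non-overlapping summit-centred peak windows, and plants consensus motifs
#' into them at controlled rates: with probability `double_rate` a peak
#' receives a same-orientation double motif (spacer drawn from
#' `spacer_dist`), otherwise with total probability `single_rate` at least
#' one single motif, so the marginal planted-single rate is exactly
#' `single_rate` and the planted-double rate exactly `double_rate`. Outside
#' peak windows, motifs are scattered at a density calibrated so that a
#' random window matches the consensus (0 mismatches) with probability
#' `background_hit_rate` — the control-region hit rate a chromosome shuffle
#' should recover. A ground-truth ledger records what was planted where.
#'
#' Motif bases are written after the background, so planted motifs are never
#' mutated; the background can still create incidental matches, which the
#' ledger lets callers separate from planted ones.
#'
#' @param chrom_sizes Chromosome-sizes tibble (default
#'   [default_sim_chrom_sizes()]).
#' @param n_peaks Number of peaks (default 2500).
#' @param peak_width Odd peak-window width in bp (default 151).
#' @param single_rate Fraction of peaks with >= 1 planted motif
#'   (default 0.86).
#' @param double_rate Fraction with a planted same-orientation pair (default
#'   0.18; must not exceed `single_rate`).
#' @param spacer_dist Named numeric vector: spacer length -> probability
#'   (default all mass on 3).
#' @param strand_prob Probability a planted motif (or pair) is on the minus
#'   strand (default 0.5).
#' @param background_hit_rate Target exact-match hit rate of a random window
#'   (default 0.37); set to 0 to plant no background motifs.
#' @param gc Background GC content (default 0.5, i.e. uniform bases).
#' @param consensus Motif to plant (default `CATTCC`).
#' @param seed Integer seed; the generator is a pure function of seed and
#'   configuration.
#' @return A list: `genome` (named character vector), `peaks` (peak tibble
#'   whose intervals are the summit windows), `ledger` (per-peak tibble:
#'   `peak_id`, `planted` in none/single/double, `strand`, `offset1`,
#'   `offset2`, `spacer` — offsets are 0-based within the window), and
#'   `background_motifs` (tibble of genome-wide planted background motif
#'   positions).
#' @export
gen_genome_with_peaks <- function(chrom_sizes = default_sim_chrom_sizes(),
                                  n_peaks = 2500, peak_width = 151,
                                  single_rate = 0.86, double_rate = 0.18,
                                  spacer_dist = c("3" = 1), strand_prob = 0.5,
                                  background_hit_rate = 0.37, gc = 0.5,
                                  consensus = "CATTCC", seed = NULL) {
  assert_chrom_sizes(chrom_sizes)
  if (peak_width %% 2 == 0) abort("`peak_width` must be odd.")
  if (double_rate > single_rate) {
    abort("`double_rate` cannot exceed `single_rate` (a double contains a single).")
  }
  if (abs(sum(spacer_dist) - 1) > 1e-9) abort("`spacer_dist` must sum to 1.")
  spacers <- as.integer(names(spacer_dist))
  k <- nchar(consensus)
  if (peak_width < 2 * k + max(spacers)) {
    abort("`peak_width` too small for the largest planted double motif.")
  }
  rc <- revcomp(consensus)
  n_off <- peak_width - k + 1

  with_optional_seed(seed, {
    # allocate peaks to chromosomes proportionally to length
    n_per <- floor(n_peaks * chrom_sizes$size / sum(chrom_sizes$size))
    rem <- n_peaks - sum(n_per)
    if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1
    if (any(n_per * peak_width > chrom_sizes$size)) {
      abort("Peaks do not fit their chromosomes; infeasible packing.")
    }

    chroms <- character(0); starts <- numeric(0)
    genome_chars <- list()
    for (ci in seq_len(nrow(chrom_sizes))) {
      L <- chrom_sizes$size[ci]
      n_c <- n_per[ci]
      s <- sort(floor(runif(n_c) * (L - peak_width + 1)))
      for (iter in seq_len(1000)) {
        bad <- which(diff(s) < peak_width)
        if (length(bad) == 0) break
        s[bad + 1] <- floor(runif(length(bad)) * (L - peak_width + 1))
        s <- sort(s)
      }
      if (any(diff(s) < peak_width)) {
        abort("Could not place non-overlapping peaks; infeasible packing.")
      }
      chroms <- c(chroms, rep(chrom_sizes$chrom[ci], n_c))
      starts <- c(starts, s)
      genome_chars[[chrom_sizes$chrom[ci]]] <- random_bases(L, gc)
    }

    peaks <- tibble(
      chrom = chroms, start = starts, end = starts + peak_width,
      peak_id = sprintf("simpeak_%04d", seq_len(n_peaks)),
      summit = starts + (peak_width - 1) / 2,
      score = 1, sample = "synthetic"
    )

    write_motif <- function(chr, pos0, minus) {
      m <- if (minus) rc else consensus
      genome_chars[[chr]][(pos0 + 1):(pos0 + k)] <<- strsplit(m, "")[[1]]
    }

    # plant peak motifs
    u <- runif(n_peaks)
    planted <- ifelse(u < double_rate, "double",
                      ifelse(u < single_rate, "single", "none"))
    minus <- runif(n_peaks) < strand_prob
    offset1 <- rep(NA_integer_, n_peaks)
    offset2 <- rep(NA_integer_, n_peaks)
    spacer <- rep(NA_integer_, n_peaks)
    for (i in seq_len(n_peaks)) {
      if (planted[i] == "none") next
      if (planted[i] == "double") {
        sp <- if (length(spacers) == 1) spacers else {
          sample(spacers, 1, prob = spacer_dist)
        }
        span <- 2 * k + sp
        o1 <- sample.int(peak_width - span + 1, 1) - 1L
        o2 <- o1 + k + sp
        write_motif(peaks$chrom[i], peaks$start[i] + o1, minus[i])
        write_motif(peaks$chrom[i], peaks$start[i] + o2, minus[i])
        offset1[i] <- o1; offset2[i] <- o2; spacer[i] <- sp
      } else {
        o1 <- sample.int(peak_width - k + 1, 1) - 1L
        write_motif(peaks$chrom[i], peaks$start[i] + o1, minus[i])
        offset1[i] <- o1
      }
    }

    # background motifs outside peak windows, calibrated to the target
    # exact-match window hit rate
    bg <- tibble(chrom = character(), pos = numeric(), strand = character())
    if (background_hit_rate > 0) {
      p_inc <- 1 - (1 - offset_match_prob(consensus, gc))^n_off
      if (background_hit_rate <= p_inc) {
        abort("`background_hit_rate` is below the incidental match rate; lower `gc` bias or raise the target.")
      }
      dens <- -log((1 - background_hit_rate) / (1 - p_inc)) / n_off
      for (ci in seq_len(nrow(chrom_sizes))) {
        chr <- chrom_sizes$chrom[ci]
        L <- chrom_sizes$size[ci]
        n_bg <- stats::rpois(1, dens * L)
        pos <- floor(runif(n_bg) * (L - k + 1))
        pk <- peaks[peaks$chrom == chr, ]
        # drop background motifs whose bases intrude into any peak window
        inside <- interval_overlaps(
          tibble(chrom = chr, start = pos, end = pos + k),
          tibble(chrom = chr, start = pk$start, end = pk$end)
        )
        pos <- pos[!inside]
        bg_minus <- runif(length(pos)) < 0.5
        for (j in seq_along(pos)) write_motif(chr, pos[j], bg_minus[j])
        bg <- bind_rows(bg, tibble(chrom = chr, pos = pos,
                                   strand = ifelse(bg_minus, "-", "+")))
      }
    }

    genome <- vapply(genome_chars, paste, character(1), collapse = "")
    ledger <- tibble(
      peak_id = peaks$peak_id, planted = planted,
      strand = ifelse(planted == "none", NA_character_,
                      ifelse(minus, "-", "+")),
      offset1 = offset1, offset2 = offset2, spacer = spacer
    )
    list(genome = genome, peaks = peaks, ledger = ledger,
         background_motifs = bg)
  })
}

#' Synthetic summit-enriched reads
#'
#' Draws single-end read positions from a mixture of a uniform genomic
#' background and summit-centred fragments, strand-balanced. The mixture
#' weight is solved so that the expected within-peak read density is
#' `enrichment`-fold the background density; `enrichment = 1` gives a flat
#' library.
#'
#' @param peaks A peak tibble.
#' @param chrom_sizes Chromosome-sizes tibble.
#' @param enrichment Fold read-density enrichment at peaks over background
#'   (default 50).
#' @param n_reads Number of reads (default 1e5).
#' @param read_length Read length in bp (default 50).
#' @param fragment_length Fragment length emulated by the summit component
#'   (default 150); fragment midpoints scatter around the summit with SD
#'   `summit_sd`.
#' @param summit_sd SD in bp of fragment midpoints around the summit
#'   (default 50).
#' @param seed Integer seed.
#' @return A read tibble (`chrom`, `five_prime`, `strand`, `read_length`)
#'   suitable for [extend_and_pile()].
#' @export
gen_reads <- function(peaks, chrom_sizes, enrichment = 50, n_reads = 1e5,
                      read_length = 50, fragment_length = 150,
                      summit_sd = 50, seed = NULL) {
  assert_peaks(peaks)
  assert_chrom_sizes(chrom_sizes)
  if (enrichment < 1) abort("`enrichment` must be >= 1.")
  if (n_reads == 0) {
    return(tibble(chrom = character(), five_prime = numeric(),
                  strand = character(), read_length = numeric()))
  }
  G <- sum(chrom_sizes$size)
  peak_bp <- sum(peaks$end - peaks$start)
  cc <- (enrichment - 1) * peak_bp / G
  f_peak <- cc / (1 + cc)
  lens <- chrom_size_lookup(chrom_sizes)
  with_optional_seed(seed, {
    at_peak <- runif(n_reads) < f_peak
    n_p <- sum(at_peak); n_b <- n_reads - n_p
    # background: chromosome proportional to length, position uniform
    bchr <- sample(chrom_sizes$chrom, n_b, replace = TRUE,
                   prob = chrom_sizes$size)
    bmid <- floor(runif(n_b) * lens[bchr])
    # peak component: fragment midpoints around a uniformly chosen summit
    pidx <- sample.int(nrow(peaks), n_p, replace = TRUE)
    pchr <- peaks$chrom[pidx]
    pmid <- round(peaks$summit[pidx] + rnorm(n_p, 0, summit_sd))
    chrom <- c(bchr, pchr)
    mid <- pmin(pmax(c(bmid, pmid), 0), lens[chrom] - 1)
    minus <- runif(n_reads) < 0.5
    five_prime <- ifelse(minus, mid + floor(fragment_length / 2),
                         mid - floor(fragment_length / 2))
    five_prime <- pmin(pmax(five_prime, 0), lens[chrom] - 1)
    tibble(chrom = chrom, five_prime = unname(five_prime),
           strand = ifelse(minus, "-", "+"),
           read_length = read_length)[sample.int(n_reads), ]
  })
}

#' Synthetic two-class expression matrix
#'
#' Simulates an FPKM-like genes-by-samples matrix with a planted signature:
#' per-gene baselines are drawn on the log2 scale, signature genes are
#' shifted between the two classes by `effect_size` standard deviations of
#' the per-gene noise, and values are returned on the linear scale
#' (`2^x - 1`, nonnegative) so that the classifier's `log2(x + 1)` transform
#' recovers exactly Gaussian class-conditionals.
#'
#' @param n_genes Number of genes (default 500).
#' @param n_samples Number of samples (default 150).
#' @param signature_size Number of shifted signature genes (default 10).
#' @param effect_size Class mean shift in units of `noise_sd` (default 1).
#' @param noise_sd Per-gene SD on the log2 scale (default 1).
#' @param class_fraction Fraction of samples in the "high" class
#'   (default 0.5).
#' @param seed Integer seed.
#' @return A list: `expr` (genes x samples matrix, linear scale), `labels`
#'   (tibble `sample`, `label`), `signature_genes` (character vector).
#' @export
gen_expression <- function(n_genes = 500, n_samples = 150,
                           signature_size = 10, effect_size = 1,
                           noise_sd = 1, class_fraction = 0.5, seed = NULL) {
  if (signature_size > n_genes) abort("`signature_size` exceeds `n_genes`.")
  if (class_fraction <= 0 || class_fraction >= 1) {
    abort("`class_fraction` must lie in (0, 1).")
  }
  with_optional_seed(seed, {
    samples <- sprintf("S%03d", seq_len(n_samples))
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    n_high <- max(1, round(class_fraction * n_samples))
    label <- rep("low", n_samples)
    label[sample.int(n_samples, n_high)] <- "high"
    base <- rnorm(n_genes, mean = 5, sd = 2)
    x <- matrix(rnorm(n_genes * n_samples, 0, noise_sd), n_genes, n_samples) + base
    sig <- sample(genes, signature_size)
    shift <- effect_size * noise_sd
    x[match(sig, genes), label == "high"] <-
      x[match(sig, genes), label == "high"] + shift
    expr <- pmax(2^x - 1, 0)
    dimnames(expr) <- list(genes, samples)
    list(expr = expr,
         labels = tibble(sample = samples, label = label),
         signature_genes = sort(sig))
  })
}
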