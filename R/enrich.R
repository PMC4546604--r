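#' Upper-tail hypergeometric probability
#'
#' Exact probability of drawing at least `x` successes in a sample of size
#' `n` from a population of `N` items of which `X` are successes — the test
#' used throughout for enrichment of observed regions over shuffled controls
#' and of gene sets over a gene universe. Computed via the exact, log-stable
#' hypergeometric tail, so values far below double underflow of individual
#' terms (e.g. 1e-288) are still meaningful.
#'
#' @param x Observed successes in the drawn set.
#' @param n Size of the drawn set.
#' @param X Total successes in the population.
#' @param N Population size.
#' @param log10_p Return log10 of the tail probability instead.
#' @return `P(H >= x)` for `H ~ Hypergeometric(N, X, n)`.
#' @examples
#' hypergeom_upper_tail(4, n = 5, X = 4, N = 10)  # 6/252
#' @export
hypergeom_upper_tail <- function(x, n, X, N, log10_p = FALSE) {
  if (any(c(x, n, X, N) < 0) || n > N || X > N || x > n) {
    abort("Inconsistent hypergeometric counts: need 0 <= x <= n <= N and X <= N.")
  }
  if (log10_p) {
    phyper(x - 1, X, N - X, n, lower.tail = FALSE, log.p = TRUE) / log(10)
  } else {
    phyper(x - 1, X, N - X, n, lower.tail = FALSE)
  }
}

enrichment_row <- function(n_obs, x_obs, n_ctrl, x_ctrl) {
  if (x_obs > n_obs || x_ctrl > n_ctrl) abort("Hit counts exceed region counts.")
  fold <- if (x_ctrl == 0) {
    if (x_obs == 0) 1 else NA_real_  # undefined when control has no hits
  } else {
    (x_obs / n_obs) / (x_ctrl / n_ctrl)
  }
  tibble(
    n_obs = n_obs, x_obs = x_obs, n_ctrl = n_ctrl, x_ctrl = x_ctrl,
    fold = fold,
    p_value = hypergeom_upper_tail(x_obs, n = n_obs, X = x_obs + x_ctrl,
                                   N = n_obs + n_ctrl),
    log10_p = hypergeom_upper_tail(x_obs, n = n_obs, X = x_obs + x_ctrl,
                                   N = n_obs + n_ctrl, log10_p = TRUE)
  )
}

#' Motif enrichment of peaks over shuffled control regions
#'
#' Measures the fraction of summit windows containing at least one consensus
#' match and compares it with the same statistic on chromosome-shuffled
#' control regions, via the upper-tail hypergeometric test (population =
#' observed plus control regions; successes = all hit regions; draw = the
#' observed set).
#'
#' @param peaks A peak tibble.
#' @param genome Named character vector of chromosome sequences (or
#'   `DNAStringSet`).
#' @param consensus,max_mismatch Consensus query (see [scan_consensus()]).
#' @param window Summit window width in bp (default 151); use `NA` to scan
#'   full peak bounds instead.
#' @param seed Integer seed for the shuffle.
#' @param n_shuffles Number of pooled shuffled control sets (default 1).
#' @return A one-row tibble: `n_obs`, `x_obs`, `n_ctrl`, `x_ctrl`, `fold`,
#'   `p_value`, `log10_p`.
#' @export
motif_enrichment <- function(peaks, genome, consensus = "CATTCC",
                             max_mismatch = 1, window = 151,
                             seed = NULL, n_shuffles = 1) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  sizes <- tibble(chrom = names(genome), size = nchar(genome))
  hit_fraction_n <- function(pk) {
    seqs <- if (is.na(window)) {
      toupper(substring(genome[pk$chrom], pk$start + 1, pk$end))
    } else {
      peak_window_sequences(pk, genome, width = window)
    }
    sum(vapply(seqs, function(s) {
      nrow(scan_consensus(s, consensus, max_mismatch)) > 0
    }, logical(1)))
  }
  x_obs <- hit_fraction_n(peaks)
  seeds <- if (is.null(seed)) rep(list(NULL), n_shuffles) else as.list(seed + seq_len(n_shuffles) - 1)
  x_ctrl <- 0L
  for (s in seeds) {
    ctrl <- shuffle_regions(peaks, sizes, seed = s)
    x_ctrl <- x_ctrl + hit_fraction_n(ctrl)
  }
  enrichment_row(nrow(peaks), x_obs, nrow(peaks) * n_shuffles, x_ctrl)
}

#' Spacer-spectrum enrichment
#'
#' Per spacer length, tests the observed double-motif region counts (a) against
#' a control spectrum from shuffled regions, and (b) against the pooled
#' (region, spacer) hits over all other spacer lengths within the observed
#' set — the two comparisons behind "enriched vs. control and vs. other
#' spacer lengths".
#'
#' @param obs,ctrl `spacer_spectrum` objects over identical spacer domains
#'   (see [spacer_spectrum()]).
#' @return A tibble with one row per spacer: counts, `fold_vs_ctrl`,
#'   `p_vs_ctrl`, `log10_p_vs_ctrl`, `fold_vs_other`, `p_vs_other`,
#'   `log10_p_vs_other`.
#' @export
spacer_enrichment <- function(obs, ctrl) {
  if (!identical(obs$spacer, ctrl$spacer)) {
    abort("`obs` and `ctrl` must share an identical spacer domain.")
  }
  n_obs <- attr(obs, "n_regions")
  n_ctrl <- attr(ctrl, "n_regions")
  if (is.null(n_obs) || is.null(n_ctrl)) {
    abort("Inputs must be spacer_spectrum objects carrying n_regions.")
  }
  total_obs <- sum(obs$n_regions_with_pair)
  rows <- lapply(seq_along(obs$spacer), function(i) {
    x <- obs$n_regions_with_pair[i]
    vs_ctrl <- enrichment_row(n_obs, x, n_ctrl, ctrl$n_regions_with_pair[i])
    # pooled (region, spacer) hits over the other spacer lengths
    x_other <- total_obs - x
    n_other <- n_obs * (length(obs$spacer) - 1)
    vs_other <- enrichment_row(n_obs, x, n_other, x_other)
    tibble(
      spacer = obs$spacer[i],
      x_obs = x, n_obs = n_obs,
      x_ctrl = ctrl$n_regions_with_pair[i], n_ctrl = n_ctrl,
      fold_vs_ctrl = vs_ctrl$fold, p_vs_ctrl = vs_ctrl$p_value,
      log10_p_vs_ctrl = vs_ctrl$log10_p,
      fold_vs_other = vs_other$fold, p_vs_other = vs_other$p_value,
      log10_p_vs_other = vs_other$log10_p
    )
  })
  bind_rows(rows)
}

#' Gene-set enrichment by hypergeometric test
#'
#' For each term (e.g. GO biological process or pathway), tests whether the
#' selected genes are over-represented relative to the universe. Genes absent
#' from the universe are dropped from `selected` with a message.
#'
#' @param selected Character vector of selected genes (e.g. peak target
#'   genes).
#' @param universe Character vector of all genes considered.
#' @param sets Named list of character vectors (term -> genes), e.g. from
#'   [read_gmt()].
#' @param adjust Add a Benjamini-Hochberg `p_adjust` column (default FALSE;
#'   raw hypergeometric p-values are reported either way).
#' @return A tibble with one row per term: `term_id`, `k`, `K`, `n`, `N`,
#'   `fold`, `p_value`, sorted by `p_value`.
#' @export
geneset_enrichment <- function(selected, universe, sets, adjust = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  if (length(sets) == 0) abort("`sets` must be non-empty.")
  selected <- unique(selected)
  dropped <- setdiff(selected, universe)
  if (length(dropped) > 0) {
    message(length(dropped), " selected gene(s) absent from universe; dropped.")
    selected <- intersect(selected, universe)
  }
  N <- length(universe)
  n <- length(selected)
  rows <- purrr::imap(sets, function(genes, term) {
    term_genes <- intersect(unique(genes), universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, selected))
    fold <- if (K == 0 || n == 0) NA_real_ else (k / n) / (K / N)
    tibble(term_id = term, k = k, K = K, n = n, N = N, fold = fold,
           p_value = hypergeom_upper_tail(k, n = n, X = K, N = N))
  })
  out <- bind_rows(rows) |> arrange(.data$p_value)
  if (adjust) out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (term, description, genes...; tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]), vapply(lines, `[`, "", 1))
}

#' Read a bedGraph score track
#'
#' @param path bedGraph file (chrom, start, end, score; 0-based half-open).
#' @return A tibble with `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    df <- as.data.frame(gr)
    return(tibble(chrom = as.character(df$seqnames), start = df$start - 1,
                  end = df$end, score = df$score))
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric", "numeric"))
  tibble(chrom = raw[[1]], start = raw[[2]], end = raw[[3]], score = raw[[4]])
}

# Value of a (chrom,start,end,score) interval track at single positions;
# NA where the track has no coverage.
track_value_at <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    tr <- track[track$chrom == chr, , drop = FALSE]
    if (nrow(tr) == 0) next
    tr <- tr[order(tr$start), ]
    idx <- findInterval(pos[sel], tr$start)
    ok <- idx >= 1 & pos[sel] < tr$end[pmax(idx, 1)]
    out[sel[ok]] <- tr$score[idx[ok]]
  }
  out
}

#' Summit-aligned conservation (or score) profile
#'
#' Averages a per-base score track (e.g. PhastCons conservation) across
#' regions aligned at their summits, giving the mean score at each offset in
#' `-flank..flank`. Positions without track coverage are excluded from the
#' mean, with the contributing region count recorded per offset.
#'
#' @param peaks A peak tibble.
#' @param track Score track tibble (see [read_bedgraph()]).
#' @param flank Flank size in bp around the summit.
#' @return A `conservation_profile` tibble with `offset`, `mean_score`, `n`.
#' @export
conservation_profile <- function(peaks, track, flank = 75) {
  assert_peaks(peaks)
  if (flank <= 0) abort("`flank` must be positive.")
  offsets <- -flank:flank
  mean_score <- numeric(length(offsets))
  n_cov <- integer(length(offsets))
  for (i in seq_along(offsets)) {
    v <- track_value_at(track, peaks$chrom, peaks$summit + offsets[i])
    n_cov[i] <- sum(!is.na(v))
    mean_score[i] <- if (n_cov[i] > 0) mean(v, na.rm = TRUE) else NA_real_
  }
  new_grammar_tbl(
    tibble(offset = offsets, mean_score = mean_score, n = n_cov),
    "conservation_profile",
    n_regions = nrow(peaks)
  )
}
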