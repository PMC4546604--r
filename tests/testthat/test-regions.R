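test_that("peak files round-trip through the summit-table dialect", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t300\tpkA\t200\t5", "chr2\t0\t151\tpkB\t75\t3"), tf)
  pk <- read_peaks(tf, sample = "s1")
  expect_equal(nrow(pk), 2)
  expect_equal(pk$summit, c(200, 75))
  expect_equal(pk$sample, c("s1", "s1"))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_peaks(pk, out)
  again <- read_peaks(out, sample = "s1")
  expect_equal(as.data.frame(again), as.data.frame(pk))
})

test_that("peakzilla dialect converts 1-based coordinates on read", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t101\t300\tpkA\t200\t5", tf)
  pk <- read_peaks(tf, dialect = "peakzilla")
  expect_equal(pk$start, 100)   # 1-based inclusive -> 0-based half-open
  expect_equal(pk$end, 300)
  expect_equal(pk$summit, 199)
})

test_that("malformed peak lines and invariant violations are rejected", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t300\t100\tpkA\t200\t5", tf)  # start >= end
  expect_error(read_peaks(tf), "start >= end")
  writeLines("chr1\t100\t300\tpkA\t999\t5", tf)  # summit outside interval
  expect_error(read_peaks(tf), "Summit outside")
  writeLines("chr1\tNOPE\t300\tpkA\t200\t5", tf)
  expect_error(read_peaks(tf), "line 1")
})

test_that("summit windows are centred, odd-width, and clipped with a flag", {
  pk <- toy_peaks(starts = 900, width = 200)  # summit 1000
  w <- summit_window(pk, 151)
  expect_equal(w$start, 925)
  expect_equal(w$end, 1076)
  expect_false(w$clipped)

  w1 <- summit_window(pk, 1)
  expect_equal(c(w1$start, w1$end), c(1000, 1001))

  near_edge <- toy_peaks(starts = 0, width = 50)  # summit 25
  sz <- toy_sizes(size = 1000)
  wc <- summit_window(near_edge, 151, chrom_sizes = sz)
  expect_equal(wc$start, 0)
  expect_equal(wc$end, 101)
  expect_true(wc$clipped)

  expect_error(summit_window(pk, 150), "odd")
})

test_that("overlap_fraction matches brute-force pairwise intersection", {
  q <- tibble::tibble(chrom = "chr1", start = c(0, 200), end = c(100, 300))
  r <- tibble::tibble(chrom = "chr1", start = 90, end = 110)
  res <- overlap_fraction(q, r)
  expect_equal(res$fraction, 0.5)
  expect_equal(res$overlaps, c(TRUE, FALSE))

  expect_equal(overlap_fraction(q, q)$fraction, 1)
  disjoint <- tibble::tibble(chrom = "chr1", start = 5000, end = 5100)
  expect_equal(overlap_fraction(q, disjoint)$fraction, 0)
  expect_error(overlap_fraction(q[0, ], r), "non-empty")

  # random instances vs a brute-force double loop
  withr::with_seed(41, {
    for (rep in 1:5) {
      qs <- sort(sample(0:500, 8)); rs <- sort(sample(0:500, 6))
      qq <- tibble::tibble(chrom = "c", start = qs, end = qs + 20)
      rr <- tibble::tibble(chrom = "c", start = rs, end = rs + 15)
      brute <- vapply(seq_len(nrow(qq)), function(i) {
        any(pmin(qq$end[i], rr$end) - pmax(qq$start[i], rr$start) >= 1)
      }, logical(1))
      expect_equal(overlap_fraction(qq, rr)$overlaps, brute)
    }
  })

  # min_overlap threshold
  expect_equal(overlap_fraction(q, r, min_overlap = 11)$fraction, 0)
})

test_that("shuffle_regions conserves counts and widths and is seed-deterministic", {
  pk <- toy_peaks(starts = c(100, 500, 2000), width = 120)
  pk$chrom <- c("chr1", "chr1", "chr2")
  sz <- tibble::tibble(chrom = c("chr1", "chr2"), size = c(1e4, 5e3))
  s1 <- shuffle_regions(pk, sz, seed = 7)
  s2 <- shuffle_regions(pk, sz, seed = 7)
  expect_equal(s1, s2)
  expect_equal(table(s1$chrom), table(pk$chrom))
  expect_equal(sort(s1$end - s1$start), sort(pk$end - pk$start))
  sz_vec <- setNames(sz$size, sz$chrom)
  expect_true(all(s1$start >= 0))
  expect_true(all(s1$end <= sz_vec[s1$chrom]))
  expect_true(all(s1$summit >= s1$start & s1$summit < s1$end))

  wide <- toy_peaks(starts = 0, width = 9999)
  expect_error(shuffle_regions(wide, toy_sizes(size = 5000)), "wider")
})

test_that("shuffled starts are uniform over the feasible range", {
  # one 100bp peak on a 10,100bp chromosome: starts must be uniform on 0..10,000
  pk <- toy_peaks(starts = 5000, width = 100)
  sz <- toy_sizes(size = 10100)
  starts <- vapply(1:10000, function(i) {
    shuffle_regions(pk, sz, seed = i)$start
  }, numeric(1))
  expect_gte(min(starts), 0)
  expect_lte(max(starts), 10000)
  bins <- cut(starts, breaks = seq(0, 10001, length.out = 11),
              include.lowest = TRUE)
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("nearest-TSS assignment equals the all-pairs minimum", {
  tss <- tibble::tibble(
    gene_id = c("geneA", "geneB"), chrom = "chr1",
    tss = c(1000, 10000), strand = c("+", "+")
  )
  pk <- toy_peaks(starts = 3950, width = 100)  # summit 4000
  a <- nearest_tss_assign(pk, tss)
  expect_equal(a$gene_id, "geneA")
  expect_equal(abs(a$distance), 3000)
  expect_equal(a$proximity_class, "distal")

  coincident <- toy_peaks(starts = 4950, width = 100)  # summit 5000
  tss0 <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 5000, strand = "+")
  a0 <- nearest_tss_assign(coincident, tss0)
  expect_equal(a0$distance, 0)
  expect_equal(a0$proximity_class, "proximal")

  # two peaks on one gene deduplicate
  two <- toy_peaks(starts = c(4900, 5100), width = 50)
  expect_equal(assigned_genes(nearest_tss_assign(two, tss0)), "g")

  # randomized oracle equivalence: exhaustive minimum over all TSS
  withr::with_seed(42, {
    n_tss <- 50
    tssr <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:n_tss), chrom = "chr1",
      tss = sample(0:1e5, n_tss), strand = sample(c("+", "-"), n_tss, TRUE)
    )
    pkr <- toy_peaks(starts = sample(0:(1e5 - 100), 40), width = 100)
    pkr$peak_id <- paste0("rpk", seq_len(40))
    got <- nearest_tss_assign(pkr, tssr)
    for (i in seq_len(nrow(pkr))) {
      d <- abs(pkr$summit[i] - tssr$tss)
      best <- which(d == min(d))
      best <- best[order(tssr$gene_id[best])][1]
      expect_equal(got$gene_id[i], tssr$gene_id[best])
      expect_equal(abs(got$distance[i]), min(d))
    }
  })
})

test_that("distance sign follows gene orientation (negative = upstream)", {
  pk <- toy_peaks(starts = 4950, width = 100)  # summit 5000
  plus <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 6000, strand = "+")
  minus <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 4000, strand = "-")
  expect_equal(nearest_tss_assign(pk, plus)$distance, -1000)   # upstream of + gene
  expect_equal(nearest_tss_assign(pk, minus)$distance, -1000)  # upstream of - gene
})

test_that("feature classification uses summit position and fixed priority", {
  ann <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 100, 200, 300, 0),
    end = c(100, 200, 300, 400, 100),
    class = c("promoter", "five_prime_utr", "exon", "intron", "exon")
  )
  pk <- toy_peaks(starts = c(40, 140, 240, 340, 8000), width = 20)
  cls <- classify_features(pk, ann)
  # peak 1 summit 50: promoter wins over the overlapping exon record
  expect_equal(cls$feature_class,
               c("promoter", "five_prime_utr", "exon", "intron", "intergenic"))
  fr <- feature_fractions(cls)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
  expect_equal(fr$fraction, rep(0.2, 5))

  # constructed 4-peak enumeration, one class each
  pk4 <- toy_peaks(starts = c(40, 140, 240, 340), width = 20)
  fr4 <- feature_fractions(classify_features(pk4, ann))
  expect_equal(fr4$fraction, c(0.25, 0.25, 0.25, 0.25, 0))
})
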