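test_that("bedGraph loading fills gaps with zero and validates input", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t10\t2", f)
  tr <- load_coverage(f, c(chr1 = 20))
  st <- peakshift:::region_signal_stats(tr, tibble::tibble(chrom = "chr1",
                                                           start = 0L, end = 20L))
  expect_equal(st$mean, 1)   # 2 over half the chromosome, 0 over the rest
  expect_equal(st$max, 2)

  empty <- withr::local_tempfile(fileext = ".bedGraph")
  file.create(empty)
  expect_warning(tr0 <- load_coverage(empty, c(chr1 = 20)), "empty")
  expect_equal(track_mass(tr0), 0)

  bad <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t5\t3\t1", bad)
  expect_error(load_coverage(bad, c(chr1 = 20)), "invalid")

  neg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t5\t-1", neg)
  expect_error(load_coverage(neg, c(chr1 = 20)), "negative")

  ovl <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t1"), ovl)
  expect_error(load_coverage(ovl, c(chr1 = 20)), "overlapping")
})

test_that("1x normalization gives genome mean 1, idempotently and linearly", {
  tr <- constant_track(4, chrom_len = 1e6)
  n1 <- normalize_to_1x(tr, 1e6)
  expect_equal(unique(n1$value), 1)

  # total mass 2e6 over effective size 1e6 -> scale 0.5
  tr2 <- constant_track(2, chrom_len = 1e6)
  n2 <- normalize_to_1x(tr2, 1e6)
  expect_equal(unique(n2$value), 1)
  expect_equal(unique(n2$value) / unique(tr2$value), 0.5)

  set.seed(2)
  df <- tibble::tibble(chrom = "chr1", start = seq(0, 990, 10),
                       end = seq(10, 1000, 10), value = runif(100, 0, 5))
  trr <- signal_track(df, c(chr1 = 1000))
  nr <- normalize_to_1x(trr, 1000)
  expect_equal(track_mass(nr) / 1000, 1, tolerance = 1e-9)
  # idempotence
  nn <- normalize_to_1x(nr, 1000)
  expect_equal(nn$value, nr$value, tolerance = 1e-12)
  # linearity: normalizing a scaled track equals normalizing the original
  sc <- signal_track(dplyr::mutate(df, value = value * 7.3), c(chr1 = 1000))
  expect_equal(normalize_to_1x(sc, 1000)$value, nr$value, tolerance = 1e-12)

  expect_error(normalize_to_1x(signal_track(df[0, ], c(chr1 = 1000))), "empty")
})

test_that("peak signal summaries average replicates and match the per-base oracle", {
  peaks <- make_peaks(100, 200, "pk")
  t1 <- constant_track(1, chrom_len = 1000)
  t3 <- constant_track(3, chrom_len = 1000)
  s <- summarize_peak_signal(list(t1, t3), peaks)
  expect_equal(s$height, 2)      # replicate means 1 and 3
  expect_equal(s$width, 100L)
  s1 <- summarize_peak_signal(t1, peaks, height_stat = "max")
  expect_equal(s1$height, 1)     # constant coverage: mean and max agree

  # triangular profile: max = 5, mean checked against per-base summation
  tri <- c(rep(0, 10), 1:5, 4:1, rep(0, 10))
  trt <- per_base_track(tri)
  pk <- make_peaks(10, 19, "tri")
  or <- per_base_oracle(trt, "chr1", 10, 19)
  expect_equal(summarize_peak_signal(trt, pk, "max")$height, 5)
  expect_equal(summarize_peak_signal(trt, pk, "mean")$height, or$mean)

  # replicate-order invariance
  expect_equal(summarize_peak_signal(list(t3, t1), peaks)$height, s$height)

  expect_error(summarize_peak_signal(t1, make_peaks(900, 1200, "out")), "bounds")
})

test_that("split-and-recombine width-weighted mean equals the whole-peak mean", {
  set.seed(8)
  v <- runif(400, 0, 4)
  tr <- per_base_track(v)
  whole <- summarize_peak_signal(tr, make_peaks(50, 350, "w"))$height
  left <- summarize_peak_signal(tr, make_peaks(50, 170, "l"))$height
  right <- summarize_peak_signal(tr, make_peaks(170, 350, "r"))$height
  expect_equal((left * 120 + right * 180) / 300, whole, tolerance = 1e-12)
})

test_that("TSS matrices align, flip strands, and flag clipped windows", {
  tssp <- tibble::tibble(gene_id = "g", chrom = "chr1", pos = 5000L, strand = "+")
  ct <- constant_track(2.5, chrom_len = 1e4)
  m <- tss_matrix(ct, tssp, flank = 2500, bin = 50)
  expect_equal(dim(m), c(1, 100))
  expect_true(all(abs(m - 2.5) < 1e-12))
  expect_equal(tss_profile(m)$signal, rep(2.5, 100))

  # single spike just downstream of a + strand TSS lands in the
  # centre-adjacent bin
  spike <- signal_track(tibble::tibble(chrom = "chr1", start = 5010L,
                                       end = 5020L, value = 100),
                        c(chr1 = 1e4))
  ms <- tss_matrix(spike, tssp, flank = 2500, bin = 50)
  expect_equal(which.max(ms[1, ]), 51)   # first bin right of the TSS

  # minus-strand row equals the reversed plus-strand row of the mirrored signal
  tssm <- tibble::tibble(gene_id = "g", chrom = "chr1", pos = 5000L, strand = "-")
  mm <- tss_matrix(spike, tssm, flank = 2500, bin = 50)
  expect_equal(mm[1, ], ms[1, 100:1])

  # clipped window: padded with zeros and flagged
  tss_edge <- tibble::tibble(gene_id = "e", chrom = "chr1", pos = 1000L, strand = "+")
  me <- tss_matrix(ct, tss_edge, flank = 2500, bin = 50)
  expect_true(attr(me, "clipped"))
  expect_equal(me[1, 1], 0)              # fully outside the chromosome
  expect_equal(me[1, 100], 2.5)

  # symmetric signal about the TSS gives a symmetric metaprofile
  sym <- signal_track(tibble::tibble(chrom = "chr1",
                                     start = c(4000L, 5500L),
                                     end = c(4500L, 6000L), value = 3),
                      c(chr1 = 1e4))
  msym <- tss_matrix(sym, tssp, flank = 2500, bin = 50)
  prof <- tss_profile(msym)$signal
  expect_equal(prof, rev(prof), tolerance = 1e-12)

  expect_error(tss_matrix(ct, tssp, flank = 2500, bin = 33), "divisible")
})

test_that("row ordering follows total signal strength", {
  tss2 <- tibble::tibble(gene_id = c("hi", "lo"), chrom = "chr1",
                         pos = c(3000L, 7000L), strand = "+")
  tr <- signal_track(tibble::tibble(chrom = "chr1", start = 2500L, end = 3500L,
                                    value = 10),
                     c(chr1 = 1e4))
  m <- tss_matrix(tr, tss2, flank = 1000, bin = 100)
  expect_equal(tss_row_order(m), c(1, 2))
})
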