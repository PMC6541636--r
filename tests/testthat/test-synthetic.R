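test_that("the generator is fully deterministic given the seed", {
  cfg <- synthetic_config(seed = 12, n_peaks = 300, n_genes = 200)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genome$genes, d2$genome$genes)
  expect_identical(d1$peaks, d2$peaks)
  expect_identical(d1$signal$counts$counts, d2$signal$counts$counts)
  expect_identical(d1$expression$table, d2$expression$table)
  d3 <- simulate_dataset(synthetic_config(seed = 13, n_peaks = 300, n_genes = 200))
  expect_false(identical(d1$peaks$truth, d3$peaks$truth))
})

test_that("config validation rejects infeasible or degenerate settings", {
  expect_error(synthetic_config(prop_shared = 0.9, prop_control_only = 0.2),
               "proportions")
  expect_error(synthetic_config(width_delta_margin = 0), "margins")
  expect_error(synthetic_config(replicates = 1), "replicates")
  expect_error(synthetic_config(n_genes = 10000, n_peaks = 10000,
                                n_chroms = 1, chrom_length = 1e6),
               "too small")
})

test_that("gene placement respects TSS spacing and strand balance", {
  cfg <- synthetic_config(seed = 2, n_genes = 300, n_peaks = 100)
  gen <- sim_genome(cfg)
  tss <- tss_table(gen$genes)
  gaps <- tss |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(min_gap = min(diff(sort(pos))), .groups = "drop")
  expect_true(all(gaps$min_gap >= 2 * 1500))
  expect_true(abs(sum(gen$genes$strand == "+") - 150) <= 1)
  expect_true(all(purrr::map2_lgl(
    gen$genes$tss, seq_len(nrow(gen$genes)),
    function(t, i) all(t >= gen$genes$start[i] & t < gen$genes$end[i])
  )))
})

test_that("planted categories hit their margins and multinomial bounds", {
  cfg <- synthetic_config(seed = 1, n_peaks = 1000, n_genes = 600)
  ds <- simulate_dataset(cfg)
  tr <- ds$peaks$truth
  expect_equal(nrow(tr), 1000)

  shared <- tr$in_control & tr$in_mutant
  p_sh <- 0.84 / 0.997
  expect_lt(abs(sum(shared) - 1000 * p_sh), 4 * sqrt(1000 * p_sh * (1 - p_sh)))

  bh <- tr$category == "broader_higher"
  expect_true(all(tr$mutant_width[bh] - tr$control_width[bh] >= 1500 + 500))
  expect_true(all(tr$mutant_height[bh] / tr$control_height[bh] >= 2.5))
  nl <- tr$category == "narrower_lower"
  expect_true(all(tr$control_width[nl] - tr$mutant_width[nl] >= 1500 + 500))
  expect_true(all(tr$mutant_width[nl] > 0))
  un <- shared & tr$category == "unchanged"
  expect_true(all(abs(tr$mutant_width[un] - tr$control_width[un]) < 1500 - 500))
  rat <- tr$mutant_height[un] / tr$control_height[un]
  expect_true(all(rat < 1.5 & rat > 1 / 1.5))
})

test_that("noise-free counts equal expectations and coverage mass matches counts", {
  cfg <- synthetic_config(seed = 5, n_peaks = 200, n_genes = 150, noise = "none")
  ds <- simulate_dataset(cfg)
  cm <- ds$signal$counts
  tr <- ds$peaks$truth
  # mutant replicate expectation: height * width / fragment_len
  mutant_present <- !is.na(tr$mutant_peak_id)
  w <- tr$mutant_width[mutant_present]
  lam <- tr$mutant_height[mutant_present] *
    (round(tr$center[mutant_present] + w / 2) - round(tr$center[mutant_present] - w / 2)) / 100
  got <- cm$counts[tr$mutant_peak_id[mutant_present], "mutant_rep1"]
  expect_equal(unname(got), unname(round(lam)))

  for (nm in names(ds$signal$tracks)) {
    k <- match(nm, colnames(cm$counts))
    expect_equal(track_mass(ds$signal$tracks[[nm]]),
                 sum(cm$counts[, k]) * 100, tolerance = 1e-9)
  }

  # doubling depth doubles library sizes (noise off)
  cfg2 <- synthetic_config(seed = 5, n_peaks = 200, n_genes = 150,
                           noise = "none", depth = 2)
  ds2 <- simulate_dataset(cfg2)
  expect_equal(ds2$signal$counts$library_sizes / cm$library_sizes,
               rep(2, 8), tolerance = 2e-3)
})

test_that("Poisson replicate means concentrate around expectations", {
  cfg <- synthetic_config(seed = 8, n_peaks = 400, n_genes = 300)
  ds <- simulate_dataset(cfg)
  cfg0 <- synthetic_config(seed = 8, n_peaks = 400, n_genes = 300, noise = "none")
  ds0 <- simulate_dataset(cfg0)
  lam <- ds0$signal$counts$counts   # noise-free counts = rounded expectations
  obs <- ds$signal$counts$counts
  # overall mean ratio over 400 regions x 8 replicates: CLT bound
  expect_equal(mean(obs) / mean(lam), 1,
               tolerance = 3 * sqrt(1 / sum(lam)) + 1e-3)
})

test_that("planted expression directions are recovered exactly by the filter", {
  cfg <- synthetic_config(seed = 3, n_genes = 800, n_peaks = 100)
  ds <- simulate_dataset(cfg)
  de <- filter_de_genes(ds$expression$table)
  expect_equal(de$direction, ds$expression$truth$planted_direction)
})

test_that("planted DE fractions are recovered at large n within 0.6 pp", {
  cfg <- synthetic_config(seed = 4, n_genes = 10000, n_peaks = 100,
                          n_chroms = 8, chrom_length = 2e7)
  ds <- simulate_dataset(cfg)
  de <- filter_de_genes(ds$expression$table)
  expect_lt(abs(mean(de$direction == "up") - 0.043), 0.006)
  expect_lt(abs(mean(de$direction == "down") - 0.032), 0.006)
})

test_that("the naive threshold caller recovers plateaus", {
  sizes <- c(chr1 = 1e4)
  expect_equal(nrow(call_peaks_threshold(constant_track(0, 1e4), 1)), 0)

  one <- signal_track(tibble::tibble(chrom = "chr1", start = 2000L, end = 4000L,
                                     value = 3), sizes)
  pk <- call_peaks_threshold(one, 1, min_width = 100)
  expect_equal(c(pk$start, pk$end), c(2000L, 4000L))

  two <- signal_track(tibble::tibble(chrom = "chr1",
                                     start = c(1000L, 2500L, 3000L),
                                     end = c(2000L, 2800L, 4000L),
                                     value = c(3, 0.5, 2)), sizes)
  pk2 <- call_peaks_threshold(two, 1, min_width = 100)
  expect_equal(pk2$start, c(1000L, 3000L))
  # contiguous qualifying intervals merge into one run
  merged <- signal_track(tibble::tibble(chrom = "chr1",
                                        start = c(1000L, 2000L),
                                        end = c(2000L, 3000L), value = c(2, 4)),
                         sizes)
  pk3 <- call_peaks_threshold(merged, 1, min_width = 100)
  expect_equal(nrow(pk3), 1)
  expect_equal(c(pk3$start, pk3$end), c(1000L, 3000L))
})

test_that("synthetic files round-trip through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 6, n_peaks = 80, n_genes = 60)
  ds <- simulate_dataset(cfg)
  write_synthetic_files(ds, dir)
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(sizes, ds$genome$chrom_sizes)
  pc <- read_peaks(file.path(dir, "peaks_control.bed"), "BED6", "control")
  expect_equal(nrow(pc), nrow(ds$peaks$control))
  expect_equal(pc$start, ds$peaks$control$start)
  tr <- load_coverage(file.path(dir, "control_rep1.bedGraph"), sizes)
  expect_equal(track_mass(tr), track_mass(ds$signal$tracks$control_rep1),
               tolerance = 1e-6)
  cm <- read_count_matrix(file.path(dir, "counts.tsv"),
                          file.path(dir, "conditions.tsv"))
  expect_equal(unname(cm$counts), unname(ds$signal$counts$counts))
  expect_equal(cm$conditions, ds$signal$counts$conditions)
})
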