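mk_pair <- function(id, cw, mw, ch, mh) {
  list(
    pair = tibble::tibble(control_peak_id = paste0("c", id),
                          mutant_peak_id = paste0("m", id)),
    ctrl = tibble::tibble(peak_id = paste0("c", id), width = cw, height = ch,
                          height_stat = "mean"),
    mut = tibble::tibble(peak_id = paste0("m", id), width = mw, height = mh,
                         height_stat = "mean")
  )
}

classify_one <- function(cw, mw, ch, mh, ...) {
  p <- mk_pair(1, cw, mw, ch, mh)
  classify_shared_peaks(p$pair, p$ctrl, p$mut, shape_thresholds(...))$category
}

test_that("width and height criteria drive the three shape categories", {
  # 1600 bp broader with equal heights
  expect_equal(classify_one(2000, 3600, 1, 1), "broader_higher")
  # equal widths, height ratio 2.2 >= 2
  expect_equal(classify_one(2000, 2000, 1.0, 2.2), "broader_higher")
  # 1400 bp broader (below threshold), ratio 1
  expect_equal(classify_one(2000, 3400, 1, 1), "unchanged")
  # conflicting signals: broader by width but lower by height
  expect_equal(classify_one(2000, 3600, 1, 0.4), "unchanged")
  # symmetric narrower+lower
  expect_equal(classify_one(3600, 2000, 1, 1), "narrower_lower")
  expect_equal(classify_one(2000, 2000, 2.2, 1.0), "narrower_lower")
})

test_that("degenerate heights are handled: zero control -> Inf ratio, both zero -> 1", {
  expect_warning(cat1 <- classify_one(2000, 2000, 0, 1), "zero control")
  expect_equal(cat1, "broader_higher")
  expect_equal(classify_one(2000, 2000, 0, 0), "unchanged")
})

test_that("classification is antisymmetric under condition swap", {
  set.seed(31)
  n <- 200
  cw <- sample(1000:4000, n, TRUE); mw <- sample(1000:4000, n, TRUE)
  ch <- runif(n, 0.5, 5); mh <- runif(n, 0.5, 5)
  pairs <- tibble::tibble(control_peak_id = paste0("c", 1:n),
                          mutant_peak_id = paste0("m", 1:n))
  cs <- tibble::tibble(peak_id = paste0("c", 1:n), width = cw, height = ch,
                       height_stat = "mean")
  ms <- tibble::tibble(peak_id = paste0("m", 1:n), width = mw, height = mh,
                       height_stat = "mean")
  fwd <- classify_shared_peaks(pairs, cs, ms)
  swapped_pairs <- tibble::tibble(control_peak_id = paste0("m", 1:n),
                                  mutant_peak_id = paste0("c", 1:n))
  rev_ <- classify_shared_peaks(swapped_pairs, ms, cs)
  map <- c(broader_higher = "narrower_lower", narrower_lower = "broader_higher",
           unchanged = "unchanged")
  expect_equal(rev_$category, unname(map[fwd$category]))
  # deterministic and order-independent
  perm <- sample.int(n)
  again <- classify_shared_peaks(pairs[perm, ], cs, ms)
  expect_equal(again$category, fwd$category[perm])
})

test_that("partition and shape fractions sum to one per level", {
  ctrl <- make_peaks(seq(0, 999000, 10000)[1:100], seq(0, 999000, 10000)[1:100] + 2000,
                     paste0("c", 1:100), condition = "control")
  # 84 shared, 16 control-only; 9 extra mutant-only
  mut <- dplyr::bind_rows(
    make_peaks(ctrl$start[1:84] + 100, ctrl$end[1:84] + 100, paste0("m", 1:84),
               condition = "mutant"),
    make_peaks(seq(2e6, 2e6 + 8e4, 1e4), seq(2e6, 2e6 + 8e4, 1e4) + 2000,
               paste0("mo", 1:9), condition = "mutant")
  )
  part <- partition_peak_sets(ctrl, mut)
  s <- summarize_partition(part)
  expect_equal(s$n, c(84L, 16L, 9L))
  expect_equal(sum(s$fraction), 1, tolerance = 1e-12)

  calls <- tibble::tibble(
    control_peak_id = part$shared$control_peak_id,
    mutant_peak_id = part$shared$mutant_peak_id,
    width_delta = 0, height_ratio = 1, category = "unchanged"
  )
  s2 <- summarize_partition(part, calls)
  sh <- s2[s2$level == "shape", ]
  expect_equal(sh$fraction, c(0, 0, 1))
  expect_equal(sum(sh$fraction), 1, tolerance = 1e-12)

  empty <- structure(list(shared = part$shared[0, ], control_only = ctrl[0, ],
                          mutant_only = mut[0, ]), class = "peak_partition")
  expect_error(summarize_partition(empty), "empty")
})

test_that("merged gene lists take the union of shape and differential evidence", {
  # three shared sites, each on its own gene promoter
  gwpl <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 11000L, 21000L),
    end = c(4000L, 14000L, 24000L),
    gene_id = c("geneX", "geneY", "geneZ"), strand = "+", clipped = FALSE
  )
  ctrl <- make_peaks(c(1500, 11500, 21500), c(3500, 13500, 23500),
                     paste0("c", 1:3), condition = "control")
  mut <- make_peaks(c(1600, 11600, 21600), c(3600, 13600, 23600),
                    paste0("m", 1:3), condition = "mutant")
  part <- partition_peak_sets(ctrl, mut)
  calls <- tibble::tibble(
    control_peak_id = paste0("c", 1:3), mutant_peak_id = paste0("m", 1:3),
    width_delta = c(2000, 0, 0), height_ratio = 1,
    category = c("broader_higher", "unchanged", "unchanged")
  )
  diff <- tibble::tibble(region_id = paste0("m", 1:3),
                         call = c("not_significant", "enriched", "not_significant"))
  gl <- merge_with_differential(calls, diff, part, gwpl)
  expect_setequal(gl$broader_higher_genes, c("geneX", "geneY"))  # shape + diff union
  expect_equal(gl$unchanged_genes, "geneZ")
  expect_equal(length(gl$narrower_lower_genes), 0)

  # differential region absent from the partition is ignored with a message
  diff2 <- dplyr::bind_rows(diff, tibble::tibble(region_id = "ghost",
                                                 call = "enriched"))
  expect_message(gl2 <- merge_with_differential(calls, diff2, part, gwpl),
                 "not in the shared partition")
  expect_equal(gl2$broader_higher_genes, gl$broader_higher_genes)
})
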