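test_that("simulation honours the fragment count, bounds, and determinism", {
  g <- small_genome()
  cfg <- small_sim_config(fragments_per_sample = 3000)
  fr1 <- simulate_sample(g, "OC", cfg, seed = 5, tumor_fraction = 0.3)
  fr2 <- simulate_sample(g, "OC", cfg, seed = 5, tumor_fraction = 0.3)
  expect_equal(nrow(fr1), 3000)
  expect_identical(fr1$start, fr2$start)
  expect_identical(fr1$end, fr2$end)
  lens <- setNames(g$chrom$length, g$chrom$name)
  expect_true(all(fr1$start >= 0))
  expect_true(all(fr1$end <= lens[fr1$chrom]))
  expect_true(all(fr1$end > fr1$start))
  # byte-identical BED output under the same seed
  p1 <- tempfile(fileext = ".bed"); p2 <- tempfile(fileext = ".bed")
  write_fragments(fr1, p1); write_fragments(fr2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("an OC sample at tumor fraction 0 follows the healthy length law", {
  g <- small_genome()
  cfg <- small_sim_config(fragments_per_sample = 10000)
  hc <- simulate_sample(g, "HC", cfg, seed = 21)
  oc0 <- simulate_sample(g, "OC", cfg, seed = 22, tumor_fraction = 0)
  p <- wilcoxon_rank_sum(hc$end - hc$start, oc0$end - oc0$start)
  expect_gt(p, 0.01)
})

test_that("planted copy-ratio segments enrich fragment counts as expected", {
  # inside/outside per-window count ratio ~ (1 - f) + f * copy_ratio
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e7), tss_per_chrom = 0,
                    cnv_segments = data.frame(chrom = "chr1", start = 4e6,
                                              end = 6.5e6, copy_ratio = 1.5),
                    n_ndr_genes = 0, fragments_per_sample = 50000,
                    seed = 31L)
  g <- build_toy_genome(cfg)
  fr <- simulate_sample(g, "OC", cfg, seed = 32, tumor_fraction = 0.3)
  mid <- (fr$start + fr$end) %/% 2
  inside <- mid >= 4e6 & mid < 6.5e6
  n_win_in <- 2.5e6 / 2000
  n_win_out <- (1e7 - 2.5e6) / 2000
  ratio <- (sum(inside) / n_win_in) / (sum(!inside) / n_win_out)
  expect_gt(ratio, 1.15 - 0.03)
  expect_lt(ratio, 1.15 + 0.03)
})

test_that("raising the tumor fraction raises short/long ratio and gain enrichment", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e7), tss_per_chrom = 0,
                    cnv_segments = data.frame(chrom = "chr1", start = 4e6,
                                              end = 6.5e6, copy_ratio = 1.5),
                    n_ndr_genes = 0, fragments_per_sample = 50000,
                    seed = 41L)
  g <- build_toy_genome(cfg)
  stats <- lapply(c(0, 0.1, 0.3), function(f) {
    fr <- simulate_sample(g, "OC", cfg, seed = 42 + round(100 * f),
                          tumor_fraction = f)
    len <- fr$end - fr$start
    mid <- (fr$start + fr$end) %/% 2
    list(sl = sum(len >= 90 & len <= 150) / sum(len >= 151 & len <= 220),
         enrich = mean(mid >= 4e6 & mid < 6.5e6))
  })
  sl <- vapply(stats, `[[`, numeric(1), "sl")
  en <- vapply(stats, `[[`, numeric(1), "enrich")
  expect_true(all(diff(sl) > 0))
  expect_true(all(diff(en) > 0))
})

test_that("cohort simulation writes a consistent, reproducible manifest", {
  g <- small_genome()
  cfg <- small_sim_config(n_healthy = 7, n_tumor = 5,
                          fragments_per_sample = 500)
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  c1 <- simulate_cohort(g, cfg, d1)
  c2 <- simulate_cohort(g, cfg, d2)
  expect_equal(nrow(c1$manifest), 12)
  expect_identical(c1$manifest$split, c2$manifest$split)
  b1 <- readBin(c1$manifest$path[1], "raw", file.size(c1$manifest$path[1]))
  b2 <- readBin(c2$manifest$path[1], "raw", file.size(c2$manifest$path[1]))
  expect_identical(b1, b2)
  # refuses to clobber an existing manifest
  expect_error(simulate_cohort(g, cfg, d1), "overwrite")
  # OC split: ceiling(2/3) train, matching a 40/19 split of 59 cases
  oc <- c1$manifest[c1$manifest$label == "OC", ]
  expect_equal(sum(oc$split == "train"), ceiling(5 * 2 / 3))
  hc <- c1$manifest[c1$manifest$label == "HC", ]
  expect_equal(abs(sum(hc$split == "train") - sum(hc$split == "test")) <= 1,
               TRUE)
})

test_that("the published cohort layout yields a 40/19 OC split", {
  # split arithmetic only; no fragments are simulated
  n_t <- 59
  expect_equal(ceiling(n_t * 2 / 3), 40)
  expect_equal(n_t - ceiling(n_t * 2 / 3), 19)
})
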