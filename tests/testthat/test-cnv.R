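test_that("window depth counts midpoints and normalizes to mean 1", {
  g <- hand_genome(c(chr1 = random_sequence(4000, seed = 33)),
                   window_size = 2000)
  fr <- fragment_set(rep("chr1", 100), seq(100, 1090, by = 10),
                     seq(100, 1090, by = 10) + 150)
  d <- window_depth(fr, g)
  expect_equal(d$raw, c(100, 0))
  expect_equal(mean(d$depth), 1)

  # hand-built 5-fragment oracle, including a boundary-straddling fragment
  fr2 <- fragment_set(rep("chr1", 5), c(0, 500, 1900, 1990, 3000),
                      c(100, 700, 2100, 2150, 3200))
  d2 <- window_depth(fr2, g)
  mids <- (fr2$start + fr2$end) %/% 2
  expect_equal(d2$raw, as.vector(table(factor(mids %/% 2000, 0:1))))
})

test_that("GC correction is the identity on GC-flat depth and removes planted bias", {
  set.seed(35)
  gc <- runif(500, 0.35, 0.6)
  flat <- manual_depth(rep(5, 500), gc = gc)
  corr <- gc_correct(flat)
  expect_equal(corr$depth, flat$depth, tolerance = 1e-9)

  # planted linear GC bias on flat copy number
  biased <- manual_depth(0.5 + gc, gc = gc)
  fixed <- gc_correct(biased)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(biased$depth) / cv(fixed$depth), 5)

  # per-decile medians of corrected depth are all equal
  grp <- cut(gc, quantile(gc, 0:10 / 10), include.lowest = TRUE)
  med <- tapply(fixed$depth, grp, median)
  expect_equal(max(med) - min(med), 0, tolerance = 1e-9)
  expect_equal(unname(med[1]), 1, tolerance = 1e-3)

  expect_error(gc_correct(manual_depth(rep(0, 100))), "all-zero")
})

test_that("the baseline panel enforces sample count and the sigma floor", {
  expect_error(build_baseline(matrix(1, 10, 4)), "at least 5")
  mat <- matrix(rep(c(1, 2), each = 6), nrow = 12, ncol = 5)
  panel <- build_baseline(mat)
  expect_equal(panel$n_panel, 5)
  # identical samples: sd floors at 0.05 * mu everywhere
  expect_equal(panel$sigma, 0.05 * panel$mu)
  expect_equal(length(panel$mu), 12)
})

test_that("segment calling merges seeded runs, bridges small gaps, obeys 2 Mb", {
  n <- 4000 # 8 Mb of 2-kb windows
  mu <- rep(1, n)
  panel <- structure(list(mu = mu, sigma = rep(0.05, n), n_panel = 10,
                          windows = NULL), class = "baseline_panel")
  base <- rep(1, n)

  # copy-neutral: no segments, score 0
  d0 <- manual_depth(base)
  call0 <- call_cnv(d0, panel)
  expect_equal(nrow(call0$segments), 0)
  expect_equal(call0$cnv_score, 0)

  # one significant window only: fails the > 2 Mb rule
  d1 <- base; d1[2000] <- 1.5
  call1 <- call_cnv(manual_depth(d1), panel)
  expect_equal(nrow(call1$segments), 0)

  # a 1200-window (2.4 Mb) elevated run with two interior 2-window dips
  idx <- 1001:2200
  d2 <- base
  d2[idx] <- 1.3
  d2[c(1300, 1301, 1800, 1801)] <- 1.0
  dv2 <- manual_depth(d2)
  call2 <- call_cnv(dv2, panel)
  expect_equal(nrow(call2$segments), 1)
  expect_equal(call2$segments$direction, "gain")
  expect_equal(call2$segments$start, (1001 - 1) * 2000)
  expect_equal(call2$segments$end, 2200 * 2000)
  # score = |mean z| * span(Mb) / 100, against a hand recomputation
  z <- (dv2$depth - panel$mu) / panel$sigma
  want <- abs(mean(z[idx])) * 2.4 / 100
  expect_equal(call2$cnv_score, want, tolerance = 1e-9)

  # a >2 Mb depletion is called as a loss
  d3 <- base; d3[501:1700] <- 0.7
  call3 <- call_cnv(manual_depth(d3), panel)
  expect_equal(call3$segments$direction, "loss")
  expect_gt(call3$cnv_score, 0)

  # a 3-window interior gap splits the run into two sub-2 Mb pieces
  d4 <- base
  d4[1001:2200] <- 1.3
  d4[1600:1602] <- 1.0
  call4 <- call_cnv(manual_depth(d4), panel)
  expect_equal(nrow(call4$segments), 0)
})

test_that("cnv score grows with the planted copy-ratio deviation", {
  n <- 3000
  panel <- structure(list(mu = rep(1, n), sigma = rep(0.05, n),
                          n_panel = 10, windows = NULL),
                     class = "baseline_panel")
  score_at <- function(r) {
    d <- rep(1, n)
    d[1001:2500] <- r
    call_cnv(manual_depth(d), panel)$cnv_score
  }
  expect_true(all(diff(vapply(c(1, 1.2, 1.4, 1.6), score_at,
                              numeric(1))) >= 0))
  expect_equal(score_at(1), 0)
})
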