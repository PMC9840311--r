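test_that("motif enumeration spans the full lexicographic 4-mer space", {
  m <- enumerate_motifs()
  expect_length(m, 256)
  expect_identical(m[1], "AAAA")
  expect_identical(m[256], "TTTT")
  expect_false(anyDuplicated(m) > 0)
  # brute-force nested product oracle
  b <- c("A", "C", "G", "T")
  oracle <- character(0)
  for (x1 in b) for (x2 in b) for (x3 in b) for (x4 in b) {
    oracle <- c(oracle, paste0(x1, x2, x3, x4))
  }
  expect_identical(m, oracle)
})

test_that("a hand fragment yields the expected plus and minus end motifs", {
  g <- hand_genome(c(chrT = "ACGTTTTTTACGT"), window_size = 4)
  fr <- fragment_set("chrT", 0, 13)
  mp <- motif_profile(fr, g)
  expect_equal(mp$n_ends_counted, 2)
  # plus end ACGT; minus end = revcomp("ACGT") = "ACGT"
  expect_equal(unname(mp$frequencies["ACGT"]), 1.0)
  expect_equal(sum(mp$frequencies), 1.0)
})

test_that("motif profile matches a substring/reverse-complement oracle", {
  seqs <- c(chr1 = random_sequence(5000, seed = 9),
            chr2 = random_sequence(3000, seed = 10))
  g <- hand_genome(seqs, window_size = 500)
  set.seed(11)
  n <- 20
  chrom <- sample(names(seqs), n, replace = TRUE)
  start <- floor(runif(n) * (nchar(seqs)[match(chrom, names(seqs))] - 300))
  len <- sample(80:250, n, replace = TRUE)
  fr <- fragment_set(chrom, start, start + len)
  mp <- motif_profile(fr, g)

  counts <- setNames(numeric(256), enumerate_motifs())
  for (i in seq_len(n)) {
    s <- seqs[[chrom[i]]]
    plus <- substr(s, start[i] + 1, start[i] + 4)
    minus <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(s, start[i] + len[i] - 3, start[i] + len[i]))))
    counts[plus] <- counts[plus] + 1
    counts[minus] <- counts[minus] + 1
  }
  expect_equal(unname(mp$frequencies), unname(counts / sum(counts)),
               tolerance = 1e-12)
  expect_equal(sum(mp$frequencies), 1)
})

test_that("truncated and ambiguous end windows are skipped, not imputed", {
  g <- hand_genome(c(chrT = "AANTTCCCGGAT"))
  # plus window AANT has an N -> skipped; minus window GGAT fine
  mp <- suppressWarnings(motif_profile(fragment_set("chrT", 0, 12), g))
  expect_equal(mp$n_ends_counted, 1)
  expect_equal(unname(mp$frequencies[revcomp("GGAT")]), 1)
  # two-base fragment at the chromosome end: plus window would run off
  fr_edge <- fragment_set("chrT", 10, 12)
  mp2 <- motif_profile(fr_edge, g)
  expect_equal(mp2$n_ends_counted, 1)
})

test_that("pooled motif profile is invariant under reverse-complementing the genome", {
  s <- random_sequence(4000, seed = 13)
  L <- nchar(s)
  g_fwd <- hand_genome(c(chr1 = s))
  g_rev <- hand_genome(c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))))
  set.seed(14)
  start <- sort(sample(0:(L - 200), 15))
  len <- sample(100:180, 15, replace = TRUE)
  fr <- fragment_set("chr1", start, start + len)
  fr_mirror <- fragment_set("chr1", L - (start + len), L - start)
  p1 <- motif_profile(fr, g_fwd)$frequencies
  p2 <- motif_profile(fr_mirror, g_rev)$frequencies
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("an empty fragment set yields a flagged all-zero profile", {
  g <- hand_genome(c(chrT = "ACGTACGTACGT"))
  fr <- fragment_set(character(0), numeric(0), numeric(0))
  expect_warning(mp <- motif_profile(fr, g), "no countable")
  expect_equal(mp$n_ends_counted, 0)
  expect_true(all(mp$frequencies == 0))
  expect_true(isTRUE(attr(mp, "empty")))
})

test_that("tumor-biased motifs dominate the cohort-level Wilcoxon ranking", {
  # default effect sizes (bias 1.3x / 0.75x) on a compact genome
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), tss_per_chrom = 0,
                    cnv_segments = NULL, n_ndr_genes = 0,
                    n_healthy = 50, n_tumor = 40,
                    fragments_per_sample = 20000, seed = 91L)
  g <- build_toy_genome(cfg)
  freqs <- matrix(0, 90, 256, dimnames = list(NULL, enumerate_motifs()))
  labels <- rep(c("HC", "OC"), c(50, 40))
  for (i in 1:90) {
    fr <- simulate_sample(g, labels[i], cfg, seed = 900 + i,
                          tumor_fraction = if (labels[i] == "OC") 0.3)
    freqs[i, ] <- motif_profile(fr, g)$frequencies
  }
  p <- apply(freqs, 2, function(v)
    wilcoxon_rank_sum(v[labels == "OC"], v[labels == "HC"]))
  biased <- names(which(g$truth$motif_bias$OC != 1))
  top_decile <- names(sort(p))[1:26]
  expect_gte(sum(top_decile %in% biased), 20)
  expect_lt(median(rank(p)[biased]), median(rank(p)))
})
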