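# Shared fixtures. Helpers are sourced once per test run, so expensive
# objects built here are cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# A random 400-kb single-chromosome genome with a handful of TSSs.
small_genome <- function() {
  cached("small_genome", {
    cfg <- small_sim_config()
    build_toy_genome(cfg)
  })
}

small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(chrom_lengths = c(chr1 = 4e5), tss_per_chrom = 8,
                   cnv_segments = NULL, n_ndr_genes = 4,
                   n_healthy = 6, n_tumor = 4,
                   fragments_per_sample = 5000, seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Minimal genome stand-in when only chromosome lengths matter (binning).
lengths_only_genome <- function(lens) {
  g <- toy_genome_from_sequences(
    setNames(rep(list(strrep("A", 10)), length(lens)), names(lens)))
  g$chrom$length <- as.numeric(lens)
  g
}

# Hand genome with explicit sequence for motif / NF oracles.
hand_genome <- function(seqs, tss = NULL, window_size = 2000) {
  toy_genome_from_sequences(seqs, tss = tss, window_size = window_size)
}

random_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Construct a depth_vector directly (windows on one chromosome).
manual_depth <- function(depth, gc = NULL, window_size = 2000) {
  n <- length(depth)
  out <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * window_size,
                    end = seq_len(n) * window_size,
                    gc = gc %||% rep(0.5, n), raw = depth,
                    depth = if (mean(depth) > 0) depth / mean(depth) else
                      depth, stringsAsFactors = FALSE)
  class(out) <- c("depth_vector", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Feature matrix from a plain matrix with labels/split.
make_fm <- function(x, labels, split, family) {
  rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
  feature_matrix(x, labels, split, family)
}

# A small simulated cohort shared by pipeline-level tests.
small_cohort_run <- function() {
  cached("small_cohort_run", {
    sim <- small_pipeline_sim()
    cfg <- run_config(outdir = file.path(tempdir(), "ocscore_smoke"),
                      sim = sim, overwrite = TRUE)
    res <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
    list(cfg = cfg, res = res)
  })
}

small_pipeline_sim <- function(seed = 11L) {
  sim_config(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6), tss_per_chrom = 20,
             cnv_segments = data.frame(chrom = "chr1", start = 1e6,
                                       end = 3.5e6, copy_ratio = 1.5),
             n_ndr_genes = 10, n_healthy = 20, n_tumor = 14,
             fragments_per_sample = 10000, seed = seed)
}

# Brute-force per-base coverage of a half-open region [a, b).
coverage_oracle <- function(fragments, a, b) {
  total <- 0
  for (x in seq.int(a, b - 1)) {
    total <- total + sum(fragments$start <= x & fragments$end > x)
  }
  total / (b - a)
}
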