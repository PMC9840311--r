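# Toy reference genome: sequences, GC track, TSS annotation, planted truth.

# GC fraction per window computed from the base-code vector of one
# chromosome. Windows are [0, w), [w, 2w), ...; the last may be short.
gc_by_window <- function(code, window_size) {
  n <- length(code)
  nw <- as.integer(ceiling(n / window_size))
  ci <- as.integer(code)
  is_gc <- as.numeric(ci == 1L | ci == 2L)
  cs <- c(0, cumsum(is_gc))
  hi <- pmin(seq_len(nw) * window_size, n)
  lo <- (seq_len(nw) - 1L) * window_size
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# 2-kb window scheme shared by the GC track and copy-number depth vectors.
window_scheme <- function(chrom_lengths, window_size) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    nw <- as.integer(ceiling(len / window_size))
    start <- (seq_len(nw) - 1) * window_size
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Designated biased 4-mer sets for the tumor class: prefixes chosen so the
# up set contains ACAA-like motifs and the down set contains GGGA.
biased_motif_sets <- function() {
  m <- enumerate_motifs()
  list(up = m[startsWith(m, "AC")], down = m[startsWith(m, "GG")])
}

#' Build a synthetic reference genome with planted truth
#'
#' Generates chromosome sequences with smoothly varying regional GC
#' content, a strand-aware TSS table, the 2-kb GC track, and the planted
#' truth set used by the simulator and by recovery tests: copy-number
#' segments, NDR-altered genes, and the per-class 5'-end motif bias map.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `toy_genome`: a list with `chrom`
#'   (data.frame `name`, `length`), `sequence` (named list of character
#'   strings), `code` (named list of raw base-code vectors), `tss`
#'   (data.frame `gene_id`, `chrom`, `position`, `strand`), `gc`
#'   (data.frame `chrom`, `start`, `end`, `gc` over 2-kb windows),
#'   `window_size`, and `truth` (list `cnv_segments`,
#'   `ndr_altered_genes`, `motif_bias`).
#' @export
#' @examples
#' g <- build_toy_genome(sim_config(chrom_lengths = c(chr1 = 2e5),
#'                                  tss_per_chrom = 5, cnv_segments = NULL,
#'                                  seed = 1))
#' nrow(g$tss)
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lens <- config$chrom_lengths
    w <- config$window_size
    sequence <- vector("list", length(lens))
    code <- vector("list", length(lens))
    names(sequence) <- names(code) <- names(lens)
    for (ch in names(lens)) {
      n <- as.integer(lens[[ch]])
      nw <- as.integer(ceiling(n / w))
      # regional GC target: reflected random walk, then light smoothing
      steps <- rnorm(nw, 0, 0.015)
      g <- 0.42 + cumsum(steps)
      g <- 0.32 + abs((g - 0.32) %% 0.52 - 0.26) # reflect into [0.32, 0.58]
      if (nw > 5) g <- as.numeric(stats::filter(g, rep(1 / 5, 5),
                                                circular = TRUE))
      p <- rep(g, each = w)[seq_len(n)]
      is_gc <- runif(n) < p
      pick <- runif(n) < 0.5
      codes <- integer(n)           # default 0 = A
      codes[is_gc & pick] <- 1L     # C
      codes[is_gc & !pick] <- 2L    # G
      codes[!is_gc & !pick] <- 3L   # T
      sequence[[ch]] <- intToUtf8(c(65L, 67L, 71L, 84L)[codes + 1L])
      code[[ch]] <- as.raw(codes)
    }
    gc <- window_scheme(lens, w)
    gc$gc <- unlist(lapply(names(lens),
                           function(ch) gc_by_window(code[[ch]], w)),
                    use.names = FALSE)

    # TSS table: grid positions >= 2 kb from either end, random strand
    tss_list <- list()
    gi <- 0L
    for (ch in names(lens)) {
      len <- as.integer(lens[[ch]])
      grid <- seq.int(2000L + config$tss_spacing, len - 2000L -
                        config$tss_spacing, by = config$tss_spacing)
      if (length(grid) == 0 && config$tss_per_chrom > 0) {
        stop("chromosome ", ch, " too short for the requested TSS layout",
             call. = FALSE)
      }
      k <- min(config$tss_per_chrom, length(grid))
      pos <- sort(sample(grid, k))
      if (k > 0) {
        tss_list[[ch]] <- data.frame(
          gene_id = sprintf("g%04d", gi + seq_len(k)),
          chrom = ch, position = pos,
          strand = sample(c("+", "-"), k, replace = TRUE),
          stringsAsFactors = FALSE)
        gi <- gi + k
      }
    }
    tss <- if (length(tss_list)) do.call(rbind, tss_list) else
      data.frame(gene_id = character(), chrom = character(),
                 position = integer(), strand = character())
    rownames(tss) <- NULL

    n_alt <- min(config$n_ndr_genes, nrow(tss))
    ndr_altered <- if (n_alt > 0) {
      data.frame(gene_id = sort(sample(tss$gene_id, n_alt)),
                 depletion_depth = config$depletion_depth,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = character(), depletion_depth = numeric())
    }

    motifs <- enumerate_motifs()
    bias_hc <- setNames(rep(1, 256), motifs)
    bias_oc <- bias_hc
    sets <- biased_motif_sets()
    bias_oc[sets$up] <- config$motif_bias_up
    bias_oc[sets$down] <- config$motif_bias_down

    genome <- structure(list(
      chrom = data.frame(name = names(lens), length = as.numeric(lens),
                         stringsAsFactors = FALSE),
      sequence = sequence,
      code = code,
      tss = tss,
      gc = gc,
      window_size = w,
      truth = list(cnv_segments = config$cnv_segments,
                   ndr_altered_genes = ndr_altered,
                   motif_bias = list(HC = bias_hc, OC = bias_oc))
    ), class = "toy_genome")
    validate_toy_genome(genome)
    genome
  })
}

#' Assemble a genome object from explicit sequences
#'
#' Builds the same container as [build_toy_genome()] from user-supplied
#' chromosome strings and an optional TSS table — the entry point for
#' hand-crafted fixtures and for real references loaded from disk.
#'
#' @param sequences named character vector / list of chromosome sequences
#'   (A/C/G/T/N).
#' @param tss optional data.frame with `gene_id`, `chrom`, `position`,
#'   `strand`.
#' @param window_size GC / copy-number window size in bp.
#' @return a `toy_genome` object with an empty truth set.
#' @export
#' @examples
#' g <- toy_genome_from_sequences(c(chrM = "ACGTACGTACGT"), window_size = 4)
#' g$gc$gc
toy_genome_from_sequences <- function(sequences, tss = NULL,
                                      window_size = 2000) {
  sequences <- as.list(sequences)
  stopifnot(length(sequences) >= 1, !is.null(names(sequences)))
  sequences <- lapply(sequences, function(s) toupper(as.character(s)))
  code <- lapply(sequences, seq_to_code)
  lens <- vapply(sequences, nchar, numeric(1))
  gc <- window_scheme(lens, window_size)
  gc$gc <- unlist(lapply(names(lens),
                         function(ch) gc_by_window(code[[ch]], window_size)),
                  use.names = FALSE)
  if (is.null(tss)) {
    tss <- data.frame(gene_id = character(), chrom = character(),
                      position = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "chrom", "position", "strand") %in% names(tss)))
  motifs <- enumerate_motifs()
  structure(list(
    chrom = data.frame(name = names(lens), length = as.numeric(lens),
                       stringsAsFactors = FALSE),
    sequence = sequences,
    code = code,
    tss = tss,
    gc = gc,
    window_size = as.integer(window_size),
    truth = list(cnv_segments = NULL,
                 ndr_altered_genes = data.frame(gene_id = character(),
                                                depletion_depth = numeric()),
                 motif_bias = list(HC = setNames(rep(1, 256), motifs),
                                   OC = setNames(rep(1, 256), motifs)))
  ), class = "toy_genome")
}

validate_toy_genome <- function(g) {
  lens <- setNames(g$chrom$length, g$chrom$name)
  if (nrow(g$tss)) {
    ok <- g$tss$position >= 2000 & g$tss$position <= lens[g$tss$chrom] - 2000
    if (!all(ok)) stop("TSS within 2 kb of a chromosome end", call. = FALSE)
  }
  if (any(g$gc$gc < 0 | g$gc$gc > 1)) stop("gc track outside [0, 1]")
  nw_expect <- sum(ceiling(lens / g$window_size))
  if (nrow(g$gc) != nw_expect) stop("gc track window count mismatch")
  invisible(g)
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy cfDNA reference genome\n")
  cat("  chromosomes:", nrow(x$chrom), "(",
      format(sum(x$chrom$length), big.mark = ","), "bp )\n")
  cat("  TSS annotated:", nrow(x$tss), "\n")
  cat("  planted CNV segments:",
      if (is.null(x$truth$cnv_segments)) 0 else nrow(x$truth$cnv_segments),
      "\n")
  cat("  NDR-altered genes:", nrow(x$truth$ndr_altered_genes), "\n")
  invisible(x)
}
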