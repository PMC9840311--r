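#' Simulation configuration for the synthetic cfDNA cohort
#'
#' Bundles every tunable of the toy-genome builder and the fragment
#' simulator. The defaults encode the study conditions the pipeline is
#' exercised under: a 100 healthy-control (HC) / 59 ovarian-cancer (OC)
#' cohort, a healthy fragment-length law with its mono-nucleosomal peak at
#' 167 bp, a shorter tumor length law (peak 150 bp), class-specific 5'-end
#' 4-mer cleavage bias, deepened nucleosome-depleted regions (NDRs) at a
#' set of altered genes, and two planted multi-megabase copy-number
#' segments.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#'   No Y chromosome is simulated.
#' @param tss_per_chrom number of transcription start sites annotated per
#'   chromosome, placed on a `tss_spacing` grid at least 2 kb from either
#'   chromosome end.
#' @param tss_spacing minimum spacing (bp) between neighbouring TSSs so
#'   promoter windows do not overlap.
#' @param window_size copy-number / GC window size in bp (2 kb).
#' @param cnv_segments data.frame with columns `chrom`, `start`, `end`,
#'   `copy_ratio` of planted somatic copy-number segments (each > 2 Mb,
#'   disjoint), or `NULL` for a copy-neutral genome.
#' @param n_ndr_genes number of genes whose promoter NDR is deepened in the
#'   tumor class.
#' @param depletion_depth depth of the tumor NDR deepening in `[0, 1]`;
#'   tumor-derived fragments see the NDR protection of altered genes
#'   multiplied by `1 - depletion_depth`.
#' @param ndr_occupancy relative cut-site weight inside a (healthy) NDR;
#'   values below 1 carve the promoter coverage dip.
#' @param occupancy_amplitude amplitude of the 190-bp-period nucleosome
#'   phasing sinusoid around each TSS.
#' @param motif_bias_up,motif_bias_down multiplicative cut-site weight for
#'   the tumor class on the 16 up-biased 4-mers (prefix `AC`) and the 16
#'   down-biased 4-mers (prefix `GG`).
#' @param n_healthy,n_tumor cohort sizes.
#' @param fragments_per_sample fragments simulated per sample.
#' @param tumor_fraction tumor fraction f in `[0, 1]` of OC samples; a
#'   vector is cycled over OC samples by [simulate_cohort()] and stands in
#'   for stage strata.
#' @param healthy_length,tumor_length fragment-length laws: lists with
#'   `mode` (mono-nucleosomal peak, bp), `scale` (Laplace scale, bp),
#'   `dinuc_mode`, `dinuc_sd`, `dinuc_weight` (di-nucleosomal normal
#'   component).
#' @param train_frac_oc fraction of OC samples assigned to the training
#'   split (ceiling); HC samples are split half/half.
#' @param seed master seed; a fixed seed makes every simulation output
#'   byte-identical.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(chrom_lengths = c(chr1 = 5e6), tss_per_chrom = 10,
#'                   cnv_segments = NULL, n_healthy = 4, n_tumor = 3,
#'                   fragments_per_sample = 1000, seed = 7)
#' cfg$n_healthy
sim_config <- function(chrom_lengths = c(chr1 = 3e7, chr2 = 3e7, chr3 = 3e7),
                       tss_per_chrom = 100,
                       tss_spacing = 6000,
                       window_size = 2000,
                       cnv_segments = data.frame(
                         chrom = c("chr1", "chr2"),
                         start = c(8e6, 1e7),
                         end = c(14e6, 1.5e7),
                         copy_ratio = c(1.5, 0.6)
                       ),
                       n_ndr_genes = 30,
                       depletion_depth = 0.9,
                       ndr_occupancy = 0.8,
                       occupancy_amplitude = 0.25,
                       motif_bias_up = 1.3,
                       motif_bias_down = 0.75,
                       n_healthy = 100,
                       n_tumor = 59,
                       fragments_per_sample = 20000,
                       tumor_fraction = c(0.1, 0.2, 0.3),
                       healthy_length = list(mode = 167, scale = 14,
                                             dinuc_mode = 334, dinuc_sd = 25,
                                             dinuc_weight = 0.15),
                       tumor_length = list(mode = 150, scale = 14,
                                           dinuc_mode = 334, dinuc_sd = 25,
                                           dinuc_weight = 0.15),
                       train_frac_oc = 2 / 3,
                       seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)), all(nzchar(names(chrom_lengths))))
  if (any(grepl("Y$", names(chrom_lengths)))) {
    stop("the toy genome excludes chromosome Y", call. = FALSE)
  }
  stopifnot(tss_per_chrom >= 0, tss_spacing > 0, window_size > 0,
            n_healthy > 0, n_tumor > 0, fragments_per_sample > 0,
            all(tumor_fraction >= 0), all(tumor_fraction <= 1),
            depletion_depth >= 0, depletion_depth <= 1,
            ndr_occupancy > 0, occupancy_amplitude >= 0,
            occupancy_amplitude < 1,
            motif_bias_up > 0, motif_bias_down > 0,
            train_frac_oc > 0, train_frac_oc < 1)
  if (!is.null(cnv_segments)) {
    stopifnot(is.data.frame(cnv_segments),
              all(c("chrom", "start", "end", "copy_ratio") %in%
                    names(cnv_segments)))
    if (nrow(cnv_segments) == 0) cnv_segments <- NULL
  }
  min_span <- 2e6
  if (!is.null(cnv_segments)) {
    if (!all(cnv_segments$chrom %in% names(chrom_lengths))) {
      stop("planted CNV segment on unknown chromosome", call. = FALSE)
    }
    span <- cnv_segments$end - cnv_segments$start
    if (any(span < min_span)) {
      stop("planted CNV segments must span at least 2 Mb", call. = FALSE)
    }
    if (any(cnv_segments$start < 0) ||
        any(cnv_segments$end > chrom_lengths[cnv_segments$chrom])) {
      stop("planted CNV segment exceeds chromosome bounds", call. = FALSE)
    }
    if (any(chrom_lengths[unique(cnv_segments$chrom)] < 2 * min_span)) {
      stop("chromosome carrying a planted CNV segment must be at least ",
           "twice the 2 Mb minimum span", call. = FALSE)
    }
    if (any(cnv_segments$copy_ratio <= 0)) {
      stop("copy_ratio must be positive", call. = FALSE)
    }
    o <- order(cnv_segments$chrom, cnv_segments$start)
    cs <- cnv_segments[o, , drop = FALSE]
    same <- duplicated(cs$chrom)
    if (any(same & cs$start < c(-Inf, head(cs$end, -1))[seq_len(nrow(cs))])) {
      stop("planted CNV segments must be disjoint", call. = FALSE)
    }
    cnv_segments <- cs
    rownames(cnv_segments) <- NULL
  }
  lenlaw_ok <- function(l) {
    is.list(l) && all(c("mode", "scale", "dinuc_mode", "dinuc_sd",
                        "dinuc_weight") %in% names(l)) &&
      l$mode > 0 && l$scale > 0 && l$dinuc_weight >= 0 && l$dinuc_weight < 1
  }
  stopifnot(lenlaw_ok(healthy_length), lenlaw_ok(tumor_length))
  structure(list(
    chrom_lengths = chrom_lengths,
    tss_per_chrom = as.integer(tss_per_chrom),
    tss_spacing = as.integer(tss_spacing),
    window_size = as.integer(window_size),
    cnv_segments = cnv_segments,
    n_ndr_genes = as.integer(n_ndr_genes),
    depletion_depth = depletion_depth,
    ndr_occupancy = ndr_occupancy,
    occupancy_amplitude = occupancy_amplitude,
    motif_bias_up = motif_bias_up,
    motif_bias_down = motif_bias_down,
    n_healthy = as.integer(n_healthy),
    n_tumor = as.integer(n_tumor),
    fragments_per_sample = as.integer(fragments_per_sample),
    tumor_fraction = tumor_fraction,
    healthy_length = healthy_length,
    tumor_length = tumor_length,
    train_frac_oc = train_frac_oc,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("cfDNA simulation config\n")
  cat("  genome:", length(x$chrom_lengths), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  cat("  cohort:", x$n_healthy, "HC /", x$n_tumor, "OC,",
      x$fragments_per_sample, "fragments/sample\n")
  cat("  tumor fraction:", paste(x$tumor_fraction, collapse = ", "), "\n")
  cat("  planted CNV segments:",
      if (is.null(x$cnv_segments)) 0 else nrow(x$cnv_segments), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
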