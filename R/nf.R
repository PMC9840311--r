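# Nucleosome footprint (NF) scoring at transcription start sites.

#' Per-gene nucleosome footprint score
#'
#' For each TSS the nucleosome-depleted region (NDR) is the strand-aware
#' window from -150 bp to +50 bp in the transcription frame (mirrored for
#' minus-strand genes), and the background is the +/- 2000 bp promoter
#' window minus the NDR. Depth of a region is the number of
#' fragment-base overlaps divided by the region length, and
#' `NF = (bg_depth - ndr_depth) / bg_depth` when the background has
#' coverage, else 0. A deepened promoter dip (relative NDR depletion)
#' raises NF towards its upper bound of 1.
#'
#' @param fragments a [fragment_set()].
#' @param genome a `toy_genome`, or a TSS data.frame with columns
#'   `gene_id`, `chrom`, `position`, `strand`.
#' @param ndr_upstream,ndr_downstream NDR extent (bp) upstream/downstream
#'   of the TSS in the transcription frame.
#' @param flank background half-width in bp.
#' @return an `nf_profile`: data.frame with `gene_id`, `chrom`,
#'   `position`, `strand`, `ndr_depth`, `bg_depth`, `nf`, plus a
#'   `sample_id` attribute. Genes whose background window runs off the
#'   chromosome are skipped with a warning.
#' @export
nf_score <- function(fragments, genome, ndr_upstream = 150,
                     ndr_downstream = 50, flank = 2000) {
  if (inherits(genome, "toy_genome")) {
    tss <- genome$tss
    lens <- setNames(genome$chrom$length, genome$chrom$name)
  } else {
    tss <- genome
    lens <- NULL
  }
  stopifnot(all(c("gene_id", "chrom", "position", "strand") %in% names(tss)))
  pos <- tss$position
  minus <- tss$strand == "-"
  win_s <- pos - flank
  win_e <- pos + flank
  ndr_s <- ifelse(minus, pos - ndr_downstream, pos - ndr_upstream)
  ndr_e <- ifelse(minus, pos + ndr_upstream, pos + ndr_downstream)
  keep <- win_s >= 0
  if (!is.null(lens)) keep <- keep & win_e <= lens[tss$chrom]
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) with promoter window off-chromosome ",
            "skipped", call. = FALSE)
  }
  tss <- tss[keep, , drop = FALSE]
  win_s <- win_s[keep]; win_e <- win_e[keep]
  ndr_s <- ndr_s[keep]; ndr_e <- ndr_e[keep]
  ndr_len <- ndr_upstream + ndr_downstream
  bg_len <- 2 * flank - ndr_len
  n_gene <- nrow(tss)
  ndr_ov <- win_ov <- numeric(n_gene)
  for (ch in unique(tss$chrom)) {
    gsel <- which(tss$chrom == ch)
    fsel <- fragments$chrom == ch
    if (!any(fsel)) next
    fr <- IRanges::IRanges(start = fragments$start[fsel] + 1L,
                           end = fragments$end[fsel])
    sum_overlap <- function(rs, re) {
      rg <- IRanges::IRanges(start = rs + 1L, end = re)
      h <- IRanges::findOverlaps(rg, fr)
      if (length(h) == 0) return(numeric(length(gsel)))
      qi <- S4Vectors::queryHits(h)
      si <- S4Vectors::subjectHits(h)
      ow <- pmin(IRanges::end(rg)[qi], IRanges::end(fr)[si]) -
        pmax(IRanges::start(rg)[qi], IRanges::start(fr)[si]) + 1
      as.numeric(tapply(ow, factor(qi, levels = seq_along(gsel)), sum,
                        default = 0))
    }
    ndr_ov[gsel] <- sum_overlap(ndr_s[gsel], ndr_e[gsel])
    win_ov[gsel] <- sum_overlap(win_s[gsel], win_e[gsel])
  }
  bg_ov <- win_ov - ndr_ov
  ndr_depth <- ndr_ov / ndr_len
  bg_depth <- bg_ov / bg_len
  nf <- ifelse(bg_depth > 0, (bg_depth - ndr_depth) / bg_depth, 0)
  out <- data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
                    position = tss$position, strand = tss$strand,
                    ndr_depth = ndr_depth, bg_depth = bg_depth, nf = nf,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- attr(fragments, "sample_id") %||% "sample"
  class(out) <- c("nf_profile", "data.frame")
  out
}
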