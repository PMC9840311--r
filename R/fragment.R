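# Fragment-size summaries and the per-megabase short/long fragmentation
# ratio profile.

#' Tile the genome (minus Y) into fixed-size bins
#'
#' @param genome a `toy_genome`.
#' @param bin_size bin width in bp (default 1 Mb); the last bin of each
#'   chromosome may be shorter.
#' @return a `bin_scheme`: data.frame with `chrom`, `start`, `end` and a
#'   `bin_size` attribute. Bins are disjoint and cover every base exactly
#'   once.
#' @export
#' @examples
#' g <- toy_genome_from_sequences(c(chr1 = strrep("ACGT", 10)),
#'                                window_size = 8)
#' make_bins(g, bin_size = 16)
make_bins <- function(genome, bin_size = 1e6) {
  stopifnot(inherits(genome, "toy_genome"), bin_size > 0)
  lens <- setNames(genome$chrom$length, genome$chrom$name)
  lens <- lens[!grepl("Y$", names(lens))]
  bins <- window_scheme(lens, bin_size)
  attr(bins, "bin_size") <- bin_size
  class(bins) <- c("bin_scheme", "data.frame")
  bins
}

# Bin index (row of the scheme) of each fragment midpoint; hard error on
# a midpoint outside the scheme (corrupt input).
bin_of_midpoint <- function(fragments, bins) {
  bin_size <- attr(bins, "bin_size")
  chroms <- unique(bins$chrom)
  offset <- setNames(match(chroms, bins$chrom) - 1L, chroms)
  n_bins <- setNames(as.integer(table(factor(bins$chrom, levels = chroms))),
                     chroms)
  if (!all(fragments$chrom %in% chroms)) {
    stop("fragment midpoint outside the bin scheme (unknown chromosome)",
         call. = FALSE)
  }
  mid <- (fragments$start + fragments$end) %/% 2
  within <- mid %/% bin_size
  if (any(within >= n_bins[fragments$chrom] | mid < 0)) {
    stop("fragment midpoint outside the bin scheme", call. = FALSE)
  }
  as.integer(offset[fragments$chrom] + within + 1L)
}

#' Per-bin short/long fragmentation profile
#'
#' Assigns each fragment to the bin containing its midpoint
#' (`floor((start + end) / 2)`), counts short (90-150 bp, inclusive) and
#' long (151-220 bp) fragments per bin, and forms the pseudocounted ratio
#' `(n_short + 0.5) / (n_long + 0.5)`. Lengths outside 90-220 bp
#' contribute to neither count; the mean insert size averages all
#' fragment lengths without restriction.
#'
#' @param fragments a [fragment_set()].
#' @param bins a [make_bins()] scheme from the same genome.
#' @return a `fragmentation_profile`: list with `sample_id`, `bins`
#'   (data.frame `chrom`, `start`, `end`, `n_short`, `n_long`, `ratio`),
#'   and `mean_insert_size`.
#' @export
fragmentation_profile <- function(fragments, bins) {
  stopifnot(inherits(bins, "bin_scheme"))
  len <- fragment_lengths(fragments)
  idx <- bin_of_midpoint(fragments, bins)
  nb <- nrow(bins)
  n_short <- tabulate(idx[len >= 90 & len <= 150], nb)
  n_long <- tabulate(idx[len >= 151 & len <= 220], nb)
  out_bins <- data.frame(chrom = bins$chrom, start = bins$start,
                         end = bins$end, n_short = n_short, n_long = n_long,
                         ratio = (n_short + 0.5) / (n_long + 0.5),
                         stringsAsFactors = FALSE)
  structure(list(sample_id = attr(fragments, "sample_id") %||% "sample",
                 bins = out_bins,
                 mean_insert_size = if (length(len)) mean(len) else NA_real_),
            class = "fragmentation_profile")
}

#' @export
print.fragmentation_profile <- function(x, ...) {
  cat("fragmentation profile:", x$sample_id, "-", nrow(x$bins), "bins,",
      sprintf("mean insert %.1f bp\n", x$mean_insert_size))
  invisible(x)
}
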