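# 5'-end 4-mer motif profiling.

#' Enumerate the 256-dimensional 4-mer motif space
#'
#' All 4-mers over {A, C, G, T} in lexicographic order, the fixed feature
#' order of every motif profile.
#'
#' @return character vector of length 256, `"AAAA"` first, `"TTTT"` last.
#' @export
#' @examples
#' head(enumerate_motifs())
enumerate_motifs <- function() {
  bases <- c("A", "C", "G", "T")
  idx <- 0:255
  paste0(bases[idx %/% 64 + 1], bases[idx %/% 16 %% 4 + 1],
         bases[idx %/% 4 %% 4 + 1], bases[idx %% 4 + 1])
}

#' 5'-end motif frequency profile of a sample
#'
#' Each double-stranded fragment contributes two 5' termini: the
#' plus-strand end motif is the reference 4-mer at `[start, start + 4)`,
#' and the minus-strand end motif is the reverse complement of the
#' reference 4-mer at `[end - 4, end)`. Ends whose 4-mer window runs off
#' the chromosome or contains a non-ACGT base are skipped.
#'
#' @param fragments a [fragment_set()].
#' @param genome a `toy_genome` (or [toy_genome_from_sequences()] object)
#'   providing reference sequence.
#' @return a `motif_profile`: list with `sample_id`, `frequencies` (named
#'   numeric of length 256 summing to 1 when any end was counted), and
#'   `n_ends_counted`.
#' @export
motif_profile <- function(fragments, genome) {
  stopifnot(inherits(genome, "toy_genome"))
  motifs <- enumerate_motifs()
  counts <- integer(256)
  n_ends <- 0L
  lens <- setNames(genome$chrom$length, genome$chrom$name)
  if (nrow(fragments)) {
    if (!all(fragments$chrom %in% names(lens))) {
      stop("fragment on chromosome absent from genome", call. = FALSE)
    }
    for (ch in unique(fragments$chrom)) {
      sel <- fragments$chrom == ch
      s <- fragments$start[sel]
      e <- fragments$end[sel]
      code <- genome$code[[ch]]
      len <- lens[[ch]]
      plus_ok <- s + 4 <= len
      minus_ok <- e - 4 >= 0
      if (any(plus_ok)) {
        v <- motif_index_plus(code, s[plus_ok])
        v <- v[!is.na(v)]
        counts <- counts + tabulate(v, 256L)
        n_ends <- n_ends + length(v)
      }
      if (any(minus_ok)) {
        v <- motif_index_minus(code, e[minus_ok])
        v <- v[!is.na(v)]
        counts <- counts + tabulate(v, 256L)
        n_ends <- n_ends + length(v)
      }
    }
  }
  freq <- if (n_ends > 0) counts / n_ends else rep(0, 256)
  out <- list(sample_id = attr(fragments, "sample_id") %||% "sample",
              frequencies = setNames(freq, motifs),
              n_ends_counted = n_ends)
  class(out) <- "motif_profile"
  if (n_ends == 0L) {
    attr(out, "empty") <- TRUE
    warning("no countable 5' ends; motif profile is all-zero",
            call. = FALSE)
  }
  out
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("5'-end motif profile:", x$sample_id, "-", x$n_ends_counted,
      "ends counted\n")
  top <- sort(x$frequencies, decreasing = TRUE)[1:5]
  cat("  top motifs:", paste(sprintf("%s=%.4f", names(top), top),
                             collapse = " "), "\n")
  invisible(x)
}
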