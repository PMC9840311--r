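# Copy-number feature: 2-kb window depth, GC correction, healthy baseline
# panel, segment calling and the scalar CNV burden score.

#' Per-window fragment depth
#'
#' Counts fragments per 2-kb genome window (the window scheme of the
#' genome's GC track) by midpoint, then normalizes to mean 1.0 across
#' windows.
#'
#' @param fragments a [fragment_set()].
#' @param genome a `toy_genome`.
#' @return a `depth_vector`: data.frame with `chrom`, `start`, `end`,
#'   `gc`, `raw` (fragment count) and `depth` (normalized, mean 1.0).
#' @export
window_depth <- function(fragments, genome) {
  stopifnot(inherits(genome, "toy_genome"))
  bins <- genome$gc
  attr(bins, "bin_size") <- genome$window_size
  idx <- bin_of_midpoint(fragments, bins)
  raw <- tabulate(idx, nrow(bins))
  if (sum(raw) == 0) stop("sample has no fragments in any window",
                          call. = FALSE)
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    gc = bins$gc, raw = raw, depth = raw / mean(raw),
                    stringsAsFactors = FALSE)
  class(out) <- c("depth_vector", "data.frame")
  out
}

# GC decile groups with small groups (< min_size windows) merged into a
# neighbour; returns an integer group id per window.
gc_groups <- function(gc, n_groups = 10, min_size = 10) {
  br <- unique(quantile(gc, probs = seq(0, 1, length.out = n_groups + 1),
                        names = FALSE))
  if (length(br) < 3) return(rep(1L, length(gc)))
  grp <- as.integer(cut(gc, breaks = br, include.lowest = TRUE))
  repeat {
    tab <- table(factor(grp, levels = seq_len(max(grp))))
    small <- which(tab > 0 & tab < min_size)
    if (length(small) == 0 || length(unique(grp)) == 1) break
    s <- small[1]
    neigh <- if (s == max(grp)) s - 1L else s + 1L
    grp[grp == s] <- neigh
    grp <- match(grp, sort(unique(grp)))
  }
  grp
}

#' GC-correct a depth vector
#'
#' Windows are grouped into GC deciles; each window's depth is divided by
#' its decile's median depth and the result re-normalized to mean 1.0.
#' Deciles with fewer than 10 windows are merged with a neighbour. A
#' depth vector that is already flat across GC is returned unchanged (up
#' to normalization).
#'
#' @param depth a [window_depth()] result.
#' @param gc_track optional GC fractions per window; defaults to the `gc`
#'   column of `depth`.
#' @return the corrected `depth_vector` (attribute `gc_corrected` set).
#' @export
gc_correct <- function(depth, gc_track = NULL) {
  stopifnot(inherits(depth, "depth_vector"))
  gc <- gc_track %||% depth$gc
  stopifnot(length(gc) == nrow(depth))
  if (all(depth$depth == 0)) stop("all-zero depth; sample unusable",
                                  call. = FALSE)
  grp <- gc_groups(gc)
  med <- tapply(depth$depth, grp, median)
  med[med <= 0] <- median(depth$depth[depth$depth > 0])
  corrected <- depth$depth / as.numeric(med[as.character(grp)])
  depth$depth <- corrected / mean(corrected)
  attr(depth, "gc_corrected") <- TRUE
  depth
}

#' Healthy baseline panel for copy-number z-scoring
#'
#' Per-window mean and standard deviation of GC-corrected depth across
#' healthy samples; the standard deviation is floored at
#' `max(observed sd, 0.05 * mean)` so that no window can produce
#' unbounded z-scores.
#'
#' @param depth_list list of `depth_vector`s from at least 5 healthy
#'   samples (or a windows-by-samples numeric matrix of corrected depth).
#' @return a `baseline_panel`: list with `mu`, `sigma`, `n_panel` and the
#'   window table.
#' @export
build_baseline <- function(depth_list) {
  if (is.matrix(depth_list)) {
    mat <- depth_list
    windows <- NULL
  } else {
    stopifnot(length(depth_list) >= 1,
              all(vapply(depth_list, inherits, logical(1), "depth_vector")))
    mat <- vapply(depth_list, function(d) d$depth,
                  numeric(nrow(depth_list[[1]])))
    windows <- depth_list[[1]][, c("chrom", "start", "end")]
  }
  if (ncol(mat) < 5) {
    stop("a baseline panel needs at least 5 healthy samples", call. = FALSE)
  }
  mu <- rowMeans(mat)
  sigma <- apply(mat, 1, sd)
  sigma <- pmax(sigma, 0.05 * mu)
  sigma <- pmax(sigma, 1e-8)
  structure(list(mu = mu, sigma = sigma, n_panel = ncol(mat),
                 windows = windows),
            class = "baseline_panel")
}

# Merge one chromosome's significance calls into candidate runs: seeds are
# |z| > z_threshold windows; a run extends through adjacent windows whose
# z exceeds extension_z in the same direction, tolerating gaps of up to
# gap_tolerance windows below the extension threshold.
merge_runs <- function(ext, seed, gap_tolerance) {
  if (!any(ext)) return(NULL)
  r <- rle(ext)
  val <- r$values
  cs <- cumsum(r$lengths)
  # bridge interior FALSE runs no longer than the gap tolerance
  interior <- which(!val & r$lengths <= gap_tolerance &
                      seq_along(val) > 1 & seq_along(val) < length(val))
  val[interior] <- TRUE
  bridged <- inverse.rle(list(lengths = r$lengths, values = val))
  r2 <- rle(bridged)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  runs <- data.frame(i1 = starts[r2$values], i2 = ends[r2$values])
  has_seed <- vapply(seq_len(nrow(runs)), function(k) {
    any(seed[runs$i1[k]:runs$i2[k]])
  }, logical(1))
  runs[has_seed, , drop = FALSE]
}

#' Call copy-number segments against a baseline panel
#'
#' Computes per-window `z = (depth - mu) / sigma`. Windows with
#' `|z| > z_threshold` seed candidate segments, which extend through
#' adjacent windows with same-direction `|z| > extension_z`, tolerating
#' gaps of at most `gap_tolerance` windows below the extension threshold.
#' Merged runs spanning more than `min_span` bp are emitted, and the CNV
#' burden is `sum(|mean_z| * span_Mb) / 100` over emitted segments — zero
#' for a copy-neutral sample.
#'
#' @param depth a GC-corrected [window_depth()] vector.
#' @param panel a [build_baseline()] panel on the same window scheme.
#' @param z_threshold seed significance threshold (|z|).
#' @param extension_z extension threshold (|z|).
#' @param gap_tolerance maximum run of sub-threshold windows bridged.
#' @param min_span minimum emitted segment span in bp (2 Mb).
#' @return a `cnv_call`: list with `segments` (data.frame `chrom`,
#'   `start`, `end`, `mean_z`, `direction`), `cnv_score`, and the
#'   per-window `z`.
#' @export
call_cnv <- function(depth, panel, z_threshold = 3, extension_z = 1,
                     gap_tolerance = 2, min_span = 2e6) {
  stopifnot(inherits(depth, "depth_vector"),
            inherits(panel, "baseline_panel"),
            length(panel$mu) == nrow(depth))
  z <- (depth$depth - panel$mu) / panel$sigma
  seg_list <- list()
  for (ch in unique(depth$chrom)) {
    sel <- which(depth$chrom == ch)
    zc <- z[sel]
    for (dir in c(1, -1)) {
      ext <- dir * zc > extension_z
      seedw <- dir * zc > z_threshold
      runs <- merge_runs(ext, seedw, gap_tolerance)
      if (is.null(runs) || nrow(runs) == 0) next
      for (k in seq_len(nrow(runs))) {
        i1 <- sel[runs$i1[k]]
        i2 <- sel[runs$i2[k]]
        span <- depth$end[i2] - depth$start[i1]
        if (span > min_span) {
          seg_list[[length(seg_list) + 1]] <- data.frame(
            chrom = ch, start = depth$start[i1], end = depth$end[i2],
            mean_z = mean(z[i1:i2]),
            direction = if (dir > 0) "gain" else "loss",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  segments <- if (length(seg_list)) do.call(rbind, seg_list) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mean_z = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  score <- if (nrow(segments)) {
    sum(abs(segments$mean_z) * (segments$end - segments$start) / 1e6) / 100
  } else {
    0
  }
  structure(list(segments = segments, cnv_score = score, z = z),
            class = "cnv_call")
}

#' @export
print.cnv_call <- function(x, ...) {
  cat("CNV call:", nrow(x$segments), "segment(s), score",
      sprintf("%.4f\n", x$cnv_score))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}
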