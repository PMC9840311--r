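# Synthetic cfDNA fragment simulator.
#
# Fragments are drawn by joint rejection sampling over (start, length):
# proposal starts are uniform over the genome, and a proposal is accepted
# with probability proportional to
#   occupancy(start) * copy_ratio(midpoint) * motif_bias(5' end motifs),
# where the last two factors apply to tumor-law fragments only. Fragments
# that would extend past a chromosome end are resampled, never clipped.

#' Per-sample collection of aligned cfDNA fragments
#'
#' @param chrom,start,end fragment coordinates, 0-based half-open.
#' @param sample_id sample identifier.
#' @param label class label, `"HC"` or `"OC"`.
#' @param chrom_lengths optional named vector for bounds checking.
#' @return a `fragment_set`: a data.frame with columns `chrom`, `start`,
#'   `end` and attributes `sample_id` and `label`.
#' @export
fragment_set <- function(chrom, start, end, sample_id = "sample",
                         label = c("HC", "OC"), chrom_lengths = NULL) {
  label <- match.arg(label)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0) || any(start >= end)) {
    stop("fragment coordinates must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!is.null(chrom_lengths)) {
    if (!all(chrom %in% names(chrom_lengths))) {
      stop("fragment on unknown chromosome", call. = FALSE)
    }
    if (any(end > chrom_lengths[chrom])) {
      stop("fragment extends past chromosome end", call. = FALSE)
    }
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  attr(df, "sample_id") <- sample_id
  attr(df, "label") <- label
  class(df) <- c("fragment_set", "data.frame")
  df
}

fragment_lengths <- function(fragments) {
  fragments$end - fragments$start
}

draw_lengths <- function(n, law) {
  if (n == 0) return(integer(0))
  di <- runif(n) < law$dinuc_weight
  out <- integer(n)
  nd <- sum(di)
  if (nd) out[di] <- as.integer(round(rnorm(nd, law$dinuc_mode, law$dinuc_sd)))
  if (n - nd) out[!di] <- rdlaplace(n - nd, law$mode, law$scale)
  out
}

# Cut-site weight around TSSs: 190-bp-period phasing sinusoid inside the
# +/- 2 kb promoter window, a constant occupancy floor inside the NDR
# ([-150, +50) in the transcription frame), flat elsewhere. `depl` is the
# per-TSS NDR depletion applied (0 for the healthy chromatin state).
occupancy_values <- function(dd, in_window, ndr_occ, amp, depl) {
  occ <- rep(1, length(dd))
  in_ndr <- in_window & dd >= -150 & dd < 50
  rest <- in_window & !in_ndr
  occ[rest] <- 1 + amp * cos(2 * pi * (dd[rest] + 100) / 190)
  occ[in_ndr] <- ndr_occ * (1 - depl[in_ndr])
  occ
}

# Vectorized occupancy for positions on one chromosome.
chrom_occupancy <- function(pos, tpos, tsgn, tdepl, ndr_occ, amp, altered) {
  n <- length(pos)
  if (length(tpos) == 0) return(rep(1, n))
  j <- findInterval(pos, tpos)
  jl <- pmax(j, 1L)
  jr <- pmin(j + 1L, length(tpos))
  dl <- abs(pos - tpos[jl])
  dr <- abs(pos - tpos[jr])
  ni <- ifelse(dl <= dr, jl, jr)
  d_gen <- pos - tpos[ni]
  dd <- d_gen * tsgn[ni]
  in_window <- abs(d_gen) < 2000
  depl <- tdepl[ni] * as.numeric(altered)
  occupancy_values(dd, in_window, ndr_occ, amp, depl)
}

# 4-mer motif indices (1..256, lexicographic) of the two 5' ends; NA when
# the window holds a non-ACGT base. start/end are 0-based half-open and
# must leave the 4-mer window on the chromosome.
motif_index_plus <- function(code, start) {
  b1 <- as.integer(code[start + 1L])
  b2 <- as.integer(code[start + 2L])
  b3 <- as.integer(code[start + 3L])
  b4 <- as.integer(code[start + 4L])
  idx <- ((b1 * 4L + b2) * 4L + b3) * 4L + b4 + 1L
  idx[b1 > 3L | b2 > 3L | b3 > 3L | b4 > 3L] <- NA_integer_
  idx
}

motif_index_minus <- function(code, end) {
  c1 <- 3L - as.integer(code[end])
  c2 <- 3L - as.integer(code[end - 1L])
  c3 <- 3L - as.integer(code[end - 2L])
  c4 <- 3L - as.integer(code[end - 3L])
  idx <- ((c1 * 4L + c2) * 4L + c3) * 4L + c4 + 1L
  idx[c1 < 0L | c2 < 0L | c3 < 0L | c4 < 0L] <- NA_integer_
  idx
}

end_motif_index <- function(code, start, end) {
  list(plus = motif_index_plus(code, start),
       minus = motif_index_minus(code, end))
}

#' Simulate one cfDNA sample
#'
#' Draws `config$fragments_per_sample` fragments. An OC sample is a
#' mixture: with probability `1 - f` a fragment follows the healthy law
#' (healthy length distribution, baseline nucleosome occupancy), and with
#' probability `f` the tumor law: shorter lengths, deepened NDRs at the
#' truth set's altered genes, start regions re-weighted by planted
#' copy-number ratios, and 5' cut sites re-weighted by the tumor motif
#' bias at both fragment termini.
#'
#' @param genome a `toy_genome`.
#' @param label `"HC"` or `"OC"`.
#' @param config a [sim_config()].
#' @param seed RNG seed for this sample.
#' @param tumor_fraction scalar override of the config tumor fraction
#'   (required when the config carries a stratum vector).
#' @param sample_id sample identifier stored on the result.
#' @return a [fragment_set()] sorted by (chrom, start, end).
#' @export
simulate_sample <- function(genome, label = c("HC", "OC"), config, seed,
                            tumor_fraction = NULL, sample_id = NULL) {
  label <- match.arg(label)
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  f <- 0
  if (label == "OC") {
    f <- tumor_fraction %||% config$tumor_fraction
    if (length(f) != 1) {
      stop("a single sample needs a scalar tumor_fraction; the config ",
           "holds a stratum vector", call. = FALSE)
    }
    stopifnot(f >= 0, f <= 1)
  }
  sample_id <- sample_id %||% paste0(label, "_s", seed)
  n_target <- config$fragments_per_sample
  chroms <- genome$chrom$name
  lens <- setNames(genome$chrom$length, chroms)
  cum <- c(0, cumsum(as.numeric(lens)))
  total <- cum[length(cum)]
  amp <- config$occupancy_amplitude
  ndr_occ <- config$ndr_occupancy

  # per-chromosome TSS lookup tables
  alt <- genome$truth$ndr_altered_genes
  depl_by_gene <- setNames(rep(0, nrow(genome$tss)), genome$tss$gene_id)
  if (nrow(alt)) depl_by_gene[alt$gene_id] <- alt$depletion_depth
  tssinfo <- lapply(chroms, function(ch) {
    t <- genome$tss[genome$tss$chrom == ch, , drop = FALSE]
    o <- order(t$position)
    t <- t[o, , drop = FALSE]
    list(pos = t$position, sgn = ifelse(t$strand == "+", 1, -1),
         depl = unname(depl_by_gene[t$gene_id]))
  })
  names(tssinfo) <- chroms

  segs <- genome$truth$cnv_segments
  max_ratio <- if (is.null(segs)) 1 else max(1, segs$copy_ratio)
  bias <- unname(genome$truth$motif_bias$OC)
  use_bias <- any(bias != 1)
  max_bias <- max(bias)
  wmax_h <- 1 + amp
  wmax_t <- (1 + amp) * max_ratio * (if (use_bias) max_bias^2 else 1)

  # Each component (healthy-law / tumor-law) is rejection-sampled to its
  # own target count so differing acceptance rates cannot distort the
  # mixture fraction.
  collect_component <- function(n_needed, tumor_law) {
    law <- if (tumor_law) config$tumor_length else config$healthy_length
    wmax <- if (tumor_law) wmax_t else wmax_h
    out_ci <- integer(0); out_start <- numeric(0); out_end <- numeric(0)
    guard <- 0L
    while (length(out_ci) < n_needed) {
      guard <- guard + 1L
      if (guard > 200L) stop("fragment rejection sampling failed to converge")
      m <- min(4e6, max(5000L, ceiling((n_needed - length(out_ci)) / 0.3)))
      len <- draw_lengths(m, law)
      u <- floor(runif(m) * total)
      ci <- findInterval(u, cum, rightmost.closed = FALSE)
      start <- u - cum[ci]
      end <- start + len
      ok <- len >= 50 & len <= 600 & end <= lens[ci]
      if (!any(ok)) next
      ci <- ci[ok]; start <- start[ok]; end <- end[ok]
      w <- numeric(length(ci))
      for (k in seq_along(chroms)) {
        sel <- which(ci == k)
        if (!length(sel)) next
        ti <- tssinfo[[k]]
        w[sel] <- chrom_occupancy(start[sel], ti$pos, ti$sgn, ti$depl,
                                  ndr_occ, amp, altered = tumor_law)
        if (tumor_law) {
          if (!is.null(segs)) {
            ss <- segs[segs$chrom == chroms[k], , drop = FALSE]
            if (nrow(ss)) {
              mid <- (start[sel] + end[sel]) %/% 2
              r <- rep(1, length(mid))
              for (si in seq_len(nrow(ss))) {
                inside <- mid >= ss$start[si] & mid < ss$end[si]
                r[inside] <- ss$copy_ratio[si]
              }
              w[sel] <- w[sel] * r
            }
          }
          if (use_bias) {
            em <- end_motif_index(genome$code[[k]], start[sel], end[sel])
            wb <- ifelse(is.na(em$plus), 1, bias[em$plus]) *
              ifelse(is.na(em$minus), 1, bias[em$minus])
            w[sel] <- w[sel] * wb
          }
        }
      }
      keep <- runif(length(ci)) < w / wmax
      out_ci <- c(out_ci, ci[keep])
      out_start <- c(out_start, start[keep])
      out_end <- c(out_end, end[keep])
    }
    idx <- seq_len(n_needed)
    list(ci = out_ci[idx], start = out_start[idx], end = out_end[idx])
  }
  parts <- with_seed(seed, {
    n_tum <- rbinom(1, n_target, f)
    list(collect_component(n_target - n_tum, tumor_law = FALSE),
         collect_component(n_tum, tumor_law = TRUE))
  })
  all_ci <- c(parts[[1]]$ci, parts[[2]]$ci)
  fr <- fragment_set(chroms[all_ci],
                     c(parts[[1]]$start, parts[[2]]$start),
                     c(parts[[1]]$end, parts[[2]]$end),
                     sample_id = sample_id, label = label,
                     chrom_lengths = lens)
  o <- order(fr$chrom, fr$start, fr$end)
  fr2 <- fr[o, , drop = FALSE]
  rownames(fr2) <- NULL
  attr(fr2, "sample_id") <- sample_id
  attr(fr2, "label") <- label
  class(fr2) <- c("fragment_set", "data.frame")
  fr2
}

#' Simulate a full cohort and write it to disk
#'
#' Simulates `n_healthy` HC and `n_tumor` OC samples, assigns each sample
#' to a train/test split (HC half/half; OC by `train_frac_oc` with
#' ceiling, matching a 40/19 split of 59 cases at 2/3), cycles the
#' configured tumor-fraction strata over OC samples, writes one BED file
#' per sample plus a manifest TSV and a truth JSON, and returns the
#' cohort in memory.
#'
#' @param genome a `toy_genome` built from the same config.
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @param overwrite logical; refuse to clobber an existing manifest unless
#'   `TRUE`.
#' @return invisibly, a list with `manifest` (data.frame `sample`,
#'   `label`, `split`, `tumor_fraction`, `path`), `fragments` (named list
#'   of `fragment_set`), and `dir`.
#' @export
simulate_cohort <- function(genome, config, outdir = tempfile("cohort_"),
                            overwrite = FALSE) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  manifest_path <- file.path(outdir, "manifest.tsv")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists at ", manifest_path,
         " (use overwrite = TRUE)", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  n_h <- config$n_healthy
  n_t <- config$n_tumor
  ids <- c(sprintf("HC%03d", seq_len(n_h)), sprintf("OC%03d", seq_len(n_t)))
  labels <- c(rep("HC", n_h), rep("OC", n_t))
  n_oc_train <- as.integer(ceiling(n_t * config$train_frac_oc))
  n_hc_train <- as.integer(round(n_h / 2))
  split <- character(n_h + n_t)
  with_seed(derive_seed(config$seed, 1L), {
    split[seq_len(n_h)] <- ifelse(
      seq_len(n_h) %in% sample(n_h, n_hc_train), "train", "test")
    split[n_h + seq_len(n_t)] <- ifelse(
      seq_len(n_t) %in% sample(n_t, n_oc_train), "train", "test")
  })
  tf <- numeric(n_h + n_t)
  tf[n_h + seq_len(n_t)] <- rep_len(config$tumor_fraction, n_t)
  manifest <- data.frame(sample = ids, label = labels, split = split,
                         tumor_fraction = tf,
                         path = file.path(outdir, paste0(ids, ".bed")),
                         stringsAsFactors = FALSE)
  fragments <- vector("list", nrow(manifest))
  names(fragments) <- ids
  for (i in seq_len(nrow(manifest))) {
    fr <- simulate_sample(genome, manifest$label[i], config,
                          seed = derive_seed(config$seed, 100L + i),
                          tumor_fraction = if (manifest$label[i] == "OC")
                            manifest$tumor_fraction[i] else NULL,
                          sample_id = ids[i])
    write_fragments(fr, manifest$path[i])
    fragments[[i]] <- fr
  }
  data.table::fwrite(manifest[, c("sample", "label", "split",
                                  "tumor_fraction")],
                     manifest_path, sep = "\t")
  truth <- list(
    cnv_segments = genome$truth$cnv_segments,
    ndr_altered_genes = genome$truth$ndr_altered_genes,
    motif_bias = lapply(genome$truth$motif_bias, as.list),
    tumor_fraction = setNames(as.list(tf[labels == "OC"]),
                              ids[labels == "OC"])
  )
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              null = "null", dataframe = "columns"),
             file.path(outdir, "truth.json"))
  invisible(list(manifest = manifest, fragments = fragments, dir = outdir))
}
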