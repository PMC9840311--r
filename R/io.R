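# File formats: BED3 fragments, manifest / TSS TSVs, FASTA, hashed
# artifact TSV/JSON helpers.

#' Read cfDNA fragments from a BED file
#'
#' BED3 (0-based half-open), tab-separated; `track`/`browser`/`#` header
#' lines are skipped. Malformed records are reported with their line
#' number.
#'
#' @param path BED file path.
#' @param genome optional `toy_genome` for chromosome-bound validation.
#' @param sample_id,label stored on the result; `sample_id` defaults to
#'   the file name without extension.
#' @return a [fragment_set()].
#' @export
read_fragments <- function(path, genome = NULL, sample_id = NULL,
                           label = "HC") {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  hdr <- grepl("^(track|browser)\\b|^#", lines) | !nzchar(lines)
  lines <- lines[!hdr]
  lineno <- lineno[!hdr]
  if (length(lines) == 0) {
    return(fragment_set(character(0), numeric(0), numeric(0),
                        sample_id = sample_id %||% "empty", label = label))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    bad <- lineno[which(nfield < 3)[1]]
    stop("malformed BED record (fewer than 3 fields) at line ", bad,
         " of ", path, call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 |
                 start >= end)
  if (length(bad)) {
    stop("invalid fragment coordinates at line ", lineno[bad[1]], " of ",
         path, call. = FALSE)
  }
  if (!is.null(genome)) {
    lens <- setNames(genome$chrom$length, genome$chrom$name)
    bad <- which(!(chrom %in% names(lens)) | end > lens[chrom])
    if (length(bad)) {
      stop("fragment outside genome bounds at line ", lineno[bad[1]],
           " of ", path, call. = FALSE)
    }
  }
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  fragment_set(chrom, start, end, sample_id = sample_id, label = label)
}

#' Write cfDNA fragments as BED3
#'
#' @param fragments a [fragment_set()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(
    data.table::data.table(chrom = fragments$chrom,
                           start = as.integer(fragments$start),
                           end = as.integer(fragments$end)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest TSV
#'
#' @param path TSV with columns `sample`, `label`, `split` (and
#'   optionally `tumor_fraction`).
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t"))
  stopifnot(all(c("sample", "label", "split") %in% names(m)))
  if (!all(m$label %in% c("HC", "OC"))) {
    stop("manifest labels must be HC or OC", call. = FALSE)
  }
  if (!all(m$split %in% c("train", "test"))) {
    stop("manifest split must be train or test", call. = FALSE)
  }
  m
}

#' Write the genome to FASTA plus a TSS table
#'
#' @param genome a `toy_genome`.
#' @param fasta,tss_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genome_files <- function(genome, fasta, tss_path) {
  seqs <- Biostrings::DNAStringSet(unlist(genome$sequence))
  names(seqs) <- names(genome$sequence)
  Biostrings::writeXStringSet(seqs, fasta)
  data.table::fwrite(genome$tss, tss_path, sep = "\t")
  invisible(c(fasta = fasta, tss = tss_path))
}

#' Load a genome from FASTA plus a TSS table
#'
#' Builds a genome container (no planted truth) from a reference FASTA
#' and a tab-separated TSS annotation with columns `gene_id`, `chrom`,
#' `position`, `strand`.
#'
#' @param fasta,tss_path input paths.
#' @param window_size copy-number / GC window size in bp.
#' @return a `toy_genome`.
#' @export
genome_from_files <- function(fasta, tss_path = NULL, window_size = 2000) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tss <- if (!is.null(tss_path)) {
    as.data.frame(data.table::fread(tss_path, sep = "\t"))
  } else {
    NULL
  }
  toy_genome_from_sequences(as.character(seqs), tss = tss,
                            window_size = window_size)
}

# ---- hashed pipeline artifacts ---------------------------------------

write_hashed_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  # 17 significant digits so numeric columns round-trip exactly
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_hashed_tsv <- function(path, expect_hash = NULL) {
  if (!file.exists(path)) {
    stop("no pipeline artifact at ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1)
  hash <- sub("^# config_hash=", "", first)
  if (!is.null(expect_hash) && !identical(hash, expect_hash)) {
    stop("artifact ", basename(path), " was produced under a different ",
         "configuration (hash mismatch); refusing to mix runs",
         call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE)
  attr(df, "config_hash") <- hash
  df
}

write_hashed_json <- function(x, path, hash) {
  x$config_hash <- hash
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", dataframe = "columns"), path)
  invisible(path)
}
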