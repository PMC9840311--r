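# Samples x features container shared by the selection and model stages.

#' Samples-by-features matrix for one feature family
#'
#' @param x numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns.
#' @param labels factor or character of class labels (`HC`/`OC`).
#' @param split character vector of `train`/`test` assignments.
#' @param family one of `"motif"`, `"fragment"`, `"nf"`, `"cnv"`.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(x, labels, split,
                           family = c("motif", "fragment", "nf", "cnv")) {
  family <- match.arg(family)
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = c("HC", "OC"))
  split <- as.character(split)
  stopifnot(nrow(x) == length(labels), nrow(x) == length(split),
            all(split %in% c("train", "test")), !anyNA(labels))
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  structure(list(x = x, labels = labels, split = split, family = family),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix [%s]: %d samples x %d features (%d train / %d test)\n",
              x$family, nrow(x$x), ncol(x$x), sum(x$split == "train"),
              sum(x$split == "test")))
  invisible(x)
}

train_rows <- function(fm) fm$split == "train"

profile_matrix <- function(values_list, feature_names) {
  m <- do.call(rbind, values_list)
  colnames(m) <- feature_names
  rownames(m) <- names(values_list)
  m
}

#' Assemble per-family feature matrices for a cohort
#'
#' Runs the family's profiling operation over every sample and stacks the
#' results into a [feature_matrix()].
#'
#' @param fragments named list of [fragment_set()]s.
#' @param genome a `toy_genome`.
#' @param manifest data.frame with `sample`, `label`, `split` matching
#'   `names(fragments)`.
#' @param bins a [make_bins()] scheme (fragment family).
#' @return a [feature_matrix()] of the family.
#' @name family_matrices
NULL

#' @rdname family_matrices
#' @export
motif_matrix <- function(fragments, genome, manifest) {
  vals <- lapply(fragments, function(fr) motif_profile(fr, genome)$frequencies)
  fm <- profile_matrix(vals, enumerate_motifs())
  feature_matrix(fm[manifest$sample, , drop = FALSE], manifest$label,
                 manifest$split, "motif")
}

#' @rdname family_matrices
#' @export
fragment_matrix <- function(fragments, bins, manifest) {
  vals <- lapply(fragments, function(fr) fragmentation_profile(fr, bins)$bins$ratio)
  ids <- sprintf("%s:%d-%d", bins$chrom, bins$start, bins$end)
  fm <- profile_matrix(vals, ids)
  feature_matrix(fm[manifest$sample, , drop = FALSE], manifest$label,
                 manifest$split, "fragment")
}

#' @rdname family_matrices
#' @export
nf_matrix <- function(fragments, genome, manifest) {
  vals <- lapply(fragments, function(fr) {
    p <- nf_score(fr, genome)
    setNames(p$nf, p$gene_id)
  })
  genes <- names(vals[[1]])
  fm <- profile_matrix(lapply(vals, function(v) unname(v[genes])), genes)
  feature_matrix(fm[manifest$sample, , drop = FALSE], manifest$label,
                 manifest$split, "nf")
}
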