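# Feature selection cascade: family-specific prefilters, then
# L1-penalized logistic regression. Selection only ever sees training
# rows, except the NF zero-fraction prefilter which by design reads the
# whole cohort (it is a missingness filter, not a label contrast).

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mann-Whitney U with the normal approximation, tie correction and
#' continuity correction — the form that scales to cohort-level feature
#' screening. Degenerate inputs (all values identical) return p = 1.
#'
#' @param x,y numeric samples from the two groups.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) return(1)
  p <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  if (!is.finite(p)) p <- 1
  min(max(p, .Machine$double.xmin), 1)
}

feature_pvalues <- function(x, labels) {
  apply(x, 2, function(col) wilcoxon_rank_sum(col[labels == "OC"],
                                              col[labels == "HC"]))
}

#' NF gene prefilter
#'
#' Drops genes with an NF score of 0 in more than 10% of all samples
#' (train and test: a coverage/missingness criterion), then genes whose
#' train-set Wilcoxon p between OC and HC is >= 0.001.
#'
#' @param fm an NF [feature_matrix()].
#' @param zero_fraction_max maximum tolerated zero-NF fraction (strictly
#'   "more than" drops, so exactly 10% survives).
#' @param p_cutoff Wilcoxon significance cutoff.
#' @return character vector of surviving gene ids, with the train
#'   p-values attached as attribute `p`.
#' @export
nf_prefilter <- function(fm, zero_fraction_max = 0.10, p_cutoff = 0.001) {
  stopifnot(inherits(fm, "feature_matrix"), fm$family == "nf")
  zf <- colMeans(fm$x == 0)
  cand <- colnames(fm$x)[zf <= zero_fraction_max]
  tr <- train_rows(fm)
  p <- if (length(cand)) {
    feature_pvalues(fm$x[tr, cand, drop = FALSE], fm$labels[tr])
  } else {
    numeric(0)
  }
  keep <- cand[p < p_cutoff]
  if (length(keep) == 0) {
    warning("no NF genes survive the prefilter; NF block will be empty",
            call. = FALSE)
  }
  structure(keep, p = p[p < p_cutoff], zero_fraction = zf[keep])
}

#' Motif prefilter
#'
#' Keeps motifs whose train-set Wilcoxon p between OC and HC is < 0.05.
#'
#' @param fm a motif [feature_matrix()].
#' @param p_cutoff Wilcoxon significance cutoff.
#' @return character vector of surviving motifs with attribute `p`.
#' @export
motif_prefilter <- function(fm, p_cutoff = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"), fm$family == "motif")
  tr <- train_rows(fm)
  p <- feature_pvalues(fm$x[tr, , drop = FALSE], fm$labels[tr])
  keep <- colnames(fm$x)[p < p_cutoff]
  if (length(keep) == 0) {
    warning("no motifs survive the prefilter; motif block will be empty",
            call. = FALSE)
  }
  structure(keep, p = p[keep])
}

# Stratified fold ids: a seeded within-class shuffle, folds assigned
# cyclically so every fold sees both classes where possible.
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                    length(idx))
    }
  })
  fold
}

#' L1-penalized (LASSO) feature selection
#'
#' Standardizes candidate features by train mean/sd, fits an L1-penalized
#' logistic regression path (50-point log grid), picks the penalty at
#' minimum mean cross-validated deviance over seeded stratified folds,
#' and keeps the features with non-zero weight there.
#'
#' @param x numeric matrix of training samples by candidate features.
#' @param labels factor of `HC`/`OC` training labels.
#' @param n_folds cross-validation folds (reduced if a class is smaller).
#' @param seed RNG seed controlling fold assignment.
#' @return a `selection_result`: list with `kept`, `weight` (non-zero
#'   coefficients on the standardized scale), `lambda`, `candidates`.
#' @export
lasso_select <- function(x, labels, n_folds = 10, seed = 1) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = c("HC", "OC"))
  if (nlevels(droplevels(labels)) < 2 || min(table(labels)) < 2) {
    stop("LASSO selection needs at least 2 samples per class", call. = FALSE)
  }
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  usable <- sdev > 0
  res <- list(kept = character(0), weight = numeric(0), lambda = NA_real_,
              candidates = colnames(x))
  if (sum(usable) == 0) {
    class(res) <- "selection_result"
    return(res)
  }
  xs <- scale(x[, usable, drop = FALSE], center = mu[usable],
              scale = sdev[usable])
  y <- as.integer(labels == "OC")
  if (ncol(xs) == 1) {
    # glmnet needs >= 2 columns; a single candidate is kept iff it carries
    # any signal at all under an unpenalized fit
    fit <- suppressWarnings(glm(y ~ xs[, 1], family = binomial()))
    w <- coef(fit)[2]
    if (is.finite(w) && abs(w) > 0) {
      res$kept <- colnames(xs)
      res$weight <- setNames(unname(w), colnames(xs))
    }
    class(res) <- "selection_result"
    return(res)
  }
  n_folds <- max(3L, min(n_folds, min(table(labels))))
  foldid <- stratified_folds(labels, n_folds, seed)
  cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                          nlambda = 50, foldid = foldid,
                          standardize = FALSE, type.measure = "deviance")
  co <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  kept <- names(co)[co != 0]
  res$kept <- kept
  res$weight <- co[kept]
  res$lambda <- cv$lambda.min
  class(res) <- "selection_result"
  res
}

#' Run the family-specific selection cascade
#'
#' Order is fixed: zero-fraction filter, Wilcoxon, LASSO for NF; Wilcoxon,
#' LASSO for motifs; LASSO only for fragmentation bins. The CNV family
#' bypasses selection entirely — it enters the OC score as a direct
#' burden score. Wilcoxon and LASSO use training rows only.
#'
#' @param fm a [feature_matrix()] (family `motif`, `fragment` or `nf`).
#' @param n_folds,seed passed to [lasso_select()].
#' @return a `selection_result` with the family recorded and prefilter
#'   p-values under `$p`.
#' @export
select_features <- function(fm, n_folds = 10, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  cand <- switch(fm$family,
                 nf = nf_prefilter(fm),
                 motif = motif_prefilter(fm),
                 fragment = colnames(fm$x),
                 stop("CNV features bypass selection", call. = FALSE))
  p <- attr(cand, "p")
  cand <- as.character(cand)
  tr <- train_rows(fm)
  res <- if (length(cand) == 0) {
    structure(list(kept = character(0), weight = numeric(0),
                   lambda = NA_real_, candidates = character(0)),
              class = "selection_result")
  } else {
    lasso_select(fm$x[tr, cand, drop = FALSE], fm$labels[tr],
                 n_folds = n_folds, seed = seed)
  }
  res$family <- fm$family
  res$p <- p
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection [%s]: %d of %d candidates kept\n",
              x$family %||% "?", length(x$kept), length(x$candidates)))
  invisible(x)
}
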