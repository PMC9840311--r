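# ROC/AUC, confusion matrices and sensitivity at fixed specificity.
# Positive = OC; "score >= cutoff" predicts positive throughout.

check_two_classes <- function(labels) {
  labels <- factor(as.character(labels), levels = c("HC", "OC"))
  if (anyNA(labels) || nlevels(droplevels(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' ROC curve and AUC
#'
#' Thresholds at the unique scores (plus an all-negative sentinel); the
#' AUC is the Mann-Whitney concordance probability, with tied cross-class
#' pairs counted as 1/2.
#'
#' @param scores numeric scores, higher = more OC-like.
#' @param labels `HC`/`OC` labels.
#' @return a `roc_curve`: list with `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == "OC")
  n_neg <- sum(labels == "HC")
  tpr <- vapply(th, function(t) sum(scores >= t & labels == "OC") / n_pos,
                numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == "HC") / n_neg,
                numeric(1))
  r <- rank(scores) # midranks: ties count 1/2 in the concordance
  auc <- (sum(r[labels == "OC"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(thresholds = th, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Confusion matrix and derived rates at a cutoff
#'
#' @param scores numeric scores.
#' @param labels `HC`/`OC` labels.
#' @param cutoff decision threshold (predict OC iff `score >= cutoff`).
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `ppv`, `npv`; undefined rates (0/0) are
#'   `NA`, never 0.
#' @export
confusion_at <- function(scores, labels, cutoff) {
  labels <- factor(as.character(labels), levels = c("HC", "OC"))
  stopifnot(is.finite(cutoff) || is.infinite(cutoff))
  pred <- scores >= cutoff
  tp <- sum(pred & labels == "OC")
  fp <- sum(pred & labels == "HC")
  tn <- sum(!pred & labels == "HC")
  fn <- sum(!pred & labels == "OC")
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       accuracy = rate(tp + tn, tp + fp + tn + fn),
       ppv = rate(tp, tp + fp),
       npv = rate(tn, tn + fn))
}

#' Sensitivity at a fixed specificity
#'
#' Finds the smallest cutoff whose specificity (over all controls)
#' reaches the target, and reports the sensitivity there. A subgroup
#' restriction (e.g. a tumor-fraction stratum standing in for early
#' stage) applies to the sensitivity numerator/denominator only, while
#' specificity always uses all controls.
#'
#' @param scores numeric scores.
#' @param labels `HC`/`OC` labels.
#' @param target_spec required specificity in `[0, 1]`.
#' @param subset optional logical vector (length of `scores`) restricting
#'   which OC samples the sensitivity is computed over.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `reachable`.
#' @export
sensitivity_at_specificity <- function(scores, labels, target_spec = 0.98,
                                       subset = NULL) {
  labels <- check_two_classes(labels)
  if (is.null(subset)) subset <- rep(TRUE, length(scores))
  stopifnot(length(subset) == length(scores))
  cand <- c(-Inf, sort(unique(scores)), Inf)
  n_neg <- sum(labels == "HC")
  cutoff <- Inf
  reachable <- FALSE
  for (ct in cand) {
    spec <- sum(scores < ct & labels == "HC") / n_neg
    if (spec >= target_spec) {
      cutoff <- ct
      reachable <- TRUE
      break
    }
  }
  pos <- labels == "OC" & subset
  sens <- if (sum(pos) == 0) NA_real_ else mean(scores[pos] >= cutoff)
  spec_at <- sum(scores < cutoff & labels == "HC") / n_neg
  list(cutoff = cutoff, sensitivity = sens, specificity = spec_at,
       reachable = reachable)
}
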