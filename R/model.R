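# Per-family SVM scorers, logistic stacking and the OC score.

svm_oriented_decision <- function(fit, x, labels = NULL) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  dv
}

# Orientation sign so that higher decision values mean OC.
decision_sign <- function(dv, labels) {
  s <- mean(dv[labels == "OC"]) - mean(dv[labels == "HC"])
  if (!is.finite(s) || s == 0) 1 else sign(s)
}

# Accuracy-maximizing threshold over observed scores, ties broken toward
# higher specificity (and then the higher cutoff).
accuracy_cutoff <- function(scores, labels) {
  cand <- sort(unique(scores))
  best <- c(acc = -1, spec = -1, cut = cand[1])
  for (ct in cand) {
    pred <- scores >= ct
    acc <- mean(pred == (labels == "OC"))
    spec <- mean(!pred[labels == "HC"])
    if (acc > best["acc"] + 1e-12 ||
        (abs(acc - best["acc"]) <= 1e-12 && spec > best["spec"] + 1e-12) ||
        (abs(acc - best["acc"]) <= 1e-12 &&
         abs(spec - best["spec"]) <= 1e-12 && ct > best["cut"])) {
      best <- c(acc = acc, spec = spec, cut = ct)
    }
  }
  unname(best["cut"])
}

#' Train a per-family SVM scorer
#'
#' Linear-kernel SVM on the selected, train-standardized features. The
#' regularization constant is chosen over a logarithmic grid by seeded
#' stratified 10-fold cross-validation maximizing accuracy; decision
#' values are mapped to `[0, 1]` probabilities by a sigmoid (Platt) fit
#' on out-of-fold decision values only; the classification cutoff is the
#' train-score threshold with the highest accuracy, ties broken toward
#' higher specificity.
#'
#' @param fm a [feature_matrix()].
#' @param selection a `selection_result` for the same family.
#' @param cost_grid candidate SVM cost values.
#' @param n_folds cross-validation folds.
#' @param seed RNG seed for fold assignment.
#' @return a `feature_model`. With an empty selection the model emits a
#'   constant score of 0.5 (with a warning at training time).
#' @export
train_feature_model <- function(fm, selection,
                                cost_grid = 10^seq(-2, 2, by = 0.5),
                                n_folds = 10, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(selection, "selection_result"))
  feats <- selection$kept
  base <- list(family = fm$family, features = feats)
  if (length(feats) == 0) {
    warning(sprintf("empty %s selection: model emits a constant 0.5",
                    fm$family), call. = FALSE)
    base$constant <- TRUE
    class(base) <- "feature_model"
    return(base)
  }
  tr <- train_rows(fm)
  if (min(table(fm$labels[tr])) < 2) {
    stop("training needs at least 2 samples per class", call. = FALSE)
  }
  x <- fm$x[tr, feats, drop = FALSE]
  y <- droplevels(fm$labels[tr])
  mu <- colMeans(x)
  sdev <- pmax(apply(x, 2, sd), 1e-12)
  xs <- scale(x, center = mu, scale = sdev)
  n_folds <- max(2L, min(n_folds, min(table(y))))
  foldid <- stratified_folds(y, n_folds, seed)

  oof <- matrix(NA_real_, nrow(xs), length(cost_grid))
  acc <- numeric(length(cost_grid))
  for (ci in seq_along(cost_grid)) {
    pred_ok <- logical(nrow(xs))
    for (k in seq_len(n_folds)) {
      hold <- foldid == k
      if (!any(hold) || min(table(droplevels(y[!hold]))) < 1) next
      fit <- e1071::svm(xs[!hold, , drop = FALSE], y[!hold],
                        kernel = "linear", cost = cost_grid[ci],
                        scale = FALSE)
      dv <- svm_oriented_decision(fit, xs[hold, , drop = FALSE])
      dv <- dv * decision_sign(
        svm_oriented_decision(fit, xs[!hold, , drop = FALSE]), y[!hold])
      oof[hold, ci] <- dv
      pred_ok[hold] <- predict(fit, xs[hold, , drop = FALSE]) == y[hold]
    }
    acc[ci] <- mean(pred_ok)
  }
  best <- which(acc >= max(acc) - 1e-12)[1] # ties toward the smaller cost
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost_grid[best],
                    scale = FALSE)
  sgn <- decision_sign(svm_oriented_decision(fit, xs), y)

  # Platt scaling on out-of-fold decision values (never in-fold), with
  # Platt's smoothed targets (N+1)/(N+2) and 1/(N+2) so that perfectly
  # separated decision values cannot drive the slope to infinity
  dv_oof <- oof[, best]
  usable <- is.finite(dv_oof)
  pos <- (y == "OC")[usable]
  t_pos <- (sum(pos) + 1) / (sum(pos) + 2)
  t_neg <- 1 / (sum(!pos) + 2)
  target <- ifelse(pos, t_pos, t_neg)
  platt <- tryCatch(
    suppressWarnings(coef(glm(target ~ dv_oof[usable],
                              family = quasibinomial()))),
    error = function(e) c(0, 1))
  if (!all(is.finite(platt))) platt <- c(0, 1)
  # guard against a degenerate (sign-flipped) calibration slope
  if (platt[2] <= 0) platt <- c(0, 1)

  model <- list(family = fm$family, features = feats, center = mu,
                scale = sdev, svm = fit, sign = sgn, cost = cost_grid[best],
                cv_accuracy = acc[best], platt = unname(platt),
                constant = FALSE)
  class(model) <- "feature_model"
  train_scores <- predict(model, fm$x[tr, , drop = FALSE])
  model$cutoff <- accuracy_cutoff(train_scores, y)
  model
}

#' Score samples with a trained feature model
#'
#' @param object a `feature_model`.
#' @param newdata a [feature_matrix()] or numeric matrix containing the
#'   model's features as columns.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.feature_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else
    as.matrix(newdata)
  if (isTRUE(object$constant)) {
    return(setNames(rep(0.5, nrow(x)), rownames(x)))
  }
  xs <- scale(x[, object$features, drop = FALSE], center = object$center,
              scale = object$scale)
  dv <- svm_oriented_decision(object$svm, xs) * object$sign
  p <- plogis(object$platt[1] + object$platt[2] * dv)
  setNames(as.numeric(p), rownames(x))
}

#' Logistic integration model of the three feature scores
#'
#' Holds the stacking coefficients `Z = b0 + bNF*NF + bFrag*Fragment +
#' bMotif*Motif`. In `"paper"` mode the coefficients are the published
#' ones, `(-2.48, 2.84, 2.01, 0.56)`, provided for formula fidelity; the
#' scale of the original score inputs is not defined by the publication,
#' so `"refit"` mode (see [fit_integration()]) is what the pipeline uses
#' for classification.
#'
#' @param mode `"paper"` or `"refit"`.
#' @param coefficients named numeric `(b0, bNF, bFrag, bMotif)` (required
#'   for refit mode when constructed directly).
#' @return an `integration_model`.
#' @export
#' @examples
#' m <- integration_model("paper")
#' logistic_score(0, 0, 0, m) # plogis(-2.48)
integration_model <- function(mode = c("paper", "refit"),
                              coefficients = NULL) {
  mode <- match.arg(mode)
  if (mode == "paper") {
    coefficients <- c(b0 = -2.48, bNF = 2.84, bFrag = 2.01, bMotif = 0.56)
  } else {
    stopifnot(!is.null(coefficients), length(coefficients) == 4)
    coefficients <- setNames(as.numeric(coefficients),
                             c("b0", "bNF", "bFrag", "bMotif"))
  }
  structure(list(mode = mode, coefficients = coefficients),
            class = "integration_model")
}

#' @export
print.integration_model <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("integration model (%s): Z = %.3f + %.3f*NF + %.3f*Fragment + %.3f*Motif\n",
              x$mode, co["b0"], co["bNF"], co["bFrag"], co["bMotif"]))
  invisible(x)
}

#' Logistic score from the three per-family model scores
#'
#' `exp(Z) / (1 + exp(Z))` with `Z = b0 + bNF*nf + bFrag*fragment +
#' bMotif*motif`.
#'
#' @param nf,fragment,motif numeric score vectors.
#' @param model an [integration_model()].
#' @return probabilities in (0, 1).
#' @export
logistic_score <- function(nf, fragment, motif, model) {
  co <- unname(model$coefficients)
  unname(plogis(co[1] + co[2] * nf + co[3] * fragment + co[4] * motif))
}

#' Refit the integration coefficients on training scores
#'
#' Unpenalized 3-covariate logistic regression by maximum likelihood;
#' constant covariates get a zero coefficient, and perfect separation
#' falls back to a small ridge penalty.
#'
#' @param scores data.frame or matrix with columns `nf`, `fragment`,
#'   `motif` (training samples).
#' @param labels `HC`/`OC` labels.
#' @param seed unused randomness guard (the fit is deterministic); kept
#'   for interface symmetry.
#' @return an [integration_model()] in refit mode.
#' @export
fit_integration <- function(scores, labels, seed = 1) {
  scores <- as.data.frame(scores)
  stopifnot(all(c("nf", "fragment", "motif") %in% names(scores)))
  labels <- factor(as.character(labels), levels = c("HC", "OC"))
  stopifnot(min(table(labels)) >= 2)
  y <- as.integer(labels == "OC")
  xm <- as.matrix(scores[, c("nf", "fragment", "motif")])
  varying <- apply(xm, 2, function(col) sd(col) > 0)
  co <- c(b0 = qlogis(max(min(mean(y), 1 - 1e-9), 1e-9)),
          bNF = 0, bFrag = 0, bMotif = 0)
  if (any(varying)) {
    xv <- xm[, varying, drop = FALSE]
    fit <- suppressWarnings(glm(y ~ xv, family = binomial()))
    separated <- !fit$converged ||
      any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8) ||
      any(abs(coef(fit)[-1]) > 50, na.rm = TRUE)
    if (separated) {
      if (ncol(xv) >= 2) {
        rf <- glmnet::glmnet(xv, y, family = "binomial", alpha = 0,
                             lambda = 0.01, standardize = FALSE)
        cc <- as.matrix(coef(rf))[, 1]
      } else {
        rf <- glmnet::glmnet(cbind(xv, .dummy = 0), y, family = "binomial",
                             alpha = 0, lambda = 0.01, standardize = FALSE)
        cc <- as.matrix(coef(rf))[, 1][1:2]
      }
      if (!all(is.finite(cc))) {
        stop("integration fit failed to converge", call. = FALSE)
      }
      co["b0"] <- cc[1]
      co[c("bNF", "bFrag", "bMotif")[varying]] <- cc[-1][seq_len(ncol(xv))]
    } else {
      cc <- coef(fit)
      cc[is.na(cc)] <- 0
      co["b0"] <- cc[1]
      co[c("bNF", "bFrag", "bMotif")[varying]] <- cc[-1]
    }
  }
  integration_model("refit", co)
}

#' OC score: logistic score plus CNV burden
#'
#' @param logistic_score,cnv_score numeric vectors.
#' @return `logistic_score + cnv_score`.
#' @export
oc_score <- function(logistic_score, cnv_score) {
  logistic_score + cnv_score
}

#' Youden-optimal classification cutoff
#'
#' The threshold maximizing sensitivity + specificity over observed
#' scores (predict OC iff `score >= cutoff`), ties broken toward higher
#' specificity and then the higher cutoff.
#'
#' @param scores numeric training scores.
#' @param labels `HC`/`OC` labels.
#' @return the cutoff value.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("HC", "OC"))
  cand <- sort(unique(scores))
  best <- c(j = -Inf, spec = -1, cut = cand[1])
  for (ct in cand) {
    pred <- scores >= ct
    sens <- mean(pred[labels == "OC"])
    spec <- mean(!pred[labels == "HC"])
    j <- sens + spec
    if (j > best["j"] + 1e-12 ||
        (abs(j - best["j"]) <= 1e-12 && spec > best["spec"] + 1e-12) ||
        (abs(j - best["j"]) <= 1e-12 && abs(spec - best["spec"]) <= 1e-12 &&
         ct > best["cut"])) {
      best <- c(j = j, spec = spec, cut = ct)
    }
  }
  unname(best["cut"])
}

#' Classify OC scores at a cutoff
#'
#' @param scores numeric OC scores.
#' @param cutoff decision threshold; predict OC iff `score >= cutoff`.
#' @return factor of predicted labels (`HC`/`OC`).
#' @export
classify_oc <- function(scores, cutoff) {
  factor(ifelse(scores >= cutoff, "OC", "HC"), levels = c("HC", "OC"))
}
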