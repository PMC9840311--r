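sep_fm <- function(n = 40, seed = 61) {
  set.seed(seed)
  labels <- rep(c("HC", "OC"), each = n / 2)
  split <- rep(rep(c("train", "test"), c(3, 1)), n / 4)
  x <- cbind(f1 = ifelse(labels == "OC", 2, -2) + rnorm(n, 0, 0.1),
             f2 = rnorm(n))
  make_fm(x, labels, split, "fragment")
}

test_that("a separable problem trains to perfect accuracy at its cutoff", {
  fm <- sep_fm()
  sel <- structure(list(kept = "f1", weight = c(f1 = 1), family = "fragment",
                        candidates = c("f1", "f2")),
                   class = "selection_result")
  m <- train_feature_model(fm, sel, seed = 3)
  tr <- fm$split == "train"
  sc <- predict(m, fm)
  expect_true(all(sc >= 0 & sc <= 1))
  pred <- sc[tr] >= m$cutoff
  expect_equal(mean(pred == (fm$labels[tr] == "OC")), 1)
  # deterministic retrain
  m2 <- train_feature_model(fm, sel, seed = 3)
  expect_identical(m$cost, m2$cost)
  expect_identical(m$platt, m2$platt)
  expect_identical(m$cutoff, m2$cutoff)
  # matrix and feature_matrix inputs score identically
  expect_equal(unname(predict(m, fm$x)), unname(sc))
})

test_that("label-shuffled training gives chance-level cross-validated accuracy", {
  set.seed(62)
  n <- 60
  labels <- sample(rep(c("HC", "OC"), each = n / 2))
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  fm <- make_fm(x, labels, rep("train", n), "motif")
  sel <- structure(list(kept = colnames(x), weight = setNames(rep(1, 10),
                                                              colnames(x)),
                        family = "motif", candidates = colnames(x)),
                   class = "selection_result")
  m <- train_feature_model(fm, sel, seed = 7)
  expect_gt(m$cv_accuracy, 0.35)
  expect_lt(m$cv_accuracy, 0.65)
})

test_that("an empty selection yields a flagged constant 0.5 scorer", {
  fm <- sep_fm()
  sel <- structure(list(kept = character(0), weight = numeric(0),
                        family = "fragment", candidates = "f1"),
                   class = "selection_result")
  expect_warning(m <- train_feature_model(fm, sel), "constant 0.5")
  expect_equal(unname(predict(m, fm)), rep(0.5, nrow(fm$x)))
})

test_that("the logistic integration formula reproduces the printed arithmetic", {
  m <- integration_model("paper")
  expect_equal(m$coefficients,
               c(b0 = -2.48, bNF = 2.84, bFrag = 2.01, bMotif = 0.56))
  expect_equal(logistic_score(0, 0, 0, m), plogis(-2.48))
  expect_equal(logistic_score(1, 1, 1, m), exp(2.93) / (1 + exp(2.93)))
  # sigmoid midpoint whenever Z = 0
  m0 <- integration_model("refit", c(0, 1, 1, 1))
  expect_equal(logistic_score(0.5, -0.3, -0.2, m0), 0.5)
})

test_that("refitting on class-identical scores collapses to the prevalence model", {
  labels <- rep(c("HC", "OC"), c(30, 20))
  sc <- data.frame(nf = rep(0.4, 50), fragment = rep(0.6, 50),
                   motif = rep(0.5, 50))
  m <- fit_integration(sc, labels)
  co <- m$coefficients
  expect_equal(unname(co[c("bNF", "bFrag", "bMotif")]), c(0, 0, 0))
  expect_equal(unname(co["b0"]), qlogis(0.4), tolerance = 1e-6)
})

test_that("the Youden cutoff follows the exhaustive sweep and tie rule", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  labels <- c("HC", "HC", "OC", "OC")
  expect_equal(youden_cutoff(scores, labels), 0.8)
  # oracle: exhaustive sweep over candidate thresholds
  cand <- sort(unique(scores))
  j <- vapply(cand, function(ct) {
    mean(scores[labels == "OC"] >= ct) + mean(scores[labels == "HC"] < ct)
  }, numeric(1))
  expect_equal(youden_cutoff(scores, labels), max(cand[j == max(j)]))
  # translation equivariance
  expect_equal(youden_cutoff(scores + 3, labels), 0.8 + 3)
  pred <- classify_oc(scores, 0.8)
  expect_identical(as.character(pred), c("HC", "HC", "OC", "OC"))
  # additive identity of the OC score
  expect_equal(oc_score(c(0.2, 0.9), c(0, 0.5)), c(0.2, 1.4))
})
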