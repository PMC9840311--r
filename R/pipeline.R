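# End-to-end pipeline: simulate -> features -> select -> train -> score
# -> evaluate, with hashed on-disk artifacts.

#' Pipeline run configuration
#'
#' @param outdir output directory for all artifacts.
#' @param sim a [sim_config()] describing the genome and cohort.
#' @param n_folds cross-validation folds for selection and SVM tuning.
#' @param cost_grid SVM cost grid.
#' @param integration_mode `"refit"` (fit the stacking coefficients on
#'   training scores) or `"paper"` (use the published coefficients as-is;
#'   illustrative, since the original score scale is not defined).
#' @param target_specificity specificity at which subgroup sensitivity is
#'   reported.
#' @param overwrite allow clobbering an existing cohort in `outdir`.
#' @return a `run_config`.
#' @export
run_config <- function(outdir = tempfile("ocscore_run_"),
                       sim = sim_config(),
                       n_folds = 10,
                       cost_grid = 10^seq(-2, 2, by = 0.5),
                       integration_mode = c("refit", "paper"),
                       target_specificity = 0.98,
                       overwrite = FALSE) {
  integration_mode <- match.arg(integration_mode)
  stopifnot(inherits(sim, "sim_config"), n_folds >= 2,
            all(cost_grid > 0), target_specificity >= 0,
            target_specificity <= 1)
  cfg <- list(outdir = outdir, sim = sim, n_folds = as.integer(n_folds),
              cost_grid = cost_grid, integration_mode = integration_mode,
              target_specificity = target_specificity,
              overwrite = isTRUE(overwrite))
  cfg$hash <- hash_object(list(sim = unclass(sim), n_folds = cfg$n_folds,
                               cost_grid = cfg$cost_grid,
                               integration_mode = cfg$integration_mode,
                               target_specificity = cfg$target_specificity))
  class(cfg) <- "run_config"
  cfg
}

pipeline_stage <- function(name, outdir, expr) {
  tryCatch(expr, error = function(e) {
    try(writeLines(paste0("failed at stage: ", name),
                   file.path(outdir, "INCOMPLETE")), silent = TRUE)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

# CNV scoring for a set of samples against a panel built from training
# healthy samples only.
cnv_scores_for <- function(fragments, genome, manifest) {
  depths <- lapply(fragments, function(fr)
    gc_correct(window_depth(fr, genome)))
  panel_ids <- manifest$sample[manifest$label == "HC" &
                                 manifest$split == "train"]
  panel <- build_baseline(depths[panel_ids])
  calls <- lapply(depths, call_cnv, panel = panel)
  list(score = vapply(calls, `[[`, numeric(1), "cnv_score")[manifest$sample],
       calls = calls, panel = panel)
}

#' Run the full OC-score pipeline
#'
#' Simulates the configured cohort (genome + per-sample fragment BEDs),
#' computes the four feature families, runs the selection cascade and the
#' per-family SVM scorers on the training split, integrates the three
#' model scores through the logistic stacking model, adds the CNV burden
#' to form the OC score, picks the Youden-optimal training cutoff, and
#' evaluates on the held-out test split. All artifacts (feature matrices,
#' models, per-sample scores, evaluation report) are written to
#' `config$outdir`, each carrying the configuration hash so artifacts of
#' different runs cannot be silently mixed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `report`, `scores` (per-sample
#'   data.frame), `models`, `selections`, `manifest`, `genome`, and
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$sim$seed
  msg <- function(...) message("[ocscore] ", sprintf(...))

  msg("stage simulate: seed %d, %d HC + %d OC", seed, config$sim$n_healthy,
      config$sim$n_tumor)
  genome <- pipeline_stage("simulate", outdir, build_toy_genome(config$sim))
  cohort <- pipeline_stage("simulate", outdir,
                           simulate_cohort(genome, config$sim,
                                           file.path(outdir, "cohort"),
                                           overwrite = config$overwrite))
  manifest <- cohort$manifest
  fragments <- cohort$fragments

  msg("stage features: %d samples", nrow(manifest))
  mats <- pipeline_stage("features", outdir, {
    bins <- make_bins(genome)
    list(motif = motif_matrix(fragments, genome, manifest),
         fragment = fragment_matrix(fragments, bins, manifest),
         nf = nf_matrix(fragments, genome, manifest))
  })

  msg("stage select")
  selections <- pipeline_stage("select", outdir, {
    lapply(setNames(names(mats), names(mats)), function(fam)
      select_features(mats[[fam]], n_folds = config$n_folds,
                      seed = derive_seed(seed, match(fam, names(mats)))))
  })
  for (fam in names(selections)) {
    msg("  %s: %d features kept", fam, length(selections[[fam]]$kept))
  }

  msg("stage train")
  models <- pipeline_stage("train", outdir, {
    lapply(setNames(names(mats), names(mats)), function(fam)
      train_feature_model(mats[[fam]], selections[[fam]],
                          cost_grid = config$cost_grid,
                          n_folds = config$n_folds,
                          seed = derive_seed(seed, 20L + match(fam, names(mats)))))
  })

  msg("stage score")
  scored <- pipeline_stage("score", outdir, {
    fam_scores <- data.frame(
      nf = unname(predict(models$nf, mats$nf)),
      fragment = unname(predict(models$fragment, mats$fragment)),
      motif = unname(predict(models$motif, mats$motif)))
    cnv <- cnv_scores_for(fragments, genome, manifest)
    tr <- manifest$split == "train"
    integ <- if (config$integration_mode == "paper") {
      integration_model("paper")
    } else {
      fit_integration(fam_scores[tr, ], manifest$label[tr])
    }
    lscore <- logistic_score(fam_scores$nf, fam_scores$fragment,
                             fam_scores$motif, integ)
    oc <- oc_score(lscore, cnv$score)
    cutoff <- youden_cutoff(oc[tr], manifest$label[tr])
    scores <- data.frame(sample = manifest$sample, label = manifest$label,
                         split = manifest$split,
                         tumor_fraction = manifest$tumor_fraction,
                         nf_score = fam_scores$nf,
                         fragment_score = fam_scores$fragment,
                         motif_score = fam_scores$motif,
                         cnv_score = unname(cnv$score),
                         logistic_score = lscore, oc_score = oc,
                         predicted = as.character(classify_oc(oc, cutoff)),
                         stringsAsFactors = FALSE)
    list(scores = scores, integration = integ, cutoff = cutoff,
         panel_n = cnv$panel$n_panel)
  })
  scores <- scored$scores

  msg("stage evaluate")
  report <- pipeline_stage("evaluate", outdir, {
    te <- scores$split == "test"
    lab_te <- scores$label[te]
    auc_of <- function(v) roc_auc(v[te], lab_te)$auc
    aucs <- list(nf = auc_of(scores$nf_score),
                 fragment = auc_of(scores$fragment_score),
                 motif = auc_of(scores$motif_score),
                 cnv = auc_of(scores$cnv_score),
                 logistic = auc_of(scores$logistic_score),
                 oc = auc_of(scores$oc_score))
    conf <- confusion_at(scores$oc_score[te], lab_te, scored$cutoff)
    sas <- sensitivity_at_specificity(scores$oc_score[te], lab_te,
                                      config$target_specificity)
    strata <- sort(unique(scores$tumor_fraction[te & scores$label == "OC"]))
    subgroup <- lapply(strata, function(tf) {
      sub <- scores$tumor_fraction[te] == tf
      s <- sensitivity_at_specificity(scores$oc_score[te], lab_te,
                                      config$target_specificity,
                                      subset = sub)
      list(tumor_fraction = tf, n = sum(sub & lab_te == "OC"),
           sensitivity = s$sensitivity)
    })
    list(n_train = sum(scores$split == "train"), n_test = sum(te),
         selected = lapply(selections, function(s) length(s$kept)),
         integration = as.list(scored$integration$coefficients),
         integration_mode = scored$integration$mode,
         oc_cutoff = scored$cutoff,
         auc_test = aucs, confusion_test = conf,
         sensitivity_at_specificity = list(
           target = config$target_specificity,
           cutoff = sas$cutoff, sensitivity = sas$sensitivity,
           specificity = sas$specificity),
         subgroup_sensitivity = subgroup)
  })

  msg("stage write")
  paths <- pipeline_stage("write", outdir, {
    h <- config$hash
    p <- list()
    for (fam in names(mats)) {
      df <- data.frame(sample = manifest$sample, label = manifest$label,
                       split = manifest$split, mats[[fam]]$x,
                       check.names = FALSE, stringsAsFactors = FALSE)
      p[[paste0("features_", fam)]] <-
        write_hashed_tsv(df, file.path(outdir,
                                       paste0("features_", fam, ".tsv")), h)
    }
    model_json <- list(
      families = lapply(models, function(m) {
        if (isTRUE(m$constant)) {
          list(family = m$family, constant = TRUE)
        } else {
          list(family = m$family, features = m$features, cost = m$cost,
               cv_accuracy = m$cv_accuracy, platt = m$platt,
               cutoff = m$cutoff)
        }
      }),
      integration = list(mode = scored$integration$mode,
                         coefficients = as.list(
                           scored$integration$coefficients)),
      oc_cutoff = scored$cutoff,
      cnv_panel_n = scored$panel_n,
      seed = seed)
    p$models <- write_hashed_json(model_json,
                                  file.path(outdir, "models.json"), h)
    p$scores <- write_hashed_tsv(scores, file.path(outdir, "scores.tsv"), h)
    p$report <- write_hashed_json(report, file.path(outdir, "report.json"),
                                  h)
    p$config <- write_hashed_json(
      list(sim = unclass(config$sim)[setdiff(names(config$sim),
                                             "cnv_segments")],
           cnv_segments = config$sim$cnv_segments,
           n_folds = config$n_folds, cost_grid = config$cost_grid,
           integration_mode = config$integration_mode,
           target_specificity = config$target_specificity),
      file.path(outdir, "run_config.json"), h)
    p
  })
  unlink(file.path(outdir, "INCOMPLETE"))
  msg("done: test AUC(OC score) = %.3f", report$auc_test$oc)
  invisible(list(report = report, scores = scores, models = models,
                 selections = selections, features = mats,
                 manifest = manifest, genome = genome,
                 integration = scored$integration, cutoff = scored$cutoff,
                 paths = paths, hash = config$hash))
}

#' Read back per-sample scores written by [run_pipeline()]
#'
#' Refuses to read an artifact whose configuration hash does not match
#' the expected one.
#'
#' @param outdir pipeline output directory.
#' @param expect_hash optional hash to enforce.
#' @return data.frame of per-sample scores.
#' @export
read_scores <- function(outdir, expect_hash = NULL) {
  read_hashed_tsv(file.path(outdir, "scores.tsv"), expect_hash)
}
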