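#' Stratified case-level cross-validation folds
#'
#' Cases (not images) are the cross-validation unit: every augmented view
#' of a case inherits its case's fold, which prevents leakage between
#' near-duplicate augmented views of the same nodule. The split is
#' stratified by class: within each class, case order is shuffled and fold
#' labels are dealt round-robin, so per-fold class counts differ by at most
#' one from perfect stratification.
#'
#' @param cases list of [PhantomCase-class] / [NoduleAnnotation-class]
#'   objects, or a data.frame with \code{case_id} and \code{label} columns.
#' @param k number of folds (default 3).
#' @param seed RNG seed; the assignment is deterministic given the seed.
#' @return a list of class \code{"foldSplit"} with elements \code{k} and
#'   \code{assignment} (named integer vector: case_id -> fold).
#' @export
makeFolds <- function(cases, k = 3L, seed = 0L) {
  if (is.data.frame(cases)) {
    ids <- cases$case_id; labels <- cases$label
  } else {
    ids <- vapply(cases, caseID, character(1))
    labels <- vapply(cases, noduleLabel, character(1))
  }
  if (anyDuplicated(ids)) stop("duplicate case ids")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  for (cl in unique(labels))
    if (sum(labels == cl) < k)
      stop("fewer ", cl, " cases (", sum(labels == cl), ") than folds (", k, ")")
  set.seed(as.integer(seed))
  assignment <- integer(length(ids))
  names(assignment) <- ids
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(k = k, assignment = assignment), class = "foldSplit")
}

#' @export
print.foldSplit <- function(x, ...) {
  cat("foldSplit with", x$k, "folds over", length(x$assignment), "cases\n")
  print(table(fold = x$assignment))
  invisible(x)
}

#' Aggregate per-patch probabilities into a case-level result
#'
#' A case is predicted malignant when its aggregated malignant probability
#' is at least 0.5 (ties go to malignant). The aggregation rule over a
#' case's augmented views defaults to the arithmetic mean.
#'
#' @param patchProbs numeric vector of per-patch malignant probabilities
#'   for one case (>= 1 values in \eqn{[0, 1]}).
#' @param method \code{"mean"} or \code{"median"}.
#' @return list with \code{probability} and \code{predicted} (class label).
#' @export
aggregateCase <- function(patchProbs, method = c("mean", "median")) {
  method <- match.arg(method)
  if (length(patchProbs) < 1L) stop("empty input: no patch probabilities")
  if (any(!is.finite(patchProbs)) || any(patchProbs < 0 | patchProbs > 1))
    stop("patch probabilities must lie in [0, 1]")
  p <- switch(method, mean = mean(patchProbs), median = stats::median(patchProbs))
  list(probability = p,
       predicted = if (p >= 0.5) "malignant" else "benign")
}

#' Build case-level results from per-patch predictions
#'
#' @param patchPreds data.frame from [predictClassifier()] (columns
#'   \code{case_id}, \code{label}, \code{p_malignant}).
#' @param method aggregation method passed to [aggregateCase()].
#' @return data.frame with one row per case: case_id, truth, probability,
#'   predicted.
#' @export
caseResults <- function(patchPreds, method = "mean") {
  ids <- unique(patchPreds$case_id)
  rows <- lapply(ids, function(id) {
    sub <- patchPreds[patchPreds$case_id == id, ]
    agg <- aggregateCase(sub$p_malignant, method)
    data.frame(case_id = id, truth = sub$label[1],
               probability = agg$probability, predicted = agg$predicted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-class and overall classification accuracy
#'
#' Benign accuracy (specificity) is the fraction of benign cases predicted
#' benign; malignant accuracy (sensitivity) the fraction of malignant
#' cases predicted malignant. Percentages are also reported rounded to one
#' decimal, the convention used for tabulating results.
#'
#' @param results data.frame with \code{truth} and \code{predicted}
#'   columns (e.g. from [caseResults()]).
#' @return list with benign/malignant/overall fractions, the same as
#'   percentages rounded to one decimal (\code{benign_pct} etc.), and the
#'   confusion counts.
#' @export
classificationMetrics <- function(results) {
  for (cl in c("benign", "malignant"))
    if (!any(results$truth == cl)) stop("no ", cl, " cases in results")
  ok <- results$truth == results$predicted
  nb <- sum(results$truth == "benign")
  nm <- sum(results$truth == "malignant")
  benign <- sum(ok & results$truth == "benign") / nb
  malignant <- sum(ok & results$truth == "malignant") / nm
  overall <- mean(ok)
  list(benign = benign, malignant = malignant, overall = overall,
       benign_pct = round(100 * benign, 1),
       malignant_pct = round(100 * malignant, 1),
       overall_pct = round(100 * overall, 1),
       counts = c(benign_correct = sum(ok & results$truth == "benign"),
                  benign_total = nb,
                  malignant_correct = sum(ok & results$truth == "malignant"),
                  malignant_total = nm))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold on the aggregated malignant probability
#' over every distinct score (tied scores form a single threshold step)
#' plus the two endpoints, and integrates by the trapezoidal rule. The
#' curve is monotone nondecreasing in both coordinates and the AUC is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric malignant scores (higher = more malignant).
#' @param truth character vector of true labels.
#' @return list of class \code{"rocCurve"}: \code{points} (data.frame fpr,
#'   tpr, ordered) and \code{auc}.
#' @export
rocCurve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  pos <- truth == "malignant"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  # group tied scores into single threshold steps
  newGroup <- c(TRUE, s[-1] != s[-length(s)])
  grp <- cumsum(newGroup)
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- which(c(newGroup[-1], TRUE))
  tpr <- c(0, tp[last] / nP)
  fpr <- c(0, fp[last] / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "rocCurve")
}

#' @export
print.rocCurve <- function(x, ...) {
  cat(sprintf("rocCurve: %d points, AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

# Assert that no case contributes patches to both a training and a test
# set (leakage audit, run on every fold).
auditNoLeakage <- function(trainPatches, testPatches) {
  trainIds <- unique(vapply(trainPatches, caseID, character(1)))
  testIds <- unique(vapply(testPatches, caseID, character(1)))
  overlap <- intersect(trainIds, testIds)
  if (length(overlap))
    stop("leakage: case(s) ", paste(overlap, collapse = ", "),
         " appear in both training and test patches")
  invisible(TRUE)
}

#' Cross-validated comparison of pretraining strategies
#'
#' Runs the full pipeline per strategy per fold with shared seeds and
#' shared data splits: VOI extraction, oblique/dihedral augmentation,
#' optionally per-class Wasserstein GAN training on the fold's isolated
#' training cases followed by classifier pretraining on generated images,
#' then fine-tuning on the fold's training patches and case-level
#' evaluation on the held-out fold. Emits a comparison table with one row
#' per strategy (benign / malignant / overall accuracy and AUC).
#'
#' @param cases list of [PhantomCase-class] objects.
#' @param strategies subset of \code{c("scratch", "wgan")}.
#' @param k number of folds.
#' @param seed master seed; all stage seeds derive from it, shared across
#'   strategies so the contrast is paired.
#' @param voiResolution VOI resampling resolution in mm.
#' @param augCfg [augmentConfig()] for training/test views.
#' @param wganCfg [wganConfig()] template; its seed is re-derived per fold
#'   and class.
#' @param preCfg [pretrainConfig()] template.
#' @param ftCfg [finetuneConfig()] template.
#' @param nGenPerClass generated images per class for pretraining.
#' @param aggregate case aggregation method.
#' @param testViews \code{"augmented"} (all views of a test case) or
#'   \code{"axial"} (central axial slice only).
#' @param foldSubset optional integer vector of fold indices to run (default
#'   all); with a subset, results cover only those folds' held-out cases
#'   (a single train/test split when one fold index is given).
#' @return list of class \code{"strategyComparison"}: \code{table}
#'   (data.frame), \code{results} (per-strategy case results), \code{roc}
#'   (per-strategy [rocCurve()]), \code{folds}.
#' @export
compareStrategies <- function(cases, strategies = c("scratch", "wgan"),
                              k = 3L, seed = 0L, voiResolution = 1,
                              augCfg = augmentConfig(),
                              wganCfg = wganConfig(widths = "tiny"),
                              preCfg = pretrainConfig(),
                              ftCfg = finetuneConfig(),
                              nGenPerClass = 64L,
                              aggregate = "mean",
                              testViews = c("augmented", "axial"),
                              foldSubset = NULL) {
  strategies <- match.arg(strategies, c("scratch", "wgan"), several.ok = TRUE)
  testViews <- match.arg(testViews)
  folds <- makeFolds(cases, k = k, seed = deriveSeed(seed, "folds"))
  vois <- extractCohortVOIs(cases, resolution = voiResolution)
  names(vois) <- vapply(cases, caseID, character(1))
  isoFlags <- vapply(cases, isIsolated, logical(1))
  labels <- vapply(cases, noduleLabel, character(1))
  names(isoFlags) <- names(labels) <- names(vois)

  axialCfg <- augmentConfig(angleMin = 0, angleMax = 0, angleStep = 1,
                            tiltAxes = "x", includeAxial = TRUE,
                            symmetryOps = "r0", outSize = augCfg$outSize)

  allResults <- stats::setNames(vector("list", length(strategies)), strategies)
  runFolds <- if (is.null(foldSubset)) seq_len(folds$k) else {
    stopifnot(all(foldSubset %in% seq_len(folds$k)))
    as.integer(foldSubset)
  }
  for (f in runFolds) {
    testIds <- names(folds$assignment)[folds$assignment == f]
    trainIds <- setdiff(names(vois), testIds)
    trainPatches <- do.call(c, lapply(trainIds, function(id)
      augmentNodule(vois[[id]], augCfg)))
    testCfg <- if (testViews == "augmented") augCfg else axialCfg
    testPatches <- do.call(c, lapply(testIds, function(id)
      augmentNodule(vois[[id]], testCfg)))
    auditNoLeakage(trainPatches, testPatches)

    ftSeed <- deriveSeed(seed, "finetune", f)
    for (strat in strategies) {
      if (strat == "wgan") {
        genImgs <- list()
        for (cl in c("benign", "malignant")) {
          # GAN training selects the fold's isolated training nodules;
          # fall back to all training cases of the class if none is isolated
          clIds <- trainIds[labels[trainIds] == cl]
          ganIds <- clIds[isoFlags[clIds]]
          if (!length(ganIds)) ganIds <- clIds
          gPatches <- trainPatches[vapply(trainPatches, caseID, character(1))
                                   %in% ganIds]
          cfg <- wganCfg
          cfg$seed <- deriveSeed(seed, paste0("wgan-", cl), f)
          cfg$batchSize <- min(cfg$batchSize, length(gPatches))
          fit <- trainWGAN(gPatches, cfg)
          z <- sampleLatent(nGenPerClass, cfg,
                            seed = deriveSeed(seed, paste0("gen-", cl), f))
          genImgs[[cl]] <- generateImages(fit$generator, z)
        }
        pc <- preCfg
        pc$seed <- deriveSeed(seed, "pretrain", f)
        model0 <- pretrainClassifier(genImgs$benign, genImgs$malignant, pc)
      } else {
        model0 <- buildClassifier(preCfg$preset,
                                  seed = deriveSeed(seed, "scratch-init", f))
      }
      fc <- ftCfg
      fc$seed <- ftSeed
      model <- finetuneClassifier(model0, trainPatches, fc)
      preds <- predictClassifier(model, testPatches)
      allResults[[strat]] <- rbind(allResults[[strat]],
                                   caseResults(preds, aggregate))
    }
  }

  table <- do.call(rbind, lapply(strategies, function(strat) {
    m <- classificationMetrics(allResults[[strat]])
    roc <- rocCurve(allResults[[strat]]$probability, allResults[[strat]]$truth)
    data.frame(strategy = strat, pretraining = if (strat == "wgan") "WGAN" else "None",
               benign_pct = m$benign_pct, malignant_pct = m$malignant_pct,
               overall_pct = m$overall_pct, auc = roc$auc,
               stringsAsFactors = FALSE)
  }))
  rocs <- lapply(allResults, function(r) rocCurve(r$probability, r$truth))
  structure(list(table = table, results = allResults, roc = rocs,
                 folds = folds), class = "strategyComparison")
}

#' @export
print.strategyComparison <- function(x, ...) {
  cat("Pretraining-strategy comparison (case-level cross-validation)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Paired pretraining-benefit experiment
#'
#' The package's headline property experiment: on small synthetic cohorts,
#' does pretraining the classifier on WGAN-generated nodule images improve
#' held-out case accuracy over training from scratch? For each seed a fresh
#' phantom cohort is generated, one stratified third is held out, and both
#' strategies are trained on the remaining cases with identical seeds,
#' splits and fine-tuning schedules, differing only in initialization
#' (WGAN-pretrained vs random). Reported is the per-seed paired contrast.
#'
#' The default study conditions are CPU-scale: 20 cases (10 per class),
#' 32 x 32 working images, 1/8-width networks, a reduced view grid
#' (tilt +/-40 degrees about both axes, 4 rotations), and short training
#' schedules.
#'
#' @param nSeeds number of independent replicate seeds.
#' @param baseSeed master seed; each replicate derives its own streams.
#' @param nBenign,nMalignant cohort composition per replicate.
#' @param verbose print per-seed results as they complete.
#' @return data.frame with one row per seed: overall held-out accuracy for
#'   scratch and WGAN-pretrained arms and their difference.
#' @export
pretrainingBenefit <- function(nSeeds = 5L, baseSeed = 0L, nBenign = 10L,
                               nMalignant = 10L, verbose = FALSE) {
  phCfg <- phantomConfig(volumeShape = c(48L, 48L, 48L),
                         diameterRange = c(8, 12))
  augCfg <- augmentConfig(angleMin = -40, angleMax = 40, angleStep = 40,
                          tiltAxes = c("x", "y"),
                          symmetryOps = c("r0", "r90", "r180", "r270"),
                          outSize = 32L)
  wganCfg <- wganConfig(widths = "tiny", epochs = 15L, nCritic = 2L,
                        batchSize = 16L, lr = 5e-4)
  preCfg <- pretrainConfig(epochs = 8L, lr = 0.02, batchSize = 16L,
                           preset = "tiny")
  ftCfg <- finetuneConfig(epochs = 40L, lr = 0.02, batchSize = 16L)
  rows <- lapply(seq_len(nSeeds), function(s) {
    cohort <- generateCohort(nBenign, nMalignant, phCfg,
                             seed = deriveSeed(baseSeed, "benefit-cohort", s))
    cmp <- compareStrategies(cohort, strategies = c("scratch", "wgan"),
                             k = 3L, seed = deriveSeed(baseSeed, "benefit", s),
                             augCfg = augCfg, wganCfg = wganCfg,
                             preCfg = preCfg, ftCfg = ftCfg,
                             nGenPerClass = 64L, foldSubset = 1L)
    row <- data.frame(seed = s,
                      scratch = cmp$table$overall_pct[cmp$table$strategy == "scratch"],
                      wgan = cmp$table$overall_pct[cmp$table$strategy == "wgan"])
    row$difference <- row$wgan - row$scratch
    if (verbose) print(row, row.names = FALSE)
    row
  })
  do.call(rbind, rows)
}
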