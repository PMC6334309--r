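test_that("the full-scale architecture reproduces the printed feature-map arithmetic", {
  tr <- classifierShapeTrace("paper")
  expect_identical(tr$side[tr$type == "conv"][1], 55L)     # conv1: (227-11)/4+1
  expect_identical(tr$channels[tr$type == "conv"][1], 96L)
  expect_identical(tr$side[tr$type == "pool"][1], 27L)     # pool1: (55-3)/2+1
  expect_identical(sum(tr$type == "conv"), 5L)
  expect_identical(sum(tr$type == "pool"), 3L)
  expect_identical(sum(tr$type == "dense"), 3L)
  expect_identical(tr$channels[nrow(tr)], 2L)
  # dropout rate on the fully connected layers
  p <- classifierPreset("paper")
  drops <- Filter(function(d) d$type == "dropout", p$defs)
  expect_true(all(vapply(drops, function(d) d$p, numeric(1)) == 0.5))
})

test_that("preprocessing resizes to the working size, center-crops, and windows intensities", {
  # any 64 x 64 patch becomes a 227 x 227 input for the full-scale preset
  m <- matrix(rnorm(64 * 64, -500, 100), 64, 64)
  out <- preprocessPatch(m, "paper")
  expect_identical(dim(out), c(227L, 227L))
  expect_gte(min(out), -1); expect_lte(max(out), 1)
  # constant patch maps to the constant windowed value
  const <- matrix(-300, 64, 64)
  expect_true(all(abs(preprocessPatch(const, "tiny") -
                        huWindowToUnit(-300)) < 1e-12))
  # resizing an already-matching patch is the identity before the crop
  m256 <- matrix(rnorm(256 * 256), 256, 256)
  expect_identical(noduleGAN:::bilinearResize(m256, 256L), m256)
  expect_identical(dim(preprocessPatch(m256, "paper")), c(227L, 227L))
  expect_error(preprocessPatch(matrix(0, 4, 5), "tiny"), "square")
})

test_that("forward pass yields probabilities that sum to one", {
  cls <- buildClassifier("tiny", seed = 1L)
  set.seed(1)
  x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3, 1))
  p <- predictClassifier(cls, x)
  expect_length(p, 3L)
  expect_true(all(p >= 0 & p <= 1))
  logits <- noduleGAN:::nnForward(cls$net, x)$out
  probs <- apply(logits, 2, function(l) exp(l - max(l)) / sum(exp(l - max(l))))
  expect_equal(colSums(probs), rep(1, 3), tolerance = 1e-6)
})

test_that("fine-tuning replaces the fully connected layers and keeps the conv stack", {
  pre <- buildClassifier("tiny", seed = 2L)
  patches <- toyPatches(n = 4L, size = 32L)
  replaced <- finetuneClassifier(pre, patches,
                                 finetuneConfig(epochs = 0L, seed = 9L))
  fcIdx <- noduleGAN:::denseLayerIdx(pre$net)
  convIdx <- setdiff(seq_along(pre$net$layers), fcIdx)
  for (i in convIdx) {
    if (length(pre$net$layers[[i]]$params))
      expect_identical(replaced$net$layers[[i]]$params,
                       pre$net$layers[[i]]$params)
  }
  for (i in fcIdx)
    expect_false(isTRUE(all.equal(replaced$net$layers[[i]]$params$W,
                                  pre$net$layers[[i]]$params$W)))
  # epochs = 0 returns the replaced model unchanged and is itself reproducible
  again <- finetuneClassifier(pre, patches, finetuneConfig(epochs = 0L, seed = 9L))
  expect_identical(again$net$layers, replaced$net$layers)
})

test_that("training separates bright-vs-dark toy images within 20 epochs", {
  patches <- toyPatches(n = 32L)
  m0 <- buildClassifier("tiny", seed = 3L)
  ft <- finetuneClassifier(m0, patches,
                           finetuneConfig(epochs = 20L, lr = 0.02,
                                          batchSize = 16L, seed = 4L))
  preds <- predictClassifier(ft, patches)
  expect_identical(mean((preds$p_malignant >= 0.5) ==
                          (preds$label == "malignant")), 1)
  # all bright-side patches get p > 0.5
  expect_true(all(preds$p_malignant[preds$label == "malignant"] > 0.5))
  # inference is a pure function: dropout off, repeated calls identical
  expect_identical(predictClassifier(ft, patches)$p_malignant,
                   preds$p_malignant)
})

test_that("pretraining on generated images runs, audits balanced sampling, and transfers", {
  set.seed(8)
  genB <- array(runif(64 * 64 * 32, -1, -0.2), c(64, 64, 32, 1))
  genM <- array(runif(64 * 64 * 32, 0.2, 1), c(64, 64, 32, 1))
  pre <- pretrainClassifier(genB, genM,
                            pretrainConfig(epochs = 2L, lr = 0.02,
                                           batchSize = 16L, seed = 5L),
                            audit = TRUE)
  expect_true(all(is.finite(pre$losses)))
  expect_length(pre$losses, 2L)
  # expected minibatch class ratio equals the dataset ratio (1:1) over an epoch
  counts <- colSums(pre$batchCounts)
  expect_equal(unname(counts["benign"] / sum(counts)), 0.5, tolerance = 0.05)
  expect_error(pretrainClassifier(genB, array(0, c(64, 64, 0, 1)),
                                  pretrainConfig()), "non-empty")
})

test_that("fine-tuning is deterministic given seeds (paired runs coincide)", {
  patches <- toyPatches(n = 8L, size = 32L)
  run <- function() {
    m0 <- buildClassifier("tiny", seed = 6L)
    ft <- finetuneClassifier(m0, patches,
                             finetuneConfig(epochs = 2L, lr = 0.02,
                                            batchSize = 8L, seed = 7L))
    predictClassifier(ft, patches)$p_malignant
  }
  expect_identical(run(), run())
})
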