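#' Classifier architecture presets
#'
#' Two presets of the AlexNet-style classifier are provided:
#' \describe{
#'   \item{\code{"paper"}}{The full-scale architecture: input resized to
#'     256 x 256 then center-cropped to 227 x 227 (so the first
#'     convolution's arithmetic \eqn{(227 - 11)/4 + 1 = 55} holds), five
#'     convolution layers (96@11x11 stride 4, then 256/384/384/256), three
#'     3 x 3 stride-2 max-pooling layers, and three fully connected layers
#'     (4096/4096/2) with dropout 0.5. Feature-map contract: conv1 outputs
#'     55 x 55 x 96 and pool1 outputs 27 x 27 x 96.}
#'   \item{\code{"tiny"}}{A CPU-scale analogue with the same
#'     conv/pool/FC organization at 32 x 32 input and small channel counts,
#'     used throughout the test-scale experiments.}
#' }
#'
#' @param preset \code{"tiny"} or \code{"paper"}.
#' @return a list describing the preset: input sizes and layer definitions.
#' @export
classifierPreset <- function(preset = c("tiny", "paper")) {
  preset <- match.arg(preset)
  he <- function(k, cin) sqrt(2 / (k * k * cin))
  if (preset == "paper") {
    defs <- list(
      nnConv(1L, 96L, 11L, stride = 4L, pad = 0L, wsd = he(11, 1)),
      nnReLU(), nnPool(3L, 2L),
      nnConv(96L, 256L, 5L, stride = 1L, pad = 2L, wsd = he(5, 96)),
      nnReLU(), nnPool(3L, 2L),
      nnConv(256L, 384L, 3L, stride = 1L, pad = 1L, wsd = he(3, 256)),
      nnReLU(),
      nnConv(384L, 384L, 3L, stride = 1L, pad = 1L, wsd = he(3, 384)),
      nnReLU(),
      nnConv(384L, 256L, 3L, stride = 1L, pad = 1L, wsd = he(3, 384)),
      nnReLU(), nnPool(3L, 2L),
      nnFlatten(),
      nnDense(6L * 6L * 256L, 4096L, wsd = 0.01), nnReLU(), nnDropout(0.5),
      nnDense(4096L, 4096L, wsd = 0.01), nnReLU(), nnDropout(0.5),
      nnDense(4096L, 2L, wsd = 0.01))
    list(preset = preset, resizeTo = 256L, cropTo = 227L, defs = defs,
         dropout = 0.5)
  } else {
    defs <- list(
      nnConv(1L, 8L, 5L, stride = 1L, pad = 2L, wsd = he(5, 1)),
      nnReLU(), nnPool(2L, 2L),
      nnConv(8L, 16L, 3L, stride = 1L, pad = 1L, wsd = he(3, 8)),
      nnReLU(), nnPool(2L, 2L),
      nnConv(16L, 16L, 3L, stride = 1L, pad = 1L, wsd = he(3, 16)),
      nnReLU(), nnPool(2L, 2L),
      nnFlatten(),
      nnDense(4L * 4L * 16L, 64L, wsd = 0.05), nnReLU(), nnDropout(0.5),
      nnDense(64L, 32L, wsd = 0.05), nnReLU(), nnDropout(0.5),
      nnDense(32L, 2L, wsd = 0.05))
    list(preset = preset, resizeTo = 32L, cropTo = 32L, defs = defs,
         dropout = 0.5)
  }
}

#' Analytic shape trace of a classifier preset
#'
#' Walks the layer definitions applying the convolution/pooling size
#' arithmetic, without building any weights.
#'
#' @param preset \code{"tiny"} or \code{"paper"}.
#' @return data.frame with columns layer, type, side, channels.
#' @export
classifierShapeTrace <- function(preset = "paper") {
  p <- classifierPreset(preset)
  side <- p$cropTo; ch <- 1L
  rows <- list()
  for (i in seq_along(p$defs)) {
    d <- p$defs[[i]]
    if (d$type == "conv") {
      side <- convOutSize(side, d$k, d$stride, d$pad); ch <- d$cout
    } else if (d$type == "pool") {
      side <- (side - d$k) %/% d$stride + 1L
    } else if (d$type == "flatten") {
      ch <- side * side * ch; side <- 1L
    } else if (d$type == "dense") {
      ch <- d$dout
    }
    rows[[i]] <- data.frame(layer = i, type = d$type, side = side,
                            channels = ch)
  }
  do.call(rbind, rows)
}

#' Build a classifier network
#'
#' Convolutions use He initialization; fully connected layers use the
#' small-Gaussian convention (their weights are the ones replaced before
#' fine-tuning). The conv/pool shape contract is asserted at construction.
#'
#' @param preset \code{"tiny"} or \code{"paper"}.
#' @param seed weight-initialization seed.
#' @return a \code{"noduleClassifier"} object (network plus preset).
#' @export
buildClassifier <- function(preset = "tiny", seed = 0L) {
  p <- classifierPreset(preset)
  tr <- classifierShapeTrace(preset)
  if (preset == "paper") {
    stopifnot(tr$side[1] == 55L, tr$channels[1] == 96L, tr$side[3] == 27L)
  }
  stopifnot(tr$channels[nrow(tr)] == 2L)
  net <- nnBuild(p$defs, seed = seed)
  structure(list(net = net, preset = p$preset), class = "noduleClassifier")
}

#' @export
print.noduleClassifier <- function(x, ...) {
  tr <- classifierShapeTrace(x$preset)
  np <- sum(vapply(x$net$layers,
                   function(l) sum(vapply(l$params, length, numeric(1))), numeric(1)))
  cat(sprintf("noduleClassifier ('%s' preset): %d layers, %s parameters\n",
              x$preset, nrow(tr), format(np, big.mark = ",")))
  invisible(x)
}

denseLayerIdx <- function(net)
  which(vapply(net$layers, function(l) l$def$type == "dense", logical(1)))

#' Preprocess a nodule patch for the classifier
#'
#' Bilinear resize to the preset's working size, center crop to the input
#' size (identity resize when the patch already matches), and linear
#' mapping from the HU window to \eqn{[-1, 1]} when the patch is on the HU
#' scale. GAN-generated images are already on the unit scale; pass
#' \code{fromHU = FALSE} for those.
#'
#' @param patch a [PatchImage-class] or square numeric matrix.
#' @param preset \code{"tiny"} or \code{"paper"}.
#' @param fromHU map intensities from the HU window to \eqn{[-1, 1]}.
#' @param window HU window.
#' @return numeric matrix \code{cropTo x cropTo}.
#' @export
preprocessPatch <- function(patch, preset = "tiny", fromHU = TRUE,
                            window = c(-1000, 400)) {
  m <- if (is(patch, "PatchImage")) patch@pixels else patch
  if (nrow(m) != ncol(m)) stop("patch must be square")
  p <- classifierPreset(preset)
  m <- bilinearResize(m, p$resizeTo)
  m <- centerCrop(m, p$cropTo)
  if (fromHU) m <- huWindowToUnit(m, window)
  m
}

#' Preprocess a set of patches into a classifier input batch
#'
#' @param patches list of [PatchImage-class] / matrices, or an image array
#'   \code{c(h, w, N, 1)}.
#' @inheritParams preprocessPatch
#' @return array \code{c(cropTo, cropTo, N, 1)}.
#' @export
preprocessPatches <- function(patches, preset = "tiny", fromHU = TRUE,
                              window = c(-1000, 400)) {
  if (is.array(patches) && length(dim(patches)) == 4L)
    patches <- lapply(seq_len(dim(patches)[3]), function(i) patches[, , i, 1])
  p <- classifierPreset(preset)
  out <- array(0, c(p$cropTo, p$cropTo, length(patches), 1L))
  for (i in seq_along(patches))
    out[, , i, 1] <- preprocessPatch(patches[[i]], preset, fromHU, window)
  out
}

#' Pretraining configuration
#'
#' The staged protocol's first stage trains the full network from random
#' initialization on the two-class task over GAN-generated images. The
#' staged protocol pins hyperparameters for the fine-tuning stage only;
#' pretraining defaults here are SGD with momentum 0.9 and are freely
#' configurable.
#'
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param momentum SGD momentum.
#' @param batchSize minibatch size.
#' @param seed seed for init and shuffling.
#' @param preset classifier preset.
#' @return list of class \code{"pretrainConfig"}.
#' @export
pretrainConfig <- function(epochs = 10L, lr = 0.001, momentum = 0.9,
                           batchSize = 32L, seed = 0L, preset = "tiny") {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 preset = preset),
            class = "pretrainConfig")
}

#' Fine-tuning configuration
#'
#' Defaults follow the full-scale protocol: SGD, 30 epochs, learning rate
#' 0.0001, applied to all layers after the fully connected layers are
#' re-initialized.
#'
#' @inheritParams pretrainConfig
#' @return list of class \code{"finetuneConfig"}.
#' @export
finetuneConfig <- function(epochs = 30L, lr = 0.0001, momentum = 0.9,
                           batchSize = 32L, seed = 0L) {
  if (epochs < 0L) stop("epochs must be >= 0")
  if (lr <= 0) stop("lr must be > 0")
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "finetuneConfig")
}

# Minibatch SGD over softmax cross-entropy. Returns the trained net, the
# per-epoch mean loss, and (optionally) the per-batch class counts for
# sampling audits.
trainSoftmax <- function(net, x, y, epochs, lr, momentum, batchSize, seed,
                         audit = FALSE) {
  N <- dim(x)[3]
  state <- optInitLike(net)
  losses <- numeric(epochs)
  batchCounts <- list()
  set.seed(as.integer(seed))
  for (epoch in seq_len(epochs)) {
    perm <- sample.int(N)
    nb <- max(1L, N %/% batchSize)
    tot <- 0
    for (b in seq_len(nb)) {
      idx <- perm[((b - 1L) * batchSize + 1L):min(b * batchSize, N)]
      fw <- nnForward(net, x[, , idx, , drop = FALSE], train = TRUE, retain = TRUE)
      net <- fw$net
      sm <- softmaxCrossEntropy(fw$out, y[idx])
      bw <- nnBackward(net, fw$caches, sm$dlogits)
      upd <- sgdStep(net, bw$grads, state, lr = lr, momentum = momentum)
      net <- upd$net; state <- upd$state
      tot <- tot + sm$loss
      if (audit) batchCounts[[length(batchCounts) + 1L]] <-
          c(benign = sum(y[idx] == 1L), malignant = sum(y[idx] == 2L))
    }
    losses[epoch] <- tot / nb
  }
  list(net = net, losses = losses,
       batchCounts = if (audit) do.call(rbind, batchCounts))
}

labelToIndex <- function(labels) {
  idx <- match(labels, c("benign", "malignant"))
  if (anyNA(idx)) stop("labels must be 'benign' or 'malignant'")
  idx
}

#' Pretrain the classifier on GAN-generated nodule images
#'
#' Trains the full network from random initialization to separate
#' generated-benign from generated-malignant images.
#'
#' @param genBenign,genMalignant image arrays \code{c(64, 64, n, 1)} on the
#'   \eqn{[-1, 1]} scale (from [generateImages()]); both must be non-empty.
#' @param config a [pretrainConfig()].
#' @param audit record per-minibatch class counts.
#' @return a \code{"noduleClassifier"} with elements \code{net},
#'   \code{preset}, \code{losses} (and \code{batchCounts} when audited).
#' @export
pretrainClassifier <- function(genBenign, genMalignant,
                               config = pretrainConfig(), audit = FALSE) {
  stopifnot(inherits(config, "pretrainConfig"))
  nb <- if (is.null(dim(genBenign))) 0L else dim(genBenign)[3]
  nm <- if (is.null(dim(genMalignant))) 0L else dim(genMalignant)[3]
  if (nb == 0L || nm == 0L)
    stop("both generated classes must be non-empty (got ", nb, " benign, ",
         nm, " malignant)")
  x <- preprocessPatches(abind4(genBenign, genMalignant), preset = config$preset,
                         fromHU = FALSE)
  y <- c(rep(1L, nb), rep(2L, nm))
  cls <- buildClassifier(config$preset,
                         seed = deriveSeed(config$seed, "pretrain-init"))
  tr <- trainSoftmax(cls$net, x, y, config$epochs, config$lr, config$momentum,
                     config$batchSize, deriveSeed(config$seed, "pretrain-shuffle"),
                     audit = audit)
  structure(list(net = tr$net, preset = config$preset, losses = tr$losses,
                 batchCounts = tr$batchCounts), class = "noduleClassifier")
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[c(1, 2, 4)], db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Fine-tune a (pre)trained classifier on real nodule patches
#'
#' The transfer step of the staged protocol: the three fully connected
#' layers are replaced by fresh random weights, the convolutional stack is
#' initialized from the given model, and the whole network is then trained
#' by SGD on the real patches. With \code{epochs = 0} the replaced-FC model
#' is returned unchanged (useful for testing the replacement contract).
#'
#' @param pretrained a \code{"noduleClassifier"} (e.g. from
#'   [pretrainClassifier()], or [buildClassifier()] for scratch training).
#' @param patches list of labeled [PatchImage-class] objects on the HU
#'   scale.
#' @param config a [finetuneConfig()].
#' @return a fine-tuned \code{"noduleClassifier"}.
#' @export
finetuneClassifier <- function(pretrained, patches, config = finetuneConfig()) {
  stopifnot(inherits(config, "finetuneConfig"))
  stopifnot(inherits(pretrained, "noduleClassifier"))
  p <- classifierPreset(pretrained$preset)
  fresh <- nnBuild(p$defs, seed = deriveSeed(config$seed, "fc-reinit"))
  fcIdx <- denseLayerIdx(fresh)
  convIdx <- setdiff(seq_along(fresh$layers), fcIdx)
  net <- nnCopyLayers(fresh, pretrained$net, convIdx)
  if (config$epochs == 0L)
    return(structure(list(net = net, preset = pretrained$preset,
                          losses = numeric(0)), class = "noduleClassifier"))
  x <- preprocessPatches(patches, preset = pretrained$preset, fromHU = TRUE)
  y <- labelToIndex(vapply(patches, noduleLabel, character(1)))
  if (length(unique(y)) < 2L) stop("fine-tuning needs patches of both classes")
  tr <- trainSoftmax(net, x, y, config$epochs, config$lr, config$momentum,
                     config$batchSize, deriveSeed(config$seed, "finetune-shuffle"))
  structure(list(net = tr$net, preset = pretrained$preset, losses = tr$losses),
            class = "noduleClassifier")
}

#' Per-patch malignant probability
#'
#' Inference is deterministic: dropout is inactive, so repeated calls give
#' identical probabilities.
#'
#' @param model a \code{"noduleClassifier"}.
#' @param patches list of [PatchImage-class] objects (HU scale) or a
#'   preprocessed input array.
#' @param fromHU whether patches are on the HU scale.
#' @param chunk forward-pass batch size.
#' @return data.frame with case_id, label, orientation, symmetry_op and
#'   p_malignant (or just p_malignant for array input).
#' @export
predictClassifier <- function(model, patches, fromHU = TRUE, chunk = 64L) {
  stopifnot(inherits(model, "noduleClassifier"))
  isList <- !is.array(patches)
  x <- if (isList) preprocessPatches(patches, model$preset, fromHU) else patches
  N <- dim(x)[3]
  pm <- numeric(N)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    logits <- nnForward(model$net, x[, , idx, , drop = FALSE], train = FALSE)$out
    e <- exp(sweep(logits, 2, apply(logits, 2, max)))
    pm[idx] <- e[2, ] / colSums(e)
  }
  if (!isList) return(pm)
  data.frame(case_id = vapply(patches, caseID, character(1)),
             label = vapply(patches, noduleLabel, character(1)),
             orientation = vapply(patches, function(p) p@orientation, character(1)),
             symmetry_op = vapply(patches, function(p) p@symmetryOp, character(1)),
             p_malignant = pm, stringsAsFactors = FALSE)
}
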