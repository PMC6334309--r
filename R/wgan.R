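#' Wasserstein GAN configuration
#'
#' The generator maps a 100-d uniform latent to a 64 x 64 image through a
#' dense projection to 4 x 4 feature maps followed by four fractionally
#' strided (transposed) 5 x 5 convolutions doubling resolution each layer
#' (4 -> 8 -> 16 -> 32 -> 64), with batch normalization on every layer
#' except the output (tanh). The critic mirrors it with four strided 5 x 5
#' convolutions and a final linear map to one unbounded score. Training
#' alternates \code{nCritic} critic steps (maximize mean real score minus
#' mean generated score, clipping every critic parameter into
#' \code{[-clipValue, clipValue]} after each update) with one generator
#' step, both under RMSprop.
#'
#' @param latentDim latent dimension (default 100).
#' @param lr RMSprop learning rate (default 0.00005).
#' @param epochs training epochs (default 1000; use the \code{"tiny"} width
#'   preset and a handful of epochs for CPU work).
#' @param clipValue weight-clipping constant c (default 0.01).
#' @param nCritic critic updates per generator update (default 5).
#' @param batchSize minibatch size (default 64).
#' @param seed master seed; named sub-streams drive weight init, latent
#'   sampling and data shuffling.
#' @param widths \code{"paper"} (512/256/128/64 generator channels) or
#'   \code{"tiny"} (64/32/16/8), or an explicit integer(4).
#' @param bnCritic apply batch normalization on every critic convolution
#'   layer (the default here); set \code{FALSE} for the later convention of
#'   a normalization-free critic.
#' @param debugCheckClip assert the clipping invariant inside the training
#'   loop after every critic update.
#' @return a validated list of class \code{"wganConfig"}.
#' @export
wganConfig <- function(latentDim = 100L, lr = 0.00005, epochs = 1000L,
                       clipValue = 0.01, nCritic = 5L, batchSize = 64L,
                       seed = 0L, widths = "paper", bnCritic = TRUE,
                       debugCheckClip = FALSE) {
  if (latentDim < 1L) stop("latentDim must be >= 1")
  if (clipValue <= 0) stop("clipValue must be > 0")
  if (nCritic < 1L) stop("nCritic must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  if (epochs < 0L) stop("epochs must be >= 0")
  if (is.character(widths))
    widths <- switch(match.arg(widths, c("paper", "tiny")),
                     paper = c(512L, 256L, 128L, 64L),
                     tiny = c(64L, 32L, 16L, 8L))
  stopifnot(length(widths) == 4L)
  structure(list(latentDim = as.integer(latentDim), lr = lr,
                 epochs = as.integer(epochs), clipValue = clipValue,
                 nCritic = as.integer(nCritic),
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 widths = as.integer(widths), bnCritic = bnCritic,
                 debugCheckClip = debugCheckClip, imageSize = 64L),
            class = "wganConfig")
}

#' Generator / critic map sizes
#'
#' The layer-shape contract: spatial side doubles per generator layer and
#' halves per critic layer.
#' @param config a [wganConfig()].
#' @return integer vector \code{c(4, 8, 16, 32, 64)}.
#' @export
generatorShapes <- function(config) c(4L, 8L, 16L, 32L, 64L)

#' Build the generator network
#'
#' @param config a [wganConfig()].
#' @param seed weight-initialization seed (defaults to a stream derived from
#'   \code{config$seed}).
#' @return an opaque parameter container (class \code{"nnNet"}).
#' @export
buildGenerator <- function(config, seed = deriveSeed(config$seed, "gen-init")) {
  w <- config$widths
  defs <- list(
    nnDense(config$latentDim, 4L * 4L * w[1]),
    nnUnflatten(4L, 4L, w[1]),
    nnBN(w[1]), nnReLU(),
    nnTConv(w[1], w[2], 5L), nnBN(w[2]), nnReLU(),
    nnTConv(w[2], w[3], 5L), nnBN(w[3]), nnReLU(),
    nnTConv(w[3], w[4], 5L), nnBN(w[4]), nnReLU(),
    nnTConv(w[4], 1L, 5L), nnTanh())
  net <- nnBuild(defs, seed = seed)
  # assert the 4 -> 8 -> 16 -> 32 -> 64 contract at construction
  probe <- nnForward(net, matrix(0, config$latentDim, 1L))$out
  stopifnot(identical(dim(probe)[1:2], c(64L, 64L)))
  attr(net, "role") <- "generator"
  attr(net, "latentDim") <- config$latentDim
  net
}

#' Build the critic network
#'
#' @inheritParams buildGenerator
#' @export
buildCritic <- function(config, seed = deriveSeed(config$seed, "critic-init")) {
  w <- rev(config$widths)   # 64 -> 128 -> 256 -> 512 at paper widths
  bn <- function(c) if (config$bnCritic) list(nnBN(c)) else list()
  defs <- c(
    list(nnConv(1L, w[1], 5L, stride = 2L, pad = 2L)), bn(w[1]), list(nnLeakyReLU()),
    list(nnConv(w[1], w[2], 5L, stride = 2L, pad = 2L)), bn(w[2]), list(nnLeakyReLU()),
    list(nnConv(w[2], w[3], 5L, stride = 2L, pad = 2L)), bn(w[3]), list(nnLeakyReLU()),
    list(nnConv(w[3], w[4], 5L, stride = 2L, pad = 2L)), bn(w[4]), list(nnLeakyReLU()),
    list(nnFlatten(), nnDense(4L * 4L * w[4], 1L)))
  net <- nnBuild(defs, seed = seed)
  probe <- nnForward(net, array(0, c(64L, 64L, 1L, 1L)))$out
  stopifnot(identical(dim(probe), c(1L, 1L)))
  attr(net, "role") <- "critic"
  net
}

#' Sample latent vectors
#'
#' Entries are i.i.d. uniform on \eqn{[-1, 1]}; deterministic given the
#' seed.
#'
#' @param n number of vectors (>= 1).
#' @param config a [wganConfig()].
#' @param seed RNG seed.
#' @return matrix \code{latentDim x n}, one column per vector.
#' @export
sampleLatent <- function(n, config, seed = config$seed) {
  if (n < 1) stop("n must be >= 1")
  set.seed(as.integer(seed))
  matrix(stats::runif(n * config$latentDim, -1, 1), config$latentDim, n)
}

#' Generate images from a trained generator
#'
#' Inference mode: batch normalization uses the stored running statistics,
#' so identical latents give identical images.
#'
#' @param gen generator from [buildGenerator()] or [trainWGAN()].
#' @param latents matrix \code{latentDim x n} from [sampleLatent()].
#' @return array \code{c(64, 64, n, 1)} with values in \eqn{[-1, 1]}.
#' @export
generateImages <- function(gen, latents) {
  if (nrow(latents) != attr(gen, "latentDim"))
    stop("latent length ", nrow(latents), " does not match the generator's ",
         "latent dimension ", attr(gen, "latentDim"))
  nnForward(gen, latents, train = FALSE)$out
}

#' Score images with the critic
#'
#' The Wasserstein critic returns one unbounded real score per image (no
#' sigmoid).
#'
#' @param critic critic network.
#' @param images array \code{c(64, 64, n, 1)} (a single \code{64 x 64}
#'   matrix is promoted).
#' @param train use batch statistics in the normalization layers.
#' @return numeric vector of n scores.
#' @export
criticScore <- function(critic, images, train = FALSE) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L, 1L))
  d <- dim(images)
  if (length(d) != 4L || d[1] != 64L || d[2] != 64L)
    stop("images must be 64 x 64 (got ", paste(d[1:2], collapse = " x "), ")")
  as.numeric(nnForward(critic, images, train = train)$out)
}

#' Empirical Wasserstein-distance estimate
#'
#' Mean critic score of the real batch minus mean score of the generated
#' batch; exactly 0 on two identical batches.
#'
#' @param critic critic network.
#' @param real,fake image batches.
#' @return scalar estimate.
#' @export
wassersteinEstimate <- function(critic, real, fake) {
  mean(criticScore(critic, real)) - mean(criticScore(critic, fake))
}

treeAdd <- function(a, b) {
  for (i in seq_along(a)) for (nm in names(a[[i]]))
    a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  a
}

# One half of a critic update: forward `images` and backprop d(mean score)/d
# params scaled by `sign`/n.
criticPassGrads <- function(critic, images, sign) {
  fw <- nnForward(critic, images, train = TRUE, retain = TRUE)
  n <- ncol(fw$out)
  dout <- matrix(sign / n, 1L, n)
  bw <- nnBackward(fw$net, fw$caches, dout)
  list(net = fw$net, grads = bw$grads, meanScore = mean(fw$out))
}

#' Train a Wasserstein GAN on one class of nodule images
#'
#' Implements the weight-clipped Wasserstein objective: for each generator
#' step, the critic is updated \code{nCritic} times to maximize
#' \eqn{E[f(real)] - E[f(G(z))]} with every critic parameter clipped into
#' \eqn{[-c, c]} after each update, then the generator is updated once to
#' maximize \eqn{E[f(G(z))]}. Both use RMSprop at the configured learning
#' rate. GANs are trained per class: pass images of one class only.
#'
#' @param images either an array \code{c(64, 64, N, 1)} with values in
#'   \eqn{[-1, 1]}, or a list of [PatchImage-class] objects (which are
#'   resized to 64 x 64 and mapped from the HU window; mixed labels are an
#'   error).
#' @param config a [wganConfig()].
#' @return list with elements \code{generator}, \code{critic},
#'   \code{trace} (data.frame: epoch, step, criticLoss, genLoss,
#'   wEstimate) and \code{config}.
#' @export
trainWGAN <- function(images, config = wganConfig()) {
  stopifnot(inherits(config, "wganConfig"))
  if (is.list(images) && !is.array(images)) {
    labs <- unique(vapply(images, noduleLabel, character(1)))
    if (length(labs) > 1L)
      stop("mixed labels in WGAN training set: ", paste(labs, collapse = ", "),
           "; GANs are trained per class")
    images <- prepareWGANImages(images)
  }
  d <- dim(images)
  if (length(d) != 4L || d[1] != 64L || d[2] != 64L)
    stop("images must be a c(64, 64, N, 1) array")
  N <- d[3]
  if (N < config$batchSize)
    stop("need at least batchSize = ", config$batchSize, " images, got ", N)

  gen <- buildGenerator(config)
  critic <- buildCritic(config)
  stateG <- optInitLike(gen)
  stateC <- optInitLike(critic)
  stepsPerEpoch <- max(1L, N %/% config$batchSize)
  trace <- vector("list", config$epochs * stepsPerEpoch)
  set.seed(deriveSeed(config$seed, "wgan-train"))
  row <- 0L

  for (epoch in seq_len(config$epochs)) {
    for (step in seq_len(stepsPerEpoch)) {
      cLoss <- NA_real_
      for (j in seq_len(config$nCritic)) {
        idx <- sample.int(N, config$batchSize, replace = N < config$batchSize)
        real <- images[, , idx, , drop = FALSE]
        z <- matrix(stats::runif(config$latentDim * config$batchSize, -1, 1),
                    config$latentDim, config$batchSize)
        gfw <- nnForward(gen, z, train = TRUE, retain = FALSE)
        gen <- gfw$net
        fake <- gfw$out
        pr <- criticPassGrads(critic, real, sign = -1)    # maximize real score
        critic <- pr$net
        pf <- criticPassGrads(critic, fake, sign = +1)    # minimize fake score
        critic <- pf$net
        upd <- rmspropStep(critic, treeAdd(pr$grads, pf$grads), stateC,
                           lr = config$lr)
        critic <- nnClip(upd$net, config$clipValue)
        stateC <- upd$state
        if (config$debugCheckClip)
          stopifnot(nnMaxAbsParam(critic) <= config$clipValue + 1e-12)
        cLoss <- pf$meanScore - pr$meanScore
      }
      z <- matrix(stats::runif(config$latentDim * config$batchSize, -1, 1),
                  config$latentDim, config$batchSize)
      gfw <- nnForward(gen, z, train = TRUE, retain = TRUE)
      cfw <- nnForward(critic, gfw$out, train = TRUE, retain = TRUE)
      n <- ncol(cfw$out)
      gLoss <- -mean(cfw$out)
      dimg <- nnBackward(cfw$net, cfw$caches, matrix(-1 / n, 1L, n))$dx
      gbw <- nnBackward(gfw$net, gfw$caches, dimg)
      updG <- rmspropStep(gen, gbw$grads, stateG, lr = config$lr)
      gen <- updG$net
      stateG <- updG$state
      row <- row + 1L
      trace[[row]] <- data.frame(epoch = epoch, step = step,
                                 criticLoss = cLoss, genLoss = gLoss,
                                 wEstimate = -cLoss)
    }
  }
  trace <- if (row > 0L) do.call(rbind, trace[seq_len(row)]) else
    data.frame(epoch = integer(), step = integer(), criticLoss = numeric(),
               genLoss = numeric(), wEstimate = numeric())
  list(generator = gen, critic = critic, trace = trace, config = config)
}

#' Convert nodule patches to a WGAN training batch
#'
#' Resizes each patch to 64 x 64 and maps intensities from the HU window to
#' \eqn{[-1, 1]}.
#'
#' @param patches list of [PatchImage-class] objects.
#' @param window HU window passed to [huWindowToUnit()].
#' @return array \code{c(64, 64, N, 1)}.
#' @export
prepareWGANImages <- function(patches, window = c(-1000, 400)) {
  out <- array(0, c(64L, 64L, length(patches), 1L))
  for (i in seq_along(patches))
    out[, , i, 1] <- huWindowToUnit(bilinearResize(patches[[i]]@pixels, 64L), window)
  out
}
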