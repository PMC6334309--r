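# The training engine is validated against numerical differentiation: for a
# small network covering every parametric layer type, analytic gradients
# must match central differences.

numGradParam <- function(net, x, y, li, nm, eps = 1e-5) {
  p <- net$layers[[li]]$params[[nm]]
  g <- numeric(length(p))
  lossAt <- function(netMod) {
    out <- noduleGAN:::nnForward(netMod, x, train = TRUE, retain = FALSE)$out
    noduleGAN:::softmaxCrossEntropy(out, y)$loss
  }
  for (j in seq_along(p)) {
    n1 <- net; n1$layers[[li]]$params[[nm]][j] <- p[j] + eps
    n2 <- net; n2$layers[[li]]$params[[nm]][j] <- p[j] - eps
    g[j] <- (lossAt(n1) - lossAt(n2)) / (2 * eps)
  }
  g
}

test_that("analytic gradients match numerical differentiation for all layer types", {
  # conv / batch-norm / leaky-relu / pool / relu / flatten / dense
  defs <- list(
    noduleGAN:::nnConv(2L, 3L, 3L, stride = 1L, pad = 1L, wsd = 0.3),
    noduleGAN:::nnBN(3L), noduleGAN:::nnLeakyReLU(0.2),
    noduleGAN:::nnPool(2L, 2L),
    noduleGAN:::nnConv(3L, 4L, 3L, stride = 2L, pad = 1L, wsd = 0.3),
    noduleGAN:::nnReLU(),
    noduleGAN:::nnFlatten(),
    noduleGAN:::nnDense(2L * 2L * 4L, 3L, wsd = 0.3))
  net <- noduleGAN:::nnBuild(defs, seed = 3L)
  set.seed(1)
  x <- array(rnorm(8 * 8 * 5 * 2), c(8, 8, 5, 2))
  y <- sample(1:3, 5, replace = TRUE)
  fw <- noduleGAN:::nnForward(net, x, train = TRUE, retain = TRUE)
  sm <- noduleGAN:::softmaxCrossEntropy(fw$out, y)
  bw <- noduleGAN:::nnBackward(fw$net, fw$caches, sm$dlogits)
  for (li in seq_along(net$layers)) {
    for (nm in names(net$layers[[li]]$params)) {
      ng <- numGradParam(net, x, y, li, nm)
      ag <- as.numeric(bw$grads[[li]][[nm]])
      # conv bias feeding batch-norm has a ~0 gradient; compare absolutely then
      expect_lt(max(abs(ng - ag)), 1e-6 + 1e-4 * max(abs(ng)))
    }
  }
  # input gradient at sampled positions
  eps <- 1e-5
  for (j in sample(length(x), 25)) {
    x1 <- x; x1[j] <- x[j] + eps
    x2 <- x; x2[j] <- x[j] - eps
    l1 <- noduleGAN:::softmaxCrossEntropy(
      noduleGAN:::nnForward(net, x1, train = TRUE, retain = FALSE)$out, y)$loss
    l2 <- noduleGAN:::softmaxCrossEntropy(
      noduleGAN:::nnForward(net, x2, train = TRUE, retain = FALSE)$out, y)$loss
    expect_lt(abs((l1 - l2) / (2 * eps) - bw$dx[j]), 1e-5)
  }
})

test_that("transposed-convolution gradients match numerical differentiation", {
  defs <- list(
    noduleGAN:::nnDense(7L, 3L * 3L * 4L, wsd = 0.3),
    noduleGAN:::nnUnflatten(3L, 3L, 4L),
    noduleGAN:::nnBN(4L), noduleGAN:::nnReLU(),
    noduleGAN:::nnTConv(4L, 2L, 5L, stride = 2L, pad = 2L, outpad = 1L, wsd = 0.3),
    noduleGAN:::nnTanh(),
    noduleGAN:::nnFlatten(),
    noduleGAN:::nnDense(6L * 6L * 2L, 2L, wsd = 0.3))
  net <- noduleGAN:::nnBuild(defs, seed = 5L)
  set.seed(2)
  z <- matrix(rnorm(7 * 4), 7, 4)
  y <- sample(1:2, 4, replace = TRUE)
  fw <- noduleGAN:::nnForward(net, z, train = TRUE, retain = TRUE)
  sm <- noduleGAN:::softmaxCrossEntropy(fw$out, y)
  bw <- noduleGAN:::nnBackward(fw$net, fw$caches, sm$dlogits)
  for (li in c(1L, 3L, 5L, 8L)) {
    for (nm in names(net$layers[[li]]$params)) {
      ng <- numGradParam(net, z, y, li, nm)
      ag <- as.numeric(bw$grads[[li]][[nm]])
      expect_lt(max(abs(ng - ag)), 1e-6 + 1e-4 * max(abs(ng)))
    }
  }
})

test_that("transposed convolutions double the map size per layer", {
  defs <- list(noduleGAN:::nnTConv(8L, 4L, 5L), noduleGAN:::nnReLU(),
               noduleGAN:::nnTConv(4L, 2L, 5L), noduleGAN:::nnReLU(),
               noduleGAN:::nnTConv(2L, 1L, 5L))
  net <- noduleGAN:::nnBuild(defs, seed = 1L)
  x <- array(rnorm(4 * 4 * 2 * 8), c(4, 4, 2, 8))
  out <- noduleGAN:::nnForward(net, x)$out
  expect_identical(dim(out), c(32L, 32L, 2L, 1L))
})

test_that("max pooling arithmetic and backward scatter are exact", {
  x <- array(0, c(5, 5, 1, 1))
  x[2, 2, 1, 1] <- 7; x[4, 5, 1, 1] <- 9
  r <- noduleGAN:::ng_maxpool(x, 5L, 5L, 1L, 1L, 3L, 2L)
  expect_identical(dim(r$out), c(2L, 2L, 1L, 1L))
  expect_equal(r$out[1, 1, 1, 1], 7)
  expect_equal(r$out[2, 2, 1, 1], 9)
  dx <- noduleGAN:::ng_maxpool_backward(array(1, c(2, 2, 1, 1)), r$argmax,
                                        5L, 5L, 1L, 1L)
  # each window scatters its unit gradient onto its argmax
  expect_equal(dx[2, 2, 1, 1], 1)   # the 7 is the max of window (1,1) only
  expect_equal(dx[4, 5, 1, 1], 1)   # the 9 is the max of window (2,2)
  expect_equal(sum(dx), 4)          # four windows, four scattered units
})

test_that("softmax cross-entropy yields proper probabilities and gradients", {
  logits <- matrix(c(2, -1, 0.5, 0.5), 2, 2)
  y <- c(1L, 2L)
  sm <- noduleGAN:::softmaxCrossEntropy(logits, y)
  expect_equal(colSums(sm$probs), c(1, 1))
  expect_equal(colSums(sm$dlogits), c(0, 0), tolerance = 1e-12)
  expect_gt(sm$loss, 0)
})

test_that("parameter clipping bounds every parameter", {
  net <- noduleGAN:::nnBuild(list(noduleGAN:::nnDense(4L, 4L, wsd = 1),
                                  noduleGAN:::nnBN(4L)), seed = 1L)
  clipped <- noduleGAN:::nnClip(net, 0.01)
  expect_lte(noduleGAN:::nnMaxAbsParam(clipped), 0.01)
  expect_gt(noduleGAN:::nnMaxAbsParam(net), 0.01)  # original unchanged
})

test_that("optimizer steps move parameters in the descent direction", {
  net <- noduleGAN:::nnBuild(list(noduleGAN:::nnDense(2L, 1L, wsd = 0.5)), seed = 2L)
  x <- matrix(c(1, 0), 2, 1)
  # squared-loss gradient descent on a single weight via the engine's SGD
  state <- noduleGAN:::optInitLike(net)
  for (i in 1:50) {
    fw <- noduleGAN:::nnForward(net, x, train = TRUE, retain = TRUE)
    dout <- 2 * (fw$out - 3)
    bw <- noduleGAN:::nnBackward(fw$net, fw$caches, dout)
    upd <- noduleGAN:::sgdStep(net, bw$grads, state, lr = 0.05, momentum = 0)
    net <- upd$net; state <- upd$state
  }
  expect_equal(as.numeric(noduleGAN:::nnForward(net, x)$out), 3, tolerance = 1e-3)
})
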