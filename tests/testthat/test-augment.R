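constVOI <- function(value = -500, side = 15L) {
  new("VOICube", intensities = array(value, rep(side, 3L)), resolution = 1,
      sideMM = side, sourceCase = "c", label = "benign")
}

test_that("a zero-degree section equals the central axial slice exactly", {
  set.seed(5)
  side <- 15L
  arr <- array(rnorm(side^3), rep(side, 3L))
  voi <- new("VOICube", intensities = arr, resolution = 1, sideMM = side,
             sourceCase = "c", label = "benign")
  c0 <- (side + 1L) %/% 2L
  for (ax in c("x", "y")) {
    sec <- obliqueSlice(voi, ax, 0)
    expect_identical(dim(pixels(sec)), c(side, side))
    expect_equal(max(abs(pixels(sec) - arr[, , c0])), 0)
  }
})

test_that("a constant VOI gives a constant interior section at every angle", {
  voi <- constVOI(-321)
  for (ax in c("x", "y")) for (a in c(-40, -15, 25, 40)) {
    sec <- pixels(obliqueSlice(voi, ax, a))
    s <- nrow(sec)
    c0 <- (s + 1L) %/% 2L
    # the line through the center along the untilted in-plane axis stays
    # inside the cube at every angle (rows index the u axis, columns v)
    inner <- if (ax == "x") sec[, c0] else sec[c0, ]
    expect_lt(max(abs(inner + 321)), 1e-9)
    # everything else is a convex blend of the constant and the padding
    expect_true(all(sec >= -1024 - 1e-9 & sec <= -321 + 1e-9))
  }
})

test_that("sections at +theta and -theta agree on a mirror-symmetric VOI", {
  # build a VOI symmetric about the central axial plane: reflecting z maps
  # the +theta section plane onto the -theta plane point-by-point
  side <- 17L
  set.seed(6)
  half <- array(rnorm(side * side * 9), c(side, side, 9))
  arr <- array(0, rep(side, 3L))
  arr[, , 9:17] <- half
  arr[, , 8:1] <- half[, , 2:9]
  voi <- new("VOICube", intensities = arr, resolution = 1, sideMM = side,
             sourceCase = "c", label = "benign")
  rng <- diff(range(arr))
  for (ax in c("x", "y")) {
    p1 <- pixels(obliqueSlice(voi, ax, 25))
    p2 <- pixels(obliqueSlice(voi, ax, -25))
    expect_lt(max(abs(p1 - p2)), 1e-5 * rng)
  }
})

test_that("dihedral expansion is lossless, distinct on asymmetric input, and obeys the group law", {
  p <- asymPatch(5L)
  out <- dihedralExpand(p)
  expect_length(out, 8L)
  # identity leaves the patch unchanged
  expect_identical(pixels(out[[1]]), pixels(p))
  # all 8 images pairwise distinct for an asymmetric patch
  keys <- vapply(out, function(q) paste(pixels(q), collapse = ","), character(1))
  expect_identical(anyDuplicated(keys), 0L)
  # rotate-90 applied four times is the identity
  m <- pixels(p)
  for (i in 1:4) m <- noduleGAN:::rot90cw(m)
  expect_identical(m, pixels(p))
  # flip twice is the identity
  expect_identical(noduleGAN:::applyDihedral(
    noduleGAN:::applyDihedral(pixels(p), "r0f"), "r0f"), pixels(p))
  expect_error(dihedralExpand(p, "r45"), "symmetry")
})

test_that("the augmentation count law holds: |orientations| x |symmetry ops|", {
  voi <- constVOI(side = 9L)
  # default: 16 nonzero angles x 2 axes x 8 ops = 256
  expect_length(augmentNodule(voi, augmentConfig()), 256L)
  # faithful-text variant: one axis, 17 angles including axial, 8 ops = 136
  cfgText <- augmentConfig(tiltAxes = "x", includeAxial = TRUE)
  expect_length(augmentNodule(voi, cfgText), 136L)
  # minimal: one axial slice, identity op only
  cfg1 <- augmentConfig(angleMin = 0, angleMax = 0, angleStep = 5,
                        tiltAxes = "x", includeAxial = TRUE, symmetryOps = "r0")
  out <- augmentNodule(voi, cfg1)
  expect_length(out, 1L)
  expect_identical(out[[1]]@orientation, "axial")
  # brute-force check over a small grid of configs
  for (step in c(10, 20, 40)) for (axes in list("x", c("x", "y"))) {
    nAngles <- length(setdiff(seq(-40, 40, step), 0))
    for (ops in list("r0", c("r0", "r90f"))) {
      cfg <- augmentConfig(angleStep = step, tiltAxes = axes, symmetryOps = ops)
      expect_length(augmentNodule(voi, cfg), nAngles * length(axes) * length(ops))
    }
  }
})

test_that("no two augmented outputs share an (orientation, symmetry op) provenance pair", {
  voi <- constVOI(side = 9L)
  out <- augmentNodule(voi, augmentConfig(angleStep = 20))
  prov <- vapply(out, function(p) paste(p@orientation, p@symmetryOp), character(1))
  expect_identical(anyDuplicated(prov), 0L)
})

test_that("section intensities stay within the convex hull of VOI plus padding", {
  set.seed(7)
  side <- 13L
  arr <- array(runif(side^3, -900, 200), rep(side, 3L))
  voi <- new("VOICube", intensities = arr, resolution = 1, sideMM = side,
             sourceCase = "c", label = "benign")
  lo <- min(arr, -1024); hi <- max(arr, -1024)
  for (a in c(-40, 35)) {
    sec <- pixels(obliqueSlice(voi, "x", a))
    expect_gte(min(sec), lo - 1e-9)
    expect_lte(max(sec), hi + 1e-9)
  }
})

test_that("augmentation config invariants and angle bounds are enforced", {
  expect_error(augmentConfig(angleStep = 3), "divisible")
  expect_error(augmentConfig(tiltAxes = "z"), "tiltAxes")
  voi <- constVOI(side = 9L)
  expect_error(obliqueSlice(voi, "x", 120), "angle")
  cfgEmpty <- augmentConfig(angleMin = 0, angleMax = 0, angleStep = 5,
                            tiltAxes = "x", includeAxial = FALSE)
  expect_error(augmentNodule(voi, cfgEmpty), "empty orientation")
})
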