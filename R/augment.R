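#' The eight symmetries of a square
#'
#' Identifiers for the dihedral-4 group used for lossless 2-d augmentation:
#' rotations by 0/90/180/270 degrees, optionally composed with a horizontal
#' flip (suffix \code{"f"}).
#'
#' @return character vector of the 8 op identifiers.
#' @export
dihedralOps <- function() c("r0", "r90", "r180", "r270", "r0f", "r90f", "r180f", "r270f")

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

applyDihedral <- function(m, op) {
  if (!op %in% dihedralOps()) stop("unknown symmetry op: ", op)
  if (grepl("f$", op)) m <- m[, ncol(m):1, drop = FALSE]
  k <- switch(sub("f$", "", op), r0 = 0L, r90 = 1L, r180 = 2L, r270 = 3L)
  for (i in seq_len(k)) m <- rot90cw(m)
  m
}

#' Augmentation configuration: oblique-section grid and symmetry ops
#'
#' The default emulates an augmentation factor of 256 sections per nodule:
#' tilt angles from -40 to +40 degrees in steps of 5, excluding 0, about
#' each of the two in-plane axes (2 x 16 = 32 orientations), each expanded
#' by the 8 dihedral symmetries. A single-axis variant including the 0-degree
#' slice (17 angles x 8 ops = 136 per nodule) is available by setting
#' \code{tiltAxes = "x"} and \code{includeAxial = TRUE}.
#'
#' @param angleMin,angleMax,angleStep tilt-angle grid in degrees;
#'   \code{angleMax - angleMin} must be divisible by \code{angleStep}.
#' @param tiltAxes subset of \code{c("x", "y")}: in-plane axes the section
#'   plane is tilted about.
#' @param includeAxial include the pure 0-degree axial slice as an extra
#'   orientation.
#' @param symmetryOps subset of [dihedralOps()].
#' @param outSize optional integer; when set, every section is bilinearly
#'   resized to \code{outSize x outSize} after extraction.
#' @return a validated list of class \code{"augmentConfig"}.
#' @export
augmentConfig <- function(angleMin = -40, angleMax = 40, angleStep = 5,
                          tiltAxes = c("x", "y"), includeAxial = FALSE,
                          symmetryOps = dihedralOps(), outSize = NULL) {
  if (angleStep <= 0) stop("angleStep must be > 0")
  if (abs((angleMax - angleMin) %% angleStep) > 1e-9)
    stop("(angleMax - angleMin) must be divisible by angleStep")
  if (!all(tiltAxes %in% c("x", "y"))) stop("tiltAxes must be a subset of c('x','y')")
  if (!all(symmetryOps %in% dihedralOps()))
    stop("symmetryOps must be a subset of dihedralOps()")
  structure(list(angleMin = angleMin, angleMax = angleMax,
                 angleStep = angleStep, tiltAxes = tiltAxes,
                 includeAxial = includeAxial, symmetryOps = symmetryOps,
                 outSize = outSize),
            class = "augmentConfig")
}

#' Extract an oblique section through the VOI center
#'
#' The section plane is the central axial plane rotated by \code{angle}
#' degrees about the chosen in-plane axis, passing through the cube center.
#' It is sampled on a square grid with the cube's side length and in-plane
#' spacing equal to the VOI resolution, by trilinear interpolation; samples
#' outside the cube take the padding intensity. At 0 degrees the section is
#' exactly the central axial slice.
#'
#' @param voi a [VOICube-class].
#' @param tiltAxis \code{"x"} or \code{"y"}.
#' @param angle tilt in degrees, within \eqn{[-90, 90]}.
#' @param pad padding intensity (default -1024).
#' @return a [PatchImage-class] with provenance recorded.
#' @export
obliqueSlice <- function(voi, tiltAxis = c("x", "y"), angle = 0, pad = -1024) {
  stopifnot(is(voi, "VOICube"))
  tiltAxis <- match.arg(tiltAxis)
  if (abs(angle) > 90) stop("angle must be within [-90, 90] degrees")
  s <- dim(voi@intensities)[1]
  c0 <- (s + 1) / 2
  th <- angle * pi / 180
  # in-plane axes of the tilted section, in voxel units
  if (tiltAxis == "x") {
    eu <- c(1, 0, 0)
    ev <- c(0, cos(th), sin(th))
  } else {
    eu <- c(cos(th), 0, sin(th))
    ev <- c(0, 1, 0)
  }
  uv <- seq_len(s) - c0
  g <- expand.grid(u = uv, v = uv)
  pts <- cbind(c0 + g$u * eu[1] + g$v * ev[1],
               c0 + g$u * eu[2] + g$v * ev[2],
               c0 + g$u * eu[3] + g$v * ev[3])
  vals <- trilinearSampleIndex(voi@intensities, pts, pad = pad)
  PatchImage(matrix(vals, s, s), sourceCase = voi@sourceCase,
             label = voi@label,
             orientation = if (angle == 0 && tiltAxis == "x") "axial"
                           else sprintf("%s%+g", tiltAxis, angle))
}

#' Expand a patch by dihedral symmetry operations
#'
#' Rotations are exact 90-degree lattice rotations and the flip is a
#' lattice mirror: no interpolation is involved, so the expansion is
#' lossless. The applied op is recorded in the provenance.
#'
#' @param patch a [PatchImage-class] (square).
#' @param ops subset of [dihedralOps()].
#' @return list of [PatchImage-class], one per op.
#' @export
dihedralExpand <- function(patch, ops = dihedralOps()) {
  stopifnot(is(patch, "PatchImage"))
  if (nrow(patch@pixels) != ncol(patch@pixels)) stop("patch must be square")
  lapply(ops, function(op) {
    PatchImage(applyDihedral(patch@pixels, op), sourceCase = patch@sourceCase,
               label = patch@label, orientation = patch@orientation,
               symmetryOp = op)
  })
}

#' Augment one nodule VOI into a set of 2-d sections
#'
#' Produces one section per (orientation, symmetry op) pair: the count law
#' is \code{length(orientations) * length(symmetryOps)}. With the default
#' configuration that is 32 x 8 = 256 images per nodule.
#'
#' @param voi a [VOICube-class].
#' @param config an [augmentConfig()].
#' @param pad padding intensity passed to [obliqueSlice()].
#' @return flat list of [PatchImage-class] objects.
#' @export
augmentNodule <- function(voi, config = augmentConfig(), pad = -1024) {
  stopifnot(inherits(config, "augmentConfig"))
  angles <- seq(config$angleMin, config$angleMax, by = config$angleStep)
  angles <- angles[angles != 0]
  orients <- list()
  for (ax in config$tiltAxes)
    for (a in angles) orients[[length(orients) + 1L]] <- list(axis = ax, angle = a)
  if (config$includeAxial)
    orients[[length(orients) + 1L]] <- list(axis = "x", angle = 0)
  if (!length(orients)) stop("empty orientation set")
  out <- vector("list", length(orients) * length(config$symmetryOps))
  pos <- 0L
  for (o in orients) {
    sec <- obliqueSlice(voi, o$axis, o$angle, pad = pad)
    if (!is.null(config$outSize))
      sec@pixels <- bilinearResize(sec@pixels, config$outSize)
    for (p in dihedralExpand(sec, config$symmetryOps)) {
      pos <- pos + 1L
      out[[pos]] <- p
    }
  }
  out
}

#' Augment every VOI in a cohort
#'
#' @param vois list of [VOICube-class] objects.
#' @param config an [augmentConfig()].
#' @return flat list of [PatchImage-class] objects across all VOIs.
#' @export
augmentCohort <- function(vois, config = augmentConfig()) {
  do.call(c, lapply(vois, augmentNodule, config = config))
}
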