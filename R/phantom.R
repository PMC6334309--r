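#' Configuration for the synthetic CT phantom generator
#'
#' The phantom generator emulates a small biopsy-confirmed nodule cohort:
#' benign nodules are smooth, near-spherical soft-tissue-density blobs;
#' malignant nodules are more irregular ellipsoids carrying radial spicules
#' and, with some probability, attachment to the pleura (chest wall).
#' Nodules are embedded in a low-density lung background with additive
#' Gaussian noise, on an HU-like intensity scale so the same preprocessing
#' window applies to phantom and real CT.
#'
#' @param volumeShape integer(3) voxels per axis.
#' @param voxelSpacing numeric(3) mm per voxel.
#' @param lungBackground background intensity in HU (aerated lung, default
#'   -800).
#' @param noduleIntensity nodule core intensity in HU (soft tissue, default
#'   +40).
#' @param noiseSigma additive Gaussian noise SD in HU.
#' @param diameterRange length-2 numeric, min/max nodule maximum diameter in
#'   mm.
#' @param spiculeCountRange length-2 integer, min/max spicule count for
#'   malignant nodules (min must be >= 1).
#' @param spiculeLengthFraction spicule length as a fraction of the nodule
#'   radius.
#' @param pleuralAttachmentProb probability that a malignant nodule is
#'   attached to the chest wall (and therefore flagged non-isolated).
#' @param benignNonIsolatedProb probability that a benign nodule abuts the
#'   chest wall (flagged non-isolated; no spicules are added).
#' @param chestWall logical, add a high-intensity chest-wall slab at the
#'   x-max face of the volume.
#' @param chestWallIntensity chest-wall intensity in HU.
#' @param huRange declared intensity range; all voxels are clamped into it.
#' @return a validated list of class \code{"phantomConfig"}.
#' @export
phantomConfig <- function(volumeShape = c(64L, 64L, 64L),
                          voxelSpacing = c(1, 1, 1),
                          lungBackground = -800,
                          noduleIntensity = 40,
                          noiseSigma = 20,
                          diameterRange = c(8, 16),
                          spiculeCountRange = c(4L, 10L),
                          spiculeLengthFraction = 0.6,
                          pleuralAttachmentProb = 0.3,
                          benignNonIsolatedProb = 0.37,
                          chestWall = TRUE,
                          chestWallIntensity = 50,
                          huRange = c(-1024, 400)) {
  stopIfNot3(volumeShape, "volumeShape")
  stopIfNot3(voxelSpacing, "voxelSpacing")
  if (any(voxelSpacing <= 0)) stop("voxelSpacing must be strictly positive")
  if (diameterRange[1] <= 0 || diameterRange[2] < diameterRange[1])
    stop("diameterRange must satisfy 0 < min <= max")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (spiculeCountRange[1] < 1L || spiculeCountRange[2] < spiculeCountRange[1])
    stop("spiculeCountRange must satisfy 1 <= min <= max")
  if (spiculeLengthFraction <= 0) stop("spiculeLengthFraction must be > 0")
  if (pleuralAttachmentProb < 0 || pleuralAttachmentProb > 1)
    stop("pleuralAttachmentProb must be in [0, 1]")
  if (benignNonIsolatedProb < 0 || benignNonIsolatedProb > 1)
    stop("benignNonIsolatedProb must be in [0, 1]")
  structure(list(volumeShape = as.integer(volumeShape),
                 voxelSpacing = as.numeric(voxelSpacing),
                 lungBackground = lungBackground,
                 noduleIntensity = noduleIntensity,
                 noiseSigma = noiseSigma,
                 diameterRange = diameterRange,
                 spiculeCountRange = as.integer(spiculeCountRange),
                 spiculeLengthFraction = spiculeLengthFraction,
                 pleuralAttachmentProb = pleuralAttachmentProb,
                 benignNonIsolatedProb = benignNonIsolatedProb,
                 chestWall = chestWall,
                 chestWallIntensity = chestWallIntensity,
                 huRange = huRange),
            class = "phantomConfig")
}

#' Generate one synthetic nodule case
#'
#' Deterministic for a fixed \code{(config, label, seed)} triple: all draws
#' come from R's RNG seeded with \code{seed}. The first draw after seeding
#' is the spicule count (malignant only), so the seeded draw can be replayed
#' for auditing. The nodule is a soft ellipsoid whose radial profile equals
#' \code{noduleIntensity} exactly inside the core and decays with a Gaussian
#' edge of SD 5\% of the diameter; spicules are line segments from the
#' surface outward with linearly decaying intensity.
#'
#' @param config a [phantomConfig()].
#' @param label \code{"benign"} or \code{"malignant"}.
#' @param seed integer seed.
#' @return a [PhantomCase-class].
#' @export
generateCase <- function(config, label, seed) {
  stopifnot(inherits(config, "phantomConfig"))
  if (!label %in% c("benign", "malignant"))
    stop("label must be 'benign' or 'malignant'")
  shape <- config$volumeShape
  sp <- config$voxelSpacing
  extent <- (shape - 1) * sp
  if (2 * config$diameterRange[2] > min(extent))
    stop("volumeShape too small: a VOI of twice the maximum configured ",
         "diameter (", 2 * config$diameterRange[2], " mm) exceeds the ",
         "volume extent (", round(min(extent), 1), " mm)")

  set.seed(as.integer(seed))
  nSpic <- if (label == "malignant") {
    sample(config$spiculeCountRange[1]:config$spiculeCountRange[2], 1L)
  } else 0L
  d <- stats::runif(1, config$diameterRange[1], config$diameterRange[2])
  rmax <- d / 2

  # ellipsoid axis radii; the largest axis carries the maximum diameter
  rng <- if (label == "malignant") c(0.72, 0.95) else c(0.92, 1)
  ratios <- stats::runif(3, rng[1], rng[2])
  ratios <- ratios / max(ratios)
  radii <- rmax * ratios

  attachProb <- if (label == "malignant") config$pleuralAttachmentProb else
    config$benignNonIsolatedProb
  attached <- config$chestWall && stats::runif(1) < attachProb

  # margin keeps nodule + spicules + smoothed edge inside the volume
  spicLen <- config$spiculeLengthFraction * rmax * 1.3
  margin <- rmax + (if (label == "malignant") spicLen else 0) + 0.15 * d + 2
  wallX <- extent[1] - 2 * sp[1]        # mm position of the chest-wall slab
  lim <- pmin(extent - margin, c(if (attached) wallX else extent[1], extent[2:3]))
  if (any(lim < margin)) stop("volumeShape too small for the configured nodule sizes")
  center <- stats::runif(3, margin, lim)
  if (attached) center[1] <- wallX - rmax - stats::runif(1, 0.5, 2)
  # snap to the voxel lattice so the VOI center voxel is exact
  center <- round(center / sp) * sp

  ax <- (seq_len(shape[1]) - 1) * sp[1]
  ay <- (seq_len(shape[2]) - 1) * sp[2]
  az <- (seq_len(shape[3]) - 1) * sp[3]

  vol <- array(config$lungBackground, dim = shape)
  amp <- config$noduleIntensity - config$lungBackground
  sigEdge <- 0.05 * d

  # nodule weight field computed in a bounding box, truncated at 3 edge-SDs
  # so the far field is exactly background
  paintBox <- function(vol, lohi, wfun) {
    ix <- which(ax >= lohi[1, 1] & ax <= lohi[2, 1])
    iy <- which(ay >= lohi[1, 2] & ay <= lohi[2, 2])
    iz <- which(az >= lohi[1, 3] & az <= lohi[2, 3])
    if (!length(ix) || !length(iy) || !length(iz)) return(vol)
    px <- ax[ix]; py <- ay[iy]; pz <- az[iz]
    g <- expand.grid(x = px, y = py, z = pz)
    w <- wfun(g$x, g$y, g$z)
    w[w < 1e-6] <- 0
    sub <- vol[ix, iy, iz, drop = FALSE]
    cand <- config$lungBackground + amp * pmin(w, 1)
    vol[ix, iy, iz] <- pmax(sub, array(cand, dim(sub)))
    vol
  }

  reach <- radii + 3 * sigEdge
  box <- rbind(center - reach, center + reach)
  vol <- paintBox(vol, box, function(x, y, z) {
    rho <- sqrt(((x - center[1]) / radii[1])^2 + ((y - center[2]) / radii[2])^2 +
                  ((z - center[3]) / radii[3])^2)
    excess <- pmax(rho - 1, 0) * mean(radii)
    ifelse(excess > 3 * sigEdge, 0, exp(-excess^2 / (2 * sigEdge^2)))
  })

  spicDirs <- NULL
  if (nSpic > 0L) {
    spicDirs <- matrix(stats::rnorm(3 * nSpic), ncol = 3)
    spicDirs <- spicDirs / sqrt(rowSums(spicDirs^2))
    for (s in seq_len(nSpic)) {
      dir <- spicDirs[s, ]
      rsurf <- 1 / sqrt(sum((dir / radii)^2))
      len <- config$spiculeLengthFraction * rmax * stats::runif(1, 0.8, 1.3)
      p0 <- center + dir * (0.9 * rsurf)
      p1 <- center + dir * (rsurf + len)
      thick <- max(1.2, 0.1 * d)
      box <- rbind(pmin(p0, p1) - 3 * thick, pmax(p0, p1) + 3 * thick)
      vol <- paintBox(vol, box, function(x, y, z) {
        # distance to the segment p0-p1 and normalized position q along it
        vx <- p1 - p0
        L2 <- sum(vx^2)
        q <- ((x - p0[1]) * vx[1] + (y - p0[2]) * vx[2] + (z - p0[3]) * vx[3]) / L2
        qc <- pmin(pmax(q, 0), 1)
        dx <- x - (p0[1] + qc * vx[1]); dy <- y - (p0[2] + qc * vx[2])
        dz <- z - (p0[3] + qc * vx[3])
        dist2 <- dx^2 + dy^2 + dz^2
        tq <- thick * (1 - 0.5 * qc)
        w <- (1 - 0.75 * qc) * exp(-dist2 / (2 * tq^2))
        ifelse(dist2 > (3 * thick)^2, 0, w)
      })
    }
  }

  if (attached) {
    # bridge from the nodule surface to the wall along +x
    p0 <- center + c(0.8 * radii[1], 0, 0)
    p1 <- c(wallX + sp[1], center[2], center[3])
    thick <- max(1, 0.12 * d)
    box <- rbind(pmin(p0, p1) - 3 * thick, pmax(p0, p1) + 3 * thick)
    vol <- paintBox(vol, box, function(x, y, z) {
      vx <- p1 - p0; L2 <- sum(vx^2)
      q <- ((x - p0[1]) * vx[1] + (y - p0[2]) * vx[2] + (z - p0[3]) * vx[3]) / L2
      qc <- pmin(pmax(q, 0), 1)
      dx <- x - (p0[1] + qc * vx[1]); dy <- y - (p0[2] + qc * vx[2])
      dz <- z - (p0[3] + qc * vx[3])
      dist2 <- dx^2 + dy^2 + dz^2
      ifelse(dist2 > (3 * thick)^2, 0, 0.9 * exp(-dist2 / (2 * thick^2)))
    })
  }

  if (config$chestWall) {
    wallIdx <- which(ax >= wallX)
    vol[wallIdx, , ] <- pmax(vol[wallIdx, , ], config$chestWallIntensity)
  }

  if (config$noiseSigma > 0)
    vol <- vol + stats::rnorm(length(vol), sd = config$noiseSigma)
  vol <- pmin(pmax(vol, config$huRange[1]), config$huRange[2])

  ann <- NoduleAnnotation(caseID = sprintf("seed%d", as.integer(seed)),
                          center = center, maxDiameter = d, label = label,
                          isolated = !attached)
  new("PhantomCase",
      volume = CTVolume(vol, spacing = sp, origin = c(0, 0, 0)),
      annotation = ann, seed = as.integer(seed),
      meta = list(nSpicules = nSpic, radii = radii, attached = attached,
                  spiculeDirs = spicDirs))
}

#' Generate a cohort of synthetic nodule cases
#'
#' Per-case seeds are derived from the master seed with a named
#' counter-based scheme ([deriveSeed()]), so the cohort is reproducible
#' independent of generation order and platform. The default cohort size
#' (27 benign / 33 malignant) mirrors a small biopsy-confirmed hospital
#' series.
#'
#' @param nBenign,nMalignant case counts (>= 0).
#' @param config a [phantomConfig()].
#' @param seed master seed.
#' @return a list of [PhantomCase-class] objects, benign cases first.
#' @export
generateCohort <- function(nBenign = 27L, nMalignant = 33L,
                           config = phantomConfig(), seed = 0L) {
  stopifnot(nBenign >= 0, nMalignant >= 0)
  labels <- c(rep("benign", nBenign), rep("malignant", nMalignant))
  cases <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cs <- deriveSeed(seed, "phantom-case", i)
    case <- generateCase(config, labels[i], cs)
    case@annotation@caseID <- sprintf("case%03d", i)
    cases[[i]] <- case
  }
  cases
}

#' Cohort manifest as a data frame
#'
#' One row per case with the annotation fields used by
#' [readAnnotations()] / [writeAnnotations()].
#'
#' @param cases list of [PhantomCase-class] objects.
#' @return a data.frame with columns case_id, label, center_x_mm,
#'   center_y_mm, center_z_mm, diameter_mm, isolated, seed.
#' @export
cohortManifest <- function(cases) {
  data.frame(
    case_id = vapply(cases, caseID, character(1)),
    label = vapply(cases, noduleLabel, character(1)),
    center_x_mm = vapply(cases, function(x) x@annotation@center[1], numeric(1)),
    center_y_mm = vapply(cases, function(x) x@annotation@center[2], numeric(1)),
    center_z_mm = vapply(cases, function(x) x@annotation@center[3], numeric(1)),
    diameter_mm = vapply(cases, function(x) x@annotation@maxDiameter, numeric(1)),
    isolated = vapply(cases, isIsolated, logical(1)),
    seed = vapply(cases, function(x) x@seed, integer(1)),
    stringsAsFactors = FALSE)
}

#' Write a cohort to disk
#'
#' Volumes go to \code{dir/<case_id>.raw} (+ JSON sidecar) in the fixture
#' format of [writeVolume()]; the manifest goes to \code{dir/manifest.csv}.
#'
#' @param cases list of [PhantomCase-class] objects.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
writeCohort <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (case in cases)
    writeVolume(case@volume, file.path(dir, paste0(caseID(case), ".raw")))
  man <- cohortManifest(cases)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Radial boundary-shell intensity variance
#'
#' A deliberately crude morphology feature: the variance of intensities in
#' the spherical shell between
#' 1.2 and 1.8 nodule radii, excluding the solid angle toward the chest
#' wall (where pleural attachment would dominate). Spiculated
#' (malignant) margins are heterogeneous there while smooth benign margins
#' are not, so this one number separates the phantom classes and serves as
#' an independent check that the generated cohort is learnable at all.
#'
#' @param case a [PhantomCase-class].
#' @return scalar variance in HU^2.
#' @export
shellVariance <- function(case) {
  v <- case@volume
  ann <- case@annotation
  d <- dim(v@intensities)
  ax <- v@origin[1] + (seq_len(d[1]) - 1) * v@spacing[1]
  ay <- v@origin[2] + (seq_len(d[2]) - 1) * v@spacing[2]
  az <- v@origin[3] + (seq_len(d[3]) - 1) * v@spacing[3]
  r <- ann@maxDiameter / 2
  box <- 1.8 * r
  ix <- which(abs(ax - ann@center[1]) <= box)
  iy <- which(abs(ay - ann@center[2]) <= box)
  iz <- which(abs(az - ann@center[3]) <= box)
  g <- expand.grid(x = ax[ix], y = ay[iy], z = az[iz])
  dist <- sqrt((g$x - ann@center[1])^2 + (g$y - ann@center[2])^2 +
                 (g$z - ann@center[3])^2)
  # exclude the solid angle toward the chest wall (+x) so pleural
  # attachment and the wall slab do not dominate the margin statistic
  cosWall <- (g$x - ann@center[1]) / pmax(dist, 1e-9)
  shell <- dist >= 1.2 * r & dist <= 1.8 * r & cosWall <= 0.55
  stats::var(as.numeric(v@intensities[ix, iy, iz])[shell])
}
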