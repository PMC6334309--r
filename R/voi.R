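#' Extract an isotropic volume of interest around a nodule
#'
#' Cuts a cube centered on the annotated nodule with physical side twice the
#' annotated maximum diameter, resampled once to an isotropic grid by
#' trilinear interpolation. The voxel count is \code{round(2 * diameter /
#' resolution)} forced odd, so the nodule center is exactly the central
#' lattice point and the physical side matches twice the diameter to within
#' one voxel. Samples falling outside the source volume take a padding
#' intensity of air density, as nodules near the pleura abut the volume
#' edge in real data.
#'
#' @param volume a [CTVolume-class].
#' @param annotation a [NoduleAnnotation-class] whose center lies inside the
#'   volume.
#' @param resolution target isotropic voxel size in mm (default 1).
#' @param pad padding intensity for out-of-volume samples (default -1024).
#' @return a [VOICube-class].
#' @export
extractVOI <- function(volume, annotation, resolution = 1, pad = -1024) {
  stopifnot(is(volume, "CTVolume"), is(annotation, "NoduleAnnotation"))
  if (resolution <= 0) stop("resolution must be > 0")
  d <- dim(volume@intensities)
  extent <- volume@origin + (d - 1) * volume@spacing
  ctr <- annotation@center
  if (any(ctr < volume@origin) || any(ctr > extent))
    stop("annotation center lies outside the volume")

  sideVox <- as.integer(round(2 * annotation@maxDiameter / resolution))
  if (sideVox %% 2L == 0L) sideVox <- sideVox + 1L
  half <- (sideVox - 1L) %/% 2L
  offs <- (-half:half) * resolution

  g <- expand.grid(x = ctr[1] + offs, y = ctr[2] + offs, z = ctr[3] + offs)
  vals <- trilinearSampleMM(volume@intensities, volume@spacing, volume@origin,
                            as.matrix(g), pad = pad)
  new("VOICube", intensities = array(vals, dim = rep(sideVox, 3L)),
      resolution = resolution, sideMM = sideVox * resolution,
      sourceCase = annotation@caseID, label = annotation@label)
}

#' Extract VOIs for a whole cohort
#'
#' @param cases list of [PhantomCase-class] objects (or a list with
#'   \code{$volume} and \code{$annotation}).
#' @param resolution isotropic voxel size in mm.
#' @param pad out-of-volume padding intensity.
#' @return a list of [VOICube-class] objects, one per case.
#' @export
extractCohortVOIs <- function(cases, resolution = 1, pad = -1024) {
  lapply(cases, function(case) {
    extractVOI(case@volume, case@annotation, resolution = resolution, pad = pad)
  })
}
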