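#' @import methods
NULL

# ---- CTVolume --------------------------------------------------------------

#' CTVolume: a 3-d CT-like intensity grid
#'
#' Holds a scalar intensity grid on the Hounsfield-unit scale together with
#' the voxel spacing and the physical origin. The array is indexed
#' \code{[x, y, z]} with x fastest (R column-major order); voxel
#' \code{(i, j, k)} is centered at \code{origin + (c(i, j, k) - 1) * spacing}
#' millimetres.
#'
#' @slot intensities 3-d numeric array of HU-like intensities.
#' @slot spacing numeric(3), mm per voxel along x, y, z; strictly positive.
#' @slot origin numeric(3), mm position of voxel (1, 1, 1).
#' @export
setClass("CTVolume",
  representation(intensities = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@intensities)
    if (length(d) != 3L || any(d < 1L)) return("intensities must be a non-empty 3-d array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0)) return("spacing must be positive on all three axes")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be numeric(3)")
    TRUE
  })

#' Construct a CTVolume
#'
#' @param intensities 3-d numeric array (x fastest).
#' @param spacing mm per voxel, length 3.
#' @param origin mm position of the first voxel, length 3.
#' @return a [CTVolume-class] object.
#' @export
CTVolume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", intensities = intensities, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

# ---- NoduleAnnotation ------------------------------------------------------

#' NoduleAnnotation: one radiologist-style nodule annotation
#'
#' @slot caseID character case identifier.
#' @slot center numeric(3), nodule center in mm, volume frame.
#' @slot maxDiameter maximum nodule diameter in mm (> 0).
#' @slot label \code{"benign"} or \code{"malignant"}.
#' @slot isolated logical; \code{FALSE} for pleura-attached nodules,
#'   which are excluded when selecting GAN training cases.
#' @export
setClass("NoduleAnnotation",
  representation(caseID = "character", center = "numeric",
                 maxDiameter = "numeric", label = "character",
                 isolated = "logical"),
  validity = function(object) {
    if (!object@label %in% c("benign", "malignant"))
      return("label must be 'benign' or 'malignant'")
    if (!is.finite(object@maxDiameter) || object@maxDiameter <= 0)
      return("maxDiameter must be > 0")
    if (length(object@center) != 3L || any(!is.finite(object@center)))
      return("center must be numeric(3)")
    TRUE
  })

#' @rdname NoduleAnnotation-class
#' @param caseID,center,maxDiameter,label,isolated see slots.
#' @export
NoduleAnnotation <- function(caseID, center, maxDiameter, label,
                             isolated = TRUE) {
  new("NoduleAnnotation", caseID = as.character(caseID),
      center = as.numeric(center), maxDiameter = as.numeric(maxDiameter),
      label = as.character(label), isolated = as.logical(isolated))
}

# ---- PhantomCase -----------------------------------------------------------

#' PhantomCase: a synthetic CT volume with its nodule annotation
#'
#' @slot volume a [CTVolume-class].
#' @slot annotation the [NoduleAnnotation-class] describing the nodule.
#' @slot seed integer seed the case was generated from.
#' @slot meta list of generator internals (spicule count, axis radii,
#'   attachment flag) recorded for auditing.
#' @export
setClass("PhantomCase",
  representation(volume = "CTVolume", annotation = "NoduleAnnotation",
                 seed = "integer", meta = "list"),
  validity = function(object) {
    v <- object@volume
    extent <- v@origin + (dim(v@intensities) - 1) * v@spacing
    c0 <- object@annotation@center
    if (any(c0 < v@origin) || any(c0 > extent))
      return("annotation center lies outside the volume")
    TRUE
  })

# ---- VOICube ---------------------------------------------------------------

#' VOICube: isotropic cube of intensities centered on a nodule
#'
#' The cube side is twice the annotated maximum diameter (to within one
#' voxel of rounding; the voxel count is forced odd so the nodule center is
#' exactly the central lattice point).
#'
#' @slot intensities 3-d numeric cube (side x side x side).
#' @slot resolution isotropic voxel size in mm.
#' @slot sideMM physical side length in mm.
#' @slot sourceCase case identifier of the source volume.
#' @slot label class label inherited from the annotation.
#' @export
setClass("VOICube",
  representation(intensities = "array", resolution = "numeric",
                 sideMM = "numeric", sourceCase = "character",
                 label = "character"),
  validity = function(object) {
    d <- dim(object@intensities)
    if (length(d) != 3L || length(unique(d)) != 1L)
      return("intensities must be a cube")
    if (d[1] %% 2L == 0L) return("cube side must be odd")
    if (object@resolution <= 0) return("resolution must be > 0")
    TRUE
  })

# ---- PatchImage ------------------------------------------------------------

#' PatchImage: a 2-d nodule section with its provenance
#'
#' @slot pixels square numeric matrix of intensities.
#' @slot sourceCase case identifier.
#' @slot label class label.
#' @slot orientation section orientation, e.g. \code{"x+25"} (tilted 25
#'   degrees about the in-plane x axis) or \code{"axial"}.
#' @slot symmetryOp dihedral symmetry op applied, e.g. \code{"r90f"}.
#' @export
setClass("PatchImage",
  representation(pixels = "matrix", sourceCase = "character",
                 label = "character", orientation = "character",
                 symmetryOp = "character"),
  validity = function(object) {
    if (nrow(object@pixels) != ncol(object@pixels))
      return("pixels must be square")
    if (!nzchar(object@sourceCase) || !nzchar(object@orientation) ||
        !nzchar(object@symmetryOp))
      return("provenance fields must be populated")
    TRUE
  })

#' @rdname PatchImage-class
#' @param pixels,sourceCase,label,orientation,symmetryOp see slots.
#' @export
PatchImage <- function(pixels, sourceCase, label, orientation, symmetryOp = "r0") {
  new("PatchImage", pixels = pixels, sourceCase = sourceCase, label = label,
      orientation = orientation, symmetryOp = symmetryOp)
}

# ---- generics and accessors ------------------------------------------------

#' Accessors for the imaging classes
#'
#' @param x an object of one of the package's imaging classes.
#' @name accessors
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "CTVolume", function(x) x@intensities)
#' @rdname accessors
#' @export
setMethod("intensities", "VOICube", function(x) x@intensities)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VOICube", function(x) rep(x@resolution, 3L))

#' @rdname accessors
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))
#' @rdname accessors
#' @export
setMethod("volumeOrigin", "CTVolume", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("caseID", function(x) standardGeneric("caseID"))
#' @rdname accessors
#' @export
setMethod("caseID", "NoduleAnnotation", function(x) x@caseID)
#' @rdname accessors
#' @export
setMethod("caseID", "PhantomCase", function(x) x@annotation@caseID)
#' @rdname accessors
#' @export
setMethod("caseID", "VOICube", function(x) x@sourceCase)
#' @rdname accessors
#' @export
setMethod("caseID", "PatchImage", function(x) x@sourceCase)

#' @rdname accessors
#' @export
setGeneric("noduleLabel", function(x) standardGeneric("noduleLabel"))
#' @rdname accessors
#' @export
setMethod("noduleLabel", "NoduleAnnotation", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("noduleLabel", "PhantomCase", function(x) x@annotation@label)
#' @rdname accessors
#' @export
setMethod("noduleLabel", "VOICube", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("noduleLabel", "PatchImage", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("isIsolated", function(x) standardGeneric("isIsolated"))
#' @rdname accessors
#' @export
setMethod("isIsolated", "NoduleAnnotation", function(x) x@isolated)
#' @rdname accessors
#' @export
setMethod("isIsolated", "PhantomCase", function(x) x@annotation@isolated)

#' @rdname accessors
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))
#' @rdname accessors
#' @export
setMethod("annotation", "PhantomCase", function(x) x@annotation)

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "PatchImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("maxDiameter", function(x) standardGeneric("maxDiameter"))
#' @rdname accessors
#' @export
setMethod("maxDiameter", "NoduleAnnotation", function(x) x@maxDiameter)

# ---- show methods ----------------------------------------------------------

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("CTVolume %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              paste(format(object@origin, digits = 3), collapse = ", ")))
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "NoduleAnnotation", function(object) {
  cat(sprintf("NoduleAnnotation %s: %s, %.1f mm, center (%s) mm, %s\n",
              object@caseID, object@label, object@maxDiameter,
              paste(format(object@center, digits = 3), collapse = ", "),
              if (object@isolated) "isolated" else "pleura-attached"))
})

setMethod("show", "PhantomCase", function(object) {
  cat("PhantomCase (seed", object@seed, ")\n  ")
  show(object@annotation)
  cat("  ")
  show(object@volume)
})

setMethod("show", "VOICube", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VOICube %s (%s): %d^3 voxels at %.2f mm (%.1f mm side)\n",
              object@sourceCase, object@label, d[1], object@resolution,
              object@sideMM))
})

setMethod("show", "PatchImage", function(object) {
  cat(sprintf("PatchImage %s (%s): %d x %d, orientation %s, op %s\n",
              object@sourceCase, object@label, nrow(object@pixels),
              ncol(object@pixels), object@orientation, object@symmetryOp))
})
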