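#' Read a 3-d volume from NIfTI or the raw fixture format
#'
#' Two formats are supported, selected by extension:
#' \itemize{
#'   \item \code{.nii} / \code{.nii.gz}: NIfTI-1 via \pkg{RNifti}. Only
#'     axis-aligned affines are accepted; oblique acquisitions are rejected
#'     with a clear error rather than silently misoriented.
#'   \item \code{.raw} / \code{.json}: the package's plain fixture format, a
#'     little-endian float64 voxel stream with a JSON sidecar declaring
#'     \code{shape}, \code{spacing}, \code{origin} and \code{dtype}. The
#'     stream is x-fastest, matching the in-memory array order.
#' }
#'
#' @param path file path (either member of a fixture pair works).
#' @return a [CTVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path) && !file.exists(paste0(tools::file_path_sans_ext(path), ".json")))
    stop("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) readVolumeNifti(path) else readVolumeRaw(path)
}

readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("format error: expected a 3-d NIfTI volume")
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)), 1)))
    stop("format error: oblique (non-axis-aligned) affine in field srow/qform; ",
         "only axis-aligned volumes are supported")
  if (any(diag(rot) < 0))
    stop("format error: flipped axis in affine field srow/qform; ",
         "only positively oriented axis-aligned volumes are supported")
  spacing <- RNifti::pixdim(img)[1:3]
  CTVolume(unclass(arr)[, , , drop = TRUE], spacing = spacing, origin = xf[1:3, 4])
}

readVolumeRaw <- function(path) {
  stem <- tools::file_path_sans_ext(path)
  jsonPath <- paste0(stem, ".json")
  rawPath <- paste0(stem, ".raw")
  if (!file.exists(jsonPath)) stop("format error: missing sidecar ", jsonPath)
  if (!file.exists(rawPath)) stop("format error: missing voxel file ", rawPath)
  hdr <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  for (f in c("shape", "spacing", "origin", "dtype"))
    if (is.null(hdr[[f]])) stop("format error: sidecar field '", f, "' missing")
  shape <- as.integer(hdr$shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L))
    stop("format error: sidecar field 'shape' must be 3 positive integers")
  if (!identical(hdr$dtype, "float64"))
    stop("format error: sidecar field 'dtype' must be 'float64'")
  nvox <- prod(shape)
  if (file.info(rawPath)$size != nvox * 8)
    stop("format error: voxel file size does not match sidecar field 'shape'")
  con <- file(rawPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = nvox, size = 8, endian = "little")
  CTVolume(array(vals, dim = shape), spacing = as.numeric(hdr$spacing),
           origin = as.numeric(hdr$origin))
}

#' Write a 3-d volume to NIfTI or the raw fixture format
#'
#' The fixture format round-trips bit-exactly ([readVolume()] returns the
#' identical grid, spacing and origin). NIfTI output carries a diagonal
#' sform built from the spacing and origin.
#'
#' @param volume a [CTVolume-class].
#' @param path output path; extension selects the format.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory ", dir, " does not exist")
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume@intensities)
    RNifti::pixdim(img) <- volume@spacing
    aff <- diag(c(volume@spacing, 1))
    aff[1:3, 4] <- volume@origin
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path)
  } else {
    stem <- tools::file_path_sans_ext(path)
    jsonlite::write_json(list(shape = dim(volume@intensities),
                              spacing = volume@spacing,
                              origin = volume@origin,
                              dtype = "float64",
                              order = "x-fastest"),
                         paste0(stem, ".json"), auto_unbox = FALSE, digits = NA)
    con <- file(paste0(stem, ".raw"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume@intensities), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read nodule annotations from a manifest CSV
#'
#' Expects the manifest columns written by [cohortManifest()]. Each row is
#' validated on load; violations report the offending row number.
#'
#' @param path CSV path.
#' @param boundsMM optional numeric(3) physical volume extent in mm; when
#'   given, centers outside \code{[0, boundsMM]} are rejected.
#' @return a list of [NoduleAnnotation-class] objects (empty for an empty
#'   file).
#' @export
readAnnotations <- function(path, boundsMM = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.info(path)$size == 0) return(list())
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(list())
  need <- c("case_id", "label", "center_x_mm", "center_y_mm", "center_z_mm",
            "diameter_mm", "isolated")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("manifest missing columns: ",
                            paste(missing, collapse = ", "))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!is.finite(row$diameter_mm) || row$diameter_mm <= 0)
      stop("validation error at row ", i, ": diameter_mm must be > 0")
    if (!row$label %in% c("benign", "malignant"))
      stop("validation error at row ", i, ": label must be benign or malignant")
    ctr <- c(row$center_x_mm, row$center_y_mm, row$center_z_mm)
    if (any(!is.finite(ctr)))
      stop("validation error at row ", i, ": non-finite center")
    if (!is.null(boundsMM) && (any(ctr < 0) || any(ctr > boundsMM)))
      stop("validation error at row ", i, ": center outside volume bounds")
    out[[i]] <- NoduleAnnotation(caseID = row$case_id, center = ctr,
                                 maxDiameter = row$diameter_mm,
                                 label = row$label,
                                 isolated = as.logical(row$isolated))
  }
  out
}

#' @rdname readAnnotations
#' @param annotations list of [NoduleAnnotation-class] objects.
#' @export
writeAnnotations <- function(annotations, path) {
  df <- data.frame(
    case_id = vapply(annotations, caseID, character(1)),
    label = vapply(annotations, noduleLabel, character(1)),
    center_x_mm = vapply(annotations, function(a) a@center[1], numeric(1)),
    center_y_mm = vapply(annotations, function(a) a@center[2], numeric(1)),
    center_z_mm = vapply(annotations, function(a) a@center[3], numeric(1)),
    diameter_mm = vapply(annotations, maxDiameter, numeric(1)),
    isolated = vapply(annotations, isIsolated, logical(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
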