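test_that("the raw fixture format round-trips bit-exactly", {
  set.seed(1)
  vol <- CTVolume(array(rnorm(6 * 5 * 4, -500, 300), c(6, 5, 4)),
                  spacing = c(0.7, 0.7, 2.0), origin = c(-10, 3, 25.5))
  path <- file.path(withr::local_tempdir(), "vol.raw")
  writeVolume(vol, path)
  back <- readVolume(path)
  expect_identical(intensities(back), intensities(vol))
  expect_identical(voxelSpacing(back), voxelSpacing(vol))
  expect_identical(volumeOrigin(back), volumeOrigin(vol))
  # rewriting is idempotent
  writeVolume(back, path)
  expect_identical(intensities(readVolume(path)), intensities(vol))
})

test_that("NIfTI round-trip preserves anisotropic spacing and origin", {
  set.seed(2)
  vol <- CTVolume(array(rnorm(8 * 7 * 6), c(8, 7, 6)),
                  spacing = c(0.7, 0.7, 2.0), origin = c(1, 2, 3))
  path <- file.path(withr::local_tempdir(), "vol.nii.gz")
  writeVolume(vol, path)
  back <- readVolume(path)
  expect_equal(voxelSpacing(back), c(0.7, 0.7, 2.0), tolerance = 1e-6)
  expect_equal(volumeOrigin(back), c(1, 2, 3), tolerance = 1e-5)
  expect_equal(intensities(back), intensities(vol), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("physical coordinates map voxel indices through origin + i * spacing", {
  arr <- array(-1000, c(10, 10, 10))
  arr[4, 6, 8] <- 500   # marker voxel
  vol <- CTVolume(arr, spacing = c(2, 1, 0.5), origin = c(10, 0, -5))
  # marker must sit at origin + (index - 1) * spacing
  expected <- c(10, 0, -5) + c(3, 5, 7) * c(2, 1, 0.5)
  got <- noduleGAN:::trilinearSampleMM(arr, c(2, 1, 0.5), c(10, 0, -5),
                                       matrix(expected, 1), pad = -1024)
  expect_equal(got, 500)
})

test_that("malformed fixtures fail with errors naming the offending field", {
  dir <- withr::local_tempdir()
  # 0-voxel shape
  jsonlite::write_json(list(shape = c(0L, 5L, 5L), spacing = c(1, 1, 1),
                            origin = c(0, 0, 0), dtype = "float64"),
                       file.path(dir, "bad.json"), auto_unbox = FALSE)
  writeBin(numeric(0), file.path(dir, "bad.raw"))
  expect_error(readVolume(file.path(dir, "bad.raw")), "shape")
  # missing sidecar field
  jsonlite::write_json(list(shape = c(2L, 2L, 2L), spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)),
                       file.path(dir, "nofield.json"), auto_unbox = FALSE)
  writeBin(numeric(8), file.path(dir, "nofield.raw"), size = 8)
  expect_error(readVolume(file.path(dir, "nofield.raw")), "dtype")
  # truncated voxel stream
  jsonlite::write_json(list(shape = c(2L, 2L, 2L), spacing = c(1, 1, 1),
                            origin = c(0, 0, 0), dtype = "float64"),
                       file.path(dir, "short.json"), auto_unbox = FALSE)
  writeBin(numeric(3), file.path(dir, "short.raw"), size = 8)
  expect_error(readVolume(file.path(dir, "short.raw")), "size")
})

test_that("oblique NIfTI affines are rejected rather than silently misread", {
  skip_if_not_installed("RNifti")
  dir <- withr::local_tempdir()
  arr <- array(0, c(4, 4, 4))
  img <- RNifti::asNifti(arr)
  th <- 20 * pi / 180
  aff <- diag(4)
  aff[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  path <- file.path(dir, "oblique.nii.gz")
  RNifti::writeNifti(img, path)
  expect_error(readVolume(path), "oblique|axis-aligned")
})

test_that("annotation manifests round-trip and validate per row", {
  dir <- withr::local_tempdir()
  anns <- list(
    NoduleAnnotation("case001", c(10, 12, 14), 9.5, "benign", TRUE),
    NoduleAnnotation("case002", c(20, 22, 24), 14, "malignant", FALSE))
  path <- file.path(dir, "manifest.csv")
  writeAnnotations(anns, path)
  back <- readAnnotations(path)
  expect_length(back, 2L)
  expect_identical(caseID(back[[2]]), "case002")
  expect_identical(noduleLabel(back[[1]]), "benign")
  expect_false(isIsolated(back[[2]]))
  expect_equal(maxDiameter(back[[1]]), 9.5)

  # row-numbered validation errors
  df <- utils::read.csv(path)
  df$diameter_mm[2] <- -1
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(readAnnotations(path), "row 2")

  # bounds check
  writeAnnotations(anns, path)
  expect_error(readAnnotations(path, boundsMM = c(15, 15, 15)), "row 2")

  # empty file -> empty list
  writeLines(character(0), path)
  expect_identical(readAnnotations(path), list())
})

test_that("a 60-row manifest yields 60 annotations", {
  dir <- withr::local_tempdir()
  cohort <- generateCohort(27L, 33L, quietPhantomConfig(), seed = 5L)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(cohortManifest(cohort), path, row.names = FALSE)
  expect_length(readAnnotations(path), 60L)
})

test_that("CTVolume validity rejects degenerate grids and spacings", {
  expect_error(CTVolume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "spacing")
  expect_error(CTVolume(array(0, c(4, 4)), spacing = c(1, 1, 1)))
  expect_error(NoduleAnnotation("x", c(1, 2, 3), -2, "benign"), "maxDiameter")
})
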