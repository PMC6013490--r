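test_that("NIfTI round trip preserves voxels and spacing", {
  v <- volume3d(array(runif(16^3), c(16, 16, 16)),
                spacing_mm = c(1, 1, 1), modality = "GRE")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path, modality = "GRE")
  expect_equal(v2$data, v$data, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(v2$spacing_mm, v$spacing_mm)
})

test_that("reading a 4D image fails with a dimensionality error", {
  a4 <- array(runif(8^3 * 2), c(8, 8, 8, 2))
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(a4), path)
  expect_error(read_volume(path), "3D")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
})

test_that("volume3d rejects non-finite voxels and non-3D input", {
  a <- array(1, c(4, 4, 4))
  a[1] <- NA
  expect_error(volume3d(a), "non-finite")
  expect_error(volume3d(matrix(1, 3, 3)), "3D")
})

test_that("normalize_intensity divides by the maximum", {
  a <- array(0, c(4, 4, 4))
  a[1] <- 500; a[2] <- 250
  v <- normalize_intensity(volume3d(a))
  expect_equal(max(v$data), 1)
  expect_equal(v$data[2], 0.5)
})

test_that("normalize_intensity is idempotent and monotone", {
  v <- volume3d(array(runif(6^3, 0, 7), c(6, 6, 6)))
  n1 <- normalize_intensity(v)
  n2 <- normalize_intensity(n1)
  expect_identical(n1$data, n2$data)
  ord <- order(as.numeric(v$data))
  expect_identical(order(as.numeric(n1$data)), ord)
  expect_true(all(n1$data >= 0 & n1$data <= 1))
})

test_that("normalize_intensity rejects degenerate volumes", {
  expect_error(normalize_intensity(volume3d(array(0, c(4, 4, 4)))),
               "degenerate")
})
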