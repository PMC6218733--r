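test_that("volume and label_map constructors enforce their invariants", {
  v <- volume(array(c(-3, 0, 1, 2, 3, 4, 5, 6), c(2, 2, 2)))
  expect_true(all(v$data >= 0))
  expect_equal(v$data[1, 1, 1], 0)  # negatives clipped
  expect_error(volume(matrix(1, 2, 2)), class = "glioseg_not_3d")
  expect_error(label_map(array(7L, c(2, 2, 2))), class = "glioseg_invalid_labels")
  expect_silent(label_map(array(rep(0:4, 10), c(5, 5, 2))))
})

test_that("NIfTI round trip is exact for volumes and label maps", {
  set.seed(11)
  dat <- array(sample(0:500, 4 * 5 * 3, replace = TRUE), c(4, 5, 3))
  v <- volume(dat, spacing = c(1, 1.5, 2), modality = "T1c")
  for (ext in c(".nii", ".nii.gz")) {
    p <- tempfile(fileext = ext)
    write_volume(v, p)
    v2 <- read_volume(p, "T1c")
    expect_identical(dim(v2$data), dim(dat))
    expect_equal(v2$data, v$data)
    expect_equal(v2$spacing, c(1, 1.5, 2), tolerance = 1e-6)
    unlink(p)
  }
  lm0 <- label_map(array(sample(0:4, 60, replace = TRUE), c(4, 5, 3)))
  p <- tempfile(fileext = ".nii.gz")
  write_label_map(lm0, p)
  expect_identical(read_label_map(p)$data, lm0$data)
  unlink(p)
})

test_that("MetaImage round trip is exact", {
  set.seed(12)
  dat <- array(sample(0:400, 24, replace = TRUE), c(2, 3, 4))
  v <- volume(dat, spacing = c(0.5, 0.5, 2))
  p <- tempfile(fileext = ".mha")
  write_volume(v, p, datatype = "int16")
  v2 <- read_volume(p)
  expect_equal(v2$data, v$data)
  expect_equal(v2$spacing, c(0.5, 0.5, 2))
  lm0 <- label_map(array(sample(0:4, 24, replace = TRUE), c(2, 3, 4)))
  p2 <- tempfile(fileext = ".mha")
  write_label_map(lm0, p2)
  expect_identical(read_label_map(p2)$data, lm0$data)
  unlink(c(p, p2))
})

test_that("negative on-disk intensities read back as zero", {
  dat <- array(5, c(4, 4, 2)); dat[2, 3, 1] <- -3
  p <- tempfile(fileext = ".nii")
  glioseg:::write_nifti(dat, c(1, 1, 1), p, "int16")
  v <- read_volume(p)
  expect_equal(v$data[2, 3, 1], 0)
  expect_equal(sum(v$data == 5), 31)
  unlink(p)
})

test_that("I/O failure modes raise named errors", {
  expect_error(read_volume(tempfile(fileext = ".nii")), class = "glioseg_missing_file")
  p <- tempfile(fileext = ".txt")
  writeLines("not a volume", p)
  expect_error(read_volume(p), class = "glioseg_unsupported_format")
  # non-NIfTI payload behind a .nii extension
  p2 <- tempfile(fileext = ".nii")
  writeBin(raw(400), p2)
  expect_error(read_volume(p2), class = "glioseg_unsupported_format")
  # non-3D MetaImage
  p3 <- tempfile(fileext = ".mha")
  writeLines(c("ObjectType = Image", "NDims = 2", "DimSize = 4 4",
               "ElementType = MET_UCHAR", "ElementDataFile = LOCAL"), p3)
  expect_error(read_volume(p3), class = "glioseg_not_3d")
  # invalid labels rejected before writing
  lm0 <- label_map(array(0L, c(2, 2, 2)))
  lm0$data[1] <- 9L
  expect_error(write_label_map(lm0, tempfile(fileext = ".nii")),
               class = "glioseg_invalid_labels")
  unlink(c(p, p2, p3))
})

test_that("brain mask cardinality equals the positive-voxel count", {
  expect_false(any(brain_mask(volume(array(0, c(3, 3, 3))))))
  expect_true(all(brain_mask(volume(array(1, c(3, 3, 3))))))
  set.seed(7)
  for (i in 1:5) {
    dat <- array(sample(0:3, 60, replace = TRUE), c(5, 4, 3))
    v <- volume(dat)
    expect_identical(sum(brain_mask(v)), sum(dat > 0))
  }
})
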