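test_that("image_volume validates shape and voxel size", {
  expect_error(image_volume(matrix(0, 4, 4)), "3D")
  expect_error(image_volume(array(0, c(2, 2, 2)), voxel_size_um = c(1, 1)),
               "voxel_size_um")
  v <- image_volume(array(runif(8), c(2, 2, 2)))
  expect_equal(unname(voxel_size(v)), c(0.645, 0.645, 1))
})

test_that("write_stack / read_stack round-trips data and voxel size", {
  arr <- array(runif(6 * 5 * 4), c(6, 5, 4))
  v <- image_volume(arr, c(0.645, 0.645, 1.0))
  f <- tempfile(fileext = ".tif")
  write_stack(v, f, command = "test run")
  r <- read_stack(f)
  expect_equal(dim(r), dim(v))
  expect_equal(as.numeric(r), as.numeric(v), tolerance = 1e-6)  # float32
  expect_equal(unname(voxel_size(r)), c(0.645, 0.645, 1.0))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$axis_order, "y,x,z")
  expect_equal(side$command, "test run")
  unlink(c(f, paste0(f, ".json")))
})

test_that("stacks with values outside [0,1] round-trip via sidecar rescaling", {
  arr <- array(rnorm(5 * 4 * 3, 0, 1), c(5, 4, 3))   # negatives and > 1
  v <- image_volume(arr)
  f <- tempfile(fileext = ".tif")
  write_stack(v, f)
  r <- read_stack(f)
  expect_equal(as.numeric(r), as.numeric(v), tolerance = 1e-6)
  unlink(c(f, paste0(f, ".json")))
})

test_that("write_stack refuses non-3D input", {
  v <- image_volume(array(0, c(3, 3, 2)))
  m <- matrix(0, 3, 3)
  class(m) <- c("image_volume", "matrix")
  attr(m, "voxel_size_um") <- c(x = 1, y = 1, z = 1)
  expect_error(write_stack(m, tempfile()), "3D")
})

test_that("16-bit integer stacks load as float in [0,1] scaled by dtype max", {
  vals <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(vals, vals), f, bits.per.sample = 16L)
  r <- read_stack(f, voxel_size_um = c(0.645, 0.645, 1))
  # writeTIFF quantizes (truncates) to value*65535; readback divides by 65535
  expect_equal(as.numeric(r[, , 1]), as.numeric(floor(vals * 65535) / 65535),
               tolerance = 1e-9)
  expect_true(all(r >= 0 & r <= 1))
  unlink(f)
})

test_that("voxel-size precedence: sidecar over tags, override over sidecar", {
  v <- image_volume(array(runif(8), c(2, 2, 2)), c(0.645, 0.645, 1))
  f <- tempfile(fileext = ".tif")
  write_stack(v, f)
  r1 <- read_stack(f)
  expect_equal(unname(voxel_size(r1)["z"]), 1)
  r2 <- read_stack(f, voxel_size_um = c(NA, NA, 2.5))
  expect_equal(unname(voxel_size(r2)), c(0.645, 0.645, 2.5))
  # no metadata anywhere -> error
  unlink(paste0(f, ".json"))
  expect_error(read_stack(f), "voxel size missing")
  unlink(f)
})
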