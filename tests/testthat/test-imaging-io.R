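test_that("scalar volumes round-trip through NIfTI exactly", {
  set.seed(11)
  a <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  vol <- scalar_volume(a, voxel_size = c(2, 2, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_scalar_volume(vol, f)
  back <- load_scalar_volume(f)
  expect_identical(back$data, vol$data)
  expect_equal(back$voxel_size, vol$voxel_size)
  expect_equal(back$affine[1:3, 1:3], vol$affine[1:3, 1:3])
  ## tensor round trip
  tv <- iso_tensor_volume(3, 1.5, 2e-10)
  ft <- withr::local_tempfile(fileext = ".nii.gz")
  write_tensor_volume(tv, ft)
  backt <- load_tensor_volume(ft)
  expect_identical(backt$data, tv$data)
})

test_that("volume constructors reject malformed input", {
  expect_error(scalar_volume(matrix(0, 3, 3)), "3-D")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(matrix(0, 4, 4))
  RNifti::writeNifti(img, f)
  expect_error(load_scalar_volume(f), "3-D")
  expect_error(load_scalar_volume(file.path(tempdir(), "nope.nii")),
               "not found")
  a <- array(1, c(3, 3, 3)); a[1, 1, 1] <- NaN
  expect_error(scalar_volume(a, mask = array(TRUE, c(3, 3, 3))),
               "non-finite.*1 voxel")
  expect_error(scalar_volume(array(1, c(3, 3, 3)), voxel_size = c(1, -1, 1)),
               "positive")
})

test_that("NODDI reparameterization follows the multiplicative convention", {
  mk <- function(x) svol(array(x, c(2, 2, 2)))
  nm <- reparameterize_noddi(mk(0.5), mk(0.2))
  expect_equal(nm$vf_inc$data[1], 0.4)
  expect_equal(nm$vf_enc$data[1], 0.4)
  expect_equal(nm$vf_water$data[1], 0.2)
  expect_equal(nm$vf_ecs$data[1], 0.6)
  ## pure-CSF voxel and fully intraneurite voxel
  expect_equal(reparameterize_noddi(mk(0.37), mk(1))$vf_ecs$data[1], 1)
  expect_equal(reparameterize_noddi(mk(1), mk(0))$vf_ecs$data[1], 0)
  ## errors
  expect_error(reparameterize_noddi(mk(1.5), mk(0.2)), "outside")
  expect_error(reparameterize_noddi(mk(0.5), svol(array(0.2, c(3, 2, 2)))),
               "grid")
})

test_that("reparameterized compartments always sum to one", {
  set.seed(42)
  for (q in 1:10) {
    a <- array(runif(27), c(3, 3, 3))
    b <- array(runif(27), c(3, 3, 3))
    nm <- reparameterize_noddi(svol(a), svol(b))
    s <- nm$vf_inc$data + nm$vf_enc$data + nm$vf_water$data
    expect_true(max(abs(s - 1)) < 1e-12)
    expect_identical(nm$vf_ecs$data, nm$vf_enc$data + nm$vf_water$data)
  }
})

test_that("eigendecomposition reconstructs the tensor and sorts values", {
  set.seed(7)
  d <- c(3, 3, 3)
  tens <- array(0, c(d, 6))
  mats <- vector("list", prod(d))
  q <- 1
  for (k in 1:3) for (j in 1:3) for (i in 1:3) {
    m <- random_spd()
    mats[[q]] <- m
    tens[i, j, k, ] <- cedflow:::tensor_pack(m)
    q <- q + 1
  }
  tv <- tensor_volume(tens, voxel_size = 1, mask = array(TRUE, d))
  eig <- eigendecompose(tv)
  q <- 1
  for (k in 1:3) for (j in 1:3) for (i in 1:3) {
    lam <- eig$values[i, j, k, ]
    E <- eig$vectors[i, j, k, , ]
    expect_true(all(diff(lam) <= 0))          ## descending
    expect_equal(crossprod(E), diag(3), tolerance = 1e-10)
    recon <- E %*% diag(lam) %*% t(E)
    expect_equal(recon, mats[[q]], tolerance = 1e-10)
    q <- q + 1
  }
  ## diagonal and identity special cases
  expect_error(cedflow:::eigen_voxel(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1),
                                            3, 3)), "symmetric")
  ev <- cedflow:::eigen_voxel(diag(c(3, 2, 1)))
  expect_equal(ev$values, c(3, 2, 1))
  expect_equal(abs(ev$vectors), diag(3), tolerance = 1e-12)
})

test_that("FA matches its closed form and is rotation invariant", {
  d <- c(1, 1, 1)
  mkeig <- function(lam, E = diag(3)) {
    tens <- array(cedflow:::tensor_pack(E %*% diag(lam) %*% t(E)),
                  c(d, 6))
    eigendecompose(tensor_volume(tens, voxel_size = 1,
                                 mask = array(TRUE, d)), eps = 0)
  }
  expect_equal(compute_fa(mkeig(c(1, 1, 1)))$data[1], 0)
  expect_equal(compute_fa(mkeig(c(1, 1e-13, 1e-13)))$data[1], 1,
               tolerance = 1e-6)
  ## frozen high-precision evaluation of the definition
  expect_equal(compute_fa(mkeig(c(1.7, 0.3, 0.3) * 1e-3))$data[1],
               0.799022203749, tolerance = 1e-9)
  ## zero tensor convention
  expect_equal(cedflow:::fa_from_lambdas(0, 0, 0), 0)
  ## rotation invariance over random rotations
  set.seed(3)
  for (q in 1:8) {
    lam <- sort(runif(3, 0.1, 2), decreasing = TRUE)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    fa0 <- compute_fa(mkeig(lam))$data[1]
    faR <- compute_fa(mkeig(lam, R))$data[1]
    expect_equal(faR, fa0, tolerance = 1e-8)
  }
})
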