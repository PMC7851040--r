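test_that("infusion region thresholds at the stated concentration fraction", {
  c0 <- 500
  a <- array(c0, c(3, 3, 3))
  reg <- infusion_region(svol(a, 2), c0)
  expect_equal(reg$n, 27L)
  expect_equal(reg$volume, 27 * 8)
  ## everything below threshold: empty region allowed
  reg0 <- infusion_region(svol(array(0.01 * c0, c(3, 3, 3)), 2), c0)
  expect_equal(reg0$n, 0L)
  expect_equal(reg0$volume, 0)
  ## mixed: only the voxels strictly above 2.5% survive
  b <- array(0.01 * c0, c(4, 1, 1)); b[1:2, 1, 1] <- 0.03 * c0
  expect_equal(infusion_region(svol(b), c0)$n, 2L)
  ## threshold is strict
  d <- array(0.025 * c0, c(2, 1, 1))
  expect_equal(infusion_region(svol(d), c0)$n, 0L)
})

test_that("RMSD matches hand evaluations and its invariances", {
  c0 <- 500
  a <- array(runif(8, 0.1, 1) * c0, c(2, 2, 2))
  va <- svol(a)
  expect_equal(rmsd(va, va, c0), 0)
  ## single voxel, full versus zero concentration
  one <- array(0, c(1, 1, 1)); one[1] <- c0
  expect_equal(rmsd(svol(one), svol(array(0, c(1, 1, 1))), c0), 1)
  ## two voxels swapped: union is both, each differs by c0
  x <- array(c(c0, 0), c(2, 1, 1)); y <- array(c(0, c0), c(2, 1, 1))
  expect_equal(rmsd(svol(x), svol(y), c0), 1)
  ## symmetry and scale covariance
  set.seed(21)
  b <- array(runif(8, 0, 1) * c0, c(2, 2, 2))
  vb <- svol(b)
  expect_equal(rmsd(va, vb, c0), rmsd(vb, va, c0))
  expect_equal(rmsd(svol(3 * a), svol(3 * b), 3 * c0),
               rmsd(va, vb, c0), tolerance = 1e-12)
  ## empty union convention
  z <- svol(array(0, c(2, 2, 2)))
  expect_equal(rmsd(z, z, c0), 0)
  expect_error(rmsd(va, svol(array(0, c(3, 2, 2))), c0), "grid")
})

test_that("principal direction recovers known region geometry", {
  c0 <- 1
  line <- array(0, c(9, 3, 3)); line[, 2, 2] <- 1
  reg <- infusion_region(svol(line), c0, 0.5)
  expect_equal(principal_direction(reg), c(1, 0, 0),
               ignore_attr = TRUE)
  ## ellipsoidal region: longest axis recovered
  d <- c(21, 21, 21)
  ell <- array(0, d)
  for (i in 1:21) for (j in 1:21) for (k in 1:21)
    if (((i - 11) / 8)^2 + ((j - 11) / 4)^2 + ((k - 11) / 2)^2 <= 1)
      ell[i, j, k] <- 1
  rege <- infusion_region(svol(ell), c0, 0.5)
  de <- principal_direction(rege)
  expect_equal(abs(de[1]), 1, tolerance = 1e-8)
  ## spherical region flags a degenerate spectrum
  sph <- array(0, d)
  for (i in 1:21) for (j in 1:21) for (k in 1:21)
    if ((i - 11)^2 + (j - 11)^2 + (k - 11)^2 <= 36) sph[i, j, k] <- 1
  regs <- infusion_region(svol(sph), c0, 0.5)
  expect_true(attr(principal_direction(regs), "degenerate"))
  ## fewer than two voxels: undefined
  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  expect_error(principal_direction(infusion_region(svol(single), c0,
                                                   0.5)),
               "undefined")
})

test_that("axis angle uses the absolute dot product in degrees", {
  expect_equal(angle_between(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angle_between(c(1, 0, 0), c(-1, 0, 0)), 0)
  expect_equal(angle_between(c(1, 0, 0), c(1, 1, 0) / sqrt(2)), 45)
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
})

test_that("penetration length is the projected extent plus one voxel", {
  c0 <- 1
  line <- array(0, c(7, 3, 3)); line[2:6, 2, 2] <- 1
  reg <- infusion_region(scalar_volume(line, voxel_size = 2,
                                       mask = array(TRUE, dim(line))),
                         c0, 0.5)
  ## 5 collinear voxels at 2 mm spacing: extent 8 mm plus one voxel
  expect_equal(penetration_length(reg, c(1, 0, 0)), 8 + 2)
  ## single voxel: one voxel size
  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  regs <- infusion_region(svol(single), c0, 0.5)
  expect_equal(penetration_length(regs, c(1, 0, 0)), 1)
  ## translation invariance
  line2 <- array(0, c(7, 3, 3)); line2[3:7, 1, 1] <- 1
  reg2 <- infusion_region(scalar_volume(line2, voxel_size = 2,
                                        mask = array(TRUE, dim(line2))),
                          c0, 0.5)
  expect_equal(penetration_length(reg2, c(1, 0, 0)),
               penetration_length(reg, c(1, 0, 0)))
})

test_that("overlap fraction implements Jaccard identities", {
  c0 <- 1
  mk <- function(sel) {
    a <- array(0, c(4, 4, 4)); a[sel] <- 1
    infusion_region(svol(a), c0, 0.5)
  }
  A <- mk(1:16); B <- mk(17:32); AB <- mk(1:32); half <- mk(1:8)
  expect_equal(overlap_fraction(A, A), 100, ignore_attr = TRUE)
  expect_equal(overlap_fraction(A, B), 0, ignore_attr = TRUE)
  ## A subset of B with half the volume
  expect_equal(overlap_fraction(half, A), 50, ignore_attr = TRUE)
  expect_equal(attr(overlap_fraction(half, A), "over_min"), 100)
  ## range and identity property
  o <- overlap_fraction(A, AB)
  expect_true(o >= 0 && o <= 100 && o < 100)
})

test_that("orientation statistics match hand-computed t tests", {
  ## textbook example: mean 2, sd 1, n 3, one-sided
  st <- orientation_stats(c(1, 2, 3), "one_sample_one_sided")
  expect_equal(st$statistic, 3.46410161514, tolerance = 1e-9)
  expect_equal(st$p_value, 0.0370899501137, tolerance = 1e-9)
  expect_equal(st$df, 2)
  ## degenerate inputs
  expect_error(orientation_stats(rep(0, 5), "one_sample_one_sided"),
               "zero variance")
  pr <- orientation_stats(c(1, 2, 3), "paired_two_sided",
                          values2 = c(1, 2, 3))
  expect_equal(pr$statistic, 0)
  expect_equal(pr$p_value, 1)
  ## ordinary paired case agrees with stats::t.test
  x <- c(5.1, 4.8, 6.2, 5.9); y <- c(4.9, 4.1, 5.8, 5.2)
  pp <- orientation_stats(x, "paired_two_sided", values2 = y)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(pp$statistic, unname(ref$statistic))
  expect_equal(pp$p_value, ref$p.value)
})
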