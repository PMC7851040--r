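test_that("tissue segmentation follows the threshold table with CSF precedence", {
  fa <- svol(array(c(0.5, 0.1, 0.05, 0.23, 0.9, 0.3, 0.0, 0.7),
                   c(2, 2, 2)))
  vfw <- svol(array(c(0.2, 0.3, 0.995, 0.5, 0.2, 0.991, 0.98, 0.2),
                    c(2, 2, 2)))
  lab <- segment_tissue(fa, vfw)
  expect_equal(as.vector(lab$labels),
               c(2L, 1L, 3L, 1L, 2L, 3L, 1L, 2L))
  ## FA exactly at the threshold goes to grey matter (closed top)
  expect_equal(lab$labels[2, 2, 1], 1L)
  ## CSF wins even at high FA
  expect_equal(lab$labels[2, 1, 2], 3L)
  expect_error(segment_tissue(fa, svol(array(0, c(3, 2, 2)))), "grid")
})

test_that("permeability laws reproduce their printed closed forms", {
  r <- 0.34e-6
  ## frozen high-precision evaluations of the printed expressions
  expect_equal(k_parallel(0.30, r), 6.06666314651e-16, tolerance = 1e-9)
  expect_equal(k_parallel(0.15, r), 5.30972380456e-17, tolerance = 1e-9)
  expect_equal(k_perpendicular(0.30, r), 2.00199411822e-17,
               tolerance = 1e-9)
  ## r^2 scaling
  v <- seq(0.2, 0.8, by = 0.1)
  expect_equal(k_parallel(v, 2 * r), 4 * k_parallel(v, r))
  expect_equal(k_perpendicular(v, 2 * r), 4 * k_perpendicular(v, r))
  ## clamping outside the fitted range
  expect_equal(k_parallel(0.05, r), k_parallel(0.15, r))
  expect_equal(k_parallel(0.95, r), k_parallel(0.80, r))
  expect_error(k_parallel(0.3, -1), "positive")
})

test_that("permeability laws are monotone and ordered where positive", {
  r <- 0.34e-6
  v <- seq(0.15, 0.80, by = 0.005)
  kp <- k_parallel(v, r)
  kt <- k_perpendicular(v, r)
  ## parallel law: positive and strictly increasing over the whole range
  expect_true(all(kp > 0))
  expect_true(all(diff(kp) > 0))
  expect_true(all(diff(kt) > 0))
  ## the printed perpendicular law changes sign near vf_ecs ~ 0.295;
  ## where it is positive it must stay below the parallel law
  pos <- kt > 0
  expect_true(any(pos) && any(!pos))
  expect_true(all(kt[pos] < kp[pos]))
  expect_true(all(v[!pos] < 0.30))
})

test_that("diffusivity builder rescales WM tensors to the tracer trace", {
  ph <- generate_phantom(phantom_spec("three_tissue", shape = c(6, 6, 9),
                                      voxel_size = 2))
  lab <- segment_tissue(ph$fa, ph$noddi$vf_water)
  expect_equal(lab$labels, ph$labels_truth)
  eig <- eigendecompose(ph$tensor)
  D0 <- tissue_constants()$D0
  D <- build_diffusivity(lab, eig)
  tr <- D$data[, , , 1] + D$data[, , , 3] + D$data[, , , 6]
  ## WM trace identity
  expect_equal(tr[lab$labels == 2L], rep(3 * D0, sum(lab$labels == 2L)),
               tolerance = 1e-10)
  ## GM voxels are isotropic D0 I with exactly zero off-diagonals
  gm <- which(lab$labels == 1L, arr.ind = TRUE)[1, ]
  m <- cedflow:::tensor_at(D, gm[1], gm[2], gm[3])
  expect_equal(m, D0 * diag(3))
  ## isotropic WM eigenvalues collapse to D0 I
  d1 <- c(1, 1, 1)
  tens <- array(cedflow:::tensor_pack(diag(3) * 7e-10), c(d1, 6))
  tv <- tensor_volume(tens, voxel_size = 2, mask = array(TRUE, d1))
  lab1 <- segment_tissue(svol(array(0.5, d1)), svol(array(0.1, d1)))
  D1 <- build_diffusivity(lab1, eigendecompose(tv))
  expect_equal(cedflow:::tensor_at(D1, 1, 1, 1), D0 * diag(3),
               tolerance = 1e-12)
})

test_that("permeability builder produces transversely isotropic SPD tensors", {
  ph <- generate_phantom(phantom_spec("uniform_wm_slab",
                                      shape = c(4, 4, 4), voxel_size = 2,
                                      vf_ecs = 0.30))
  lab <- segment_tissue(ph$fa, ph$noddi$vf_water)
  eig <- eigendecompose(ph$tensor)
  con <- tissue_constants()
  ## constant mode: eigenvalues are the fixed baseline pair
  Kc <- build_permeability(lab, eig, law = permeability_law("constant"))
  m <- cedflow:::tensor_at(Kc, 2, 2, 2)
  ev <- eigen(m, symmetric = TRUE)
  expect_equal(sort(ev$values, decreasing = TRUE),
               c(con$k_par_dti, con$k_perp_dti, con$k_perp_dti))
  ## principal axis matches the fibre direction up to sign
  expect_equal(abs(sum(ev$vectors[, 1] * ph$fibres[2, 2, 2, ])), 1,
               tolerance = 1e-8)
  ## noddi mode at vf_ecs = 0.30 gives the law values
  Kn <- build_permeability(lab, eig, noddi = ph$noddi,
                           law = permeability_law("noddi"))
  evn <- eigen(cedflow:::tensor_at(Kn, 2, 2, 2), symmetric = TRUE)$values
  expect_equal(sort(evn, decreasing = TRUE),
               c(k_parallel(0.30), k_perpendicular(0.30),
                 k_perpendicular(0.30)), tolerance = 1e-12)
  expect_true(all(evn > 0))
  ## baseline mode ignores NODDI maps entirely
  Kc2 <- build_permeability(lab, eig, noddi = ph$noddi,
                            law = permeability_law("constant"))
  expect_identical(Kc$data, Kc2$data)
  ## noddi mode requires the maps
  expect_error(build_permeability(lab, eig, law = permeability_law("noddi")),
               "requires NODDI")
})

test_that("CSF properties are configurable with documented defaults", {
  csf <- csf_properties()
  expect_equal(csf$D_csf, tissue_constants()$D0)
  expect_equal(csf$K_csf, 1e-13)
  expect_equal(csf_properties(K_csf = 5e-14)$K_csf, 5e-14)
})

test_that("unit conversions are exact", {
  expect_equal(cedflow:::cm2_s_to_m2_s(1.54e-6), 1.54e-10)
  expect_equal(ul_min_to_m3_s(3), 5e-11)
  expect_equal(per_min_to_per_s(0.01), 1 / 6000)
  expect_equal(mol_L_to_mol_m3(0.5), 500)
  expect_equal(cedflow:::um_to_m(0.34), 3.4e-7)
})
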