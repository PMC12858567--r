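test_that("segmentation reproduces ground-truth masks and tolerates noise", {
  ph <- make_cortical_tube_phantom(outer_radius = 1, inner_radius = 0.6,
                                   length = 0.06, voxel_size = 12,
                                   tmd_mean = 900, seed = 1)
  seg <- segment_volume(ph$volume, segmentation_params(gauss_sigma = 0,
                                                       threshold = 450))
  expect_identical(as.vector(seg), as.vector(ph$mask))
  noisy <- make_cortical_tube_phantom(outer_radius = 1, inner_radius = 0.6,
                                      length = 0.06, voxel_size = 12,
                                      tmd_mean = 900, noise_sd = 100,
                                      seed = 4)
  segn <- segment_volume(noisy$volume,
                         segmentation_params(gauss_sigma = 1.2,
                                             gauss_support = 2,
                                             threshold = 450))
  expect_lt(mean(segn != noisy$mask), 0.01)
  empty <- voxel_volume(array(0, c(8, 8, 8)), 12)
  expect_warning(m <- segment_volume(empty, segmentation_params(
    gauss_sigma = 0, threshold = 450)), "empty")
  expect_false(any(m))
})

test_that("Euler characteristic matches exhaustive cube-complex counting", {
  # deterministic small shapes
  solid <- array(TRUE, c(3, 3, 3))
  expect_identical(euler_characteristic(solid), 1L)     # ball
  torus <- array(FALSE, c(5, 5, 3))
  torus[2:4, 2:4, 2] <- TRUE
  torus[3, 3, 2] <- FALSE
  expect_identical(euler_characteristic(torus), 0L)     # one handle
  hollow <- array(TRUE, c(4, 4, 4))
  hollow[2:3, 2:3, 2:3] <- FALSE
  expect_identical(euler_characteristic(hollow), 2L)    # spherical shell
  # random fixtures up to 20^3, exact agreement with the oracle
  set.seed(20)
  for (n in c(6L, 12L, 20L)) {
    m <- array(runif(n^3) < 0.35, rep(n, 3))
    expect_identical(euler_characteristic(m), as.integer(oracle_euler(m)))
  }
})

test_that("a single solid torus gives Conn.D = 1/TV", {
  voi <- array(FALSE, c(12, 12, 5))
  voi[3:10, 3:10, 2:3] <- TRUE
  voi[5:8, 5:8, 2:3] <- FALSE
  vol <- voxel_volume(voi * 900, 100)        # 0.1 mm voxels
  tm <- trabecular_morphometry(voi, vol, metrics = c("conn_d"))
  expect_identical(tm$euler, 0L)
  tv <- length(voi) * 0.1^3
  expect_equal(tm$conn_d, 1 / tv)
})

test_that("lattice phantom morphometry recovers thickness, spacing and number", {
  ph <- make_trabecular_lattice_phantom(rod_diameter = 0.06, pitch = 0.30,
                                        n_cells = 2, voxel_size = 12, seed = 1)
  tm <- trabecular_morphometry(ph$mask, ph$volume)
  h <- 0.012
  expect_equal(tm$bvtv, ph$truth$bvtv)
  expect_lt(abs(tm$tb_th - ph$truth$tb_th), h)          # within one voxel
  expect_lt(abs(tm$tb_n - ph$truth$tb_n) / ph$truth$tb_n, 0.10)
  # sphere-fit separation of a 3D rod lattice exceeds the face gap s - d but
  # stays below the diagonal pore diameter sqrt(2)s - d
  expect_gt(tm$tb_sp, ph$truth$tb_sp)
  expect_lt(tm$tb_sp, sqrt(2) * 0.30 - 0.06)
  expect_equal(tm$conn_d, ph$truth$conn_d)
  expect_equal(tm$tb_tmd, 900)
  # plate-model flag is exact on the lattice: 1/(Tb.Th + Tb.Sp) with the
  # nominal thickness/separation sums to the pitch
  tmp <- trabecular_morphometry(ph$mask, ph$volume, tb_n_method = "plate",
                                metrics = c("tb_th", "tb_sp", "tb_n"))
  expect_equal(tmp$tb_n, 1 / (tmp$tb_th + tmp$tb_sp))
})

test_that("solid block VOI reports BV/TV 1 with flagged undefined separation", {
  blk <- make_trabecular_lattice_phantom(fill = TRUE, n_cells = 1,
                                         voxel_size = 24)
  tm <- trabecular_morphometry(blk$mask, blk$volume,
                               metrics = c("bvtv", "tb_sp"))
  expect_equal(tm$bvtv, 1.0)
  expect_true(is.na(tm$tb_sp))
  expect_true("tb_sp_undefined_no_background" %in% tm$flags)
})

test_that("BV/TV and Tb.Th are invariant under right-angle rotations", {
  ph <- make_trabecular_lattice_phantom(rod_diameter = 0.06, pitch = 0.24,
                                        n_cells = 2, voxel_size = 15, seed = 2)
  tm0 <- trabecular_morphometry(ph$mask, ph$volume,
                                metrics = c("bvtv", "tb_th"))
  rots <- list(function(m) aperm(m, c(2, 1, 3))[dim(m)[2]:1, , , drop = FALSE],
               function(m) aperm(m, c(1, 3, 2))[, dim(m)[3]:1, , drop = FALSE],
               function(m) aperm(m, c(3, 2, 1))[, , dim(m)[1]:1, drop = FALSE])
  for (rot in rots) {
    mr <- rot(ph$mask)
    volr <- voxel_volume(rot(ph$volume$data), 15)
    tmr <- trabecular_morphometry(mr, volr, metrics = c("bvtv", "tb_th"))
    expect_equal(tmr$bvtv, tm0$bvtv)
    expect_lt(abs(tmr$tb_th - tm0$tb_th), 0.015)        # one voxel
  }
})

test_that("peel increases measured TMD when surface voxels are depressed", {
  # partial-volume emulation: surface voxels at 600, core at 900
  ph <- make_cortical_tube_phantom(outer_radius = 0.6, inner_radius = 0.2,
                                   length = 0.12, voxel_size = 12,
                                   tmd_mean = 900, seed = 1)
  data <- ph$volume$data
  surf <- ph$mask & !bonefrag:::peel_mask(ph$mask, 1)
  data[surf] <- 600
  vol <- voxel_volume(data, 12)
  t0 <- trabecular_morphometry(ph$mask, vol, peel_voxels = 0,
                               metrics = "tb_tmd")
  t2 <- trabecular_morphometry(ph$mask, vol, peel_voxels = 2,
                               metrics = "tb_tmd")
  expect_gt(t2$tb_tmd, t0$tb_tmd)
  expect_equal(t2$tb_tmd, 900)
})

test_that("annulus cortical morphometry recovers the closed forms and converges", {
  truth <- list(ct_ar = pi * (1 - 0.36), i_min = pi / 4 * (1 - 0.6^4),
                ct_th = 0.4)
  errs <- sapply(c(24, 12), function(vs) {
    ph <- make_cortical_tube_phantom(outer_radius = 1, inner_radius = 0.6,
                                     length = 0.1, voxel_size = vs, seed = 1)
    cm <- cortical_morphometry(ph$mask, ph$volume)
    c(ct_ar = abs(cm$ct_ar / truth$ct_ar - 1),
      i_min = abs(cm$i_min / truth$i_min - 1),
      ct_th = abs(cm$ct_th / truth$ct_th - 1))
  })
  expect_lt(max(errs[, 2]), 0.02)                       # 12 um within 2%
  expect_true(all(errs[, 2] <= errs[, 1] + 1e-6))       # refinement improves
})

test_that("cortical porosity and TMD follow the phantom ground truth", {
  ph <- make_cortical_tube_phantom(outer_radius = 1, inner_radius = 0.6,
                                   length = 0.08, voxel_size = 12,
                                   porosity = 0.05, seed = 7)
  cm <- cortical_morphometry(ph$mask, ph$volume)
  expect_lt(abs(cm$ct_po - ph$truth$ct_po), 0.005)
  uni <- make_cortical_tube_phantom(outer_radius = 0.8, inner_radius = 0.4,
                                    length = 0.08, voxel_size = 12,
                                    tmd_mean = 900, seed = 2)
  cmu <- cortical_morphometry(uni$mask, uni$volume)
  expect_equal(cmu$ct_tmd, 900)
})

test_that("I_min matches the elliptical-ring closed form and is rotation-stable", {
  # elliptical ring, outer (a, b) = (0.8, 0.5) mm, inner scaled by 0.5:
  # I_min = pi/4 * a * b^3 * (1 - 0.5^4)
  h <- 0.01
  n <- 180
  cx <- (seq_len(n) - 0.5) * h - 0.9
  ell_ring <- function(phi) {
    X <- outer(cx, rep(1, n)); Y <- outer(rep(1, n), cx)
    xr <- X * cos(phi) + Y * sin(phi); yr <- -X * sin(phi) + Y * cos(phi)
    ((xr / 0.8)^2 + (yr / 0.5)^2 <= 1) &
      !((xr / 0.4)^2 + (yr / 0.25)^2 <= 1)
  }
  i_true <- pi / 4 * 0.8 * 0.5^3 * (1 - 0.5^4)
  mask0 <- array(ell_ring(0), c(n, n, 2))
  cm0 <- cortical_morphometry(mask0, voxel_volume(mask0 * 900, 10))
  expect_equal(cm0$i_min, i_true, tolerance = 0.005)
  expect_equal(cm0$tt_ar, pi * 0.8 * 0.5, tolerance = 0.005)
  # in-plane rotation changes only the discretization
  mask45 <- array(ell_ring(pi / 4), c(n, n, 2))
  cm45 <- cortical_morphometry(mask45, voxel_volume(mask45 * 900, 10))
  expect_lt(abs(cm45$i_min / cm0$i_min - 1), 0.005)
})

test_that("broken cortical rings are excluded with a warning", {
  ph <- make_cortical_tube_phantom(outer_radius = 0.6, inner_radius = 0.4,
                                   length = 0.06, voxel_size = 12, seed = 1)
  mask <- ph$mask
  mask[, , 2] <- FALSE                                   # empty slice
  expect_warning(cm <- cortical_morphometry(mask, ph$volume), "excluded")
  expect_equal(cm$n_slices_used, dim(mask)[3] - 1L)
  all_broken <- array(FALSE, dim(mask))
  expect_error(cortical_morphometry(all_broken, ph$volume), "broken")
})
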