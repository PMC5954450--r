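test_that("binarization separates phases and is idempotent on binary input", {
  d <- c(20L, 20L, 20L)
  # bimodal image, modes 40 and 200 with equal counts
  withr::with_seed(1, {
    vals <- sample(rep(c(40, 200), each = prod(d) / 2))
  })
  gv <- gray_volume(array(vals, d), 0.01)
  bv <- binarize(gv)
  expect_gt(bv$provenance$threshold, 40)
  expect_lt(bv$provenance$threshold, 200)
  expect_identical(bv$data, array(vals, d) > bv$provenance$threshold)

  # noisy rendering of a known mask recovers >= 99.9% of voxels
  ball <- generate_phantom(phantom_spec("ball", 33, 0.01, list(radius = 12)))
  withr::with_seed(2, {
    noisy <- ball$volume$data * 255 + rnorm(prod(dim(ball$volume$data)),
                                            sd = 10)
  })
  noisy <- array(pmin(pmax(round(noisy), 0), 255), dim(ball$volume$data))
  rec <- binarize(gray_volume(noisy, 0.01))
  expect_gte(mean(rec$data == ball$volume$data), 0.999)

  # already binary 0/255: output equals input > 0
  bin255 <- gray_volume(ball$volume$data * 255, 0.01)
  expect_identical(binarize(bin255)$data, ball$volume$data)

  expect_error(binarize(gray_volume(array(7, d), 0.01)), "no threshold")
})

test_that("purify keeps the largest component and fills enclosed cavities", {
  d <- c(48L, 24L, 24L)
  two <- make_ball_mask(d, c(12, 12, 12), 8) |
    make_ball_mask(d, c(36, 12, 12), 4)
  out <- purify(bin_volume(two, 0.01))
  expect_identical(out$data, make_ball_mask(d, c(12, 12, 12), 8))

  hollow <- make_ball_mask(c(24L, 24L, 24L), c(12, 12, 12), 9) &
    !make_ball_mask(c(24L, 24L, 24L), c(12, 12, 12), 5)
  filled <- purify(bin_volume(hollow, 0.01))
  expect_identical(filled$data, make_ball_mask(c(24L, 24L, 24L),
                                               c(12, 12, 12), 9))

  # open-pore lattice is already purified
  lat <- generate_phantom(phantom_spec("rod_lattice", 32, 0.01,
                                       list(spacing = 8, radius = 2)))
  expect_identical(purify(lat$volume)$data, lat$volume$data)

  expect_error(purify(bin_volume(array(FALSE, c(8, 8, 8)), 0.01)), "empty")
})

test_that("bone volume fraction is the exact voxel count ratio", {
  m <- array(FALSE, c(2L, 2L, 2L))
  m[c(1, 4, 7)] <- TRUE
  expect_equal(bone_volume_fraction(bin_volume(m, 1)), 0.375)
  expect_equal(bone_volume_fraction(bin_volume(array(TRUE, c(10, 10, 10)),
                                               1)), 1.0)
})

test_that("Euler connectivity matches topology on known solids", {
  box <- bin_volume(array(TRUE, c(5L, 5L, 5L)), 0.01)
  eb <- euler_connectivity(box)
  expect_identical(eb$delta_chi, 1L)
  expect_identical(eb$conn, 0L)

  et <- euler_connectivity(bin_volume(make_torus(), 0.01))
  expect_identical(et$delta_chi, 0L)
  expect_identical(et$conn, 1L)

  # 3x3x3-node lattice skeleton: conn = E - V + 1 = 28
  ph <- generate_phantom(phantom_spec("rod_lattice", 40, 0.01,
                                      list(spacing = 12, radius = 2)))
  expect_identical(ph$truth$n_nodes_per_axis, 3L)
  expect_identical(oracle_lattice_cycle_rank(3), 28L)
  expect_identical(euler_connectivity(ph$volume)$conn, 28L)

  # ConnD normalization by physical stack volume
  e <- euler_connectivity(bin_volume(ph$volume$data, 0.02))
  expect_equal(e$conn_density, e$conn / (prod(dim(ph$volume$data)) * 0.02^3))
})

test_that("local thickness matches the brute-force maximal-sphere oracle", {
  cyl <- generate_phantom(phantom_spec("cylinder", c(21, 21, 16), 0.01,
                                       list(radius = 5)))
  lt <- local_thickness(cyl$volume, "foreground", keep_map = TRUE)
  oracle <- oracle_thickness_map(cyl$volume$data) * cyl$volume$voxel_size
  expect_equal(lt$map, oracle, tolerance = 1e-12)

  # mean diameter within one voxel of 10 voxels
  expect_lt(abs(lt$mean - 0.10), 0.01 + 1e-9)

  # random-field phantom, background phase, same convention
  rf <- generate_phantom(phantom_spec("random_field", 18, 0.01,
                                      list(target_vf = 0.4,
                                           corr_length = 2.5), seed = 4))
  ltb <- local_thickness(rf$volume, "background", keep_map = TRUE)
  expect_equal(ltb$map, oracle_thickness_map(!rf$volume$data) * 0.01,
               tolerance = 1e-12)
})

test_that("plate and ball thickness agree with geometry within one voxel", {
  pl <- generate_phantom(phantom_spec("plate_stack", c(32, 32, 22), 0.02,
                                      list(thickness = 7, gap = 4)))
  expect_lt(abs(local_thickness(pl$volume, "foreground")$mean - 0.14),
            0.02 + 1e-9)
  expect_lt(abs(local_thickness(pl$volume, "background")$mean - 0.08),
            0.02 + 1e-9)

  ball <- generate_phantom(phantom_spec("ball", 26, 0.01, list(radius = 10)))
  m <- local_thickness(ball$volume, "foreground", keep_map = TRUE)$map
  thicknesses <- round(m[ball$volume$data] / 0.01)
  modal <- as.integer(names(which.max(table(thicknesses))))
  expect_equal(modal, 20, tolerance = 1)

  # thickness maps of complementary phases never share support
  fgm <- local_thickness(ball$volume, "foreground", keep_map = TRUE)$map
  bgm <- local_thickness(ball$volume, "background", keep_map = TRUE)$map
  expect_false(any(fgm > 0 & bgm > 0))
  expect_error(local_thickness(bin_volume(array(TRUE, c(8, 8, 8)), 0.01),
                               "background"), "empty")
})

test_that("isosurface area matches analytic solids", {
  ball <- generate_phantom(phantom_spec("ball", 31, 0.01, list(radius = 12)))
  sd_ <- surface_density(ball$volume)
  # area within 3% of 4 pi r^2 implies bs_bv within 4% of 3/r
  expect_equal(sd_$area, 4 * pi * (12 * 0.01)^2, tolerance = 0.03)
  expect_equal(sd_$bs_bv, ball$truth$bs_bv, tolerance = 0.04)

  box <- generate_phantom(phantom_spec("box", c(34, 40, 46), 0.01,
                                       list(extent = c(20, 26, 32))))
  expect_equal(surface_density(box$volume)$bs_bv, box$truth$bs_bv,
               tolerance = 0.05)

  # doubling the voxel size halves the surface density
  b1 <- surface_density(bin_volume(ball$volume$data, 0.01))$bs_bv
  b2 <- surface_density(bin_volume(ball$volume$data, 0.02))$bs_bv
  expect_equal(b2, b1 / 2, tolerance = 1e-12)
})

test_that("all parameters transform correctly under voxel-size rescaling", {
  rf <- generate_phantom(phantom_spec("random_field", 40, 0.01,
                                      list(target_vf = 0.35,
                                           corr_length = 3), seed = 9))
  v1 <- bin_volume(rf$volume$data, 0.01)
  v2 <- bin_volume(rf$volume$data, 0.02)
  s1 <- summarize_morphometry(v1, n_directions = 128)
  s2 <- summarize_morphometry(v2, n_directions = 128)
  expect_equal(s2$bv_tv, s1$bv_tv)
  expect_identical(s2$conn, s1$conn)
  expect_equal(s2$da, s1$da, tolerance = 1e-12)
  expect_equal(s2$tb_th, 2 * s1$tb_th, tolerance = 1e-12)
  expect_equal(s2$tb_sp, 2 * s1$tb_sp, tolerance = 1e-12)
  expect_equal(s2$conn_density, s1$conn_density / 8, tolerance = 1e-12)
  expect_equal(s2$bs_bv, s1$bs_bv / 2, tolerance = 1e-12)
  expect_equal(s2$relative_resolution, s1$relative_resolution,
               tolerance = 1e-12)
})

test_that("degenerate all-foreground volume reports missing fabric with a flag", {
  s <- summarize_morphometry(bin_volume(array(TRUE, c(20, 20, 20)), 0.01),
                             n_directions = 128)
  expect_equal(s$bv_tv, 1.0)
  expect_identical(s$conn, 0L)
  expect_true(is.na(s$da))
  expect_true(any(grepl("fabric", s$flags)))
  expect_true(any(grepl("thickness", s$flags)))
})
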