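# Descriptor correctness: analytic limits, brute-force oracle agreement,
# monotonicity, and the baseline extrapolation.

test_that("cell volume is voxel count times physical voxel volume", {
  lab <- array(0L, c(12, 12, 12))
  lab[2:11, 2:11, 2:11] <- 1L
  expect_equal(cell_volume(labeled_volume(lab, c(1, 1, 1)), 1), 1000)
  expect_equal(cell_volume(labeled_volume(lab, c(0.1, 0.1, 0.1)), 1), 1)
  expect_error(cell_volume(labeled_volume(lab, c(1, 1, 1)), 7), "not present")

  vol <- digital_ball(5, 0.2)
  expect_equal(cell_volume(vol, 1), 4 / 3 * pi * 125, tolerance = 0.02)
})

test_that("surface area approaches the analytic sphere value", {
  vol <- digital_ball(10, 0.5)
  sa <- cell_surface_area(vol, 1)
  expect_equal(sa, 4 * pi * 100, tolerance = 0.03)
  # voxel-face counting stays an upper bound
  expect_gt(voxel_face_area(vol, 1), sa)

  lab <- array(0L, c(14, 14, 14))
  lab[3:12, 3:12, 3:12] <- 1L
  cvol <- labeled_volume(lab, c(1, 1, 1))
  expect_equal(voxel_face_area(cvol, 1), 600)
  expect_lt(cell_surface_area(cvol, 1), voxel_face_area(cvol, 1))

  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 1L
  sv <- labeled_volume(single, c(1, 1, 1))
  s1 <- cell_surface_area(sv, 1)
  expect_gt(s1, 0)
  expect_lt(s1, 6)
})

test_that("solidity is 1 for convex cells and the corner hull matches scipy", {
  lab <- array(0L, c(12, 12, 12))
  lab[3:10, 3:10, 3:10] <- 1L
  vol <- labeled_volume(lab, c(1, 1, 1))
  so <- solidity(vol, 1)
  # iso-surface convention: convex cells score 1 up to the sub-voxel
  # concavities of the faceted mesh
  expect_equal(so$solidity, 1, tolerance = 3e-3)
  expect_equal(corner_hull_volume(vol, 1), 8^3, tolerance = 1e-12)

  # 3-armed orthogonal cross: corner hull against the independent oracle
  cr <- array(0L, c(15, 15, 15))
  cr[3:13, 8, 8] <- 1L; cr[8, 3:13, 8] <- 1L; cr[8, 8, 3:13] <- 1L
  cvol <- labeled_volume(cr, c(1, 1, 1))
  pts <- scleromorph:::voxel_corner_points(cvol$labels == 1, cvol$spacing)
  expect_equal(corner_hull_volume(cvol, 1), scipy_hull_volume(pts),
               tolerance = 1e-9)

  # lobed phantoms lose solidity
  ph <- make_lobed_cell(lobed_cell_spec(n_lobes = 12, bump_amplitude = 0.35,
                                        seed = 4))
  expect_lt(solidity(ph$volume, 1)$solidity, 0.97)

  flat <- array(0L, c(4, 4, 4)); flat[2, 2:3, 2:3] <- 1L
  expect_error(solidity(labeled_volume(flat, c(1, 1, 1)), 2), "not present")
})

test_that("largest empty sphere matches analytic and degenerate limits", {
  vol <- digital_ball(8, 1)
  les <- largest_empty_sphere(vol, 1)
  expect_lt(abs(les$diameter - 16), 1)

  bar <- array(0L, c(3, 3, 22)); bar[2, 2, 2:21] <- 1L
  bvol <- labeled_volume(bar, c(1, 1, 1))
  lb <- largest_empty_sphere(bvol, 1)
  expect_lt(lb$diameter, 2.1)

  # inscribed sphere never exceeds the equivalent sphere
  for (seed in 1:5) {
    rv <- random_label_volume(seed, 12)
    for (lb_ in setdiff(unique(as.vector(rv$labels)), 0L)) {
      v <- cell_volume(rv, lb_)
      d <- largest_empty_sphere(rv, lb_)$diameter
      expect_lte(d, (6 * v / pi)^(1 / 3) + sqrt(sum(rv$spacing^2)))
    }
  }
})

test_that("LES and contact tables agree exactly with brute-force oracles", {
  for (seed in 1:8) {
    rv <- random_label_volume(seed, 14)
    m <- rv$labels == 1
    if (any(m) && any(!m))
      expect_equal(largest_empty_sphere(rv, 1)$diameter,
                   les_oracle(m, rv$spacing), tolerance = 1e-12)
    got <- as.data.frame(contact_areas(rv))
    want <- contact_oracle(rv$labels, rv$spacing)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("contact patches: full face, pierced ring, and separated cubes", {
  lab <- array(0L, c(6, 6, 10))
  lab[2:5, 2:5, 2:5] <- 1L
  lab[2:5, 2:5, 6:9] <- 2L
  vol <- labeled_volume(lab, c(1, 1, 1))
  ct <- contact_areas(vol)
  expect_equal(ct$area, 16)
  expect_equal(ct$n_patches, 1)

  # carve the central 2x2 window: ring remains one patch of area 12
  lab2 <- lab
  lab2[3:4, 3:4, 5] <- 0L
  ct2 <- contact_areas(labeled_volume(lab2, c(1, 1, 1)))
  expect_equal(ct2$area, 12)
  expect_equal(ct2$n_patches, 1)

  # full 1-voxel gap: no contact row at all
  lab3 <- lab
  lab3[, , 5] <- 0L
  expect_equal(nrow(contact_areas(labeled_volume(lab3, c(1, 1, 1)))), 0)
})

test_that("neighbour counts follow the 3x3x3 cube-packing and tissue truth", {
  lab <- array(0L, c(8, 8, 8))
  id <- 0L
  for (x in 0:2) for (y in 0:2) for (z in 0:2) {
    id <- id + 1L
    lab[2:3 + 2 * z, 2:3 + 2 * y, 2:3 + 2 * x] <- id
  }
  vol <- labeled_volume(lab, c(1, 1, 1))
  ct <- contact_areas(vol)
  centre <- 14L  # the (z=1,y=1,x=1) block in the iteration order
  expect_equal(neighbour_count(ct, centre), 6)

  tis <- make_tissue(tissue_spec(n_cells = 10, domain_size = c(40, 40, 40),
                                 ics_fraction = 0, seed = 2))
  ct <- contact_areas(tis$volume)
  adj <- tis$truth$adjacency
  for (lb in 1:10) {
    want <- sum(adj$label_a == lb | adj$label_b == lb)
    expect_equal(neighbour_count(ct, lb), want)
  }
})

test_that("descriptors are monotone under voxel addition", {
  set.seed(42)
  lab <- array(0L, c(10, 10, 10))
  lab[4:6, 4:6, 4:6] <- 1L
  vol <- labeled_volume(lab, c(1, 1, 1))
  v0 <- cell_volume(vol, 1)
  h0 <- corner_hull_volume(vol, 1)
  d0 <- largest_empty_sphere(vol, 1)$diameter
  grown <- lab
  grown[4:6, 4:6, 7] <- 1L
  grown[3, 4:6, 4:6] <- 1L
  gvol <- labeled_volume(grown, c(1, 1, 1))
  expect_gte(cell_volume(gvol, 1), v0)
  expect_gte(corner_hull_volume(gvol, 1), h0)
  expect_gte(largest_empty_sphere(gvol, 1)$diameter, d0)
})

test_that("descriptors are exactly invariant under 90-degree rotation", {
  ph <- make_lobed_cell(lobed_cell_spec(n_lobes = 6, bump_amplitude = 0.3,
                                        spacing = c(0.8, 0.8, 0.8), seed = 3))
  vol <- ph$volume
  rot <- labeled_volume(aperm(vol$labels, c(2, 1, 3))[dim(vol$labels)[2]:1, , ],
                        vol$spacing)
  expect_equal(cell_volume(rot, 1), cell_volume(vol, 1))
  expect_equal(largest_empty_sphere(rot, 1)$diameter,
               largest_empty_sphere(vol, 1)$diameter, tolerance = 1e-12)
  expect_equal(corner_hull_volume(rot, 1), corner_hull_volume(vol, 1),
               tolerance = 1e-9)
  # iso-surface triangulation uses a fixed cell diagonal, so mesh-based
  # descriptors are rotation-robust only to discretization level
  expect_equal(solidity(rot, 1)$solidity, solidity(vol, 1)$solidity,
               tolerance = 1e-3)
  expect_equal(cell_surface_area(rot, 1), cell_surface_area(vol, 1),
               tolerance = 1e-3)
})

test_that("the isometric LES baseline extrapolates as volume^(1/3)", {
  ref <- data.frame(volume = c(500, 520, 480), les_diameter = c(9.8, 10.1, 9.6))
  vq <- mean(ref$volume)
  expect_equal(les_baseline(ref, vq), mean(ref$les_diameter), tolerance = 0.01)
  expect_equal(les_baseline(ref, 13 * vq) / les_baseline(ref, vq),
               13^(1 / 3), tolerance = 1e-12)
  expect_error(les_baseline(ref[0, ], 100), "non-empty")

  # lobed cells at 13x volume stay below the no-lobe extrapolation
  small <- make_lobed_cell(lobed_cell_spec(base_radii = c(5, 5, 5),
                                           n_lobes = 0, spacing = c(0.5, 0.5, 0.5),
                                           seed = 1))
  rsmall <- data.frame(volume = cell_volume(small$volume, 1),
                       les_diameter = largest_empty_sphere(small$volume, 1)$diameter)
  big <- make_lobed_cell(lobed_cell_spec(base_radii = rep(5 * 13^(1 / 3), 3),
                                         n_lobes = 12, bump_amplitude = 0.35,
                                         spacing = c(0.5, 0.5, 0.5), seed = 2))
  vbig <- cell_volume(big$volume, 1)
  dbig <- largest_empty_sphere(big$volume, 1)$diameter
  expect_lt(dbig, les_baseline(rsmall, vbig))
})

test_that("wall thickness maps recover slabs, shells, and bimodal walls", {
  # 5-voxel slab at 0.2 um spacing: thickness 1.0 um in the interior
  slab <- array(FALSE, c(11, 20, 20))
  slab[4:8, , ] <- TRUE
  tm <- wall_thickness_map(slab, c(0.2, 0.2, 0.2))
  interior <- tm$thickness[6, 5:16, 5:16]
  expect_true(all(abs(interior - 1.0) <= 0.2 + 1e-9))

  # hollow sphere shell of 3-voxel wall: uniform thickness ~3 voxels
  n <- 31
  ax <- (1:n) - (n + 1) / 2
  P1 <- array(ax, c(n, n, n)); P2 <- array(rep(ax, each = n), c(n, n, n))
  P3 <- array(rep(ax, each = n * n), c(n, n, n))
  rr <- sqrt(P1^2 + P2^2 + P3^2)
  shell <- rr >= 9 & rr <= 12
  ts <- wall_thickness_map(shell, c(1, 1, 1))
  expect_equal(ts$mean, 3, tolerance = 0.35)

  # bimodal: thickness-5 slab adjoining a thickness-9 slab
  bim <- array(FALSE, c(14, 12, 24))
  bim[5:9, , 1:12] <- TRUE
  bim[3:11, , 13:24] <- TRUE
  tb <- wall_thickness_map(bim, c(1, 1, 1))
  thin_plateau <- tb$thickness[7, 6, 4:9]
  thick_plateau <- tb$thickness[7, 6, 16:21]
  expect_true(all(abs(thin_plateau - 5) <= 1))
  expect_true(all(abs(thick_plateau - 9) <= 1))

  expect_error(wall_thickness_map(array(FALSE, c(3, 3, 3)), c(1, 1, 1)),
               "empty")
})

test_that("the excess mask isolates above-average wall loops", {
  slab <- array(FALSE, c(11, 16, 16))
  slab[4:8, , ] <- TRUE
  tm <- wall_thickness_map(slab, c(1, 1, 1))
  expect_false(any(thickness_excess_mask(tm)))  # uniform: nothing above mean

  bim <- array(FALSE, c(14, 12, 24))
  bim[5:9, , 1:12] <- TRUE
  bim[3:11, , 13:24] <- TRUE
  tb <- wall_thickness_map(bim, c(1, 1, 1))
  ex <- thickness_excess_mask(tb, threshold = 7)
  # inscribed spheres of the thick slab bleed a few voxels across the
  # junction; far from it the thin slab must stay below threshold
  expect_true(all(which(ex, arr.ind = TRUE)[, 3] >= 8))
  expect_true(any(ex[, , 16:21]))
  expect_false(any(ex[, , 1:7]))
})

test_that("measure_cells excludes border-touching cells", {
  lab <- array(0L, c(10, 10, 12))
  lab[3:6, 3:6, 3:6] <- 1L
  lab[3:6, 3:6, 9:12] <- 2L   # touches the x border
  vol <- labeled_volume(lab, c(1, 1, 1))
  rec <- measure_cells(vol, lobes = FALSE)
  expect_equal(rec$label, 1L)
  expect_equal(rec$volume, 64)

  empty <- measure_cells(labeled_volume(array(0L, c(4, 4, 4)), c(1, 1, 1)))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("label", "volume", "solidity", "les_diameter",
                    "lobe_count") %in% names(empty)))
})
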