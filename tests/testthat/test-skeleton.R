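# Skeletonization, smoothing, pruning, and lobe counting.

test_that("morphological smoothing is identity at radius 0 and sphere-stable", {
  ph <- make_lobed_cell(lobed_cell_spec(base_radii = c(6, 6, 6), n_lobes = 0,
                                        spacing = c(0.5, 0.5, 0.5), seed = 1))
  m <- ph$volume$labels == 1
  expect_identical(smooth_mask(m, 0), m)
  sm <- smooth_mask(m, 3)
  expect_lt(abs(sum(sm) - sum(m)) / sum(m), 0.01)
  expect_error(smooth_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)), 2),
               "erased")
})

test_that("smoothing removes 1-voxel pimples but keeps lobe-scale bumps", {
  # cube with a single-voxel pimple in the middle of a face
  m <- array(FALSE, c(20, 20, 20))
  m[5:14, 5:14, 5:14] <- TRUE
  pimpled <- m
  pimpled[15, 10, 10] <- TRUE
  sm <- smooth_mask(pimpled, 2)
  expect_false(sm[15, 10, 10])

  lob <- make_lobed_cell(lobed_cell_spec(n_lobes = 6, bump_amplitude = 0.35,
                                         seed = 2))
  m2 <- lob$volume$labels == 1
  sm2 <- smooth_mask(m2, 2)
  expect_gt(sum(sm2 & m2) / sum(m2), 0.95)  # lobes survive
})

test_that("thin shapes skeletonize to their centrelines", {
  bar <- array(FALSE, c(5, 5, 24)); bar[3, 3, 3:22] <- TRUE
  sk <- skeletonize_cell(bar, c(1, 1, 1))
  expect_equal(nrow(sk$voxels), 20)
  expect_equal(length(skeleton_endpoints(sk)), 2)

  # L-shaped tube: two endpoints, one path through the corner
  L <- array(FALSE, c(6, 20, 20))
  L[3:4, 3:4, 3:16] <- TRUE
  L[3:4, 3:16, 3:4] <- TRUE
  skL <- skeletonize_cell(L, c(1, 1, 1))
  expect_equal(length(skeleton_endpoints(skL)), 2)
  deg <- scleromorph:::skeleton_degrees(skL)
  expect_equal(sum(deg > 2), 0)  # no junctions on a simple path

  ball <- digital_ball(4, 1)
  skB <- skeletonize_cell(ball$labels == 1, c(1, 1, 1))
  expect_lte(length(skeleton_endpoints(skB)), 2)
})

test_that("skeletons stay inside the mask and connected for connected masks", {
  ph <- make_lobed_cell(lobed_cell_spec(n_lobes = 4, bump_amplitude = 0.35,
                                        seed = 7))
  m <- ph$volume$labels == 1
  sk <- skeletonize_cell(m, ph$volume$spacing)
  inside <- mapply(function(z, y, x) m[z, y, x],
                   sk$voxels[, 1], sk$voxels[, 2], sk$voxels[, 3])
  expect_true(all(inside))
  # connectivity via the edge graph
  n <- nrow(sk$voxels)
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  adj <- split(c(sk$edges[, 2], sk$edges[, 1]),
               c(sk$edges[, 1], sk$edges[, 2]))
  while (length(frontier)) {
    nxt <- setdiff(unlist(adj[as.character(frontier)]), which(seen))
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  expect_true(all(seen))
})

test_that("pruning removes short spurs, never paths, and is monotone", {
  # Y skeleton: long stem + long arm + short 2-um spur
  y <- array(FALSE, c(3, 20, 20))
  y[2, 10, 2:12] <- TRUE                # stem
  y[2, 11:18, 13] <- TRUE               # arm
  y[2, 9:7, 13] <- TRUE                 # 3-voxel spur
  y[2, 10, 13] <- TRUE                  # junction
  sk <- skeletonize_cell(y, c(1, 1, 1))
  expect_equal(length(skeleton_endpoints(sk)), 3)
  pr <- prune_skeleton(sk, 4)
  expect_equal(length(skeleton_endpoints(pr)), 2)
  expect_identical(prune_skeleton(sk, 0)$voxels, sk$voxels)

  bar <- array(FALSE, c(3, 3, 14)); bar[2, 2, 2:13] <- TRUE
  skb <- skeletonize_cell(bar, c(1, 1, 1))
  expect_identical(prune_skeleton(skb, 5)$voxels, skb$voxels)   # < path length
  expect_identical(prune_skeleton(skb, 50)$voxels, skb$voxels)  # bare path kept

  # monotone: higher threshold never yields more endpoints
  ph <- make_lobed_cell(lobed_cell_spec(n_lobes = 8, bump_amplitude = 0.35,
                                        seed = 3))
  m <- smooth_mask(ph$volume$labels == 1, 2)
  an <- lobe_tip_anchors(m, ph$volume$spacing)
  skl <- skeletonize_cell(m, ph$volume$spacing, anchors = an)
  eps <- vapply(c(0, 2, 4, 8), function(t)
    length(skeleton_endpoints(prune_skeleton(skl, t))), 1L)
  expect_true(all(diff(eps) <= 0))
})

test_that("lobe counts: isodiametric floor and recovery of planted lobes", {
  ell <- make_lobed_cell(lobed_cell_spec(base_radii = c(11, 9, 9), n_lobes = 0,
                                         spacing = c(0.6, 0.6, 0.6), seed = 1))
  expect_equal(count_lobes(ell$volume, 1), 2)

  bar <- array(0L, c(5, 5, 30)); bar[3, 3, 3:28] <- 1L
  expect_equal(count_lobes(labeled_volume(bar, c(1, 1, 1)), 1,
                           smoothing_radius = 0), 2)

  for (K in c(4, 8, 12)) {
    rec <- vapply(1:5, function(s) {
      ph <- make_lobed_cell(lobed_cell_spec(n_lobes = K, bump_amplitude = 0.35,
                                            seed = s))
      count_lobes(ph$volume, 1)
    }, 1L)
    expect_true(all(abs(rec - K) <= 2),
                info = sprintf("K=%d -> %s", K, paste(rec, collapse = ",")))
  }
})

test_that("endpoint counts are invariant under axis permutation", {
  ph <- make_lobed_cell(lobed_cell_spec(n_lobes = 6, bump_amplitude = 0.35,
                                        seed = 9))
  vol <- ph$volume
  n0 <- count_lobes(vol, 1)
  perm <- labeled_volume(aperm(vol$labels, c(3, 1, 2)), vol$spacing[c(3, 1, 2)])
  expect_equal(count_lobes(perm, 1), n0)
})
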