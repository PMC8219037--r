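# Despiking, band integration, NMF unmixing, OMP fitting, peak localization.

lib <- default_reference_library()

test_that("despike leaves clean cubes alone, catches planted spikes, idempotent", {
  clean <- make_hyperspectral_cube(
    cube_spec(shape = c(10, 10), endmember_names = c("cellulose", "pectin_de_high"),
              noise_sd = 0, n_spikes = 0, seed = 2), lib)
  expect_equal(nrow(despike(clean$cube)$spikes), 0)

  spiked <- make_hyperspectral_cube(
    cube_spec(shape = c(16, 16), endmember_names = c("cellulose", "pectin_de_high"),
              noise_sd = 0.02, n_spikes = 5, seed = 9), lib)
  ds <- despike(spiked$cube)
  found <- merge(ds$spikes, spiked$truth$spikes)
  expect_gte(nrow(found), 4)
  # non-spike voxels: median alteration well under 1%
  ch <- abs(ds$cube$cube - spiked$cube$cube) / pmax(spiked$cube$cube, 1e-12)
  tr <- spiked$truth$spikes
  for (i in seq_len(nrow(tr))) ch[tr$y[i], tr$x[i], tr$band[i]] <- NA
  expect_lt(median(ch, na.rm = TRUE), 0.01)

  ds2 <- despike(ds$cube)
  expect_equal(nrow(ds2$spikes), 0)
  expect_equal(ds2$cube$cube, ds$cube$cube)
})

test_that("two spikes in adjacent bands of one pixel are both flagged", {
  mk <- make_hyperspectral_cube(
    cube_spec(shape = c(4, 4), endmember_names = "cellulose",
              noise_sd = 0, n_spikes = 0, seed = 1), lib)
  cc <- mk$cube$cube
  cc[2, 2, 100] <- cc[2, 2, 100] + 50 * max(cc[2, 2, ])
  cc[2, 2, 101] <- cc[2, 2, 101] + 40 * max(cc[2, 2, ])
  ds <- despike(hyperspectral_cube(cc, mk$cube$wavenumbers))
  own <- ds$spikes[ds$spikes$y == 2 & ds$spikes$x == 2, ]
  expect_true(all(c(100, 101) %in% own$band))
})

test_that("band integration: constant, chord-baseline, and CH-window imaging", {
  w <- seq(2800, 3100, by = 1)
  cube <- hyperspectral_cube(array(1, c(2, 2, length(w))), w)
  img <- integrate_band(cube, c(2831, 3009), baseline = "none")
  expect_equal(img, matrix(178, 2, 2), tolerance = 1e-12)

  line <- array(rep(0.01 * (w - 2800) + 2, each = 4), c(2, 2, length(w)))
  lc <- hyperspectral_cube(line, w)
  expect_lt(max(abs(integrate_band(lc, c(2831, 3009), baseline = "linear"))),
            1e-9)
  expect_error(integrate_band(cube, c(2700, 2900)), "outside")
  expect_error(integrate_band(cube, c(3000, 2900)), "lo < hi")

  mk <- make_hyperspectral_cube(
    cube_spec(shape = c(16, 16), endmember_names = "cellulose",
              noise_sd = 0, n_spikes = 0, seed = 5), lib)
  img <- integrate_band(mk$cube, c(2831, 3009))
  expect_gt(cor(as.vector(img), as.vector(mk$truth$abundances[, , 1])), 0.99)
})

test_that("NMF recovers endmembers with a monotone objective, deterministically", {
  one <- make_hyperspectral_cube(
    cube_spec(shape = c(8, 8), endmember_names = "cellulose",
              noise_sd = 0, n_spikes = 0, seed = 3), lib)
  n1 <- nmf_unmix(one$cube, k = 1, seed = 5, max_iter = 500)
  expect_gte(scleromorph:::cosine_sim(n1$endmembers[1, ],
                                      lib$intensities[, "cellulose"]),
             1 - 1e-9)

  am <- list(data.frame(y = 6, x = 6, width = 2.5, height = 1),
             data.frame(y = 18, x = 18, width = 2.5, height = 1))
  two <- make_hyperspectral_cube(
    cube_spec(shape = c(24, 24), endmember_names = c("cellulose", "pectin_de_high"),
              abundance_model = am, noise_sd = 0, n_spikes = 0, seed = 7), lib)
  n2 <- nmf_unmix(two$cube, k = 2, seed = 3, max_iter = 2000, tol = 1e-12)
  mt <- match_endmembers(n2, lib)
  expect_setequal(mt$assigned, c("cellulose", "pectin_de_high"))
  expect_true(all(mt$similarity >= 0.99))

  expect_true(all(diff(n2$objective) <= 1e-8 * n2$objective[1]))
  expect_true(all(n2$endmembers >= 0))
  expect_true(all(n2$abundances >= 0))

  n2b <- nmf_unmix(two$cube, k = 2, seed = 3, max_iter = 2000, tol = 1e-12)
  expect_identical(n2$endmembers, n2b$endmembers)
  expect_identical(n2$abundances, n2b$abundances)

  neg <- two$cube
  neg$cube[1, 1, 1] <- -1
  expect_error(nmf_unmix(neg, k = 2), "non-negative")
})

test_that("endmember assignment separates chemistry and flags zero rows", {
  res <- structure(list(
    endmembers = rbind(lib$intensities[, "cellulose"], 0),
    abundances = array(0, c(1, 1, 2)), objective = 1, seed = 1L, k = 2L,
    wavenumbers = lib$wavenumbers), class = "nmf_result")
  mt <- match_endmembers(res, lib)
  expect_equal(mt$assigned[1], "cellulose")
  expect_equal(mt$similarity[1], 1, tolerance = 1e-12)
  expect_true(is.na(mt$assigned[2]))

  sims <- vapply(lib$names, function(nm)
    scleromorph:::cosine_sim(lib$intensities[, "cellulose"],
                             lib$intensities[, nm]), 1)
  pect <- sims[grep("pectin", names(sims))]
  expect_gt(sims["cellulose"] - max(pect), 0.1)
})

test_that("OMP recovers exact mixtures and noisy single references", {
  y <- 0.7 * lib$intensities[, "cellulose"] + 0.3 * lib$intensities[, "pectin_de_high"]
  fit <- omp_fit(spectrum(lib$wavenumbers, y), lib, max_atoms = 2,
                 residual_tol = 1e-10)
  expect_setequal(fit$selected, c("cellulose", "pectin_de_high"))
  expect_equal(unname(fit$coefficients[order(fit$selected)]),
               c(0.7, 0.3)[order(fit$selected)], tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-6)

  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    ref <- lib$intensities[, "xylan"]
    noisy <- pmax(ref * (1 + rnorm(length(ref), sd = 0.05)), 0)
    f <- omp_fit(spectrum(lib$wavenumbers, noisy), lib, max_atoms = 3)
    if (length(f$selected) && f$selected[1] == "xylan") hits <- hits + 1
  }
  expect_gte(hits, 19)

  # three-component wall mixture: all three chemistries contribute
  mix <- 0.5 * lib$intensities[, "cellulose"] +
    0.3 * lib$intensities[, "glucomannan"] +
    0.2 * lib$intensities[, "pectin_de_high"]
  fm <- omp_fit(spectrum(lib$wavenumbers, mix), lib, max_atoms = 3,
                residual_tol = 1e-10)
  expect_setequal(fm$selected, c("cellulose", "glucomannan", "pectin_de_high"))
  expect_equal(unname(fm$coefficients[c("cellulose", "glucomannan",
                                        "pectin_de_high")]),
               c(0.5, 0.3, 0.2), tolerance = 1e-6)

  expect_error(omp_fit(spectrum(1:10, rep(1, 10)),
                       structure(list(names = character(0)),
                                 class = "reference_library")), "empty")
})

test_that("OMP residuals decrease per atom and vanish on full support", {
  y <- 0.6 * lib$intensities[, "cellulose"] + 0.4 * lib$intensities[, "xylan"]
  sp <- spectrum(lib$wavenumbers, y)
  r1 <- omp_fit(sp, lib, max_atoms = 1, residual_tol = 0)$residual_norm
  r2 <- omp_fit(sp, lib, max_atoms = 2, residual_tol = 0)$residual_norm
  expect_lt(r2, r1)
  rfull <- omp_fit(sp, lib, max_atoms = length(lib$names),
                   residual_tol = 0)$residual_norm
  expect_lt(rfull, 1e-9)
})

test_that("peak localization resolves sub-sample marker band positions", {
  axis <- seq(800, 900, by = 1)
  g843 <- make_reference_spectrum("w", data.frame(center = 843, width = 14,
                                                  height = 1), axis)
  expect_equal(band_peak_position(g843, c(820, 870)), 843, tolerance = 0.5)

  for (ctr in c(853, 856)) {
    g <- make_reference_spectrum("p", data.frame(center = ctr, width = 14,
                                                 height = 1), axis)
    expect_equal(band_peak_position(g, c(830, 880)), ctr, tolerance = 0.5)
  }

  flat <- spectrum(axis, rep(2, length(axis)))
  expect_true(is.na(band_peak_position(flat, c(820, 880))))
  expect_error(band_peak_position(g843, c(843, 843.5)), "3 samples")
})
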