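# Hyperspectral workflow: cosmic-ray despiking, band-integral imaging, NMF
# endmember extraction (multiplicative updates on the Frobenius loss),
# non-negative orthogonal matching pursuit against a reference library,
# and sub-sample marker-band peak localization.

#' Remove cosmic-ray spikes from a hyperspectral cube
#'
#' Per-pixel spectral running-median test: samples whose residual against
#' the window median exceeds `z_threshold` robust standard deviations are
#' replaced by that median; all other samples are untouched, which makes
#' the filter idempotent.
#'
#' @param cube a [hyperspectral_cube()] with >= 5 bands
#' @param z_threshold robust z-score cutoff (default 8)
#' @param window odd spectral median window length (default 5)
#' @return list with `cube` (despiked) and `spikes` (data.frame y, x, band)
#' @export
despike <- function(cube, z_threshold = 8, window = 5L) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  dm <- dim(cube$cube)
  if (dm[3] < 5) stop("despiking needs at least 5 bands")
  window <- min(window, dm[3] - (1 - dm[3] %% 2))
  if (window %% 2 == 0) window <- window - 1L
  out <- cube$cube
  hits <- NULL
  for (y in seq_len(dm[1])) {
    for (x in seq_len(dm[2])) {
      s <- cube$cube[y, x, ]
      med <- stats::runmed(s, window, endrule = "median")
      # intensity-relative residuals: Raman shot noise scales with signal,
      # so an absolute cutoff would be dominated by the empty bands
      floor_i <- 0.05 * max(med) + 1e-300
      rel <- (s - med) / pmax(med, floor_i)
      # 0.02 floor: genuine band curvature at ~2 cm^-1 sampling produces
      # up to ~13% relative median residual; spikes are 2000%+
      sdr <- max(stats::mad(rel), 0.02)
      bad <- which(abs(rel) > z_threshold * sdr)
      if (length(bad)) {
        out[y, x, bad] <- med[bad]
        hits <- rbind(hits, data.frame(y = y, x = x, band = bad))
      }
    }
  }
  if (is.null(hits))
    hits <- data.frame(y = integer(0), x = integer(0), band = integer(0))
  list(cube = hyperspectral_cube(pmax(out, 0), cube$wavenumbers,
                                 cube$pixel_spacing),
       spikes = hits)
}

#' Band-integral image
#'
#' Per-pixel trapezoidal integral of the spectrum over a wavenumber window
#' (e.g. the CH stretching region 2831-3009 cm^-1 to image total organic
#' material). With `baseline = "linear"` the chord between the window
#' endpoints is subtracted first.
#'
#' @param cube a [hyperspectral_cube()]
#' @param window `(lo, hi)` in cm^-1, within the axis
#' @param baseline `"none"` or `"linear"`
#' @return numeric matrix `(y, x)` of integrals
#' @export
integrate_band <- function(cube, window, baseline = c("none", "linear")) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  baseline <- match.arg(baseline)
  w <- cube$wavenumbers
  if (window[1] >= window[2]) stop("window must satisfy lo < hi")
  if (window[1] < min(w) || window[2] > max(w))
    stop("integration window outside the wavenumber axis")
  sel <- which(w >= window[1] & w <= window[2])
  if (length(sel) < 2) stop("integration window contains fewer than 2 samples")
  ws <- w[sel]
  # trapezoid weights on the sub-axis
  dw <- diff(ws)
  tw <- c(dw / 2, 0) + c(0, dw / 2)
  dm <- dim(cube$cube)
  flat <- matrix(cube$cube, dm[1] * dm[2], dm[3])[, sel, drop = FALSE]
  img <- flat %*% tw
  if (baseline == "linear") {
    ilo <- flat[, 1]; ihi <- flat[, ncol(flat)]
    span <- ws[length(ws)] - ws[1]
    # exact integral of the chord between the endpoints
    img <- img - (ilo + ihi) / 2 * span
  }
  matrix(img, dm[1], dm[2])
}

#' Non-negative matrix factorization unmixing
#'
#' Factorizes the (pixels x bands) matrix into non-negative abundances and
#' endmember spectra by multiplicative updates minimizing the Frobenius
#' reconstruction error, from a seeded random non-negative start. The
#' objective trace is non-increasing; iteration stops at `max_iter` or
#' when the relative objective change falls below `tol`.
#'
#' @param cube a non-negative [hyperspectral_cube()]
#' @param k number of endmembers (the reference analysis used k = 6)
#' @param seed integer seed for the random initialization
#' @param max_iter maximum iterations
#' @param tol relative objective-change stopping tolerance
#' @return object of class `nmf_result`: list with `endmembers` (k x bands),
#'   `abundances` (y, x, k array), `objective` (per-iteration trace),
#'   `seed`, `k`, `wavenumbers`
#' @export
nmf_unmix <- function(cube, k = 6L, seed = 1L, max_iter = 500L, tol = 1e-7) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  if (k < 1) stop("k must be >= 1")
  if (any(cube$cube < 0)) stop("cube must be non-negative (despike/clip first)")
  dm <- dim(cube$cube)
  X <- matrix(cube$cube, dm[1] * dm[2], dm[3])
  if (k > dm[3]) stop("k (", k, ") exceeds the number of bands (", dm[3], ")")
  eps <- 1e-12
  res <- with_seed(seed, {
    W <- matrix(runif(nrow(X) * k, 0.1, 1), nrow(X), k) * sqrt(mean(X) / k + eps)
    H <- matrix(runif(k * ncol(X), 0.1, 1), k, ncol(X)) * sqrt(mean(X) / k + eps)
    obj <- numeric(0)
    for (it in seq_len(max_iter)) {
      W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + eps)
      H <- H * (t(W) %*% X) / ((t(W) %*% W) %*% H + eps)
      o <- sum((X - W %*% H)^2)
      obj <- c(obj, o)
      if (it > 1 && abs(obj[it - 1] - o) <= tol * max(obj[1], eps)) break
    }
    list(W = W, H = H, obj = obj)
  })
  structure(list(endmembers = res$H,
                 abundances = array(res$W, c(dm[1], dm[2], k)),
                 objective = res$obj, seed = as.integer(seed), k = as.integer(k),
                 wavenumbers = cube$wavenumbers),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("<nmf_result> k = %d, %d iterations, final objective %.4g\n",
              x$k, length(x$objective), x$objective[length(x$objective)]))
  invisible(x)
}

#' Assign NMF endmembers to reference-library components
#'
#' Cosine-similarity matrix between endmembers and library spectra with a
#' greedy best-first assignment. All-zero endmembers are flagged
#' unassigned.
#'
#' @param result an [nmf_unmix()] result
#' @param library a [reference_library()] on the same wavenumber axis
#' @return data.frame: `endmember`, `assigned` (library name or NA),
#'   `similarity`
#' @export
match_endmembers <- function(result, library) {
  stopifnot(inherits(result, "nmf_result"), inherits(library, "reference_library"))
  if (length(result$wavenumbers) != length(library$wavenumbers) ||
      any(result$wavenumbers != library$wavenumbers))
    stop("endmembers and library must share one wavenumber axis")
  k <- result$k
  L <- length(library$names)
  sim <- matrix(NA_real_, k, L, dimnames = list(NULL, library$names))
  for (i in seq_len(k))
    for (j in seq_len(L))
      sim[i, j] <- cosine_sim(result$endmembers[i, ], library$intensities[, j])
  assigned <- rep(NA_character_, k)
  simbest <- rep(NA_real_, k)
  free_r <- seq_len(k); free_c <- seq_len(L)
  work <- sim
  while (length(free_r) && length(free_c) && any(is.finite(work[free_r, free_c]))) {
    sub <- work[free_r, free_c, drop = FALSE]
    ij <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    r <- free_r[ij[1]]; cc <- free_c[ij[2]]
    assigned[r] <- library$names[cc]
    simbest[r] <- sim[r, cc]
    free_r <- setdiff(free_r, r)
    free_c <- setdiff(free_c, cc)
  }
  data.frame(endmember = seq_len(k), assigned = assigned, similarity = simbest)
}

#' Non-negative orthogonal matching pursuit against a reference library
#'
#' Greedy sparse fit of a spectrum as a non-negative linear combination of
#' library spectra: at each step the library entry with the largest
#' positive correlation to the residual is added and all coefficients are
#' refit by non-negative least squares; stops at `max_atoms` atoms, when
#' the residual norm fraction falls below `residual_tol`, or when no entry
#' correlates positively. Concentrations cannot be negative, hence the
#' constraint.
#'
#' @param spec a [spectrum()] on the library's axis (resampled if needed)
#' @param library a [reference_library()]
#' @param max_atoms maximum number of selected references
#' @param residual_tol stopping residual as a fraction of the input norm
#' @return object of class `omp_fit`: list with `selected` (names),
#'   `coefficients` (non-negative, named), `residual_norm` (fraction)
#' @export
omp_fit <- function(spec, library, max_atoms = 3L, residual_tol = 0.05) {
  stopifnot(inherits(spec, "spectrum"), inherits(library, "reference_library"))
  if (!length(library$names)) stop("empty reference library")
  if (max_atoms > length(library$names))
    stop("max_atoms exceeds the library size")
  y <- approx(spec$wavenumbers, spec$intensities,
              xout = library$wavenumbers, rule = 2)$y
  D <- library$intensities            # bands x L
  Dn <- sweep(D, 2, pmax(sqrt(colSums(D^2)), 1e-300), "/")
  ynorm <- sqrt(sum(y^2))
  if (ynorm == 0)
    return(structure(list(selected = character(0),
                          coefficients = numeric(0), residual_norm = 0),
                     class = "omp_fit"))
  r <- y
  sel <- integer(0)
  coef <- numeric(0)
  repeat {
    corr <- as.vector(t(Dn) %*% r)
    corr[sel] <- -Inf
    j <- which.max(corr)
    if (!is.finite(corr[j]) || corr[j] <= 0) break
    sel <- c(sel, j)
    fit <- pracma::lsqnonneg(D[, sel, drop = FALSE], y)
    coef <- fit$x
    r <- y - D[, sel, drop = FALSE] %*% coef
    if (sqrt(sum(r^2)) / ynorm < residual_tol) break
    if (length(sel) >= max_atoms) break
  }
  structure(list(selected = library$names[sel],
                 coefficients = stats::setNames(as.numeric(coef),
                                                library$names[sel]),
                 residual_norm = sqrt(sum(r^2)) / ynorm),
            class = "omp_fit")
}

#' @export
print.omp_fit <- function(x, ...) {
  cat("<omp_fit>", if (length(x$selected))
    paste(sprintf("%s=%.3g", x$selected, x$coefficients), collapse = ", ")
    else "(no atoms)",
    sprintf("| residual %.3g\n", x$residual_norm))
  invisible(x)
}

#' Sub-sample peak position within a search window
#'
#' Argmax within the window refined by a 3-point parabola through the
#' neighbouring samples, giving sub-sample resolution (needed to separate
#' the 853 vs 856 cm^-1 pectin esterification markers at realistic
#' spectrometer sampling). Returns `NA` for a flat (peak-free) window.
#'
#' @param spec a [spectrum()]
#' @param search_window `(lo, hi)` in cm^-1
#' @return peak position in cm^-1, or `NA_real_` if the window is flat
#' @export
band_peak_position <- function(spec, search_window) {
  stopifnot(inherits(spec, "spectrum"))
  w <- spec$wavenumbers
  sel <- which(w >= search_window[1] & w <= search_window[2])
  if (length(sel) < 3)
    stop("search window must contain at least 3 samples")
  y <- spec$intensities[sel]
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1e-300))
    return(NA_real_)   # flat: no peak
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(w[sel][i])
  x3 <- w[sel][(i - 1):(i + 1)]
  y3 <- y[(i - 1):(i + 1)]
  # exact parabola through three points; vertex position
  d21 <- (y3[2] - y3[1]) / (x3[2] - x3[1])
  d32 <- (y3[3] - y3[2]) / (x3[3] - x3[2])
  a <- (d32 - d21) / (x3[3] - x3[1])
  if (a >= 0) return(x3[2])  # degenerate/flat curvature
  b <- d21 - a * (x3[1] + x3[2])
  -b / (2 * a)
}
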