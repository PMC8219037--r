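# Phantom generators with known ground truth: star-convex lobed cells,
# Voronoi tissues with walls and intercellular space (ICS), Gaussian-band
# reference spectra, and mixed hyperspectral cubes. These emulate the study
# conditions of developing shell tissue (isodiametric-to-polylobate cells
# imaged by SBF-SEM; Raman maps of cell wall sections) so every descriptor
# can be validated against a constructed truth.

#' Specification of a synthetic lobed cell
#'
#' The cell is star-convex: its surface radius is
#' `r(u) = r_ellipsoid(u) * (1 + bump_amplitude * sum_k g_k(u))` where the
#' `g_k` are unit-height angular bumps (von Mises-Fisher profiles with
#' concentration `bump_sharpness`) centred on `n_lobes` directions placed
#' quasi-uniformly on a Fibonacci sphere and jittered by the seed.
#'
#' Defaults emulate a mid-development sclereid: 10 µm mean radius at 0.6 µm
#' voxels (about 17 voxels per radius, the scale at which the study's
#' ~1000^2 x 100 voxel stacks resolve single cells).
#'
#' @param base_radii ellipsoid semi-axes `(µm, µm, µm)` in (z, y, x) order
#' @param n_lobes number of lobes K >= 0
#' @param bump_amplitude lobe height as a fraction of the local radius, in [0, 1)
#' @param bump_sharpness concentration of the angular bump profile
#'   (dimensionless; larger = narrower lobes)
#' @param spacing voxel spacing `(sz, sy, sx)` µm
#' @param seed integer RNG seed
#' @return an object of class `lobed_cell_spec`
#' @export
lobed_cell_spec <- function(base_radii = c(10, 10, 10), n_lobes = 0L,
                            bump_amplitude = 0.3, bump_sharpness = 12,
                            spacing = c(0.6, 0.6, 0.6), seed = 1L) {
  if (any(base_radii <= 0)) stop("radii must be positive")
  if (bump_amplitude < 0 || bump_amplitude >= 1)
    stop("bump_amplitude must be in [0, 1)")
  if (n_lobes < 0) stop("n_lobes must be >= 0")
  structure(list(base_radii = as.numeric(base_radii),
                 n_lobes = as.integer(n_lobes),
                 bump_amplitude = bump_amplitude,
                 bump_sharpness = bump_sharpness,
                 spacing = check_spacing(spacing),
                 seed = as.integer(seed)),
            class = "lobed_cell_spec")
}

# radius of the perturbed ellipsoid along unit directions (rows of u, (z,y,x))
lobed_radius <- function(u, base_radii, dirs, amplitude, sharpness) {
  rell <- 1 / sqrt((u[, 1] / base_radii[1])^2 +
                   (u[, 2] / base_radii[2])^2 +
                   (u[, 3] / base_radii[3])^2)
  bump <- 0
  if (nrow(dirs)) {
    for (k in seq_len(nrow(dirs))) {
      ct <- u %*% dirs[k, ]
      bump <- bump + exp(sharpness * (ct - 1))
    }
  }
  rell * (1 + amplitude * bump)
}

#' Generate a lobed-cell phantom
#'
#' Voxelizes the star-convex surface of the spec on a grid just large
#' enough to contain it and returns the volume together with the ground
#' truth (lobe count, bump directions, quadrature estimate of the
#' continuous volume).
#'
#' @param spec a [lobed_cell_spec()]
#' @return list with elements `volume` (a [labeled_volume()], one cell of
#'   label 1) and `truth` (list: `n_lobes`, `directions`, `volume_um3`)
#' @export
make_lobed_cell <- function(spec) {
  stopifnot(inherits(spec, "lobed_cell_spec"))
  dirs <- with_seed(spec$seed, {
    d <- fibonacci_sphere(spec$n_lobes)
    if (nrow(d)) {
      d <- d + matrix(rnorm(3 * nrow(d), sd = 0.08), ncol = 3)
      d <- d / sqrt(rowSums(d^2))
    }
    d
  })
  # worst-case radius: overlapping bump tails can push sum(g_k) above 1
  rmax <- max(spec$base_radii) * (1 + spec$bump_amplitude *
                                    max(1, spec$n_lobes) * 1.0)
  rmax <- min(rmax, max(spec$base_radii) * (1 + spec$bump_amplitude * 2.5))
  half <- ceiling(rmax / spec$spacing) + 2
  dm <- 2 * half + 1
  centre <- (half + 0.5) * spec$spacing  # physical coords of grid centre

  ax1 <- ((seq_len(dm[1]) - 0.5) * spec$spacing[1]) - centre[1]
  ax2 <- ((seq_len(dm[2]) - 0.5) * spec$spacing[2]) - centre[2]
  ax3 <- ((seq_len(dm[3]) - 0.5) * spec$spacing[3]) - centre[3]
  P1 <- array(ax1, dm)
  P2 <- array(rep(ax2, each = dm[1]), dm)
  P3 <- array(rep(ax3, each = dm[1] * dm[2]), dm)
  rho <- sqrt(P1^2 + P2^2 + P3^2)
  rho[rho == 0] <- 1e-12
  u <- cbind(as.vector(P1 / rho), as.vector(P2 / rho), as.vector(P3 / rho))
  rsurf <- lobed_radius(u, spec$base_radii, dirs,
                        spec$bump_amplitude, spec$bump_sharpness)
  inside <- array(as.vector(rho) <= rsurf, dm)

  if (any(inside[c(1, dm[1]), , ]) || any(inside[, c(1, dm[2]), ]) ||
      any(inside[, , c(1, dm[3])]))
    stop("cell touches the grid boundary; descriptors would be truncated")

  # quadrature estimate of the continuous volume: V = (1/3) integral r^3 dOmega
  uq <- fibonacci_sphere(20000)
  rq <- lobed_radius(uq, spec$base_radii, dirs,
                     spec$bump_amplitude, spec$bump_sharpness)
  vol_cont <- (4 * pi / 3) * mean(rq^3)

  labels <- array(0L, dm)
  labels[inside] <- 1L
  list(volume = labeled_volume(labels, spec$spacing),
       truth = list(n_lobes = spec$n_lobes, directions = dirs,
                    volume_um3 = vol_cont))
}

#' Specification of a synthetic multi-cell tissue
#'
#' Cells are the Voronoi regions of seeded points; walls (background) are
#' carved where regions meet, and a seeded fraction of each interface is
#' opened into intercellular space, fragmenting the remaining contact.
#'
#' @param n_cells number of cells (>= 1)
#' @param domain_size physical extent `(µm, µm, µm)` in (z, y, x)
#' @param wall_thickness background wall thickness in µm (0 = touching cells)
#' @param ics_fraction fraction of each cell-cell interface opened into ICS,
#'   in [0, 1]
#' @param spacing voxel spacing
#' @param seed integer RNG seed
#' @return an object of class `tissue_spec`
#' @export
tissue_spec <- function(n_cells = 8L, domain_size = c(40, 40, 40),
                        wall_thickness = 0, ics_fraction = 0,
                        spacing = c(1, 1, 1), seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (wall_thickness < 0) stop("wall_thickness must be >= 0")
  if (ics_fraction < 0 || ics_fraction > 1)
    stop("ics_fraction must be in [0, 1]")
  structure(list(n_cells = as.integer(n_cells),
                 domain_size = as.numeric(domain_size),
                 wall_thickness = wall_thickness,
                 ics_fraction = ics_fraction,
                 spacing = check_spacing(spacing),
                 seed = as.integer(seed)),
            class = "tissue_spec")
}

#' Generate a Voronoi tissue phantom
#'
#' @param spec a [tissue_spec()]
#' @param points optional n x 3 matrix of seed points (µm, (z,y,x)); sampled
#'   with minimum separation when omitted
#' @return list with `volume` (a [labeled_volume()]) and `truth` (list:
#'   `points`, `adjacency` data.frame of label pairs in contact after ICS
#'   opening, `voronoi_adjacency` of the raw partition)
#' @export
make_tissue <- function(spec, points = NULL) {
  stopifnot(inherits(spec, "tissue_spec"))
  ds <- spec$domain_size
  sepmin <- max(2 * spec$wall_thickness, 3 * max(spec$spacing))
  pts <- points
  res <- with_seed(spec$seed, {
    if (is.null(pts)) {
      pts <- matrix(NA_real_, spec$n_cells, 3)
      got <- 0L
      for (try in seq_len(20000)) {
        cand <- runif(3) * ds
        ok <- got == 0 ||
          min(sqrt(colSums((t(pts[seq_len(got), , drop = FALSE]) - cand)^2))) >= sepmin
        if (ok) {
          got <- got + 1L
          pts[got, ] <- cand
          if (got == spec$n_cells) break
        }
      }
      if (got < spec$n_cells)
        stop("could not place ", spec$n_cells,
             " seeds with separation >= ", signif(sepmin, 3), " µm")
    }
    dm <- pmax(2L, round(ds / spec$spacing))
    ax <- lapply(1:3, function(a) (seq_len(dm[a]) - 0.5) * spec$spacing[a])
    # nearest seed per voxel
    d1 <- array(Inf, dm)
    i1 <- array(0L, dm)
    P1 <- array(ax[[1]], dm)
    P2 <- array(rep(ax[[2]], each = dm[1]), dm)
    P3 <- array(rep(ax[[3]], each = dm[1] * dm[2]), dm)
    for (i in seq_len(spec$n_cells)) {
      di <- sqrt((P1 - pts[i, 1])^2 + (P2 - pts[i, 2])^2 + (P3 - pts[i, 3])^2)
      closer <- di < d1
      d1[closer] <- di[closer]
      i1[closer] <- i
    }
    labels <- i1

    # raw Voronoi adjacency from shared faces
    adj <- face_adjacency(labels, 0L)

    # open a seeded fraction of each interface into ICS: parallel stripes
    # across the interface (channel-like, as in net-forming intercellular
    # space), which fragments the remaining contact into separate patches
    opened_pairs <- NULL
    if (spec$ics_fraction > 0 && nrow(adj)) {
      for (r in seq_len(nrow(adj))) {
        fa <- interface_faces(labels, adj$label_a[r], adj$label_b[r])
        nf <- nrow(fa)
        if (!nf) next
        ctr <- (fa[, 1:3, drop = FALSE] + fa[, 4:6, drop = FALSE]) / 2 - 0.5
        ctr <- sweep(ctr, 2, spec$spacing, "*")
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cc <- as.vector(ctr %*% u)
        rng <- max(cc) - min(cc)
        if (spec$ics_fraction >= 1) {
          carve <- seq_len(nf)
        } else if (rng <= 0) {
          carve <- sample.int(nf, round(spec$ics_fraction * nf))
        } else {
          nb <- max(1L, round(spec$ics_fraction * 6))
          period <- rng / nb * (1 + 1e-9)
          phase <- (cc - min(cc) + runif(1) * period) %% period
          carve <- which(phase < spec$ics_fraction * period)
        }
        if (!length(carve)) next
        for (ci in carve) {
          labels[fa[ci, 1], fa[ci, 2], fa[ci, 3]] <- 0L
          labels[fa[ci, 4], fa[ci, 5], fa[ci, 6]] <- 0L
        }
        if (length(carve) >= nf)
          opened_pairs <- rbind(opened_pairs, adj[r, c("label_a", "label_b")])
      }
    }

    # erode each region to carve background walls
    if (spec$wall_thickness > 0) {
      keep <- array(FALSE, dm)
      for (i in seq_len(spec$n_cells)) {
        m <- labels == i
        if (!any(m)) stop("tissue spec produced an empty cell (label ", i, ")")
        dt <- cpp_edt(m, spec$spacing)
        keep <- keep | (m & dt > spec$wall_thickness / 2)
      }
      labels[!keep] <- 0L
    }
    for (i in seq_len(spec$n_cells))
      if (!any(labels == i))
        stop("tissue spec produced an empty cell (label ", i, ")")

    adjacency <- adj
    if (!is.null(opened_pairs)) {
      keep_row <- !(paste(adj$label_a, adj$label_b) %in%
                      paste(opened_pairs$label_a, opened_pairs$label_b))
      adjacency <- adj[keep_row, , drop = FALSE]
    }
    if (spec$ics_fraction >= 1)
      adjacency <- adj[0, , drop = FALSE]
    list(labels = labels, pts = pts, adjacency = adjacency, voronoi = adj)
  })
  list(volume = labeled_volume(res$labels, spec$spacing),
       truth = list(points = res$pts, adjacency = res$adjacency,
                    voronoi_adjacency = res$voronoi))
}

# label pairs sharing >= 1 face between 6-adjacent voxels (R shift scan,
# independent of the C++ contact path)
face_adjacency <- function(labels, background) {
  pairs <- NULL
  dm <- dim(labels)
  collect <- function(a, b) {
    sel <- a != b & a != background & b != background
    if (!any(sel)) return(NULL)
    cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
  }
  p1 <- collect(labels[-dm[1], , , drop = FALSE], labels[-1, , , drop = FALSE])
  p2 <- collect(labels[, -dm[2], , drop = FALSE], labels[, -1, , drop = FALSE])
  p3 <- collect(labels[, , -dm[3], drop = FALSE], labels[, , -1, drop = FALSE])
  pairs <- unique(rbind(p1, p2, p3))
  if (is.null(pairs))
    return(data.frame(label_a = integer(0), label_b = integer(0)))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  data.frame(label_a = pairs[, 1], label_b = pairs[, 2])
}

# voxel index pairs (za,ya,xa,zb,yb,xb) of all shared faces between two labels
interface_faces <- function(labels, la, lb) {
  dm <- dim(labels)
  out <- NULL
  for (axis in 1:3) {
    n <- dm[axis]
    idxA <- switch(axis,
                   which(labels[-n, , , drop = FALSE] == la & labels[-1, , , drop = FALSE] == lb),
                   which(labels[, -n, , drop = FALSE] == la & labels[, -1, , drop = FALSE] == lb),
                   which(labels[, , -n, drop = FALSE] == la & labels[, , -1, drop = FALSE] == lb))
    idxB <- switch(axis,
                   which(labels[-n, , , drop = FALSE] == lb & labels[-1, , , drop = FALSE] == la),
                   which(labels[, -n, , drop = FALSE] == lb & labels[, -1, , drop = FALSE] == la),
                   which(labels[, , -n, drop = FALSE] == lb & labels[, , -1, drop = FALSE] == la))
    sub <- dm; sub[axis] <- sub[axis] - 1L
    if (length(idxA)) {
      ci <- arrayInd(idxA, sub)
      cb <- ci; cb[, axis] <- cb[, axis] + 1L
      out <- rbind(out, cbind(ci, cb))
    }
    if (length(idxB)) {
      ci <- arrayInd(idxB, sub)
      ca <- ci; ca[, axis] <- ca[, axis] + 1L
      out <- rbind(out, cbind(ca, ci))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 6)
  colnames(out) <- c("za", "ya", "xa", "zb", "yb", "xb")
  out
}

#' Build a Gaussian-band reference spectrum
#'
#' Sum of Gaussian peaks on the given axis; the standard way this package
#' composes synthetic pure-component spectra (cellulose-, hemicellulose-
#' and pectin-like references with their marker bands).
#'
#' @param name component name
#' @param bands data.frame or matrix with columns `(center, width, height)`;
#'   `center`/`width` in cm^-1 (width = FWHM), height in arbitrary counts
#' @param axis wavenumber axis in cm^-1
#' @return a [spectrum()]
#' @export
make_reference_spectrum <- function(name, bands, axis) {
  bands <- as.data.frame(bands)
  y <- numeric(length(axis))
  if (nrow(bands)) {
    names(bands)[1:3] <- c("center", "width", "height")
    if (any(bands$center < min(axis)) || any(bands$center > max(axis)))
      stop("band centers must lie within the wavenumber axis")
    for (i in seq_len(nrow(bands))) {
      sigma <- bands$width[i] / (2 * sqrt(2 * log(2)))
      y <- y + bands$height[i] * exp(-0.5 * ((axis - bands$center[i]) / sigma)^2)
    }
  }
  spectrum(axis, y, name = name)
}

#' Default six-component reference library
#'
#' Synthetic Gaussian-band stand-ins for the carbohydrate references used in
#' cell wall unmixing: cellulose (bands at 378, 1095, 1380 plus CH stretch),
#' two hemicelluloses (xylan- and glucomannan-like), and three pectins whose
#' ~850 cm^-1 marker band position encodes the degree of esterification
#' (856 cm^-1 for 10-34%, 853 cm^-1 for >85%, 855 cm^-1 for the mid class).
#'
#' @param axis wavenumber axis (default 300 to 3100 cm^-1, 2 cm^-1 steps)
#' @return a [reference_library()]
#' @export
default_reference_library <- function(axis = seq(300, 3100, by = 2)) {
  b <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    colnames(m) <- c("center", "width", "height")
    m
  }
  specs <- list(
    cellulose = make_reference_spectrum("cellulose", b(
      378, 18, 0.5,  436, 18, 0.3,  1095, 16, 1.0,  1120, 16, 0.7,
      1380, 20, 0.6, 2897, 40, 0.9), axis),
    xylan = make_reference_spectrum("xylan", b(
      497, 22, 0.5,  898, 18, 0.6,  1094, 20, 0.8,  1460, 26, 0.5,
      2910, 45, 0.8), axis),
    glucomannan = make_reference_spectrum("glucomannan", b(
      428, 20, 0.4,  869, 18, 0.5,  1064, 20, 0.7,  1376, 22, 0.4,
      2885, 45, 0.8), axis),
    pectin_de_low = make_reference_spectrum("pectin_de_low", b(
      856, 14, 0.8,  1078, 20, 0.5,  1330, 24, 0.4,  1608, 30, 0.6,
      2945, 45, 0.7), axis),
    pectin_de_mid = make_reference_spectrum("pectin_de_mid", b(
      855, 14, 0.8,  1078, 20, 0.5,  1444, 24, 0.4,  1735, 22, 0.4,
      2945, 45, 0.7), axis),
    pectin_de_high = make_reference_spectrum("pectin_de_high", b(
      853, 14, 0.8,  1078, 20, 0.5,  1444, 24, 0.4,  1740, 22, 0.7,
      2945, 45, 0.7), axis))
  reference_library(specs, metadata = list(
    cellulose = "cellulose", xylan = "hemicellulose",
    glucomannan = "hemicellulose", pectin_de_low = "esterification 10-34%",
    pectin_de_mid = "esterification 35-84%",
    pectin_de_high = "esterification >85%"), axis = axis)
}

#' Specification of a synthetic hyperspectral cube
#'
#' @param shape image shape `(ny, nx)` in pixels
#' @param endmember_names library entries to mix
#' @param abundance_model optional list (one per endmember) of data.frames
#'   with columns `(y, x, width, height)` describing Gaussian abundance
#'   blobs in pixel units; seeded random blobs when omitted
#' @param noise_sd relative (multiplicative) noise standard deviation
#' @param n_spikes number of single-pixel single-band cosmic-ray spikes
#' @param seed integer RNG seed
#' @return an object of class `cube_spec`
#' @export
cube_spec <- function(shape = c(32, 32), endmember_names,
                      abundance_model = NULL, noise_sd = 0.02,
                      n_spikes = 0L, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(shape = as.integer(shape),
                 endmember_names = endmember_names,
                 abundance_model = abundance_model,
                 noise_sd = noise_sd, n_spikes = as.integer(n_spikes),
                 seed = as.integer(seed)),
            class = "cube_spec")
}

#' Generate a mixed hyperspectral cube with ground truth
#'
#' Each pixel spectrum is the abundance-weighted sum of the selected
#' library spectra, degraded by multiplicative Gaussian noise (Raman shot
#' noise scales with intensity) and single-pixel single-band spikes of
#' 20-100x the local intensity.
#'
#' @param spec a [cube_spec()]
#' @param library a [reference_library()] containing `spec$endmember_names`
#' @return list with `cube` (a [hyperspectral_cube()]) and `truth` (list:
#'   `abundances` array (y, x, endmember), `spikes` data.frame (y, x, band))
#' @export
make_hyperspectral_cube <- function(spec, library) {
  stopifnot(inherits(spec, "cube_spec"), inherits(library, "reference_library"))
  miss <- setdiff(spec$endmember_names, library$names)
  if (length(miss)) stop("endmembers not in library: ", paste(miss, collapse = ", "))
  ny <- spec$shape[1]; nx <- spec$shape[2]
  ne <- length(spec$endmember_names)
  nb <- length(library$wavenumbers)

  res <- with_seed(spec$seed, {
    model <- spec$abundance_model
    if (is.null(model)) {
      model <- lapply(seq_len(ne), function(e) {
        nblob <- 2L
        data.frame(y = runif(nblob, 1, ny), x = runif(nblob, 1, nx),
                   width = runif(nblob, 0.15, 0.3) * min(ny, nx),
                   height = runif(nblob, 0.5, 1))
      })
    }
    ab <- array(0, c(ny, nx, ne))
    gy <- matrix(seq_len(ny), ny, nx)
    gx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    for (e in seq_len(ne)) {
      m <- model[[e]]
      for (i in seq_len(nrow(m)))
        ab[, , e] <- ab[, , e] + m$height[i] *
          exp(-((gy - m$y[i])^2 + (gx - m$x[i])^2) / (2 * m$width[i]^2))
    }
    S <- library$intensities[, match(spec$endmember_names, library$names),
                             drop = FALSE]  # bands x ne
    flat <- matrix(ab, ny * nx, ne)
    cube <- array(flat %*% t(S), c(ny, nx, nb))
    if (spec$noise_sd > 0)
      cube <- pmax(cube * (1 + array(rnorm(length(cube), sd = spec$noise_sd),
                                     dim(cube))), 0)
    spikes <- data.frame(y = integer(0), x = integer(0), band = integer(0))
    if (spec$n_spikes > 0) {
      sy <- sample.int(ny, spec$n_spikes, replace = TRUE)
      sx <- sample.int(nx, spec$n_spikes, replace = TRUE)
      sb <- sample.int(nb, spec$n_spikes, replace = TRUE)
      fac <- runif(spec$n_spikes, 20, 100)
      for (i in seq_len(spec$n_spikes)) {
        local <- max(cube[sy[i], sx[i], ], 1e-3 * max(cube))
        cube[sy[i], sx[i], sb[i]] <- cube[sy[i], sx[i], sb[i]] + fac[i] * local
      }
      spikes <- data.frame(y = sy, x = sx, band = sb)
    }
    list(cube = cube, ab = ab, spikes = spikes)
  })
  list(cube = hyperspectral_cube(res$cube, library$wavenumbers),
       truth = list(abundances = res$ab, spikes = res$spikes))
}
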