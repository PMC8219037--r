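# File I/O for the standard formats the pipeline touches: multipage TIFF
# label stacks and hyperspectral cubes, PLY/STL meshes, CSV spectra and
# descriptor tables. Label containers are 16-bit, auto-promoted to 32-bit
# for labels above 65535; cubes are 32-bit with the intensity scale kept in
# the wavenumber sidecar so round trips are lossless at container precision.

#' Read a multipage TIFF label stack
#'
#' Pages are stacked in page order as the z axis; pixel values must be
#' integers (cell labels).
#'
#' @param path TIFF file path
#' @param spacing voxel spacing `(sz, sy, sx)` in µm
#' @param background_label passed through to [labeled_volume()]
#' @return a [labeled_volume()]
#' @export
read_label_stack <- function(path, spacing, background_label = 0L) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("ragged page shapes in ", path)
  ints <- vapply(pages, function(p) is.integer(p) ||
                   (is.numeric(p) && all(p == round(p))), logical(1))
  if (!all(ints))
    stop("non-integer pixel type in ", path, ": not a label stack")
  nz <- length(pages)
  ny <- shapes[1, 1]; nx <- shapes[2, 1]
  labels <- array(0L, c(nz, ny, nx))
  for (z in seq_len(nz)) labels[z, , ] <- as.integer(pages[[z]])
  labeled_volume(labels, spacing, background_label)
}

#' Write a label volume as a multipage TIFF
#'
#' 16-bit pages for labels up to 65535, 32-bit above that; labels beyond
#' the 32-bit signed range are refused rather than truncated.
#'
#' @param vol a [labeled_volume()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_label_stack <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  maxlab <- max(vol$labels, 0L)
  if (maxlab <= 65535L) {
    denom <- 65535
    bps <- 16L
  } else if (maxlab <= .Machine$integer.max) {
    denom <- 2^32 - 1
    bps <- 32L
  } else {
    stop("labels above ", .Machine$integer.max,
         " cannot be stored without truncation")
  }
  pages <- lapply(seq_len(dim(vol$labels)[1]), function(z)
    vol$labels[z, , ] / denom)
  tiff::writeTIFF(pages, path, bits.per.sample = bps)
  invisible(path)
}

#' Write a triangle mesh as ASCII PLY or STL
#'
#' Format chosen by file extension (`.ply` or `.stl`). STL stores
#' per-triangle vertices; [read_mesh()] re-welds identical coordinates so
#' round trips preserve topology.
#'
#' @param vertices numeric matrix, n x 3 (x, y, z) in µm
#' @param faces integer matrix, m x 3 of 1-based vertex indices
#' @param path output path ending in `.ply` or `.stl`
#' @return `path`, invisibly
#' @export
write_mesh <- function(vertices, faces, path) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (nrow(vertices) == 0 || nrow(faces) == 0)
    stop("empty mesh")
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop("vertices and faces must have 3 columns")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("faces index vertices outside 1..", nrow(vertices))
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(vertices)),
                 "property double x", "property double y", "property double z",
                 paste("element face", nrow(faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(vertices, 1, function(v)
      paste(format(v, digits = 17), collapse = " ")), con)
    writeLines(apply(faces - 1L, 1, function(f)
      paste(c(3L, f), collapse = " ")), con)
  } else if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(faces))) {
      tri <- vertices[faces[i, ], , drop = FALSE]
      n <- pracma::cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      nl <- sqrt(sum(n^2)); if (nl > 0) n <- n / nl
      writeLines(c(paste("facet normal", paste(format(n, digits = 17), collapse = " ")),
                   "outer loop",
                   paste("vertex", apply(tri, 1, function(v)
                     paste(format(v, digits = 17), collapse = " "))),
                   "endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    stop("unsupported mesh extension '", ext, "' (use .ply or .stl)")
  }
  invisible(path)
}

#' Read an ASCII PLY or STL mesh
#'
#' @param path mesh file ending in `.ply` or `.stl`
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based)
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "ply") {
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    hdr <- which(lines == "end_header")
    vl <- lines[(hdr + 1):(hdr + nv)]
    fl <- lines[(hdr + nv + 1):(hdr + nv + nf)]
    vertices <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[1:3])))
    faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) as.integer(x[2:4]) + 1L))
    list(vertices = vertices, faces = faces)
  } else if (ext == "stl") {
    vlines <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(x)
      as.numeric(x[2:4])))
    key <- apply(coords, 1, function(v) paste(format(v, digits = 17), collapse = "_"))
    uk <- !duplicated(key)
    vertices <- coords[uk, , drop = FALSE]
    idx <- match(key, key[uk])
    faces <- matrix(idx, ncol = 3, byrow = TRUE)
    list(vertices = vertices, faces = faces)
  } else {
    stop("unsupported mesh extension '", ext, "'")
  }
}

#' Enclosed volume of a closed, consistently oriented triangle mesh
#' @param vertices n x 3 matrix
#' @param faces m x 3 index matrix (1-based)
#' @return volume in µm^3
#' @export
mesh_volume <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(a * cr) / 6)
}

#' Total area of a triangle mesh
#' @inheritParams mesh_volume
#' @return area in µm^2
#' @export
mesh_area <- function(vertices, faces) {
  u <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  w <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Read a two-column spectrum CSV (wavenumber, intensity)
#' @param path CSV path
#' @return a [spectrum()] with ascending axis
#' @export
read_spectrum_csv <- function(path) {
  d <- read.csv(path)
  if (ncol(d) < 2 || !is.numeric(d[[1]]) || !is.numeric(d[[2]]))
    stop("spectrum CSV must have two numeric columns (wavenumber, intensity)")
  spectrum(d[[1]], d[[2]])
}

#' Write a spectrum as a two-column CSV
#' @param spec a [spectrum()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  d <- data.frame(wavenumber = spec$wavenumbers, intensity = spec$intensities)
  write.csv(format(d, digits = 17, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a hyperspectral cube (band-sequential TIFF + wavenumber sidecar)
#'
#' Pages of the TIFF are bands in sidecar row order; the sidecar CSV carries
#' the wavenumber axis and the intensity scale used on write.
#'
#' @param path_tiff multipage TIFF, one page per band
#' @param path_wavenumbers sidecar CSV with columns `wavenumber` and `scale`
#' @param pixel_spacing pixel size `(µm, µm)`
#' @return a [hyperspectral_cube()]
#' @export
read_cube <- function(path_tiff, path_wavenumbers, pixel_spacing = c(1, 1)) {
  side <- read.csv(path_wavenumbers)
  pages <- tiff::readTIFF(path_tiff, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != nrow(side))
    stop("cube has ", length(pages), " bands but sidecar lists ", nrow(side))
  scale <- if ("scale" %in% names(side)) side$scale[1] else 1
  ny <- dim(pages[[1]])[1]; nx <- dim(pages[[1]])[2]
  cube <- array(0, c(ny, nx, length(pages)))
  for (b in seq_along(pages)) cube[, , b] <- pages[[b]] * scale
  hyperspectral_cube(cube, side$wavenumber, pixel_spacing)
}

#' Write a hyperspectral cube as band-sequential TIFF + sidecar CSV
#' @param x a [hyperspectral_cube()]
#' @param path_tiff output TIFF path
#' @param path_wavenumbers output sidecar CSV path
#' @return `path_tiff`, invisibly
#' @export
write_cube <- function(x, path_tiff, path_wavenumbers) {
  stopifnot(inherits(x, "hyperspectral_cube"))
  scale <- max(x$cube, 1e-300)
  pages <- lapply(seq_len(dim(x$cube)[3]), function(b) x$cube[, , b] / scale)
  tiff::writeTIFF(pages, path_tiff, bits.per.sample = 32L)
  side <- data.frame(wavenumber = x$wavenumbers, scale = scale)
  write.csv(format(side, digits = 17, trim = TRUE), path_wavenumbers,
            row.names = FALSE, quote = FALSE)
  invisible(path_tiff)
}

#' Write per-cell descriptor records as CSV
#' @param records data.frame, one row per cell
#' @param path output path
#' @return `path`, invisibly
#' @export
write_records_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor table written by [write_records_csv()]
#' @param path CSV path
#' @return data.frame
#' @export
read_records_csv <- function(path) {
  read.csv(path)
}
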