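#' Labeled 3D segmentation volume
#'
#' The substrate of all morphometry: a 3D grid of integer cell labels
#' indexed `(z, y, x)` with physical voxel spacing `(sz, sy, sx)` in µm.
#' Label `background_label` (default 0) marks not-a-cell voxels
#' (intercellular space or exterior); every other label is one cell.
#'
#' @param labels 3D integer array, dimensions `(nz, ny, nx)`
#' @param spacing numeric length 3, voxel edge lengths `(sz, sy, sx)` in µm
#' @param background_label integer label meaning not-a-cell (default 0)
#' @return an object of class `labeled_volume`
#' @export
labeled_volume <- function(labels, spacing, background_label = 0L) {
  if (length(dim(labels)) != 3)
    stop("`labels` must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  spacing <- check_spacing(spacing)
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, spacing = spacing,
         background_label = as.integer(background_label)),
    class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  dm <- dim(x$labels)
  labs <- setdiff(unique(as.vector(x$labels)), x$background_label)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels (z,y,x), spacing (%g, %g, %g) um, %d cell(s)\n",
              dm[1], dm[2], dm[3], x$spacing[1], x$spacing[2], x$spacing[3],
              length(labs)))
  invisible(x)
}

#' Single Raman spectrum
#'
#' A wavenumber axis (cm^-1) with non-negative intensities. Axes are stored
#' ascending; descending input is flipped on construction.
#'
#' @param wavenumbers strictly monotonic numeric axis in cm^-1
#' @param intensities non-negative numeric vector of the same length
#' @param name optional component name
#' @return an object of class `spectrum`
#' @export
spectrum <- function(wavenumbers, intensities, name = NULL) {
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  dw <- diff(wavenumbers)
  if (length(dw) && !(all(dw > 0) || all(dw < 0)))
    stop("wavenumber axis must be strictly monotonic")
  if (length(dw) && all(dw < 0)) {
    wavenumbers <- rev(wavenumbers)
    intensities <- rev(intensities)
  }
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = as.numeric(intensities),
                 name = name),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum>%s %d bands, %.1f-%.1f cm^-1\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Hyperspectral Raman cube
#'
#' @param cube 3D array `(y, x, band)` of non-negative intensities
#' @param wavenumbers band axis in cm^-1, length `dim(cube)[3]`
#' @param pixel_spacing pixel size `(µm, µm)`
#' @return an object of class `hyperspectral_cube`
#' @export
hyperspectral_cube <- function(cube, wavenumbers, pixel_spacing = c(1, 1)) {
  if (length(dim(cube)) != 3)
    stop("`cube` must be a 3D array (y, x, band)")
  if (dim(cube)[3] != length(wavenumbers))
    stop("band dimension (", dim(cube)[3], ") does not match wavenumber axis (",
         length(wavenumbers), ")")
  if (any(cube < 0)) stop("cube intensities must be non-negative")
  dw <- diff(wavenumbers)
  if (length(dw) && all(dw < 0)) {
    wavenumbers <- rev(wavenumbers)
    cube <- cube[, , rev(seq_along(wavenumbers)), drop = FALSE]
  }
  structure(list(cube = cube, wavenumbers = as.numeric(wavenumbers),
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  dm <- dim(x$cube)
  cat(sprintf("<hyperspectral_cube> %d x %d pixels, %d bands (%.0f-%.0f cm^-1)\n",
              dm[1], dm[2], dm[3], min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Reference library of pure-component spectra
#'
#' Named pure-component spectra resampled (linear interpolation) onto one
#' shared wavenumber axis, with optional per-entry metadata such as the
#' pectin esterification class.
#'
#' @param spectra named list of [spectrum()] objects
#' @param metadata optional named list (per entry) of metadata strings
#' @param axis target wavenumber axis; defaults to the first spectrum's axis
#' @return an object of class `reference_library`
#' @export
reference_library <- function(spectra, metadata = NULL, axis = NULL) {
  if (!length(spectra)) stop("library must contain at least one spectrum")
  nms <- names(spectra)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("spectra must be uniquely named")
  if (is.null(axis)) axis <- spectra[[1]]$wavenumbers
  mat <- vapply(spectra, function(s) {
    approx(s$wavenumbers, s$intensities, xout = axis, rule = 2)$y
  }, numeric(length(axis)))
  mat <- pmax(mat, 0)
  structure(list(wavenumbers = as.numeric(axis),
                 intensities = mat,   # bands x entries
                 names = nms,
                 metadata = metadata),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library> %d entries on %d bands: %s\n",
              length(x$names), length(x$wavenumbers),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Extract one library entry as a spectrum
#' @param library a [reference_library()]
#' @param name entry name
#' @return a [spectrum()]
#' @export
library_spectrum <- function(library, name) {
  i <- match(name, library$names)
  if (is.na(i)) stop("no library entry named '", name, "'")
  spectrum(library$wavenumbers, library$intensities[, i], name = name)
}
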