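# Lobe counting via curve skeletons: morphological shape smoothing, 3D
# homotopic thinning (distance-ordered, topology-preserving), length-based
# branch pruning, and endpoint counting. Endpoints of the pruned medial
# line correspond to the main lobes of a cell; near-spherical cells are
# scored as 2 lobes by convention (a thinned ball collapses to a short
# path with two ends).

#' Morphological smoothing of a cell mask
#'
#' Closing followed by opening with a discrete ball of the given voxel
#' radius, both implemented exactly through the Euclidean distance
#' transform. Removes voxel-scale segmentation artefacts while retaining
#' lobe-scale features, so that only main lobes are counted downstream.
#'
#' @param mask 3D logical array
#' @param radius_vox integer ball radius in voxels (0 = identity)
#' @return smoothed logical array
#' @export
smooth_mask <- function(mask, radius_vox) {
  if (radius_vox < 0) stop("radius must be >= 0")
  if (radius_vox == 0) return(mask)
  storage.mode(mask) <- "logical"
  iso <- c(1, 1, 1)
  # midpoint ball convention: a ball of radius exactly r has single-voxel
  # lattice tips at (0,0,r), so opening with it cannot remove face
  # pimples; r + 1/2 covers the intended continuous ball
  r <- radius_vox + 0.5
  dilate <- function(m) m | (cpp_edt(!m, iso) <= r)
  erode <- function(m) m & (cpp_edt(m, iso) > r)
  out <- dilate(erode(erode(dilate(mask))))   # closing, then opening
  if (!any(out))
    stop("smoothing erased the mask entirely (radius too large)")
  out
}

#' Curve skeleton of a cell mask by homotopic thinning
#'
#' One-voxel-wide medial skeleton: simple points (whose removal preserves
#' object and background topology) are deleted in increasing order of the
#' distance transform until only the medial line and its endpoints remain.
#' Connectivity of a connected mask is preserved; a disconnected mask is
#' thinned per component with a warning.
#'
#' @param mask 3D logical array, non-empty
#' @param spacing voxel spacing `(sz, sy, sx)` µm
#' @param anchors optional 3D logical array of voxels the thinning may
#'   never delete (e.g. [lobe_tip_anchors()]); `NULL` = plain thinning
#' @return object of class `skeleton3d`: list with `voxels` (n x 3 array
#'   indices), `coords` (n x 3 µm positions, (z,y,x)), `edges` (m x 2 index
#'   pairs of 26-adjacent skeleton voxels), `spacing`, `dim`
#' @export
skeletonize_cell <- function(mask, spacing, anchors = NULL) {
  spacing <- check_spacing(spacing)
  if (!any(mask)) stop("empty mask")
  storage.mode(mask) <- "logical"
  ncomp <- max(label_components(mask, 26))
  if (ncomp > 1)
    warning("mask has ", ncomp, " components; skeletonizing each")
  pri <- cpp_edt(mask, spacing)
  if (is.null(anchors)) anchors <- logical(0)
  else storage.mode(anchors) <- "logical"
  sk <- cpp_thin(mask, pri, anchors)
  skeleton_from_mask(sk, spacing)
}

#' Lobe-tip anchor voxels of a cell mask
#'
#' Marks one voxel per main lobe. The cell's radial excess
#' `e(v) = |pos(v) - c| - r_ellipsoid(u_v)` measures how far the cell
#' protrudes beyond the ellipsoid fitted to its second moments (exact for
#' any unlobed ellipsoid, so smooth elongation generates no excess).
#' Voxels whose excess passes `excess_fraction` of the maximum (with a
#' 1.25-voxel floor that rejects digitization staircase) and that are weak
#' local maxima of the excess are lobe-tip candidates; greedy non-maximum
#' suppression then accepts peaks in order of decreasing excess, skipping
#' candidates within `min_separation_deg` of an accepted peak as seen
#' from the centroid. Anchors force the homotopic thinning to keep a
#' branch into every main lobe — the role the tube-penalty parameters
#' play in centreline-tree extraction. Unlobed cells produce no anchors
#' (and thin to a plain medial path scored as 2 lobes downstream).
#'
#' @param mask 3D logical array (one connected cell)
#' @param spacing voxel spacing µm
#' @param excess_fraction candidate threshold as a fraction of the
#'   maximum radial excess (default 0.35: main lobes only)
#' @param min_separation_deg angular suppression radius between accepted
#'   lobe peaks (default 30)
#' @return 3D logical array marking anchor voxels (possibly none)
#' @export
lobe_tip_anchors <- function(mask, spacing, excess_fraction = 0.35,
                             min_separation_deg = 30) {
  spacing <- check_spacing(spacing)
  storage.mode(mask) <- "logical"
  dm <- dim(mask)
  idx <- which(mask)
  pos <- sweep(arrayInd(idx, dm) - 0.5, 2, spacing, "*")
  # reference body: ellipsoid fitted by second moments (exact for any
  # unlobed ellipsoid, so smooth elongation produces no excess)
  centre <- colMeans(pos)
  rel <- sweep(pos, 2, centre)
  S <- crossprod(rel) / nrow(rel)
  eg <- eigen(S, symmetric = TRUE)
  axes <- sqrt(pmax(5 * eg$values, 1e-12))  # uniform solid ellipsoid
  rr <- sqrt(rowSums(rel^2))
  u <- rel / pmax(rr, 1e-12)
  w <- u %*% eg$vectors
  r_ell <- 1 / sqrt(rowSums(sweep(w, 2, axes, "/")^2))
  e <- rr - r_ell
  anchors <- array(FALSE, dm)
  floor_t <- 1.25 * max(spacing)
  emax <- max(e)
  if (emax <= floor_t) return(anchors)  # ball-like: no lobes to anchor
  thr <- max(floor_t, excess_fraction * emax)
  # candidates must be weak local maxima of the excess: suppresses the
  # cap rims of smoothly elongated (but unlobed) cells
  evals <- array(-Inf, dm)
  evals[idx] <- e
  offs <- offsets26()
  ismax <- rep(TRUE, length(idx))
  vox <- arrayInd(idx, dm)
  for (o in seq_len(nrow(offs))) {
    z <- vox[, 1] + offs[o, 1]; y <- vox[, 2] + offs[o, 2]
    x <- vox[, 3] + offs[o, 3]
    inb <- z >= 1 & z <= dm[1] & y >= 1 & y <= dm[2] & x >= 1 & x <= dm[3]
    nbv <- rep(-Inf, length(idx))
    nbv[inb] <- evals[cbind(z[inb], y[inb], x[inb])]
    ismax <- ismax & e >= nbv
  }
  cand <- which(e > thr & ismax)
  cand <- cand[order(e[cand], decreasing = TRUE)]
  dirs <- rel[cand, , drop = FALSE] / rr[cand]
  cosmin <- cos(min_separation_deg * pi / 180)
  acc <- integer(0)
  for (i in seq_along(cand)) {
    if (!length(acc) ||
        all(dirs[acc, , drop = FALSE] %*% dirs[i, ] < cosmin))
      acc <- c(acc, i)
  }
  anchors[idx[cand[acc]]] <- TRUE
  anchors
}

skeleton_from_mask <- function(sk, spacing) {
  dm <- dim(sk)
  idx <- which(sk)
  vox <- arrayInd(idx, dm)
  n <- length(idx)
  # edges between 26-adjacent skeleton voxels (each pair once)
  offs <- offsets26()
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  pos <- match(idx, idx)  # identity; lookup table built below
  lookup <- integer(prod(dm))
  lookup[idx] <- seq_len(n)
  edges <- NULL
  for (o in seq_len(nrow(offs))) {
    z <- vox[, 1] + offs[o, 1]; y <- vox[, 2] + offs[o, 2]; x <- vox[, 3] + offs[o, 3]
    ok <- z >= 1 & z <= dm[1] & y >= 1 & y <= dm[2] & x >= 1 & x <= dm[3]
    li <- z[ok] + dm[1] * ((y[ok] - 1) + dm[2] * (x[ok] - 1))
    nb <- lookup[li]
    hit <- nb > 0
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], nb[hit]))
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  structure(list(voxels = vox,
                 coords = sweep(vox - 0.5, 2, spacing, "*"),
                 edges = edges, spacing = spacing, dim = dm),
            class = "skeleton3d")
}

#' @export
print.skeleton3d <- function(x, ...) {
  cat(sprintf("<skeleton3d> %d voxels, %d edges, %d endpoint(s)\n",
              nrow(x$voxels), nrow(x$edges), length(skeleton_endpoints(x))))
  invisible(x)
}

skeleton_degrees <- function(skel) {
  n <- nrow(skel$voxels)
  tabulate(c(skel$edges[, 1], skel$edges[, 2]), nbins = n)
}

#' Endpoint indices of a skeleton (nodes of degree <= 1)
#' @param skel a `skeleton3d`
#' @return integer node indices
#' @export
skeleton_endpoints <- function(skel) {
  which(skeleton_degrees(skel) <= 1)
}

#' Prune short terminal branches of a skeleton
#'
#' Iteratively removes terminal branches (endpoint up to the first
#' junction) whose path length along the voxel chain is below
#' `min_branch_len`, until stable. Branches ending at another endpoint
#' (i.e. the skeleton is a bare path) are never removed, so the skeleton
#' stays connected.
#'
#' @param skel a `skeleton3d`
#' @param min_branch_len minimum terminal branch length in µm
#' @return pruned `skeleton3d`
#' @export
prune_skeleton <- function(skel, min_branch_len) {
  if (min_branch_len <= 0) return(skel)
  repeat {
    n <- nrow(skel$voxels)
    if (n <= 2) return(skel)
    deg <- skeleton_degrees(skel)
    adj <- vector("list", n)
    for (e in seq_len(nrow(skel$edges))) {
      a <- skel$edges[e, 1]; b <- skel$edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    drop <- logical(n)
    for (ep in which(deg == 1)) {
      path <- ep
      prev <- 0L
      cur <- ep
      len <- 0
      repeat {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) != 1) break   # junction (or isolated end)
        step <- sqrt(sum(((skel$coords[cur, ] - skel$coords[nxt, ]))^2))
        if (deg[nxt] >= 3) {          # reached a junction: branch complete
          len <- len + step
          if (len < min_branch_len) drop[path] <- TRUE
          break
        }
        if (deg[nxt] == 1) break      # pure path: keep
        len <- len + step
        prev <- cur
        cur <- nxt
        path <- c(path, cur)
      }
    }
    if (!any(drop)) return(skel)
    keep <- which(!drop)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    e <- skel$edges
    e <- e[!drop[e[, 1]] & !drop[e[, 2]], , drop = FALSE]
    skel$voxels <- skel$voxels[keep, , drop = FALSE]
    skel$coords <- skel$coords[keep, , drop = FALSE]
    skel$edges <- cbind(remap[e[, 1]], remap[e[, 2]])
  }
}

#' Count main lobes of a cell
#'
#' Endpoints of the pruned skeleton of the smoothed cell mask, floored at
#' 2: an isodiametric cell thins to a short path and is scored as 2 lobes.
#' The default pruning length adapts to cell size (half the LES radius),
#' so only main lobes are counted at every developmental stage.
#'
#' @param vol a [labeled_volume()]
#' @param label cell label
#' @param smoothing_radius morphological smoothing radius in voxels
#' @param min_branch_len pruning threshold in µm; `NULL` = half the LES
#'   radius of the smoothed cell
#' @return integer lobe count (>= 2)
#' @export
count_lobes <- function(vol, label, smoothing_radius = 2L,
                        min_branch_len = NULL) {
  m <- cell_mask(vol, label)
  # cells only a few voxels across can vanish under the full smoothing;
  # step the radius down rather than fail
  repeat {
    sm <- tryCatch(smooth_mask(m, smoothing_radius), error = function(e) NULL)
    if (!is.null(sm)) break
    smoothing_radius <- smoothing_radius - 1L
  }
  m <- sm
  dt <- cpp_edt(m, vol$spacing)
  if (is.null(min_branch_len))
    min_branch_len <- 0.5 * max(dt)  # half the LES radius
  anchors <- lobe_tip_anchors(m, vol$spacing)
  sk <- cpp_thin(m, dt, anchors)
  skel <- skeleton_from_mask(sk, vol$spacing)
  skel <- prune_skeleton(skel, min_branch_len)
  max(length(skeleton_endpoints(skel)), 2L)
}

#' Export a skeleton as a CSV edge list
#' @param skel a `skeleton3d`
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_skeleton_csv <- function(skel, path) {
  e <- skel$edges
  d <- data.frame(
    z_from = skel$coords[e[, 1], 1], y_from = skel$coords[e[, 1], 2],
    x_from = skel$coords[e[, 1], 3],
    z_to = skel$coords[e[, 2], 1], y_to = skel$coords[e[, 2], 2],
    x_to = skel$coords[e[, 2], 3])
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
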