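# Shared fixtures and independent brute-force oracles.

# digital ball of physical radius r_um on an isotropic grid
digital_ball <- function(r_um, spacing, margin = 3L) {
  n <- 2L * ceiling(r_um / spacing) + 2L * margin + 1L
  ax <- ((seq_len(n)) - 0.5) * spacing - (n / 2) * spacing
  P1 <- array(ax, c(n, n, n))
  P2 <- array(rep(ax, each = n), c(n, n, n))
  P3 <- array(rep(ax, each = n * n), c(n, n, n))
  m <- (P1^2 + P2^2 + P3^2) <= r_um^2
  lab <- array(0L, c(n, n, n))
  lab[m] <- 1L
  labeled_volume(lab, rep(spacing, 3))
}

# brute-force largest-empty-sphere diameter: all foreground voxels against
# all background voxels
les_oracle <- function(mask, spacing) {
  idx <- which(mask)
  bg <- which(!mask)
  if (!length(bg)) return(Inf)
  ci <- arrayInd(idx, dim(mask))
  cb <- t(arrayInd(bg, dim(mask)))
  best <- 0
  for (i in seq_along(idx)) {
    d2 <- colSums(((cb - ci[i, ]) * spacing)^2)
    best <- max(best, min(d2))
  }
  2 * sqrt(best)
}

# brute-force contact enumeration: per label pair, face areas and patch
# counts via O(F^2) adjacency (faces connected when both voxel sides are
# 26-adjacent)
contact_oracle <- function(labels, spacing, background = 0L) {
  dm <- dim(labels)
  faces <- list()
  fa <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
          spacing[1] * spacing[2])
  for (x in seq_len(dm[3])) for (y in seq_len(dm[2])) for (z in seq_len(dm[1])) {
    la <- labels[z, y, x]
    nb <- list(c(z + 1, y, x, 1), c(z, y + 1, x, 2), c(z, y, x + 1, 3))
    for (b in nb) {
      if (b[1] > dm[1] || b[2] > dm[2] || b[3] > dm[3]) next
      lb <- labels[b[1], b[2], b[3]]
      if (la == background || lb == background || la == lb) next
      if (la < lb)
        faces[[length(faces) + 1]] <- c(la, lb, z, y, x, b[1], b[2], b[3], b[4])
      else
        faces[[length(faces) + 1]] <- c(lb, la, b[1], b[2], b[3], z, y, x, b[4])
    }
  }
  if (!length(faces))
    return(data.frame(label_a = integer(0), label_b = integer(0),
                      area = numeric(0), n_patches = integer(0)))
  F <- do.call(rbind, faces)
  out <- list()
  for (key in unique(paste(F[, 1], F[, 2]))) {
    sub <- F[paste(F[, 1], F[, 2]) == key, , drop = FALSE]
    nf <- nrow(sub)
    parent <- seq_len(nf)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nf)) for (j in seq_len(nf)) {
      if (i >= j) next
      if (max(abs(sub[i, 3:5] - sub[j, 3:5])) <= 1 &&
          max(abs(sub[i, 6:8] - sub[j, 6:8])) <= 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    roots <- length(unique(vapply(seq_len(nf), find, 1L)))
    out[[length(out) + 1]] <- data.frame(
      label_a = sub[1, 1], label_b = sub[1, 2],
      area = sum(fa[sub[, 9]]), n_patches = roots)
  }
  res <- do.call(rbind, out)
  res[order(res$label_a, res$label_b), , drop = FALSE]
}

# independent convex-hull volume via scipy (pre-installed python)
scipy_hull_volume <- function(pts) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.table(pts, f, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(paste0(
    "import numpy as np\nfrom scipy.spatial import ConvexHull\n",
    "p = np.loadtxt('%s', delimiter=',')\nprint(repr(ConvexHull(p).volume))"), f)
  out <- suppressWarnings(system2("python", "-", input = code, stdout = TRUE))
  as.numeric(out[length(out)])
}

# random multi-label volume for oracle-equivalence checks
random_label_volume <- function(seed, max_dim = 16L) {
  set.seed(seed)
  dm <- sample(8:max_dim, 3, replace = TRUE)
  labels <- array(sample(0:3, prod(dm), replace = TRUE,
                         prob = c(0.4, 0.2, 0.2, 0.2)), dm)
  labeled_volume(labels, runif(3, 0.5, 2))
}
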