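# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Quasi-uniform unit directions on the sphere (Fibonacci lattice), n x 3
# in (z, y, x) component order.
fibonacci_sphere <- function(n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * i
  cbind(z = z, y = r * sin(theta), x = r * cos(theta))
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (sz, sy, sx) in µm",
         call. = FALSE)
  spacing
}

# 26-neighbourhood offsets as a 26 x 3 integer matrix (dz, dy, dx).
offsets26 <- function() {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ])
}

# Connected-component labeling of a 3D logical mask (26- or 6-connectivity).
label_components <- function(mask, connectivity = 26) {
  storage.mode(mask) <- "logical"
  cpp_label_components(mask, as.integer(connectivity))
}

# cosine similarity between two vectors; NA if either is all-zero
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
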