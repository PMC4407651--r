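# Geometry builders and independent flow oracles shared across tests.

# digitised sphere of radius r voxels, padded
sphere_mask <- function(r, pad = 3) {
  d <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  g <- expand.grid(1:d, 1:d, 1:d)
  array(rowSums((g - ctr)^2) <= r^2, c(d, d, d))
}

# plane Poiseuille slab: aperture `a` fluid rows inside an n^3 cell,
# flow along x, walls normal to y
slab_mask <- function(n, a) {
  stopifnot(a < n)
  lo <- floor((n - a) / 2) + 1L
  m <- array(FALSE, c(n, n, n))
  m[, lo:(lo + a - 1L), ] <- TRUE
  m
}

# square duct of side `a`, walls `w`, length `len`, axis z
duct_mask <- function(a, w = 4L, len = 8L) {
  n <- a + 2L * w
  m <- array(FALSE, c(n, n, len))
  m[(w + 1L):(w + a), (w + 1L):(w + a), ] <- TRUE
  m
}

# straight circular channel along z: radius r voxels in a (2r+2m)^2 x len box
channel_mask <- function(r, margin = 7L, len = 40L) {
  n <- 2L * (r + margin)
  ctr <- (n + 1) / 2
  g <- expand.grid(1:n, 1:n)
  circ <- matrix((g[, 1] - ctr)^2 + (g[, 2] - ctr)^2 <= r^2, n, n)
  m <- array(FALSE, c(n, n, len))
  for (k in seq_len(len)) m[, , k] <- circ
  m
}

# mean slab (Poiseuille) velocity in voxel units: phi * a^2 / 12
poiseuille_mean <- function(n, a) (a / n) * a^2 / 12

# series solution for the mean velocity in a square duct of side s,
# unit pressure gradient, unit viscosity: u_mean = C * s^2
duct_series_coef <- function(terms = 400) {
  i <- seq(1, 2 * terms - 1, by = 2)
  (1 - 192 / pi^5 * sum(tanh(i * pi / 2) / i^5)) / 12
}

# relative error helper
rel_err <- function(x, ref) abs(x / ref - 1)
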