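# Independent oracles used across the suite. These re-derive quantities by a
# different route than the implementation (finite differences, brute-force
# loops, closed forms) and must stay independent of the code they check.

# Central finite difference of the incompressible uniaxial strain energy
# psi(l) = (2 mu / a^2) (2 l^(-a/2) + l^a - 3); its derivative is the
# uniaxial nominal stress.
fd_uniaxial_stress <- function(lambda, mu, alpha, h = 1e-7) {
  psi <- function(l) (2 * mu / alpha^2) * (2 * l^(-alpha / 2) + l^alpha - 3)
  (psi(lambda + h) - psi(lambda - h)) / (2 * h)
}

# Spectral-form lateral Piola stress: Pxx = dpsi/dlambda1 - p / lambda1 with
# lambda1 = lambda^(-1/2), computed by finite differences of the full
# three-stretch energy. Must vanish for the analytic pressure.
fd_lateral_stress <- function(lambda, mu, alpha, p, h = 1e-7) {
  l1 <- lambda^(-1 / 2)
  psi3 <- function(a, b, c) (2 * mu / alpha^2) * (a^alpha + b^alpha + c^alpha - 3)
  dpsi_dl1 <- (psi3(l1 + h, l1, lambda) - psi3(l1 - h, l1, lambda)) / (2 * h)
  dpsi_dl1 - p / l1
}

# Brute-force point-to-capsule-surface distance: plain scalar loops over
# segments, one arithmetic step at a time.
brute_surface_distance <- function(px, py, pz, filament) {
  nodes <- as.data.frame(filament)
  child <- nodes[nodes$parent != -1, , drop = FALSE]
  best <- Inf
  for (k in seq_len(nrow(child))) {
    pa <- nodes[match(child$parent[k], nodes$id), ]
    ax <- pa$x; ay <- pa$y; az <- pa$z; r0 <- pa$radius
    bx <- child$x[k]; by <- child$y[k]; bz <- child$z[k]; r1 <- child$radius[k]
    dx <- bx - ax; dy <- by - ay; dz <- bz - az
    len2 <- dx^2 + dy^2 + dz^2
    tt <- if (len2 == 0) 0 else ((px - ax) * dx + (py - ay) * dy + (pz - az) * dz) / len2
    tt <- min(max(tt, 0), 1)
    cx <- ax + tt * dx; cy <- ay + tt * dy; cz <- az + tt * dz
    d <- sqrt((px - cx)^2 + (py - cy)^2 + (pz - cz)^2) - (r0 + tt * (r1 - r0))
    d <- max(d, 0)
    if (d < best) best <- d
  }
  best
}

brute_count_near <- function(puncta, filament, threshold = 2.5) {
  sum(vapply(seq_len(nrow(puncta)), function(i) {
    brute_surface_distance(puncta$x[i], puncta$y[i], puncta$z[i], filament)
  }, numeric(1)) <= threshold)
}

# Rotation matrix about an axis (Rodrigues form) for rigid-invariance tests.
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

apply_rigid <- function(xyz, R, shift) {
  out <- as.matrix(xyz) %*% t(R)
  sweep(out, 2, shift, "+")
}

# Noiseless analytic Ogden curve on a uniform stretch grid.
make_ogden_curve <- function(mu, alpha, n = 100, lo = 0.85, hi = 1,
                             cycle = NA_integer_, phase = "averaged") {
  lam <- seq(lo, hi, length.out = n)
  hyperelastic_curve(lam, ogden_stress(lam, ogden_parameters(mu, alpha)),
                     cycle = cycle, phase = phase)
}
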