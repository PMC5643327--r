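# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Brute-force layer-line oracle: axial-frequency peak of the helical
# structure factor |sum_j exp(i(2 pi Z z_j - n phi_j))| for an ideal
# helix of `n_sub` points, searched on a coarse grid over the first
# axial-frequency period and refined locally.  Returns the signed peak Z
# and the fine grid spacing.
oracle_layer_line <- function(rise, twist, n, n_sub = 2000L,
                              coarse = 2e-4, fine = 1e-6) {
  j <- 0:(n_sub - 1L)
  z <- j * rise
  phi <- j * twist * pi / 180
  power <- function(Z) {
    vapply(Z, function(zz) {
      Mod(sum(exp(1i * (2 * pi * zz * z - n * phi))))
    }, numeric(1))
  }
  half <- 1 / (2 * rise)
  zg <- seq(-half, half, by = coarse)
  p <- power(zg)
  z0 <- zg[which.max(p)]
  zf <- seq(z0 - 2 * coarse, z0 + 2 * coarse, by = fine)
  pf <- power(zf)
  list(Z = zf[which.max(pf)], spacing = fine)
}

# uniform random proper rotation (QR of a Gaussian matrix, det corrected)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# analytic buried area of two equal spheres under the delta-SASA/2
# convention: each solvent sphere (radius rs = r + probe) loses a cap of
# height rs - d/2; buried = (2 caps)/2 = one cap = 2 pi rs (rs - d/2)
cap_buried_area <- function(r, d, probe = 1.4) {
  rs <- r + probe
  if (d >= 2 * rs) return(0)
  2 * pi * rs * (rs - d / 2)
}

# nine published straight-filament symmetries, used across suites
table1 <- flagsym::filament_symmetry_table()
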