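## Shared test utilities: tiny fixtures and independent oracles.

## Exhaustive nearest-neighbour reference for the cell labelling: all-pairs
## distances, minimum-image in-plane, first minimum wins (lowest index).
brute_force_occupants <- function(px, py, grid, box = NULL) {
  cc <- cell_centers(grid)
  occ <- matrix(NA_integer_, grid$bins[1], grid$bins[2])
  for (i in seq_len(grid$bins[1])) for (j in seq_len(grid$bins[2])) {
    dx <- cc$x[i] - px
    dy <- cc$y[j] - py
    if (!is.null(box)) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
    }
    occ[i, j] <- which.min(dx * dx + dy * dy)
  }
  occ
}

## Random saturated three-carbon conformer with fixed bond length and a
## non-degenerate bond angle, in arbitrary orientation.
random_conformer <- function(bond = 0.153) {
  ci <- stats::rnorm(3)
  u1 <- stats::rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
  repeat {
    u2 <- stats::rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    if (abs(sum(u1 * u2)) < 0.9) break
  }
  list(c_prev = ci + bond * u1, c_i = ci, c_next = ci + bond * u2)
}

## Random planar cis double-bond fragment (C_(i-1), C_i, C_(i+1), C_(i+2))
## with interior angles phi1, phi2, embedded in a random 3D plane.
random_cis_fragment <- function(phi1 = stats::runif(1, 100, 140) * pi / 180,
                                phi2 = stats::runif(1, 100, 140) * pi / 180) {
  e1 <- stats::rnorm(3); e1 <- e1 / sqrt(sum(e1^2))
  tmp <- stats::rnorm(3)
  e2 <- tmp - sum(tmp * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  pt <- function(x, y) x * e1 + y * e2
  b <- 0.134
  ci <- pt(0, 0)
  ci1 <- pt(b, 0)
  list(c_prev = ci + 0.153 * pt(cos(phi1), sin(phi1)),
       c_i = ci, c_i1 = ci1,
       c_next2 = ci1 + 0.153 * pt(cos(pi - phi2), sin(pi - phi2)),
       phi1 = phi1, phi2 = phi2)
}

## Rotation matrix about the z axis.
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

## Minimal single-frame membrane with explicit coordinates for hand-built
## geometry tests.
tiny_frame <- function(coords, box = c(10, 10, 10), names = NULL, resid = NULL) {
  membrane_frame(coords, box = box, atom_names = names, residue_ids = resid)
}
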