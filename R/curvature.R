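#' Leaflet height field
#'
#' Collects each grid cell's occupant coordinate along the bilayer normal
#' into a surface S(x, y), the Monge-patch representation all curvature
#' computations operate on.  `height_field()` reads the coordinate from a
#' `cell_assignment`; `height_field_from_function()` samples an analytic
#' surface at the cell centres (used with the synthetic fixtures).
#'
#' @param assignment a `cell_assignment`.
#' @param leaflet tag stored on the field (`"top"` or `"bottom"`).
#' @return An object of class `height_field` with matrix `h` (nm), the
#'   `grid` and the leaflet tag.
#' @export
height_field <- function(assignment, leaflet = "top") {
  structure(list(h = assignment$normal_coord, grid = assignment$grid,
                 leaflet = leaflet),
            class = "height_field")
}

#' @rdname height_field
#' @param f function of two vectors (x, y in nm) returning heights.
#' @param grid a [make_grid()] object.
#' @export
height_field_from_function <- function(f, grid, leaflet = "top") {
  cc <- cell_centers(grid)
  h <- outer(cc$x, cc$y, f)
  structure(list(h = h, grid = grid, leaflet = leaflet),
            class = "height_field")
}

## Finite-difference derivative matrices.  Periodic grids use central
## differences with wrap-around; breathing grids fall back to one-sided
## differences at the edges.
fd_axis <- function(h, axis, d, periodic) {
  n <- dim(h)[axis]
  if (n < 3L) stop("at least 3 bins per axis are required for derivatives")
  idx_p <- c(2:n, 1L)
  idx_m <- c(n, 1:(n - 1L))
  shift <- function(m, idx) if (axis == 1L) m[idx, , drop = FALSE]
                            else m[, idx, drop = FALSE]
  d1 <- (shift(h, idx_p) - shift(h, idx_m)) / (2 * d)
  d2 <- (shift(h, idx_p) - 2 * h + shift(h, idx_m)) / d^2
  if (!periodic) {
    # one-sided 2nd-order first derivative, standard one-sided 2nd derivative
    if (axis == 1L) {
      d1[1L, ] <- (-3 * h[1L, ] + 4 * h[2L, ] - h[3L, ]) / (2 * d)
      d1[n, ] <- (3 * h[n, ] - 4 * h[n - 1L, ] + h[n - 2L, ]) / (2 * d)
      d2[1L, ] <- (h[1L, ] - 2 * h[2L, ] + h[3L, ]) / d^2
      d2[n, ] <- (h[n, ] - 2 * h[n - 1L, ] + h[n - 2L, ]) / d^2
    } else {
      d1[, 1L] <- (-3 * h[, 1L] + 4 * h[, 2L] - h[, 3L]) / (2 * d)
      d1[, n] <- (3 * h[, n] - 4 * h[, n - 1L] + h[, n - 2L]) / (2 * d)
      d2[, 1L] <- (h[, 1L] - 2 * h[, 2L] + h[, 3L]) / d^2
      d2[, n] <- (h[, n] - 2 * h[, n - 1L] + h[, n - 2L]) / d^2
    }
  }
  list(d1 = d1, d2 = d2)
}

#' Finite-difference surface derivatives
#'
#' Central finite differences of the height field with periodic wrap-around
#' for box-mode grids; breathing grids use one-sided differences at the
#' edges (flagged in the result).  Spacings are the cell edge lengths.
#'
#' @param hf a [height_field()].
#' @return List of matrices `Sx`, `Sy`, `Sxx`, `Syy`, `Sxy` plus the grid
#'   and a `periodic` flag.
#' @export
surface_derivatives <- function(hf) {
  g <- hf$grid
  d <- g$lengths / g$bins
  per <- isTRUE(g$periodic)
  ax <- fd_axis(hf$h, 1L, d[1], per)
  ay <- fd_axis(hf$h, 2L, d[2], per)
  sxy <- fd_axis(ax$d1, 2L, d[2], per)$d1
  list(Sx = ax$d1, Sy = ay$d1, Sxx = ax$d2, Syy = ay$d2, Sxy = sxy,
       grid = g, periodic = per)
}

#' Fundamental forms of the leaflet surface
#'
#' Treating the surface as the Monge patch (x, y, h(x, y)), the tangent
#' vectors are S_x = (1, 0, h_x) and S_y = (0, 1, h_y), giving the first
#' fundamental form E = S_x . S_x, F = S_x . S_y, G = S_y . S_y.  The unit
#' normal is N = (S_x x S_y) / |S_x x S_y| and the second fundamental form
#' is L = S_xx . N, M = S_xy . N, N2 = S_yy . N with second-derivative
#' vectors (0, 0, h_xx) etc.
#'
#' @param deriv output of [surface_derivatives()].
#' @param orientation `+1` keeps the normal pointing along the + normal
#'   axis, `-1` flips it (used for the bottom leaflet so both leaflets of a
#'   bent membrane report a consistent curvature sign).
#' @return List of per-cell matrices `E`, `F`, `G`, `L`, `M`, `N2` and the
#'   normal z-component `Nz`.
#' @export
fundamental_forms <- function(deriv, orientation = 1) {
  hx <- deriv$Sx; hy <- deriv$Sy
  E <- 1 + hx^2
  F_ <- hx * hy
  G <- 1 + hy^2
  # S_x x S_y = (-h_x, -h_y, 1); norm = sqrt(EG - F^2) >= 1
  nrm <- sqrt(E * G - F_^2)
  s <- sign(orientation)
  L <- s * deriv$Sxx / nrm
  M <- s * deriv$Sxy / nrm
  N2 <- s * deriv$Syy / nrm
  list(E = E, F = F_, G = G, L = L, M = M, N2 = N2, Nz = s / nrm)
}

#' Mean and Gaussian curvature from the fundamental forms
#'
#' J = (E N + G L - 2 F M) / (2 (E G - F^2)) and
#' K = (L N - M^2) / (E G - F^2), the standard combinations of the first
#' and second fundamental forms for the principal curvatures kappa_1,2:
#' J = (kappa_1 + kappa_2) / 2, K = kappa_1 kappa_2, so J^2 >= K
#' everywhere.
#'
#' @param forms output of [fundamental_forms()].
#' @return An object of class `curvature_field` with matrices `J` (nm^-1)
#'   and `K` (nm^-2) plus the forms.
#' @export
curvatures <- function(forms) {
  den <- forms$E * forms$G - forms$F^2
  J <- (forms$E * forms$N2 + forms$G * forms$L - 2 * forms$F * forms$M) /
       (2 * den)
  K <- (forms$L * forms$N2 - forms$M^2) / den
  structure(c(list(J = J, K = K), forms), class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("curvature_field: %d x %d cells, J in [%.4g, %.4g] nm^-1, K in [%.4g, %.4g] nm^-2\n",
              nrow(x$J), ncol(x$J), min(x$J), max(x$J), min(x$K), max(x$K)))
  invisible(x)
}

## Signed mode indices of an n-point DFT, in fft output order.
dft_modes <- function(n) {
  k <- 0:(n - 1L)
  ifelse(k <= n %/% 2, k, k - n)
}

#' Ideal Fourier band filter of a height field
#'
#' Transforms the height field to Fourier space, keeps only the modes
#' inside the band (brick-wall filter), and transforms back.  Bands can be
#' given as fractions of the available modes (`r_low`, `r_high` in
#' \[0, 1\], radial index r(m, n) = sqrt((m/m_max)^2 + (n/n_max)^2)/sqrt(2)
#' over signed mode indices) or as absolute wave vectors (`q_low`,
#' `q_high` in nm^-1, converted to per-axis mode counts m_q = q L_x / 2 pi,
#' n_q = q L_y / 2 pi, defining an elliptical band).  The DC mode is kept
#' only when the lower edge of the band is exactly 0.
#'
#' @param hf a [height_field()] on a periodic (box-mode) grid.
#' @param r_low,r_high fractional band edges, or
#' @param q_low,q_high absolute band edges in nm^-1 (mutually exclusive
#'   with the fractional style).
#' @return A filtered `height_field`.
#' @export
spectral_filter <- function(hf, r_low = NULL, r_high = NULL,
                            q_low = NULL, q_high = NULL) {
  g <- hf$grid
  if (!isTRUE(g$periodic))
    stop("spectral filtering requires a periodic (box-mode) grid")
  frac <- !is.null(r_low) || !is.null(r_high)
  absq <- !is.null(q_low) || !is.null(q_high)
  if (frac && absq)
    stop("specify either a fractional (r) or an absolute (q) band, not both")
  if (!frac && !absq)
    stop("no filter band given")
  nx <- g$bins[1]; ny <- g$bins[2]
  mx <- dft_modes(nx); my <- dft_modes(ny)
  if (frac) {
    if (is.null(r_low)) r_low <- 0
    if (is.null(r_high)) r_high <- 1
    if (r_low > r_high) stop("r_low must be <= r_high")
    mmax <- max(abs(mx)); nmax <- max(abs(my))
    r <- sqrt(outer((mx / mmax)^2, (my / nmax)^2, "+") / 2)
    keep <- r >= r_low & r <= r_high
    if (r_low > 0) keep[1, 1] <- FALSE
  } else {
    if (is.null(q_low)) q_low <- 0
    if (is.null(q_high)) q_high <- Inf
    if (q_low > q_high) stop("q_low must be <= q_high")
    # mode (m, n) carries wave vector 2 pi sqrt((m/Lx)^2 + (n/Ly)^2)
    qmode <- 2 * pi * sqrt(outer((mx / g$lengths[1])^2,
                                 (my / g$lengths[2])^2, "+"))
    keep <- qmode >= q_low & qmode <= q_high
    if (q_low > 0) keep[1, 1] <- FALSE
    nondc <- keep
    nondc[1, 1] <- FALSE
    if (!any(nondc))
      warning("band selects no non-DC mode; output is the DC plane or zero")
  }
  H <- stats::fft(hf$h)
  H[!keep] <- 0
  out <- stats::fft(H, inverse = TRUE) / length(H)
  res <- max(abs(Im(out)))
  if (res > 1e-8) warning("large imaginary residue after inverse FFT: ", res)
  hf$h <- Re(out)
  hf
}

#' Curvature of a leaflet, optionally band-filtered
#'
#' Convenience pipeline: apply an ideal Fourier band filter to the height
#' field (when a band is given), then compute derivatives, fundamental
#' forms and the mean/Gaussian curvature fields.
#'
#' @param hf a [height_field()].
#' @param r_low,r_high,q_low,q_high optional band, see [spectral_filter()].
#' @param orientation normal orientation, see [fundamental_forms()].
#' @return A `curvature_field`.
#' @export
membrane_curvature <- function(hf, r_low = NULL, r_high = NULL,
                               q_low = NULL, q_high = NULL,
                               orientation = if (identical(hf$leaflet, "bottom")) -1 else 1) {
  if (!is.null(r_low) || !is.null(r_high) || !is.null(q_low) || !is.null(q_high))
    hf <- spectral_filter(hf, r_low, r_high, q_low, q_high)
  curvatures(fundamental_forms(surface_derivatives(hf), orientation))
}
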