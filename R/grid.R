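## In-plane axes complementary to the bilayer normal.
plane_axes <- function(normal_axis) setdiff(1:3, normal_axis)

## Minimum-image displacement along one axis of box length L.
min_image <- function(dx, L) dx - L * round(dx / L)

#' Per-lipid reference points
#'
#' Computes the (mass-weighted) centre of mass of each lipid's representative
#' atom group, by default the head-group selection.  These points stand in
#' for the lipid in leaflet assignment and in the nearest-lipid competition
#' for grid cells.
#'
#' @param frame a [membrane_frame()].
#' @param sel a [make_selections()] object.
#' @param atoms which selection to average over: `"heads"` (default),
#'   `"lipids"` or `"tails"`.
#' @param mass `"name"` to weight by element masses inferred from atom
#'   names, `"unit"` for unweighted averages.
#' @return Numeric matrix, n_lipids x 3 (nm).
#' @export
lipid_reference_points <- function(frame, sel, atoms = c("heads", "lipids", "tails"),
                                   mass = c("name", "unit")) {
  atoms <- match.arg(atoms)
  mass <- match.arg(mass)
  lists <- sel[[atoms]]
  if (is.null(lists)) stop("selection has no '", atoms, "' atom lists")
  pts <- t(vapply(lists, function(ix) {
    if (!length(ix)) stop("empty reference atom group for a lipid")
    w <- if (mass == "unit") rep(1, length(ix)) else atom_masses(frame$atom_names[ix])
    tw <- sum(w)
    if (tw <= 0) stop("lipid reference group has zero total mass")
    colSums(frame$coords[ix, , drop = FALSE] * w) / tw
  }, numeric(3)))
  pts
}

#' Assign lipids to leaflets
#'
#' `mean_plane` labels a lipid `top` when its reference point lies above the
#' mean reference coordinate along the bilayer normal.  `tail_vector` labels
#' a lipid `top` when the vector from its tail-atom centre of mass to its
#' reference point has a positive component along the normal; this is robust
#' for undulating membranes where a top-leaflet lipid can dip below the
#' global mean plane.
#'
#' @param points reference points from [lipid_reference_points()].
#' @param frame a [membrane_frame()].
#' @param sel a [make_selections()] object.
#' @param method `"mean_plane"` (default) or `"tail_vector"`.
#' @param mass passed to the tail centre-of-mass computation.
#' @return Character vector of `"top"`/`"bottom"`, one per lipid, class
#'   `leaflet_assignment`.
#' @export
assign_leaflets <- function(points, frame, sel,
                            method = c("mean_plane", "tail_vector"),
                            mass = c("name", "unit")) {
  method <- match.arg(method)
  ax <- sel$normal_axis
  z <- points[, ax]
  if (method == "mean_plane") {
    lab <- ifelse(z > mean(z), "top", "bottom")
  } else {
    if (is.null(sel$tails))
      stop("tail_vector leaflet assignment requires tail atom selections")
    tails <- lipid_reference_points(frame, sel, atoms = "tails", mass = mass)
    lab <- ifelse(z - tails[, ax] > 0, "top", "bottom")
  }
  structure(lab, class = "leaflet_assignment")
}

#' Define the analysis grid
#'
#' `box` mode spans the frame's in-plane box lengths with the origin at 0;
#' `breathing` mode spans the min/max in-plane reference-point coordinates of
#' the frame, following the outermost lipids.
#'
#' @param frame a [membrane_frame()] (box mode reads its box lengths).
#' @param points reference points (needed for breathing mode).
#' @param mode `"box"` or `"breathing"`.
#' @param bins integer bins per in-plane axis; a single value is used for
#'   both axes.
#' @param normal_axis bilayer normal axis index (1, 2 or 3).
#' @param fallback_box box lengths to use when `frame$box` is `NULL`
#'   (typically the first frame's box).
#' @return An object of class `grid_spec` with fields `origin`, `lengths`,
#'   `bins`, `axes` (the two in-plane axis indices), `normal_axis` and
#'   `periodic`.
#' @export
make_grid <- function(frame, points = NULL, mode = c("box", "breathing"),
                      bins = 100L, normal_axis = 3L, fallback_box = NULL) {
  mode <- match.arg(mode)
  bins <- as.integer(bins)
  if (length(bins) == 1L) bins <- c(bins, bins)
  if (any(bins < 2L)) stop("at least 2 bins per axis are required")
  axes <- plane_axes(normal_axis)
  if (mode == "box") {
    box <- frame$box
    if (is.null(box)) box <- fallback_box
    if (is.null(box)) stop("box-mode grid requires box dimensions")
    origin <- c(0, 0)
    lengths <- box[axes]
  } else {
    if (is.null(points)) stop("breathing grid requires reference points")
    origin <- apply(points[, axes, drop = FALSE], 2, min)
    lengths <- apply(points[, axes, drop = FALSE], 2, max) - origin
  }
  if (any(lengths <= 0))
    stop("degenerate grid extent (all lipids collinear in-plane?)")
  structure(list(origin = as.numeric(origin), lengths = as.numeric(lengths),
                 bins = bins, axes = axes, normal_axis = as.integer(normal_axis),
                 periodic = (mode == "box")),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d bins over %.4g x %.4g nm (%s), cell area %.4g nm^2\n",
              x$bins[1], x$bins[2], x$lengths[1], x$lengths[2],
              if (x$periodic) "periodic box" else "breathing", cell_area(x)))
  invisible(x)
}

#' Grid cell geometry
#'
#' `cell_area()` returns the area of one grid cell in nm^2;
#' `cell_centers()` the cell-centre coordinates along each in-plane axis.
#'
#' @param grid a [make_grid()] object.
#' @return `cell_area()`: a number. `cell_centers()`: list with components
#'   `x` and `y` (lengths `bins[1]`, `bins[2]`).
#' @export
cell_area <- function(grid) prod(grid$lengths / grid$bins)

#' @rdname cell_area
#' @export
cell_centers <- function(grid) {
  d <- grid$lengths / grid$bins
  list(x = grid$origin[1] + (seq_len(grid$bins[1]) - 0.5) * d[1],
       y = grid$origin[2] + (seq_len(grid$bins[2]) - 0.5) * d[2])
}

## Nearest-competitor labelling over the whole grid.  Competitors are given
## as in-plane coordinates; ids are assigned in input order and ties go to
## the earliest competitor, so callers order lipids (ascending index) before
## protein atoms.  Distances are 2D; in box mode the two in-plane axes use
## the minimum-image convention.
nearest_competitor <- function(px, py, grid, box_lengths = NULL) {
  cc <- cell_centers(grid)
  best <- matrix(Inf, grid$bins[1], grid$bins[2])
  occ <- matrix(NA_integer_, grid$bins[1], grid$bins[2])
  use_pbc <- grid$periodic && !is.null(box_lengths)
  for (k in seq_along(px)) {
    dx <- cc$x - px[k]
    dy <- cc$y - py[k]
    if (use_pbc) {
      dx <- min_image(dx, box_lengths[1])
      dy <- min_image(dy, box_lengths[2])
    }
    d2 <- outer(dx * dx, dy * dy, "+")
    m <- d2 < best
    if (any(m)) {
      occ[m] <- k
      best[m] <- d2[m]
    }
  }
  occ
}

#' Label grid cells with their nearest lipid
#'
#' Every cell of one leaflet's grid is labelled with the lipid whose in-plane
#' reference point is closest to the cell centre (2D Euclidean distance,
#' minimum-image in box mode).  Distance ties are broken towards the lowest
#' lipid index so output is deterministic.
#'
#' @param points reference points of all lipids (n_lipids x 3, nm).
#' @param grid a [make_grid()] object.
#' @param frame the [membrane_frame()] providing box lengths for periodic
#'   distances.
#' @param lipid_ids integer indices (into `points` rows) of the lipids of
#'   this leaflet.
#' @return An object of class `cell_assignment`: `occupant` (integer matrix,
#'   positive lipid index, negative protein competitor), `normal_coord`
#'   (matrix of the occupant's coordinate along the normal, nm), plus the
#'   grid.
#' @export
map_to_cells <- function(points, grid, frame, lipid_ids = seq_len(nrow(points))) {
  if (!length(lipid_ids)) stop("at least one lipid per leaflet is required")
  ax <- grid$axes
  pts <- points[lipid_ids, , drop = FALSE]
  occ <- nearest_competitor(pts[, ax[1]], pts[, ax[2]], grid,
                            box_lengths = frame$box[ax])
  occupant <- matrix(lipid_ids[occ], grid$bins[1], grid$bins[2])
  zc <- matrix(points[, grid$normal_axis][occupant],
               grid$bins[1], grid$bins[2])
  structure(list(occupant = occupant, normal_coord = zc, grid = grid),
            class = "cell_assignment")
}

#' @export
print.cell_assignment <- function(x, ...) {
  np <- sum(x$occupant < 0)
  cat(sprintf("cell_assignment: %d x %d cells, %d occupants%s\n",
              nrow(x$occupant), ncol(x$occupant),
              length(unique(as.vector(x$occupant))),
              if (np) sprintf(" (%d protein cells)", np) else ""))
  invisible(x)
}

#' Protein atoms eligible for the grid competition
#'
#' A protein atom competes for a leaflet's grid cells only when, among that
#' leaflet's lipids whose in-plane (minimum-image) distance to the atom is
#' within `precision_radius`, at least one lies above and at least one lies
#' beneath the atom along the bilayer normal.  This "precision" criterion
#' keeps solvent-exposed protein atoms off the membrane grid.
#'
#' @param frame a [membrane_frame()].
#' @param sel selections with a protein group.
#' @param points lipid reference points.
#' @param leaflets a [assign_leaflets()] vector.
#' @param precision_radius in-plane cutoff in nm (> 0).
#' @return List with integer atom-index vectors `top` and `bottom`.
#' @export
include_protein <- function(frame, sel, points, leaflets, precision_radius) {
  if (is.null(sel$protein)) stop("no protein atoms selected")
  if (precision_radius <= 0) stop("precision_radius must be > 0")
  ax <- plane_axes(sel$normal_axis)
  nx <- sel$normal_axis
  box <- frame$box
  eligible <- function(leaf) {
    lip <- which(leaflets == leaf)
    if (!length(lip)) return(integer(0))
    lz <- points[lip, nx]
    keep <- vapply(sel$protein, function(a) {
      dx <- points[lip, ax[1]] - frame$coords[a, ax[1]]
      dy <- points[lip, ax[2]] - frame$coords[a, ax[2]]
      if (!is.null(box)) {
        dx <- min_image(dx, box[ax[1]])
        dy <- min_image(dy, box[ax[2]])
      }
      near <- dx * dx + dy * dy <= precision_radius^2
      any(near & lz > frame$coords[a, nx]) && any(near & lz < frame$coords[a, nx])
    }, logical(1))
    sel$protein[keep]
  }
  list(top = eligible("top"), bottom = eligible("bottom"))
}

#' Label grid cells with their nearest lipid or protein atom
#'
#' As [map_to_cells()], but eligible protein atoms compete for cells under
#' the same nearest-distance criterion.  Protein-occupied cells carry a
#' negative occupant code (`-atom_index`) and the winning atom's coordinate
#' along the normal; protein atoms lose distance ties to lipids.
#'
#' @inheritParams map_to_cells
#' @param protein_atoms integer indices of eligible protein atoms for this
#'   leaflet (e.g. from [include_protein()]).
#' @return A `cell_assignment`; see [map_to_cells()].
#' @export
map_with_protein <- function(points, protein_atoms, grid, frame,
                             lipid_ids = seq_len(nrow(points))) {
  if (!length(protein_atoms))
    return(map_to_cells(points, grid, frame, lipid_ids))
  ax <- grid$axes
  lp <- points[lipid_ids, , drop = FALSE]
  pp <- frame$coords[protein_atoms, , drop = FALSE]
  px <- c(lp[, ax[1]], pp[, ax[1]])
  py <- c(lp[, ax[2]], pp[, ax[2]])
  occ <- nearest_competitor(px, py, grid, box_lengths = frame$box[ax])
  nl <- length(lipid_ids)
  codes <- c(lipid_ids, -protein_atoms)
  occupant <- matrix(codes[occ], grid$bins[1], grid$bins[2])
  zsrc <- c(points[, grid$normal_axis][lipid_ids],
            frame$coords[protein_atoms, grid$normal_axis])
  zc <- matrix(zsrc[occ], grid$bins[1], grid$bins[2])
  structure(list(occupant = occupant, normal_coord = zc, grid = grid),
            class = "cell_assignment")
}
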