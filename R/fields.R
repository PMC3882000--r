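#' Per-cell membrane thickness for one frame
#'
#' For each grid cell the thickness is the difference between the top- and
#' bottom-leaflet occupant coordinates along the bilayer normal.  When both
#' occupants are protein atoms the thickness is a user-specified value; when
#' exactly one occupant is protein the plain coordinate difference is scaled
#' by `scaling_value`, which smooths regions transiently occupied by
#' flexible parts of a protein.
#'
#' @param top,bottom `cell_assignment` objects of the two leaflets on the
#'   same grid.
#' @param protein_value thickness (nm) reported for protein/protein cells.
#' @param scaling_value factor in (0, 1] applied to mixed lipid/protein
#'   cells.
#' @return List with matrices `values` (nm) and `case` (`"ll"`, `"pp"`,
#'   `"lp"`).
#' @export
thickness_frame <- function(top, bottom, protein_value = 0, scaling_value = 1) {
  if (!identical(top$grid$bins, bottom$grid$bins) ||
      !isTRUE(all.equal(top$grid$lengths, bottom$grid$lengths)))
    stop("top and bottom assignments are on different grids")
  if (protein_value < 0) stop("protein_value must be >= 0")
  if (scaling_value <= 0 || scaling_value > 1)
    stop("scaling_value must be in (0, 1]")
  diffs <- top$normal_coord - bottom$normal_coord
  tp <- top$occupant < 0
  bp <- bottom$occupant < 0
  values <- diffs
  case <- matrix("ll", nrow(diffs), ncol(diffs))
  both <- tp & bp
  mixed <- xor(tp, bp)
  values[both] <- protein_value
  case[both] <- "pp"
  values[mixed] <- scaling_value * diffs[mixed]
  case[mixed] <- "lp"
  list(values = values, case = case)
}

#' Per-lipid and protein areas for one frame and leaflet
#'
#' The area of a lipid is the number of grid cells it occupies times the
#' cell area; the protein area is the analogous sum over protein-occupied
#' cells.  Areas are exactly conservative: lipid areas plus protein area
#' equal the grid area.
#'
#' @param assignment a `cell_assignment`.
#' @param lipid_ids integer ids of the leaflet's lipids; lipids occupying
#'   zero cells are reported with area 0.
#' @return List with `lipid_areas` (named numeric, nm^2), `protein_area`
#'   (nm^2) and `cell_area`.
#' @export
apl_frame <- function(assignment, lipid_ids = NULL) {
  a <- cell_area(assignment$grid)
  occ <- as.vector(assignment$occupant)
  lip <- occ[occ > 0]
  if (is.null(lipid_ids)) lipid_ids <- sort(unique(lip))
  counts <- tabulate(match(lip, lipid_ids), nbins = length(lipid_ids))
  areas <- counts * a
  names(areas) <- as.character(lipid_ids)
  list(lipid_areas = areas, protein_area = sum(occ < 0) * a, cell_area = a)
}

#' Accumulate per-frame cell values into a time-averaged field
#'
#' Averages per-cell values over the frames in which the cell actually held
#' a lipid: protein-occupied (or otherwise masked) frames are excluded
#' per cell, so cells transiently covered by a protein average only their
#' lipid frames.  Cells with no contributing frame carry `NaN`.
#'
#' @param frames list of numeric matrices (one per frame, equal dims).
#' @param exclude optional list of logical matrices marking cells to exclude
#'   in the corresponding frame (e.g. protein-occupied cells).
#' @param sd_type `"population"` (divide by N, default) or `"sample"`
#'   (N - 1).
#' @param property_tag,leaflet metadata stored on the result.
#' @return An object of class `property_field` with matrices `mean`, `std`,
#'   `count`.
#' @export
accumulate_fields <- function(frames, exclude = NULL,
                              sd_type = c("population", "sample"),
                              property_tag = "property", leaflet = "both") {
  sd_type <- match.arg(sd_type)
  if (!length(frames)) stop("at least one frame is required")
  dims <- dim(frames[[1L]])
  s <- matrix(0, dims[1], dims[2])
  s2 <- matrix(0, dims[1], dims[2])
  n <- matrix(0L, dims[1], dims[2])
  for (k in seq_along(frames)) {
    v <- frames[[k]]
    if (!identical(dim(v), dims)) stop("frame ", k, " has mismatched dimensions")
    use <- is.finite(v)
    if (!is.null(exclude)) use <- use & !exclude[[k]]
    s[use] <- s[use] + v[use]
    s2[use] <- s2[use] + v[use]^2
    n[use] <- n[use] + 1L
  }
  mean_ <- ifelse(n > 0, s / n, NaN)
  var_ <- ifelse(n > 0, pmax(s2 / n - mean_^2, 0), NaN)
  if (sd_type == "sample")
    var_ <- ifelse(n > 1, var_ * n / (n - 1L), ifelse(n == 1, 0, NaN))
  structure(list(mean = mean_, std = sqrt(var_), count = n,
                 property_tag = property_tag, leaflet = leaflet),
            class = "property_field")
}

#' @export
print.property_field <- function(x, ...) {
  cat(sprintf("property_field '%s' (%s leaflet): %d x %d cells, frames per cell %d..%d\n",
              x$property_tag, x$leaflet, nrow(x$mean), ncol(x$mean),
              min(x$count), max(x$count)))
  invisible(x)
}

#' Area-per-lipid time traces
#'
#' Collects per-lipid areas over frames and derives per-frame mean, min and
#' max over the leaflet's lipids plus the protein area, the per-frame trace
#' format used for convergence monitoring.
#'
#' @param assignments list of `cell_assignment` objects (one per frame,
#'   same leaflet).
#' @param times numeric frame times (ps).
#' @param lipid_ids lipids belonging to this leaflet.
#' @return List with `summary` (data.frame: time, mean, min, max,
#'   protein_area) and `per_lipid` (matrix frames x lipids, nm^2).
#' @export
area_traces <- function(assignments, times = seq_along(assignments) - 1,
                        lipid_ids = NULL) {
  if (!length(assignments)) stop("at least one frame is required")
  if (is.null(lipid_ids)) {
    occ <- as.vector(assignments[[1L]]$occupant)
    lipid_ids <- sort(unique(occ[occ > 0]))
  }
  per <- t(vapply(assignments, function(a)
    apl_frame(a, lipid_ids)$lipid_areas, numeric(length(lipid_ids))))
  prot <- vapply(assignments, function(a) apl_frame(a, lipid_ids)$protein_area,
                 numeric(1))
  present <- per > 0
  mean_ <- rowSums(per) / pmax(rowSums(present), 1L)
  list(summary = data.frame(time = times,
                            mean = mean_,
                            min = apply(ifelse(present, per, Inf), 1, min),
                            max = apply(per, 1, max),
                            protein_area = prot),
       per_lipid = per)
}
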