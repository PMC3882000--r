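#' Grid assignments for a frame sequence
#'
#' Runs the per-frame front end shared by all analyses: reference points,
#' leaflet assignment, grid construction, protein eligibility (when a
#' precision radius is given and protein atoms are selected) and the
#' nearest-occupant cell labelling of both leaflets.
#'
#' @param frames list of [membrane_frame()] objects.
#' @param sel a [make_selections()] object.
#' @param bins bins per in-plane axis.
#' @param mode grid mode, `"box"` or `"breathing"`.
#' @param precision optional protein precision radius (nm).
#' @param leaflet_method passed to [assign_leaflets()].
#' @param freeze_leaflets reuse the first frame's leaflet assignment for all
#'   frames (guards against spurious flips); default recomputes per frame.
#' @param mass centre-of-mass weighting, see [lipid_reference_points()].
#' @return List (one element per frame) of lists with `top`, `bottom`
#'   (`cell_assignment`s), `points`, `leaflets`, `grid`, `top_ids`,
#'   `bottom_ids`.
#' @export
map_frames <- function(frames, sel, bins = 100L, mode = "box",
                       precision = NULL, leaflet_method = "mean_plane",
                       freeze_leaflets = FALSE, mass = "name") {
  fallback <- frames[[1L]]$box
  frozen <- NULL
  lapply(frames, function(fr) {
    pts <- lipid_reference_points(fr, sel, mass = mass)
    leaf <- if (freeze_leaflets && !is.null(frozen)) frozen
            else assign_leaflets(pts, fr, sel, method = leaflet_method, mass = mass)
    if (freeze_leaflets && is.null(frozen)) frozen <<- leaf
    grid <- make_grid(fr, pts, mode = mode, bins = bins,
                      normal_axis = sel$normal_axis, fallback_box = fallback)
    top_ids <- which(leaf == "top")
    bottom_ids <- which(leaf == "bottom")
    if (!is.null(precision) && !is.null(sel$protein)) {
      elig <- include_protein(fr, sel, pts, leaf, precision)
      top <- map_with_protein(pts, elig$top, grid, fr, top_ids)
      bottom <- map_with_protein(pts, elig$bottom, grid, fr, bottom_ids)
    } else {
      top <- map_to_cells(pts, grid, fr, top_ids)
      bottom <- map_to_cells(pts, grid, fr, bottom_ids)
    }
    list(top = top, bottom = bottom, points = pts, leaflets = leaf,
         grid = grid, top_ids = top_ids, bottom_ids = bottom_ids)
  })
}

#' Local membrane thickness over a trajectory
#'
#' @inheritParams map_frames
#' @param protein_value,scaling_value see [thickness_frame()].
#' @param ... passed to [map_frames()].
#' @return List with the time-averaged `field` (a `property_field`), the
#'   per-frame value matrices `per_frame`, the `maps` from [map_frames()]
#'   and the mean occupant coordinates `normal_coords` per leaflet.
#' @export
analyze_thickness <- function(frames, sel, bins = 100L,
                              protein_value = 0, scaling_value = 1, ...) {
  maps <- map_frames(frames, sel, bins = bins, ...)
  per <- lapply(maps, function(m)
    thickness_frame(m$top, m$bottom, protein_value, scaling_value))
  vals <- lapply(per, `[[`, "values")
  excl <- lapply(per, function(p) p$case == "pp")
  field <- accumulate_fields(vals, exclude = excl, property_tag = "thickness")
  field <- attach_grid(field, maps[[1L]]$grid)
  nc <- list(top = Reduce(`+`, lapply(maps, function(m) m$top$normal_coord)) / length(maps),
             bottom = Reduce(`+`, lapply(maps, function(m) m$bottom$normal_coord)) / length(maps))
  list(field = field, per_frame = vals, maps = maps, normal_coords = nc)
}

#' Local area per lipid over a trajectory
#'
#' @inheritParams map_frames
#' @param ... passed to [map_frames()].
#' @return List with per-leaflet time-averaged APL `fields` (cell value =
#'   area of the cell's occupant lipid), per-leaflet [area_traces()]
#'   `traces`, and the `maps`.
#' @export
analyze_apl <- function(frames, sel, bins = 100L, ...) {
  maps <- map_frames(frames, sel, bins = bins, ...)
  times <- vapply(frames, function(fr) fr$time, numeric(1))
  one_leaflet <- function(leaf) {
    assigns <- lapply(maps, `[[`, leaf)
    per <- lapply(assigns, function(a) {
      ap <- apl_frame(a)
      lut <- ap$lipid_areas
      occ <- a$occupant
      v <- matrix(NA_real_, nrow(occ), ncol(occ))
      lip <- occ > 0
      v[lip] <- lut[as.character(occ[lip])]
      v
    })
    excl <- lapply(assigns, function(a) a$occupant < 0)
    field <- accumulate_fields(per, exclude = excl, property_tag = "apl",
                               leaflet = leaf)
    field <- attach_grid(field, maps[[1L]]$grid)
    list(field = field,
         traces = area_traces(assigns, times,
                              lipid_ids = maps[[1L]][[paste0(leaf, "_ids")]]))
  }
  res <- list(top = one_leaflet("top"), bottom = one_leaflet("bottom"))
  list(fields = list(top = res$top$field, bottom = res$bottom$field),
       traces = list(top = res$top$traces, bottom = res$bottom$traces),
       maps = maps)
}

#' Grid-mapped deuterium order parameters over a trajectory
#'
#' @inheritParams map_frames
#' @param chain,carbon chain name and carbon position to map.
#' @param protein_fill value for protein-occupied cells.
#' @param ... passed to [map_frames()].
#' @return List with per-leaflet `fields`, the per-frame `records` and the
#'   [per_lipid_report()] `report`.
#' @export
analyze_order <- function(frames, sel, bins = 100L, chain = "sn1",
                          carbon = 7L, protein_fill = 0, ...) {
  maps <- map_frames(frames, sel, bins = bins, ...)
  records <- chain_scd_frames(frames, sel)
  fields <- lapply(c(top = "top", bottom = "bottom"), function(leaf) {
    fld <- map_scd_to_grid(records, lapply(maps, `[[`, leaf), chain, carbon,
                           protein_fill = protein_fill, leaflet = leaf)
    attach_grid(fld, maps[[1L]]$grid)
  })
  # per-cell mean coordinate of the mapped carbon along the normal, for the
  # grid PDB output (the pseudo-atom sits at the carbon's average depth)
  carbon_z <- lapply(c(top = "top", bottom = "bottom"), function(leaf) {
    per <- lapply(seq_along(frames), function(k) {
      lut <- vapply(sel$chains[[chain]], function(idx)
        frames[[k]]$coords[idx[carbon], sel$normal_axis], numeric(1))
      occ <- maps[[k]][[leaf]]$occupant
      v <- matrix(NA_real_, nrow(occ), ncol(occ))
      v[occ > 0] <- lut[occ[occ > 0]]
      v
    })
    zf <- accumulate_fields(per)$mean
    zf[!is.finite(zf)] <- 0
    zf
  })
  list(fields = fields, carbon_z = carbon_z, records = records,
       report = per_lipid_report(records))
}

#' Leaflet curvature over a trajectory
#'
#' Builds each leaflet's height field per frame, optionally band-filters
#' it, computes mean and Gaussian curvature and averages over frames.
#'
#' @inheritParams map_frames
#' @param r_low,r_high,q_low,q_high optional filter band
#'   (see [spectral_filter()]).
#' @param ... passed to [map_frames()].
#' @return List with per-leaflet `J` and `K` `property_field`s and the
#'   per-frame `curvature_field`s.
#' @export
analyze_curvature <- function(frames, sel, bins = 100L,
                              r_low = NULL, r_high = NULL,
                              q_low = NULL, q_high = NULL, ...) {
  maps <- map_frames(frames, sel, bins = bins, ...)
  per <- lapply(c(top = "top", bottom = "bottom"), function(leaf) {
    lapply(maps, function(m)
      membrane_curvature(height_field(m[[leaf]], leaflet = leaf),
                         r_low, r_high, q_low, q_high))
  })
  fld <- function(leaf, what) {
    f <- accumulate_fields(lapply(per[[leaf]], `[[`, what),
                           property_tag = paste0("curvature_", tolower(what)),
                           leaflet = leaf)
    attach_grid(f, maps[[1L]]$grid)
  }
  list(J = list(top = fld("top", "J"), bottom = fld("bottom", "J")),
       K = list(top = fld("top", "K"), bottom = fld("bottom", "K")),
       per_frame = per)
}
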