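#' Write a property field as a B-factor annotated PDB grid
#'
#' Emits one pseudo-atom per grid cell: the in-plane cell-centre coordinates
#' plus the time-averaged coordinate of the cell's occupants along the
#' normal, with the property value in the B-factor column.  Leaflets are
#' encoded as chain identifiers (top = A, bottom = B).  Coordinates are
#' written in angstrom; property values are clamped to the B-factor column
#' range \[-9.99, 999.99\], with clamping noted in a REMARK.
#'
#' @param fields named list of `property_field`s (names `top`/`bottom`), or
#'   a single field.
#' @param normal_coords matching list of matrices of mean occupant
#'   coordinates along the normal (nm), e.g. a time-mean of
#'   `assignment$normal_coord`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_pdb <- function(fields, normal_coords, path) {
  if (inherits(fields, "property_field")) {
    fields <- list(top = fields)
    normal_coords <- list(top = normal_coords)
  }
  con <- file(path, "w")
  on.exit(close(con))
  chains <- c(top = "A", bottom = "B")
  clamped <- FALSE
  for (leaf in names(fields)) {
    v <- fields[[leaf]]$mean
    if (any(is.finite(v) & (v < -9.99 | v > 999.99))) clamped <- TRUE
  }
  writeLines("REMARK   grid-mapped membrane property; B-factor = property value", con)
  if (clamped)
    writeLines("REMARK   some values exceeded [-9.99, 999.99] and were clamped", con)
  serial <- 0L
  for (leaf in names(fields)) {
    fld <- fields[[leaf]]
    cc_ <- fld$cell_centers
    if (is.null(cc_)) stop("field lacks cell centre coordinates; see attach_grid()")
    z <- normal_coords[[leaf]]
    v <- fld$mean
    v[!is.finite(v)] <- 0
    v <- pmin(pmax(v, -9.99), 999.99)
    for (j in seq_along(cc_$y)) for (i in seq_along(cc_$x)) {
      serial <- serial + 1L
      writeLines(sprintf("ATOM  %5d  C   GRD %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                         serial %% 100000L, chains[[leaf]],
                         ((serial - 1L) %% 9999L) + 1L,
                         cc_$x[i] * 10, cc_$y[j] * 10, z[i, j] * 10,
                         1.0, v[i, j]), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Attach grid geometry to a property field
#'
#' Stores the cell-centre coordinates on a field so [write_grid_pdb()] can
#' place its pseudo-atoms.
#'
#' @param field a `property_field`.
#' @param grid the [make_grid()] the field was computed on.
#' @return The field with a `cell_centers` component.
#' @export
attach_grid <- function(field, grid) {
  field$cell_centers <- cell_centers(grid)
  field
}

#' Read back a grid PDB written by [write_grid_pdb()]
#'
#' Strict fixed-column parse; used for round-trip validation.
#'
#' @param path PDB path.
#' @return data.frame with columns `chain`, `x`, `y`, `z` (nm) and `b`.
#' @export
read_grid_pdb <- function(path) {
  lines <- grep("^ATOM  ", readLines(path), value = TRUE)
  data.frame(chain = substr(lines, 22, 22),
             x = as.numeric(substr(lines, 31, 38)) / 10,
             y = as.numeric(substr(lines, 39, 46)) / 10,
             z = as.numeric(substr(lines, 47, 54)) / 10,
             b = as.numeric(substr(lines, 61, 66)))
}

#' Write a field matrix as plain text
#'
#' One row per y-bin, one column per x-bin, `%10.5f` formatting, `nan` for
#' cells with no contributing frame.  Bottom-leaflet matrices are mirrored
#' across the y axis (x column order reversed) so that the two leaflets
#' overlay in the same view.
#'
#' @param m numeric matrix indexed `[x_bin, y_bin]`, or a `property_field`
#'   (its `mean` is written).
#' @param path output path.
#' @param leaflet `"top"` (as-is) or `"bottom"` (mirrored).
#' @return `path`, invisibly.
#' @export
write_matrix_field <- function(m, path, leaflet = c("top", "bottom")) {
  leaflet <- match.arg(leaflet)
  if (inherits(m, "property_field")) m <- m$mean
  out <- t(m)                               # rows = y bins
  if (leaflet == "bottom") out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  out[abs(out) < 5e-6] <- 0                 # avoid "-0.00000" at %.5f
  txt <- apply(out, 1, function(row)
    paste(ifelse(is.finite(row), sprintf("%10.5f", row), sprintf("%10s", "nan")),
          collapse = " "))
  writeLines(txt, path)
  invisible(path)
}

#' Read a plain-text field matrix
#'
#' @param path file from [write_matrix_field()].
#' @param leaflet undo the bottom-leaflet mirroring when `"bottom"`.
#' @return Numeric matrix indexed `[x_bin, y_bin]` (NaN for `nan` cells).
#' @export
read_matrix_field <- function(path, leaflet = c("top", "bottom")) {
  leaflet <- match.arg(leaflet)
  rows <- lapply(strsplit(trimws(readLines(path)), "\\s+"), as.numeric)
  out <- do.call(rbind, rows)
  if (leaflet == "bottom") out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  t(out)
}

#' Running average of a series
#'
#' Centred moving average of window `w`; at the series ends the window is
#' truncated to the available frames (no padding).  Elements may be numbers
#' or matrices of equal dimension.
#'
#' @param series numeric vector or list of matrices.
#' @param window integer window length, `1 <= window <= length(series)`.
#' @return Object of the same shape as `series`.
#' @export
running_average <- function(series, window = 1L) {
  window <- as.integer(window)
  n <- if (is.list(series)) length(series) else length(series)
  if (window < 1L) stop("window must be >= 1")
  if (window > n) stop("window (", window, ") exceeds number of frames (", n, ")")
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  pick <- function(t) max(1L, t - half_lo):min(n, t + half_hi)
  if (is.list(series)) {
    lapply(seq_len(n), function(t) Reduce(`+`, series[pick(t)]) / length(pick(t)))
  } else {
    vapply(seq_len(n), function(t) mean(series[pick(t)]), numeric(1))
  }
}

#' Write a per-frame matrix series
#'
#' Writes the running-averaged series either as one matrix file per frame
#' (`<prefix>_f<k>.dat`) or concatenated into a single multi-frame file
#' with `# frame k` separators, for kinematic visualization.
#'
#' @param series list of matrices (one per frame, `[x_bin, y_bin]`).
#' @param window running-average window, see [running_average()].
#' @param path_prefix output prefix.
#' @param leaflet mirroring as in [write_matrix_field()].
#' @param concat single concatenated file instead of one file per frame.
#' @param coord_series optional list of per-frame occupant normal-coordinate
#'   matrices; when given (with `grid`) a companion grid-coordinate PDB is
#'   written per frame for kinematic matching of matrices and positions.
#' @param grid the [make_grid()] the series lives on (for the companion
#'   PDBs).
#' @return Character vector of the file(s) written, invisibly.
#' @export
write_per_frame <- function(series, window = 1L, path_prefix,
                            leaflet = "top", concat = FALSE,
                            coord_series = NULL, grid = NULL) {
  sm <- running_average(series, window)
  if (!is.null(coord_series)) {
    if (is.null(grid)) stop("companion PDBs require the grid")
    zs <- running_average(coord_series, window)
    for (k in seq_along(sm)) {
      fld <- attach_grid(structure(list(mean = sm[[k]], std = 0 * sm[[k]],
                                        count = matrix(1L, nrow(sm[[k]]), ncol(sm[[k]])),
                                        property_tag = "per_frame",
                                        leaflet = leaflet),
                                   class = "property_field"), grid)
      write_grid_pdb(stats::setNames(list(fld), leaflet),
                     stats::setNames(list(zs[[k]]), leaflet),
                     sprintf("%s_f%d.pdb", path_prefix, k))
    }
  }
  if (concat) {
    path <- paste0(path_prefix, "_frames.dat")
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_along(sm)) {
      writeLines(sprintf("# frame %d", k), con)
      tmp <- tempfile()
      write_matrix_field(sm[[k]], tmp, leaflet)
      writeLines(readLines(tmp), con)
      unlink(tmp)
    }
    return(invisible(path))
  }
  paths <- sprintf("%s_f%d.dat", path_prefix, seq_along(sm))
  for (k in seq_along(sm)) write_matrix_field(sm[[k]], paths[k], leaflet)
  invisible(paths)
}

#' Write area-per-lipid time traces as XVG-like text
#'
#' Whitespace-separated columns: time, mean, min, max, protein area, then
#' optionally one column per lipid.
#'
#' @param traces output of [area_traces()].
#' @param path output path.
#' @param per_lipid include per-lipid columns.
#' @return `path`, invisibly.
#' @export
write_area_traces <- function(traces, path, per_lipid = FALSE) {
  s <- traces$summary
  m <- cbind(s$time, s$mean, s$min, s$max, s$protein_area)
  hdr <- "# time mean min max protein_area"
  if (per_lipid) {
    m <- cbind(m, traces$per_lipid)
    ids <- colnames(traces$per_lipid)
    if (is.null(ids)) ids <- seq_len(ncol(traces$per_lipid))
    hdr <- paste(hdr, paste0("lipid", ids, collapse = " "))
  }
  txt <- apply(m, 1, function(row) paste(sprintf("%12.5f", row), collapse = " "))
  writeLines(c(hdr, txt), path)
  invisible(path)
}
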