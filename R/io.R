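#' Construct a membrane frame
#'
#' A `membrane_frame` holds one snapshot: per-atom coordinates in nm, the
#' rectangular box lengths in nm, atom/residue identifiers and the frame time
#' in ps.  All analysis functions in the package consume this representation
#' regardless of the source file format.
#'
#' @param coords numeric matrix, n_atoms x 3, positions in nm.
#' @param box numeric length-3 vector of box lengths in nm, or `NULL` when
#'   the source carries no box information.
#' @param atom_names character vector of atom names (length n_atoms).
#' @param residue_ids integer vector of residue identifiers (length n_atoms).
#' @param time frame time in ps.
#' @return An object of class `membrane_frame`.
#' @export
membrane_frame <- function(coords, box = NULL, atom_names = NULL,
                           residue_ids = NULL, time = 0) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L)
      stop("box must have 3 lengths (rectangular box)")
    if (any(box <= 0))
      stop("box lengths must be strictly positive")
  }
  if (is.null(atom_names)) atom_names <- rep("X", n)
  if (is.null(residue_ids)) residue_ids <- rep(1L, n)
  if (length(atom_names) != n || length(residue_ids) != n)
    stop("atom_names and residue_ids must match the number of atoms")
  structure(list(coords = coords, box = box,
                 atom_names = as.character(atom_names),
                 residue_ids = as.integer(residue_ids),
                 time = as.numeric(time)),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("membrane_frame: %d atoms, t = %g ps, box = %s nm\n",
              nrow(x$coords), x$time,
              if (is.null(x$box)) "none" else paste(signif(x$box, 5), collapse = " x ")))
  invisible(x)
}

n_atoms <- function(frame) nrow(frame$coords)

## Reject triclinic cells; the grid mapping assumes an axis-aligned rectangle.
check_rectangular <- function(offdiag, where) {
  if (any(abs(offdiag) > 1e-6))
    stop("triclinic box in ", where,
         ": only rectangular boxes are supported")
}

#' Read a GRO structure file
#'
#' Reads all frames of a (possibly multi-frame) Gromacs GRO file.
#' Coordinates in GRO files are already in nm.  Frame times are taken from
#' a `t= <ps>` tag on the title line when present, otherwise the 0-based
#' frame index is used.
#'
#' @param path path to a `.gro` file.
#' @return A list of [membrane_frame()] objects.
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("cannot read GRO file: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("malformed GRO file (bad atom count): ", path)
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    resid <- as.integer(substr(atom_lines, 1L, 5L))
    aname <- trimws(substr(atom_lines, 11L, 15L))
    x <- as.numeric(substr(atom_lines, 21L, 28L))
    y <- as.numeric(substr(atom_lines, 29L, 36L))
    z <- as.numeric(substr(atom_lines, 37L, 44L))
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])
    if (length(boxline) >= 9L) check_rectangular(boxline[4:9], path)
    box <- boxline[1:3]
    tm <- length(frames)
    m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m))
    frames[[length(frames) + 1L]] <-
      membrane_frame(cbind(x, y, z), box = box, atom_names = aname,
                     residue_ids = resid, time = tm)
    i <- i + 3L + nat
  }
  if (!length(frames)) stop("no frames found in GRO file: ", path)
  frames
}

## Parse the CRYST1 record of a PDB file; NULL if absent.  Lengths nm.
pdb_box <- function(path) {
  lines <- readLines(path, n = 500L)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  a <- as.numeric(substr(cl[1], 7, 15))
  b <- as.numeric(substr(cl[1], 16, 24))
  c <- as.numeric(substr(cl[1], 25, 33))
  ang <- c(as.numeric(substr(cl[1], 34, 40)),
           as.numeric(substr(cl[1], 41, 47)),
           as.numeric(substr(cl[1], 48, 54)))
  check_rectangular(ang - 90, path)
  if (any(is.na(c(a, b, c))) || all(c(a, b, c) == 1)) return(NULL)
  c(a, b, c) / 10
}

#' Read a PDB structure (single- or multi-model) into membrane frames
#'
#' Coordinates are converted from angstrom to nm.  Multi-model files yield
#' one frame per MODEL; model times are the 0-based model index in ps
#' (PDB files carry no time stamps).
#'
#' @param path path to a `.pdb` file.
#' @return A list of [membrane_frame()] objects.
#' @export
read_pdb_frames <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  box <- pdb_box(path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nat <- ncol(xyz) / 3L
  lapply(seq_len(nrow(xyz)), function(k) {
    co <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE) / 10
    membrane_frame(co, box = box, atom_names = pdb$atom$elety[seq_len(nat)],
                   residue_ids = pdb$atom$resno[seq_len(nat)], time = k - 1)
  })
}

read_any_frames <- function(path, ref = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") return(read_gro(path))
  if (ext == "pdb") return(read_pdb_frames(path))
  if (ext == "dcd") {
    if (is.null(ref))
      stop("a DCD trajectory requires a structure file for atom identities")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    return(lapply(seq_len(nrow(xyz)), function(k) {
      co <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE) / 10
      membrane_frame(co, box = NULL, atom_names = ref$atom_names,
                     residue_ids = ref$residue_ids, time = k - 1)
    }))
  }
  stop("unreadable or unsupported format '", ext, "': ", path,
       " (supported: gro, pdb, dcd)")
}

#' Load trajectory frames
#'
#' Reads a structure file and (optionally) a trajectory, returning frames in
#' file order restricted to a time window and stride.  When the trajectory
#' frames carry no box information the structure's box (first frame) is used
#' for every frame.
#'
#' @param structure path to a PDB or GRO structure file.
#' @param trajectory optional path to a trajectory (multi-model PDB,
#'   multi-frame GRO, or DCD).  When `NULL` the structure's own frames are
#'   used.
#' @param begin,end time window in ps (inclusive).
#' @param stride keep every `stride`-th frame of the window.
#' @return A list of [membrane_frame()] objects.
#' @export
load_frames <- function(structure, trajectory = NULL,
                        begin = -Inf, end = Inf, stride = 1L) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  sframes <- read_any_frames(structure)
  ref <- sframes[[1L]]
  frames <- if (is.null(trajectory)) sframes else read_any_frames(trajectory, ref)
  ntraj <- n_atoms(frames[[1L]])
  if (ntraj != n_atoms(ref))
    stop(sprintf("atom count mismatch: structure has %d atoms, trajectory has %d",
                 n_atoms(ref), ntraj))
  if (is.null(ref$box) && is.null(frames[[1L]]$box))
    stop("neither structure nor trajectory provides box dimensions")
  fallback <- if (!is.null(frames[[1L]]$box)) frames[[1L]]$box else ref$box
  frames <- lapply(frames, function(fr) {
    if (is.null(fr$box)) fr$box <- fallback
    fr
  })
  times <- vapply(frames, function(fr) fr$time, numeric(1))
  keep <- which(times >= begin & times <= end)
  keep <- keep[seq_along(keep) %% stride == 1L | stride == 1L]
  frames[keep]
}

#' Read a Gromacs NDX index file
#'
#' Parses `[ name ]` group headers followed by whitespace-separated 1-based
#' atom indices (the Gromacs NDX dialect).
#'
#' @param path path to the `.ndx` file.
#' @return A named list of integer vectors of 1-based atom indices.
#' @export
read_ndx <- function(path) {
  if (!file.exists(path)) stop("cannot read NDX file: ", path)
  lines <- readLines(path)
  lines <- sub(";.*$", "", lines)
  hdr <- grep("^\\s*\\[.*\\]\\s*$", lines)
  if (!length(hdr)) stop("no index groups found in ", path)
  names_ <- trimws(gsub("\\[|\\]", "", lines[hdr]))
  bounds <- c(hdr, length(lines) + 1L)
  groups <- lapply(seq_along(hdr), function(k) {
    body <- lines[seq(bounds[k] + 1L, bounds[k + 1L] - 1L)]
    idx <- suppressWarnings(as.integer(unlist(strsplit(trimws(body), "\\s+"))))
    idx <- idx[!is.na(idx)]
    idx
  })
  names(groups) <- names_
  groups
}

#' Write a Gromacs NDX index file
#'
#' @param groups named list of integer vectors of 1-based atom indices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ndx <- function(groups, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(groups)) {
    writeLines(sprintf("[ %s ]", nm), con)
    idx <- groups[[nm]]
    for (s in split(idx, ceiling(seq_along(idx) / 15)))
      writeLines(paste(s, collapse = " "), con)
  }
  invisible(path)
}

## Split a 1-based atom index group into per-lipid lists, following the
## residue boundaries of the frame (default) or fixed-size blocks.
split_group <- function(idx, frame, split = "residue", block_size = NULL) {
  if (split == "residue") {
    rid <- frame$residue_ids[idx]
    unname(split(idx, factor(rid, levels = unique(rid))))
  } else {
    if (is.null(block_size) || block_size < 1L)
      stop("block splitting requires a positive block_size")
    if (length(idx) %% block_size != 0L)
      stop("group length ", length(idx),
           " is not a multiple of block_size ", block_size)
    unname(split(idx, ceiling(seq_along(idx) / block_size)))
  }
}

## Match a per-lipid split of some group onto the lipid order defined by
## the lipid group (by residue id of the first atom).
align_to_lipids <- function(sub_lists, lipid_lists, frame, what) {
  lip_res <- vapply(lipid_lists, function(ix) frame$residue_ids[ix[1L]], integer(1))
  sub_res <- vapply(sub_lists, function(ix) frame$residue_ids[ix[1L]], integer(1))
  pos <- match(lip_res, sub_res)
  if (anyNA(pos))
    stop("group '", what, "' does not cover every lipid residue")
  sub_lists[pos]
}

#' Build validated atom selections from index groups
#'
#' Turns named NDX groups into the per-lipid selection lists used by all
#' analyses: the lipid atoms, the head-group atoms representing each lipid
#' (centre-of-mass group), optional tail atoms (for the tail-vector leaflet
#' criterion), optional ordered acyl-chain carbon lists with double-bond
#' flags, and optional protein atoms.  Indices in NDX files are 1-based;
#' internally the same 1-based convention is kept (R indexing).
#'
#' @param groups named list from [read_ndx()].
#' @param frame a [membrane_frame()] used for residue boundaries and
#'   validation.
#' @param lipids,heads names of the lipid and head-group groups.
#' @param tails optional name of a tail-atom group.
#' @param chains optional character vector of chain group names (e.g.
#'   `c(sn1 = "SN1", sn2 = "SN2")`); each chain group must list carbons
#'   head-to-tail within every lipid residue.
#' @param unsat optional list (one element per chain) of integer positions
#'   `k` meaning a cis double bond between chain carbons `k` and `k + 1`.
#' @param protein optional name of a protein group.
#' @param normal bilayer normal axis, one of `"x"`, `"y"`, `"z"`.
#' @param split `"residue"` (default) or `"block"` lipid enumeration.
#' @param block_size atoms per lipid when `split = "block"`.
#' @return An object of class `selections`.
#' @export
make_selections <- function(groups, frame, lipids = "lipids", heads = lipids,
                            tails = NULL, chains = NULL, unsat = NULL,
                            protein = NULL, normal = "z",
                            split = c("residue", "block"), block_size = NULL) {
  split <- match.arg(split)
  normal_axis <- match(match.arg(normal, c("x", "y", "z")), c("x", "y", "z"))
  get_group <- function(nm) {
    if (!nm %in% names(groups))
      stop("index group '", nm, "' not found; available groups: ",
           paste(names(groups), collapse = ", "))
    g <- groups[[nm]]
    if (!length(g)) stop("index group '", nm, "' is empty")
    if (any(g < 1L | g > n_atoms(frame)))
      stop("index group '", nm, "' references atoms outside the structure")
    g
  }
  lipid_lists <- split_group(get_group(lipids), frame, split, block_size)
  all_idx <- unlist(lipid_lists)
  if (anyDuplicated(all_idx))
    stop("lipid atom lists are not disjoint")
  head_lists <- align_to_lipids(split_group(get_group(heads), frame, split, block_size),
                                lipid_lists, frame, heads)
  tail_lists <- NULL
  if (!is.null(tails))
    tail_lists <- align_to_lipids(split_group(get_group(tails), frame, split, block_size),
                                  lipid_lists, frame, tails)
  chain_lists <- NULL
  if (!is.null(chains)) {
    chain_lists <- lapply(chains, function(nm)
      align_to_lipids(split_group(get_group(nm), frame, split, block_size),
                      lipid_lists, frame, nm))
    names(chain_lists) <- if (is.null(names(chains))) chains else names(chains)
    if (!is.null(unsat) && length(unsat) != length(chain_lists))
      stop("unsat must provide one entry per chain")
  }
  prot <- if (!is.null(protein)) get_group(protein) else NULL
  structure(list(lipids = lipid_lists, heads = head_lists, tails = tail_lists,
                 chains = chain_lists, unsat = unsat, protein = prot,
                 normal_axis = normal_axis),
            class = "selections")
}

#' @export
print.selections <- function(x, ...) {
  cat(sprintf("selections: %d lipids, normal axis %s%s%s%s\n",
              length(x$lipids), c("x", "y", "z")[x$normal_axis],
              if (!is.null(x$tails)) ", tails" else "",
              if (!is.null(x$chains)) sprintf(", %d chains", length(x$chains)) else "",
              if (!is.null(x$protein)) sprintf(", %d protein atoms", length(x$protein)) else ""))
  invisible(x)
}

n_lipids <- function(sel) length(sel$lipids)

## Atomic masses for COM weighting, keyed on the leading element letter of
## the atom name.  United-atom chain beads (C) dominate; unknown names get
## carbon mass.  Unit weighting is available everywhere via mass = "unit".
atom_masses <- function(names_) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06)
  el <- toupper(substr(gsub("^[0-9]+", "", names_), 1L, 1L))
  m <- tab[el]
  m[is.na(m)] <- 12.011
  unname(m)
}
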