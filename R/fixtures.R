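## Geometric acyl-chain builder.  A chain is a planar zigzag of fixed bond
## length: saturated carbons turn alternately by +/- (180 - 109.47) degrees,
## a cis double bond turns twice by +60 degrees (120-degree sp2 angles,
## flanking carbons on the same side of the bond).  The chain plane is
## spanned by the chain axis (leaflet-inward, optionally tilted) and a
## horizontal azimuth direction.
chain_2d <- function(n_carbons, bond = 0.153, double_bond = NULL) {
  sat <- (180 - 2 * asin(sqrt(2 / 3)) * 180 / pi)  # 70.53 deg zigzag turn
  theta <- 0
  sign_ <- 1
  dirs <- matrix(0, n_carbons - 1L, 2L)
  ang <- 0
  for (k in seq_len(n_carbons - 1L)) {
    if (k == 1L) {
      ang <- sat / 2 * sign_
    } else if (!is.null(double_bond) && k %in% double_bond) {
      sign_ <- -sign_
      ang <- ang + 60 * sign_          # 120-degree angle at C_k
    } else if (!is.null(double_bond) && (k - 1L) %in% double_bond) {
      ang <- ang + 60 * sign_          # same turn direction: cis kink
    } else {
      sign_ <- -sign_
      ang <- ang + sat * sign_
    }
    dirs[k, ] <- c(cos(ang * pi / 180), sin(ang * pi / 180))
  }
  pos <- rbind(c(0, 0), apply(dirs * bond, 2, cumsum))
  pos
}

## Embed a 2D chain into 3D: u = chain axis (unit), v = in-plane zigzag
## direction (unit, orthogonal to u).
embed_chain <- function(chain2d, origin, u, v) {
  t(origin + t(chain2d[, 1, drop = FALSE] %*% t(u) +
               chain2d[, 2, drop = FALSE] %*% t(v)))
}

## Jittered lattice of n_side x n_side points over the in-plane box.
lattice_points <- function(n_side, box_xy, jitter_frac) {
  sp <- box_xy / n_side
  gx <- (seq_len(n_side) - 0.5) * sp[1]
  gy <- (seq_len(n_side) - 0.5) * sp[2]
  pts <- cbind(rep(gx, times = n_side), rep(gy, each = n_side))
  pts + cbind(stats::runif(nrow(pts), -jitter_frac * sp[1], jitter_frac * sp[1]),
              stats::runif(nrow(pts), -jitter_frac * sp[2], jitter_frac * sp[2]))
}

#' Generate a synthetic membrane with analytically known properties
#'
#' Builds geometric (not thermodynamic) bilayer snapshots for testing:
#' lipids on jittered lattices per leaflet, head atoms on an analytic
#' surface, united-atom acyl chains as all-trans zigzags with tetrahedral
#' backbone angles, optionally tilted with uniform random azimuth or
#' carrying one planar cis double bond.  `embedded_cylinder` adds a
#' cylindrical atom array spanning the bilayer, with an annular ring of
#' lipids hugging the cylinder surface.  The returned ground truth records
#' leaflet labels, the analytic surface, and expected thickness / S_CD /
#' curvature values.
#'
#' @param kind one of `"flat"`, `"sinusoid"`, `"sphere_cap"`,
#'   `"cylinder_patch"`, `"tilted_chains"`, `"cis_bond"`,
#'   `"embedded_cylinder"`.
#' @param box box lengths (nm); the third entry is the normal extent.
#' @param n_side lipids per lattice side per leaflet (n_side^2 lipids).
#' @param separation leaflet head-to-head distance (nm).
#' @param amplitude,n_waves sinusoid amplitude (nm) and integer mode count.
#' @param radius sphere / cylinder radius (nm); for `embedded_cylinder`,
#'   the protein radius.
#' @param tilt chain tilt from the normal (degrees, `tilted_chains`).
#' @param n_carbons carbons per acyl chain (2 chains per lipid).
#' @param double_bond position k of a cis bond between carbons k and k+1
#'   (`cis_bond` kind).
#' @param n_frames number of snapshots (lipids re-jittered each frame).
#' @param jitter in-plane lattice jitter as a fraction of the spacing;
#'   kept small so nearest-neighbour cell assignment stays unambiguous.
#' @param z_jitter head-group normal jitter (nm); 0 keeps surfaces exact.
#' @param seed RNG seed; output is deterministic for fixed spec and seed.
#' @return List with `frames` (list of [membrane_frame()]), `sel`
#'   (selections), `groups` (NDX-style index groups) and `ground_truth`.
#' @export
make_membrane <- function(kind = c("flat", "sinusoid", "sphere_cap",
                                   "cylinder_patch", "tilted_chains",
                                   "cis_bond", "embedded_cylinder"),
                          box = c(5.3, 5.3, 8), n_side = 7L,
                          separation = 3.6, amplitude = 0.5, n_waves = 1L,
                          radius = 20, tilt = 0, n_carbons = 14L,
                          double_bond = 9L, n_frames = 1L,
                          jitter = 0.1, z_jitter = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "embedded_cylinder" && radius >= min(box[1:2]) / 2)
    stop("cylinder radius must be smaller than half the box")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  zmid <- box[3] / 2
  surf <- switch(kind,
    sinusoid = function(x, y) amplitude * sin(2 * pi * n_waves * x / box[1]),
    sphere_cap = {
      cx <- box[1] / 2; cy <- box[2] / 2
      rmax2 <- (box[1]^2 + box[2]^2) / 4
      if (radius^2 <= rmax2) stop("sphere radius too small for the box")
      function(x, y) sqrt(radius^2 - (x - cx)^2 - (y - cy)^2) - radius
    },
    cylinder_patch = {
      cx <- box[1] / 2
      if (radius^2 <= (box[1] / 2)^2) stop("cylinder radius too small for the box")
      function(x, y) sqrt(radius^2 - (x - cx)^2) - radius
    },
    function(x, y) 0 * x)
  surf_top <- function(x, y) zmid + separation / 2 + surf(x, y)
  surf_bot <- function(x, y) zmid - separation / 2 + surf(x, y)

  prot_radius <- if (kind == "embedded_cylinder") radius else NULL
  db <- if (kind == "cis_bond") double_bond else NULL
  tilt_rad <- if (kind == "tilted_chains") tilt * pi / 180 else 0
  n_chain_atoms <- 2L * n_carbons
  atoms_per_lipid <- 1L + n_chain_atoms

  ## in-plane lipid sites for one leaflet (frame-independent part)
  leaflet_sites <- function() {
    if (kind == "embedded_cylinder") {
      ring_r <- prot_radius + 0.2
      n_ring <- max(8L, round(2 * pi * ring_r / 0.8))
      # full-circle random rotation: annular lipids diffuse around the
      # protein, so every ring lipid samples all azimuths over time
      ph <- (seq_len(n_ring) - 1) / n_ring * 2 * pi + stats::runif(1, 0, 2 * pi)
      ring <- cbind(box[1] / 2 + ring_r * cos(ph), box[2] / 2 + ring_r * sin(ph))
      # exclusion decided on the unjittered lattice so the lipid count is
      # identical in every frame; jitter applied to the kept sites only
      sp <- box[1:2] / n_side
      gx <- (seq_len(n_side) - 0.5) * sp[1]
      gy <- (seq_len(n_side) - 0.5) * sp[2]
      lat <- cbind(rep(gx, times = n_side), rep(gy, each = n_side))
      d2 <- (lat[, 1] - box[1] / 2)^2 + (lat[, 2] - box[2] / 2)^2
      lat <- lat[d2 > (ring_r + 0.6)^2, , drop = FALSE]
      lat <- lat + cbind(stats::runif(nrow(lat), -jitter * sp[1], jitter * sp[1]),
                         stats::runif(nrow(lat), -jitter * sp[2], jitter * sp[2]))
      rbind(ring, lat)
    } else {
      lattice_points(n_side, box[1:2], jitter)
    }
  }

  build_frame <- function(t_ps) {
    coords <- list(); anames <- list(); resids <- list()
    leaf_label <- character(0)
    res <- 0L
    for (leaf in c("top", "bottom")) {
      sgn <- if (leaf == "top") 1 else -1
      sites <- leaflet_sites()
      nl <- nrow(sites)
      leaf_label <- c(leaf_label, rep(leaf, nl))
      sfun <- if (leaf == "top") surf_top else surf_bot
      for (i in seq_len(nl)) {
        res <- res + 1L
        hx <- sites[i, 1]; hy <- sites[i, 2]
        hz <- sfun(hx, hy) + if (z_jitter > 0) stats::runif(1, -z_jitter, z_jitter) else 0
        head <- c(hx, hy, hz)
        azim <- stats::runif(1, 0, 2 * pi)
        # chain axis: leaflet-inward, tilted from the normal by tilt_rad
        u <- c(sin(tilt_rad) * cos(azim), sin(tilt_rad) * sin(azim),
               -sgn * cos(tilt_rad))
        # zigzag plane spins uniformly about the chain axis (chains rotate
        # about their director), giving the classic axially averaged S_CD
        w1 <- c(-sin(azim), cos(azim), 0)
        w2 <- cross3(u, w1)
        spin <- stats::runif(1, 0, 2 * pi)
        v <- cos(spin) * w1 + sin(spin) * w2
        c2d <- chain_2d(n_carbons, double_bond = db)
        lipid_xyz <- head
        for (ch in 1:2) {
          off <- head + (ch - 1.5) * 0.25 * c(cos(azim), sin(azim), 0) +
            u * 0.25
          lipid_xyz <- rbind(lipid_xyz, embed_chain(c2d, off, u, v))
        }
        coords[[length(coords) + 1L]] <- lipid_xyz
        anames[[length(anames) + 1L]] <-
          c("P8", paste0("C", seq_len(n_carbons)), paste0("D", seq_len(n_carbons)))
        resids[[length(resids) + 1L]] <- rep(res, atoms_per_lipid)
      }
    }
    n_lip <- res
    prot_idx <- NULL
    if (kind == "embedded_cylinder") {
      # rings every 0.2 nm, including one exactly at each leaflet plane
      zs <- seq(zmid - separation / 2 - 0.2, zmid + separation / 2 + 0.2, by = 0.2)
      rr <- seq(0, prot_radius - 0.2, by = 0.25)
      pts <- do.call(rbind, lapply(rr, function(r) {
        if (r == 0) return(cbind(box[1] / 2, box[2] / 2))
        np <- max(6L, round(2 * pi * r / 0.25))
        ph <- (seq_len(np) - 1) / np * 2 * pi
        cbind(box[1] / 2 + r * cos(ph), box[2] / 2 + r * sin(ph))
      }))
      prot <- do.call(rbind, lapply(zs, function(z) cbind(pts, z)))
      res <- res + 1L
      coords[[length(coords) + 1L]] <- prot
      anames[[length(anames) + 1L]] <- rep("CA", nrow(prot))
      resids[[length(resids) + 1L]] <- rep(res, nrow(prot))
    }
    co <- do.call(rbind, coords)
    fr <- membrane_frame(co, box = box,
                         atom_names = unlist(anames),
                         residue_ids = unlist(resids), time = t_ps)
    list(frame = fr, n_lipids = n_lip, leaflet = leaf_label)
  }

  built <- lapply(seq_len(n_frames) - 1, build_frame)
  frames <- lapply(built, `[[`, "frame")
  n_lip <- built[[1L]]$n_lipids
  leaf_label <- built[[1L]]$leaflet

  lipid_starts <- (seq_len(n_lip) - 1L) * atoms_per_lipid
  lipid_groups <- lapply(lipid_starts, function(s) s + seq_len(atoms_per_lipid))
  head_groups <- lapply(lipid_starts, function(s) s + 1L)
  tail_groups <- lapply(lipid_starts, function(s)
    s + 1L + c(n_carbons, n_chain_atoms))       # last carbon of each chain
  sn1 <- lapply(lipid_starts, function(s) s + 1L + seq_len(n_carbons))
  sn2 <- lapply(lipid_starts, function(s) s + 1L + n_carbons + seq_len(n_carbons))
  prot_atoms <- if (kind == "embedded_cylinder")
    (n_lip * atoms_per_lipid + 1L):n_atoms(frames[[1L]]) else NULL
  unsat <- if (!is.null(db)) list(sn1 = db, sn2 = db) else NULL

  sel <- structure(list(lipids = lipid_groups, heads = head_groups,
                        tails = tail_groups,
                        chains = list(sn1 = sn1, sn2 = sn2),
                        unsat = unsat, protein = prot_atoms,
                        normal_axis = 3L),
                   class = "selections")

  groups <- list(lipids = unlist(lipid_groups), heads = unlist(head_groups),
                 tails = unlist(tail_groups), sn1 = unlist(sn1),
                 sn2 = unlist(sn2))
  if (!is.null(prot_atoms)) groups$protein <- prot_atoms

  gt <- list(kind = kind, leaflet = leaf_label, thickness = separation,
             surface_top = surf_top, surface_bottom = surf_bot,
             box = box, zmid = zmid,
             scd_all_trans = -0.5,
             scd_tilted = -(3 * cos(tilt_rad)^2 - 1) / 4,
             curvature_J = switch(kind, sphere_cap = 1 / radius,
                                  cylinder_patch = 1 / (2 * radius), 0),
             curvature_K = switch(kind, sphere_cap = 1 / radius^2, 0),
             protein_radius = prot_radius,
             protein_area = if (!is.null(prot_radius)) pi * prot_radius^2 else NULL,
             double_bond = db, alpha = if (!is.null(db)) pi / 6 else NULL)

  list(frames = frames, sel = sel, groups = groups, ground_truth = gt)
}

#' Write membrane frames as a (multi-frame) GRO file
#'
#' @param frames a [membrane_frame()] or list of them.
#' @param path output path.
#' @param resnames optional per-atom residue names (default `LIP`).
#' @return `path`, invisibly.
#' @export
write_gro <- function(frames, path, resnames = NULL) {
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- n_atoms(fr)
    if (is.null(resnames)) resnames <- rep("LIP", n)
    writeLines(sprintf("synthetic membrane, t= %.3f", fr$time), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       fr$residue_ids %% 100000L, resnames,
                       substr(fr$atom_names, 1, 5), seq_len(n) %% 100000L,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}
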