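vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

new_molecular_frame <- function(x, y, z) {
  structure(list(x = x, y = y, z = z), class = "molecular_frame")
}

#' Molecular frame of a saturated acyl-chain carbon
#'
#' For a methylene carbon C_i with heavy-atom neighbours C_(i-1) and
#' C_(i+1), the frame's z axis points along C_(i+1) - C_(i-1), the x axis is
#' normal to the plane of the three carbons, and y = z x x completes a
#' right-handed orthonormal triad.  The two C-H (C-D) bonds of the united
#' atom lie symmetrically about the carbon plane in the x-y plane of this
#' frame, which is what makes the tensor contraction of [scd_saturated()]
#' exact for tetrahedral geometry.
#'
#' @param c_prev,c_i,c_next positions (length-3, nm) of C_(i-1), C_i,
#'   C_(i+1).
#' @return A `molecular_frame` with unit vectors `x`, `y`, `z`.
#' @export
molecular_frame_saturated <- function(c_prev, c_i, c_next) {
  zv <- c_next - c_prev
  a <- c_i - c_prev
  b <- c_next - c_i
  xv <- cross3(a, b)
  if (vnorm(xv) < 1e-10 * vnorm(a) * vnorm(b))
    stop("collinear carbon positions: molecular frame undefined")
  z <- unit(zv)
  x <- unit(xv)
  new_molecular_frame(x, cross3(z, x), z)
}

#' Molecular frame of a double-bond carbon pair
#'
#' For a cis double bond C_i=C_(i+1), the z axis is parallel to the bond,
#' the x axis is orthogonal to the local sp2 plane (computed from the heavy
#' atoms C_(i-1), C_i, C_(i+1); explicit deuteriums are not required), and
#' y = z x x.  Both deuteriums of the bond lie in the y-z plane of this
#' frame for planar sp2 geometry.
#'
#' @param c_prev,c_i,c_i1 positions (nm) of C_(i-1), C_i, C_(i+1).
#' @return A `molecular_frame`.
#' @export
molecular_frame_unsaturated <- function(c_prev, c_i, c_i1) {
  a <- c_i - c_prev
  b <- c_i1 - c_i
  xv <- cross3(a, b)
  if (vnorm(xv) < 1e-10 * vnorm(a) * vnorm(b))
    stop("collinear carbons: sp2 plane undefined")
  z <- unit(b)
  x <- unit(xv)
  new_molecular_frame(x, cross3(z, x), z)
}

## Instantaneous order tensor of one molecular frame:
## S_ij = (3 cos(theta_i) cos(theta_j) - delta_ij) / 2, theta_i the angle
## between molecular axis i and the bilayer normal.  Traceless by the
## cos^2 sum identity.
order_tensor_frame <- function(mframe, normal) {
  cosv <- c(sum(mframe$x * normal), sum(mframe$y * normal), sum(mframe$z * normal))
  (3 * tcrossprod(cosv) - diag(3)) / 2
}

#' Time-averaged order parameter tensor
#'
#' Averages the instantaneous tensor S_ij = <3 cos(theta_i) cos(theta_j) -
#' delta_ij> / 2 over a sequence of molecular frames.  theta_i is the angle
#' between molecular-frame axis i and the bilayer normal.
#'
#' @param mframes a single `molecular_frame` or a list of them (time
#'   series).
#' @param normal_axis bilayer normal: axis index (1-3) or a unit 3-vector.
#' @return 3x3 symmetric traceless matrix with attribute `n_frames`,
#'   dimnames `x`, `y`, `z`.
#' @export
order_tensor <- function(mframes, normal_axis = 3L) {
  if (inherits(mframes, "molecular_frame")) mframes <- list(mframes)
  if (!length(mframes)) stop("at least one molecular frame is required")
  normal <- if (length(normal_axis) == 3L) unit(normal_axis)
            else replace(numeric(3), as.integer(normal_axis), 1)
  S <- matrix(0, 3, 3)
  for (mf in mframes) S <- S + order_tensor_frame(mf, normal)
  S <- S / length(mframes)
  dimnames(S) <- list(c("x", "y", "z"), c("x", "y", "z"))
  attr(S, "n_frames") <- length(mframes)
  S
}

#' Deuterium order parameter of a saturated carbon
#'
#' Contracts an order tensor to the deuterium order parameter of a
#' methylene carbon, S_CD = 2/3 S_xx + 1/3 S_yy.  The only geometric
#' assumption is a tetrahedral D-C-D angle of 109.5 degrees.
#'
#' @param S 3x3 order tensor from [order_tensor()] (molecular frame from
#'   [molecular_frame_saturated()]).
#' @return S_CD (dimensionless, in \[-0.5, 1\]).
#' @export
scd_saturated <- function(S) {
  2 / 3 * S[1, 1] + 1 / 3 * S[2, 2]
}

#' Deuterium order parameters of a double-bond carbon pair
#'
#' For carbons C_i=C_(i+1) of a cis double bond, with deuteriums placed on
#' the bisectors of the actual heavy-atom angles (rather than assuming
#' fixed 120-degree geometry):
#' \deqn{S_{C_iD_1} = \cos^2\alpha_1 S_{yy} + \sin^2\alpha_1 S_{zz}
#'   - 2\cos\alpha_1 \sin\alpha_1 S_{yz}}
#' \deqn{S_{C_{i+1}D_2} = \cos^2\alpha_2 S_{yy} + \sin^2\alpha_2 S_{zz}
#'   + 2\cos\alpha_2 \sin\alpha_2 S_{yz}}
#' where `alpha1` = (pi - angle(C_(i-1), C_i, C_(i+1))) / 2 and `alpha2` =
#' (pi - angle(C_i, C_(i+1), C_(i+2))) / 2 are the bisector half-angles.
#'
#' @param S 3x3 order tensor (frame from [molecular_frame_unsaturated()]).
#' @param alpha1,alpha2 bisector half-angles in radians.
#' @return Named numeric vector `c(d1 = ..., d2 = ...)`.
#' @export
scd_unsaturated <- function(S, alpha1, alpha2) {
  c(d1 = cos(alpha1)^2 * S[2, 2] + sin(alpha1)^2 * S[3, 3] -
         2 * cos(alpha1) * sin(alpha1) * S[2, 3],
    d2 = cos(alpha2)^2 * S[2, 2] + sin(alpha2)^2 * S[3, 3] +
         2 * cos(alpha2) * sin(alpha2) * S[2, 3])
}

## Interior angle at vertex b of the triangle (a, b, c), radians.
vertex_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v))))
}

bisector_half_angle <- function(a, b, c) {
  phi <- vertex_angle(a, b, c)
  if (phi > pi - 1e-8) stop("degenerate carbon angle (180 degrees)")
  (pi - phi) / 2
}

#' Per-frame S_CD for every carbon of every chain
#'
#' Walks each lipid's acyl chains over a sequence of frames and computes the
#' instantaneous deuterium order parameter of every interior carbon.
#' Saturated carbons use [molecular_frame_saturated()] and
#' [scd_saturated()]; carbons flagged as double-bond starts (selection
#' `unsat`) use [molecular_frame_unsaturated()] and [scd_unsaturated()]
#' with bisector half-angles measured from the instantaneous heavy-atom
#' geometry.  Terminal carbons have no defined frame and are reported as
#' `NA`.
#'
#' @param frames list of [membrane_frame()] objects.
#' @param sel selections with `chains` (and optionally `unsat`).
#' @return A data.frame with columns `frame`, `lipid`, `chain`, `carbon`,
#'   `scd`.
#' @export
chain_scd_frames <- function(frames, sel) {
  if (is.null(sel$chains)) stop("selections carry no acyl-chain carbon lists")
  nrm <- replace(numeric(3), sel$normal_axis, 1)
  out <- list()
  chains <- names(sel$chains)
  for (f in seq_along(frames)) {
    co <- frames[[f]]$coords
    for (ci in seq_along(sel$chains)) {
      per_lipid <- sel$chains[[ci]]
      dbl <- if (!is.null(sel$unsat)) sel$unsat[[ci]] else integer(0)
      for (l in seq_along(per_lipid)) {
        idx <- per_lipid[[l]]
        nc <- length(idx)
        scd <- rep(NA_real_, nc)
        k <- 2L
        while (k <= nc - 1L) {
          p <- co[idx[k - 1L], ]; q <- co[idx[k], ]; r <- co[idx[k + 1L], ]
          if (k %in% dbl) {
            # double bond between carbons k and k+1
            if (k + 2L > nc)
              stop("double bond at chain end: flanking carbon missing")
            s2 <- co[idx[k + 2L], ]
            mf <- molecular_frame_unsaturated(p, q, r)
            S <- order_tensor_frame(mf, nrm)
            a1 <- bisector_half_angle(p, q, r)
            a2 <- bisector_half_angle(q, r, s2)
            v <- scd_unsaturated(S, a1, a2)
            scd[k] <- v[["d1"]]
            scd[k + 1L] <- v[["d2"]]
            k <- k + 2L
            next
          }
          mf <- molecular_frame_saturated(p, q, r)
          scd[k] <- scd_saturated(order_tensor_frame(mf, nrm))
          k <- k + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          frame = f, lipid = l, chain = chains[ci],
          carbon = seq_len(nc), scd = scd)
      }
    }
  }
  do.call(rbind, out)
}

#' Grid maps of the deuterium order parameter
#'
#' Assigns to every grid cell the instantaneous S_CD of the cell's occupant
#' lipid for one (chain, carbon) pair, per frame, then averages over the
#' frames in which the cell held a lipid.  Lipids compete for cells via
#' their reference group (not per carbon); protein cells carry
#' `protein_fill`.
#'
#' @param records data.frame from [chain_scd_frames()].
#' @param assignments list of `cell_assignment` objects, one per frame.
#' @param chain,carbon chain name and carbon position to map.
#' @param protein_fill value written to protein-occupied cells.
#' @param leaflet tag stored on the result.
#' @return A `property_field`; `mean` holds `protein_fill` where the cell
#'   was protein-occupied in every frame.
#' @export
map_scd_to_grid <- function(records, assignments, chain, carbon,
                            protein_fill = 0, leaflet = "top") {
  sub <- records[records$chain == chain & records$carbon == carbon, ]
  if (!nrow(sub)) stop("carbon ", carbon, " absent from chain '", chain, "'")
  frames <- sort(unique(sub$frame))
  if (length(assignments) != length(frames))
    stop("number of assignments does not match the number of frames")
  vals <- vector("list", length(frames))
  excl <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    sf <- sub[sub$frame == frames[k], ]
    lut <- rep(NA_real_, max(sf$lipid))
    lut[sf$lipid] <- sf$scd
    occ <- assignments[[k]]$occupant
    v <- matrix(NA_real_, nrow(occ), ncol(occ))
    lipcell <- occ > 0
    v[lipcell] <- lut[occ[lipcell]]
    vals[[k]] <- v
    excl[[k]] <- !lipcell
  }
  fld <- accumulate_fields(vals, exclude = excl, property_tag = "scd",
                           leaflet = leaflet)
  allprot <- Reduce(`&`, excl)
  fld$mean[allprot] <- protein_fill
  fld
}

#' Time-averaged order parameters per lipid
#'
#' Averages the per-frame S_CD of each (lipid, chain, carbon) over time and
#' derives the conventional per-carbon profile (mean over lipids) per
#' chain.
#'
#' @param records data.frame from [chain_scd_frames()].
#' @return List of data.frames: `per_lipid` (lipid, chain, carbon,
#'   mean_scd, n_frames) and `profile` (chain, carbon, mean_scd).
#' @export
per_lipid_report <- function(records) {
  ok <- !is.na(records$scd)
  key <- interaction(records$lipid, records$chain, records$carbon, drop = FALSE)
  agg <- stats::aggregate(scd ~ lipid + chain + carbon, data = records[ok, ],
                          FUN = mean)
  cnt <- stats::aggregate(scd ~ lipid + chain + carbon, data = records[ok, ],
                          FUN = length)
  per <- data.frame(lipid = agg$lipid, chain = agg$chain, carbon = agg$carbon,
                    mean_scd = agg$scd, n_frames = cnt$scd)
  per <- per[order(per$chain, per$lipid, per$carbon), ]
  prof <- stats::aggregate(mean_scd ~ chain + carbon, data = per, FUN = mean)
  rownames(per) <- NULL
  list(per_lipid = per, profile = prof[order(prof$chain, prof$carbon), ])
}

#' Explicit-deuterium order parameter (reference computation)
#'
#' Computes S_CD = <3 cos^2(theta_CD) - 1> / 2 directly from explicitly
#' placed deuterium directions, the definition the tensor contractions
#' reproduce.  For a saturated carbon the two deuteriums sit symmetrically
#' about the carbon plane at the tetrahedral angle; for a double-bond
#' carbon the single deuterium lies in the sp2 plane on the external
#' bisector.  Used for validation.
#'
#' @param c_prev,c_i,c_next carbon positions (nm).
#' @param normal unit bilayer normal (3-vector).
#' @param type `"saturated"` (average over both D) or `"unsaturated"`
#'   (single in-plane D; `c_next` is then the double-bond partner).
#' @return S_CD.
#' @export
scd_explicit_deuterium <- function(c_prev, c_i, c_next, normal,
                                   type = c("saturated", "unsaturated")) {
  type <- match.arg(type)
  a <- unit(c_prev - c_i)
  b <- unit(c_next - c_i)
  if (type == "unsaturated") {
    d <- -unit(a + b)              # external bisector, in the sp2 plane
    ct <- sum(d * normal)
    return((3 * ct^2 - 1) / 2)
  }
  bis <- -unit(a + b)              # in-plane external bisector
  perp <- unit(cross3(a, b))       # normal to the carbon plane
  half <- acos(-1 / 3) / 2         # half the tetrahedral D-C-D angle
  d1 <- cos(half) * bis + sin(half) * perp
  d2 <- cos(half) * bis - sin(half) * perp
  ct2 <- c(sum(d1 * normal)^2, sum(d2 * normal)^2)
  mean((3 * ct2 - 1) / 2)
}
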