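test_that("saturated molecular frames are right-handed, orthonormal and equivariant", {
  # all-trans zigzag along lab z: frame z axis is the lab z axis
  b <- 0.153; g <- asin(sqrt(2 / 3))
  cp <- c(0, 0, 0)
  ci <- b * c(sin(g), 0, cos(g))
  cn <- ci + b * c(-sin(g), 0, cos(g))
  mf <- molecular_frame_saturated(cp, ci, cn)
  expect_equal(mf$z, c(0, 0, 1))

  set.seed(31)
  for (k in 1:20) {
    conf <- random_conformer()
    f <- molecular_frame_saturated(conf$c_prev, conf$c_i, conf$c_next)
    B <- cbind(f$x, f$y, f$z)
    expect_equal(crossprod(B), diag(3), tolerance = 1e-10)
    expect_equal(det(B), 1, tolerance = 1e-10)
    # rigid rotation rotates the frame identically
    a <- stats::runif(1, 0, 2 * pi)
    R <- rot_z(a)
    f2 <- molecular_frame_saturated(as.vector(R %*% conf$c_prev),
                                    as.vector(R %*% conf$c_i),
                                    as.vector(R %*% conf$c_next))
    expect_equal(f2$x, as.vector(R %*% f$x), tolerance = 1e-10)
    expect_equal(f2$z, as.vector(R %*% f$z), tolerance = 1e-10)
  }
  expect_error(molecular_frame_saturated(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)),
               "collinear")
})

test_that("double-bond frames align z with the bond and x with the sp2 normal", {
  # planar cis bond in the lab xz plane: frame x axis is +/- lab y
  frag <- list(c_prev = c(-0.5, 0, 0.866), c_i = c(0, 0, 0),
               c_i1 = c(1, 0, 0), c_next2 = c(1.5, 0, 0.866))
  mf <- molecular_frame_unsaturated(frag$c_prev, frag$c_i, frag$c_i1)
  expect_equal(abs(mf$x), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(sum(mf$z * (frag$c_i1 - frag$c_i)) /
                 sqrt(sum((frag$c_i1 - frag$c_i)^2)), 1, tolerance = 1e-12)

  set.seed(32)
  for (k in 1:20) {
    fr <- random_cis_fragment()
    f <- molecular_frame_unsaturated(fr$c_prev, fr$c_i, fr$c_i1)
    B <- cbind(f$x, f$y, f$z)
    expect_equal(crossprod(B), diag(3), tolerance = 1e-10)
    expect_equal(det(B), 1, tolerance = 1e-10)
  }
})

test_that("order tensors are traceless with the expected limiting values", {
  # frame z parallel to the normal in every frame
  mf <- structure(list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1)),
                  class = "molecular_frame")
  S <- order_tensor(list(mf, mf), normal_axis = 3)
  expect_equal(unname(diag(S)), c(-0.5, -0.5, 1))
  expect_equal(sum(diag(S)), 0)

  # isotropic frames: S -> 0 at Monte-Carlo rate
  set.seed(33)
  n <- 4000
  mfs <- lapply(seq_len(n), function(k) {
    conf <- random_conformer()
    molecular_frame_saturated(conf$c_prev, conf$c_i, conf$c_next)
  })
  Siso <- order_tensor(mfs, 3)
  expect_lt(max(abs(Siso)), 3 / sqrt(n))

  # tracelessness is exact for every random tensor
  for (mfk in mfs[1:50])
    expect_equal(sum(diag(order_tensor(mfk, 3))), 0, tolerance = 1e-14)
})

test_that("the saturated S_CD contraction equals the explicit-deuterium computation", {
  set.seed(34)
  nrm <- c(0, 0, 1)
  errs <- vapply(1:300, function(k) {
    conf <- random_conformer()
    S <- order_tensor(molecular_frame_saturated(conf$c_prev, conf$c_i, conf$c_next), 3)
    abs(scd_saturated(S) -
        scd_explicit_deuterium(conf$c_prev, conf$c_i, conf$c_next, nrm, "saturated"))
  }, numeric(1))
  expect_lt(max(errs), 1e-6)

  # all-trans chain parallel to the normal: S_CD = -1/2 exactly
  fix <- make_membrane("flat", n_side = 3, seed = 35)
  rec <- chain_scd_frames(fix$frames, fix$sel)
  expect_true(all(rec$scd[!is.na(rec$scd)] == -0.5))
  # terminal carbons have no frame
  expect_true(all(is.na(rec$scd[rec$carbon == 1])))

  # a chain director at the magic angle with azimuthal spinning averages to 0
  magic <- acos(1 / sqrt(3)) * 180 / pi
  fixm <- make_membrane("tilted_chains", tilt = magic, n_side = 8,
                        n_frames = 6, seed = 36)
  recm <- chain_scd_frames(fixm$frames, fixm$sel)
  mid <- recm$carbon %in% 4:11 & !is.na(recm$scd)
  expect_lt(abs(mean(recm$scd[mid])), 0.01)
})

test_that("the double-bond S_CD expressions match their deuterium oracle", {
  set.seed(37)
  nrm <- c(0, 0, 1)
  errs <- vapply(1:300, function(k) {
    fr <- random_cis_fragment()
    S <- order_tensor(molecular_frame_unsaturated(fr$c_prev, fr$c_i, fr$c_i1), 3)
    v <- scd_unsaturated(S, (pi - fr$phi1) / 2, (pi - fr$phi2) / 2)
    o1 <- scd_explicit_deuterium(fr$c_prev, fr$c_i, fr$c_i1, nrm, "unsaturated")
    o2 <- scd_explicit_deuterium(fr$c_i, fr$c_i1, fr$c_next2, nrm, "unsaturated")
    max(abs(v[["d1"]] - o1), abs(v[["d2"]] - o2))
  }, numeric(1))
  expect_lt(max(errs), 1e-6)

  # exact 120-degree angles: equals the fixed 30-degree bisector form
  fr <- random_cis_fragment(phi1 = 2 * pi / 3, phi2 = 2 * pi / 3)
  S <- order_tensor(molecular_frame_unsaturated(fr$c_prev, fr$c_i, fr$c_i1), 3)
  expect_equal(scd_unsaturated(S, (pi - fr$phi1) / 2, (pi - fr$phi2) / 2),
               scd_unsaturated(S, pi / 6, pi / 6))

  # symmetric geometry with S_yz = 0: the two records coincide
  Ssym <- matrix(c(0.1, 0, 0, 0, -0.3, 0, 0, 0, 0.2), 3, 3)
  v <- scd_unsaturated(Ssym, pi / 7, pi / 7)
  expect_equal(v[["d1"]], v[["d2"]])

  expect_error(chain_scd_frames(make_membrane("flat", n_side = 2, seed = 1)$frames,
                                structure(list(chains = NULL), class = "selections")),
               "chain")
})

test_that("S_CD is invariant under rotation about the normal and stays bounded", {
  fix <- make_membrane("tilted_chains", tilt = 25, n_side = 4, seed = 38)
  rec <- chain_scd_frames(fix$frames, fix$sel)
  fr <- fix$frames[[1]]
  ctr <- c(fr$box[1] / 2, fr$box[2] / 2, 0)
  fr2 <- fr
  fr2$coords <- t(rot_z(0.7) %*% (t(fr$coords) - ctr) + ctr)
  rec2 <- chain_scd_frames(list(fr2), fix$sel)
  ok <- !is.na(rec$scd)
  expect_equal(rec2$scd[ok], rec$scd[ok], tolerance = 1e-10)
  expect_true(all(rec$scd[ok] >= -0.5 - 1e-12 & rec$scd[ok] <= 1 + 1e-12))
})

test_that("grid-mapped S_CD inherits the occupant lipid's value", {
  fix <- make_membrane("flat", n_side = 4, seed = 39)
  fr <- fix$frames[[1]]
  sel <- fix$sel
  maps <- map_frames(list(fr), sel, bins = 16)
  rec <- chain_scd_frames(list(fr), sel)

  # uniform all-trans value: field is constant -0.5
  fld <- map_scd_to_grid(rec, list(maps[[1]]$top), "sn1", 7)
  expect_true(all(fld$mean == -0.5))
  expect_true(all(fld$count == 1L))

  # two-lipid leaflet: field values match the occupancy map
  ids <- maps[[1]]$top_ids[1:2]
  two <- map_to_cells(lipid_reference_points(fr, sel), maps[[1]]$grid, fr, ids)
  rec_mod <- rec
  rec_mod$scd[rec_mod$lipid == ids[1] & rec_mod$chain == "sn1" & rec_mod$carbon == 7] <- 0.11
  rec_mod$scd[rec_mod$lipid == ids[2] & rec_mod$chain == "sn1" & rec_mod$carbon == 7] <- 0.22
  fld2 <- map_scd_to_grid(rec_mod, list(two), "sn1", 7)
  lut <- c(0.11, 0.22)[match(two$occupant, ids)]
  expect_equal(as.vector(fld2$mean), lut)

  # protein cells carry the fill value exactly
  occ <- two$occupant
  occ[1:3, 1] <- -1L
  twop <- two
  twop$occupant <- occ
  fld3 <- map_scd_to_grid(rec_mod, list(twop), "sn1", 7, protein_fill = 9.9)
  expect_true(all(fld3$mean[1:3, 1] == 9.9))
  expect_error(map_scd_to_grid(rec, list(two), "sn1", 99), "absent")
})

test_that("the order pipeline reports the mapped carbon's depth for the grid PDB", {
  fix <- make_membrane("flat", n_side = 3, seed = 42)
  res <- analyze_order(fix$frames, fix$sel, bins = 8, chain = "sn1", carbon = 7)
  fr <- fix$frames[[1]]
  top_lipids <- which(fix$ground_truth$leaflet == "top")
  z7 <- unname(fr$coords[fix$sel$chains$sn1[[top_lipids[1]]][7], 3])
  expect_equal(as.vector(res$carbon_z$top), rep(z7, 64), tolerance = 1e-10)
  expect_true(all(res$fields$top$mean == -0.5))
})

test_that("per-lipid reports average over time with the tilt closed form", {
  fix <- make_membrane("flat", n_side = 3, seed = 40)
  rec1 <- chain_scd_frames(fix$frames, fix$sel)
  rep1 <- per_lipid_report(rec1)
  expect_true(all(rep1$per_lipid$mean_scd == -0.5))

  # two frames: the mean of the per-frame values
  rec_two <- rbind(transform(rec1, frame = 1),
                   transform(rec1, frame = 2, scd = rec1$scd + 0.2))
  rep2 <- per_lipid_report(rec_two)
  expect_true(all(abs(rep2$per_lipid$mean_scd - (-0.4)) < 1e-12))
  expect_true(all(rep2$per_lipid$n_frames == 2L))

  # tilted ensemble: chain-average matches -(3 cos^2(theta) - 1)/4
  fixt <- make_membrane("tilted_chains", tilt = 30, n_side = 10,
                        n_frames = 5, seed = 41)
  rept <- per_lipid_report(chain_scd_frames(fixt$frames, fixt$sel))
  prof <- rept$profile
  mid <- prof$carbon %in% 4:11
  expect_equal(mean(prof$mean_scd[mid]), fixt$ground_truth$scd_tilted,
               tolerance = 0.02)
})
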