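test_that("lipid reference points are mass-weighted centres of mass", {
  # single atom: its own position
  fr <- tiny_frame(rbind(c(1, 2, 3)), names = "P", resid = 1L)
  sel <- structure(list(lipids = list(1L), heads = list(1L), normal_axis = 3L),
                   class = "selections")
  expect_equal(lipid_reference_points(fr, sel)[1, ], c(1, 2, 3))

  # two equal-mass atoms: midpoint
  fr2 <- tiny_frame(rbind(c(0, 0, 0), c(0, 0, 2)), names = c("C1", "C2"),
                    resid = c(1L, 1L))
  sel2 <- structure(list(lipids = list(1:2), heads = list(1:2), normal_axis = 3L),
                    class = "selections")
  expect_equal(lipid_reference_points(fr2, sel2)[1, ], c(0, 0, 1))

  # unequal masses: brute-force weighted mean over P (30.974) C (12.011) H (1.008)
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  fr3 <- tiny_frame(co, names = c("P8", "C2", "H1"), resid = rep(1L, 3))
  sel3 <- structure(list(lipids = list(1:3), heads = list(1:3), normal_axis = 3L),
                    class = "selections")
  w <- c(30.974, 12.011, 1.008)
  expect_equal(lipid_reference_points(fr3, sel3)[1, ],
               colSums(co * w) / sum(w))
  expect_equal(lipid_reference_points(fr3, sel3, mass = "unit")[1, ],
               colMeans(co))
})

test_that("flat bilayer leaflets are recovered by both assignment methods", {
  fix <- make_membrane("flat", n_side = 5, seed = 11)
  fr <- fix$frames[[1]]
  pts <- lipid_reference_points(fr, fix$sel)
  gt <- fix$ground_truth$leaflet
  expect_equal(as.character(assign_leaflets(pts, fr, fix$sel, "mean_plane")), gt)
  expect_equal(as.character(assign_leaflets(pts, fr, fix$sel, "tail_vector")), gt)
})

test_that("tail-vector assignment beats the mean plane on strong undulations", {
  # amplitude exceeding the half-separation pushes top-leaflet lipids below
  # the global mean plane
  fix <- make_membrane("sinusoid", amplitude = 1.0, separation = 1.6,
                       n_side = 9, seed = 2)
  fr <- fix$frames[[1]]
  pts <- lipid_reference_points(fr, fix$sel)
  gt <- fix$ground_truth$leaflet
  mp <- as.character(assign_leaflets(pts, fr, fix$sel, "mean_plane"))
  tv <- as.character(assign_leaflets(pts, fr, fix$sel, "tail_vector"))
  expect_gt(sum(mp != gt), 0)
  expect_identical(tv, gt)
})

test_that("a monolayer with tails pointing down is labelled all top", {
  fix <- make_membrane("flat", n_side = 4, seed = 3)
  fr <- fix$frames[[1]]
  keep <- which(fix$ground_truth$leaflet == "top")
  pts <- lipid_reference_points(fr, fix$sel)
  sel_top <- fix$sel
  sel_top$lipids <- sel_top$lipids[keep]
  sel_top$heads <- sel_top$heads[keep]
  sel_top$tails <- sel_top$tails[keep]
  pts_top <- lipid_reference_points(fr, sel_top)
  tv <- assign_leaflets(pts_top, fr, sel_top, "tail_vector")
  expect_true(all(tv == "top"))
  expect_error(assign_leaflets(pts_top, fr,
                               structure(list(lipids = sel_top$lipids,
                                              heads = sel_top$heads,
                                              tails = NULL, normal_axis = 3L),
                                         class = "selections"),
                               "tail_vector"),
               "tail")
})

test_that("grid geometry follows the box or the outermost lipids", {
  fr <- tiny_frame(rbind(c(1, 1, 1)), box = c(5.3, 5.3, 7))
  g <- make_grid(fr, bins = 100, normal_axis = 3)
  expect_equal(cell_area(g), (5.3 / 100)^2)
  expect_equal(g$origin, c(0, 0))
  expect_equal(g$lengths, c(5.3, 5.3))

  pts <- cbind(c(1, 4, 2), c(0, 6, 3), c(0, 0, 0))
  gb <- make_grid(fr, pts, mode = "breathing", bins = 10, normal_axis = 3)
  expect_equal(gb$origin, c(1, 0))
  expect_equal(gb$lengths, c(3, 6))
  expect_false(gb$periodic)

  # frame without box: the provided fallback (first frame's) box is used
  fr_nobox <- membrane_frame(rbind(c(1, 1, 1)))
  g2 <- make_grid(fr_nobox, bins = 10, normal_axis = 3, fallback_box = c(4, 5, 6))
  expect_equal(g2$lengths, c(4, 5))

  expect_error(make_grid(fr_nobox, bins = 10, normal_axis = 3), "box")
  pts_line <- cbind(c(1, 1, 1), c(0, 3, 6), c(0, 0, 0))
  expect_error(make_grid(fr, pts_line, mode = "breathing", bins = 5,
                         normal_axis = 3), "degenerate")
})

test_that("cell labelling matches symmetry cases", {
  fr <- tiny_frame(rbind(c(0, 0, 0)), box = c(4, 4, 4))
  g <- make_grid(fr, bins = 8, normal_axis = 3)

  one <- map_to_cells(rbind(c(1, 1, 2)), g, fr, 1L)
  expect_true(all(one$occupant == 1L))
  expect_true(all(one$normal_coord == 2))

  pts <- rbind(c(1, 2, 2), c(3, 2, 2))       # L/4 and 3L/4
  two <- map_to_cells(pts, g, fr, 1:2)
  expect_equal(sum(two$occupant == 1L), 32)
  expect_equal(sum(two$occupant == 2L), 32)
})

test_that("cell labelling equals the exhaustive nearest-neighbour oracle", {
  set.seed(71)
  for (rep in 1:12) {
    box <- c(stats::runif(1, 4, 8), stats::runif(1, 4, 8), 5)
    fr <- tiny_frame(rbind(c(0, 0, 0)), box = box)
    g <- make_grid(fr, bins = 50, normal_axis = 3)
    n <- 20
    pts <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                 stats::runif(n, 0, 5))
    got <- map_to_cells(pts, g, fr, seq_len(n))
    ref <- brute_force_occupants(pts[, 1], pts[, 2], g, box)
    expect_identical(got$occupant, ref)
  }
})

test_that("occupancy counts are translation-equivariant and partition the grid", {
  set.seed(72)
  box <- c(6, 6, 5)
  fr <- tiny_frame(rbind(c(0, 0, 0)), box = box)
  g <- make_grid(fr, bins = 30, normal_axis = 3)
  n <- 15
  pts <- cbind(stats::runif(n, 0, 6), stats::runif(n, 0, 6), stats::runif(n))
  base <- map_to_cells(pts, g, fr, seq_len(n))
  expect_equal(length(base$occupant), 900)
  counts <- tabulate(base$occupant, n)

  # shifting by one box lattice vector leaves per-lipid counts unchanged
  shifted <- pts
  shifted[, 1] <- shifted[, 1] + box[1]
  moved <- map_to_cells(shifted, g, fr, seq_len(n))
  expect_equal(tabulate(moved$occupant, n), counts)
})

test_that("protein eligibility needs same-leaflet lipids above and beneath", {
  fix <- make_membrane("embedded_cylinder", box = c(6.4, 6.4, 8), radius = 1.5,
                       n_side = 8, z_jitter = 0.1, seed = 13)
  fr <- fix$frames[[1]]
  sel <- fix$sel
  pts <- lipid_reference_points(fr, sel)
  leaf <- assign_leaflets(pts, fr, sel)
  elig <- include_protein(fr, sel, pts, leaf, precision_radius = 2.5)

  # direct predicate evaluation per atom as the oracle
  oracle <- function(leafname, radius) {
    lip <- which(leaf == leafname)
    keep <- vapply(sel$protein, function(a) {
      dx <- pts[lip, 1] - fr$coords[a, 1]
      dy <- pts[lip, 2] - fr$coords[a, 2]
      dx <- dx - fr$box[1] * round(dx / fr$box[1])
      dy <- dy - fr$box[2] * round(dy / fr$box[2])
      near <- dx^2 + dy^2 <= radius^2
      any(near & pts[lip, 3] > fr$coords[a, 3]) &&
        any(near & pts[lip, 3] < fr$coords[a, 3])
    }, logical(1))
    sel$protein[keep]
  }
  expect_identical(elig$top, oracle("top", 2.5))
  expect_identical(elig$bottom, oracle("bottom", 2.5))
  expect_gt(length(elig$top), 0)
  expect_gt(length(elig$bottom), 0)

  # mid-plane atoms lie below every top-leaflet lipid: never eligible
  zmid <- fix$ground_truth$zmid
  midplane <- sel$protein[abs(fr$coords[sel$protein, 3] - zmid) < 0.05]
  expect_length(intersect(elig$top, midplane), 0)
  expect_length(intersect(elig$bottom, midplane), 0)

  # infinite radius equals the all-lipid predicate
  elig_inf <- include_protein(fr, sel, pts, leaf, precision_radius = 1e6)
  expect_identical(elig_inf$top, oracle("top", 1e6))

  # an atom far above the membrane is never eligible
  fr2 <- fr
  fr2$coords <- rbind(fr$coords, c(3.2, 3.2, fr$box[3] + 5))
  fr2$atom_names <- c(fr$atom_names, "CA")
  fr2$residue_ids <- c(fr$residue_ids, max(fr$residue_ids))
  sel2 <- sel
  sel2$protein <- c(sel$protein, nrow(fr2$coords))
  elig2 <- include_protein(fr2, sel2, pts, leaf, precision_radius = 1.0)
  expect_false(nrow(fr2$coords) %in% c(elig2$top, elig2$bottom))
})

test_that("protein atoms compete like lipids and lose distance ties", {
  fr <- tiny_frame(rbind(c(2, 2, 2), c(1, 1, 3.5)), box = c(4, 4, 4))
  g <- make_grid(fr, bins = 20, normal_axis = 3)
  pts <- rbind(c(1, 1, 3.5))

  # no eligible protein atoms reduces to plain lipid mapping
  plain <- map_to_cells(pts, g, fr, 1L)
  with_none <- map_with_protein(pts, integer(0), g, fr, 1L)
  expect_identical(plain$occupant, with_none$occupant)

  # a distinct protein atom wins the cells nearer to it, per the oracle
  comp <- map_with_protein(pts, 1L, g, fr, 1L)
  ref <- brute_force_occupants(c(1, 2), c(1, 2), g, fr$box)
  expect_identical(comp$occupant, matrix(c(1L, -1L)[ref], 20, 20))
  # protein cells carry the winning atom's normal coordinate
  expect_true(all(comp$normal_coord[comp$occupant == -1L] == 2))

  # protein atom at the same point as the lipid: lipid wins every tie
  all_tie <- map_with_protein(pts, 2L, g, fr, 1L)
  expect_true(all(all_tie$occupant == 1L))
})
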