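# In-test naive oracle: triple loop over the identical placement set,
# written independently of the package's vectorized scan.
naive_census <- function(receptor, ligand, restraints, grid_spacing,
                         n_rotations, clash_dist, padding = NULL) {
  rec <- as.matrix(receptor$beads[, c("x", "y", "z")])
  lig <- as.matrix(ligand$beads[, c("x", "y", "z")])
  off0 <- sweep(lig, 2, colMeans(lig))
  nres <- if (is.null(restraints)) 0L else nrow(restraints)
  if (is.null(padding)) {
    lig_radius <- if (nrow(lig) > 1) max(sqrt(rowSums(off0^2))) else 0
    padding <- lig_radius + clash_dist +
      if (nres > 0) max(restraints$upper) else 0
  }
  grid <- placement_grid(receptor, padding, grid_spacing)
  rots <- rotation_set(n_rotations)
  anchors <- NULL
  if (nres > 0) {
    anchors <- lapply(seq_len(nres), function(k) {
      on_rec_a <- any(receptor$beads$chain == restraints$chain_a[k] &
                      receptor$beads$residue == restraints$resid_a[k])
      if (on_rec_a) {
        list(rec = which(receptor$beads$chain == restraints$chain_a[k] &
                         receptor$beads$residue == restraints$resid_a[k])[1],
             lig = which(ligand$beads$chain == restraints$chain_b[k] &
                         ligand$beads$residue == restraints$resid_b[k])[1])
      } else {
        list(rec = which(receptor$beads$chain == restraints$chain_b[k] &
                         receptor$beads$residue == restraints$resid_b[k])[1],
             lig = which(ligand$beads$chain == restraints$chain_a[k] &
                         ligand$beads$residue == restraints$resid_a[k])[1])
      }
    })
  }
  counts <- rep(0, nres + 1)
  for (rot in rots) {
    off <- off0 %*% t(rot)
    for (g in seq_len(nrow(grid))) {
      placed <- sweep(off, 2, grid[g, ], `+`)
      clash <- FALSE
      for (j in seq_len(nrow(placed)))
        for (r in seq_len(nrow(rec)))
          if (sqrt(sum((placed[j, ] - rec[r, ])^2)) < clash_dist)
            clash <- TRUE
      if (clash) next
      ns <- 0
      for (k in seq_len(nres)) {
        d <- sqrt(sum((rec[anchors[[k]]$rec, ] -
                       placed[anchors[[k]]$lig, ])^2))
        if (d >= restraints$lower[k] && d <= restraints$upper[k]) ns <- ns + 1
      }
      for (k in 0:ns) counts[k + 1] <- counts[k + 1] + 1
    }
  }
  stats::setNames(counts, as.character(0:nres))
}

tiny_receptor <- coarse_structure(
  data.frame(chain = "R", residue = 1:2, x = c(0, 3), y = 0, z = 0))
tiny_ligand <- coarse_structure(
  data.frame(chain = "L", residue = 1, x = 0, y = 0, z = 0))

test_that("scan counts equal the naive brute-force census on a tiny toy", {
  r <- distance_restraint("R", 1, "L", 1, 0, 4)
  sc <- scan_interaction_space(tiny_receptor, tiny_ligand, r,
                               grid_spacing = 2, n_rotations = 1,
                               clash_dist = 3)
  expect_lte(sc$n_placements, 1000)
  oracle <- naive_census(tiny_receptor, tiny_ligand, r, 2, 1, 3)
  expect_equal(sc$counts, oracle)
  # clash-only scan agrees too
  sc0 <- scan_interaction_space(tiny_receptor, tiny_ligand, NULL,
                                grid_spacing = 2, n_rotations = 1,
                                clash_dist = 3, padding = 6)
  oracle0 <- naive_census(tiny_receptor, tiny_ligand, NULL, 2, 1, 3,
                          padding = 6)
  expect_equal(sc0$counts, oracle0)
})

test_that("scan matches the oracle with a multi-bead ligand and rotations", {
  lig2 <- coarse_structure(
    data.frame(chain = "L", residue = 1:2, x = c(0, 2.5), y = 0, z = 0))
  r <- rbind(distance_restraint("R", 1, "L", 1, 0, 5),
             distance_restraint("R", 2, "L", 2, 2, 7))
  class(r) <- c("restraint_set", "data.frame")
  sc <- scan_interaction_space(tiny_receptor, lig2, r, grid_spacing = 3,
                               n_rotations = 6, clash_dist = 3)
  oracle <- naive_census(tiny_receptor, lig2, r, 3, 6, 3)
  expect_equal(sc$counts, oracle)
})

test_that("counts are monotone non-increasing in k on every fixture", {
  for (seed in c(3, 8)) {
    for (sc_name in c("census", "two_lobe", "symmetric")) {
      t <- gen_toy_structures(seed, sc_name)
      sc <- scan_interaction_space(t$receptor, t$ligand, t$restraints,
                                   t$params$grid_spacing,
                                   t$params$n_rotations,
                                   t$params$clash_dist)
      expect_true(all(diff(sc$counts) <= 0))
    }
  }
})

test_that("an unsatisfiable restraint yields zero consistent placements", {
  # upper bound below the minimum achievable anchor distance: the ligand
  # anchor can never get closer than the clash distance
  r <- distance_restraint("R", 1, "L", 1, 0, 1)
  sc <- scan_interaction_space(tiny_receptor, tiny_ligand, r,
                               grid_spacing = 2, n_rotations = 1,
                               clash_dist = 3)
  expect_equal(unname(sc$counts["1"]), 0)
})

test_that("rigid translation of the whole system leaves counts invariant", {
  t <- gen_toy_structures(4, "census")
  shift <- c(11.3, -7.1, 5.9)
  move <- function(s) {
    b <- s$beads
    b[, c("x", "y", "z")] <- sweep(as.matrix(b[, c("x", "y", "z")]), 2,
                                   shift, `+`)
    coarse_structure(b, s$radius)
  }
  sc1 <- scan_interaction_space(t$receptor, t$ligand, t$restraints,
                                t$params$grid_spacing, t$params$n_rotations,
                                t$params$clash_dist)
  sc2 <- scan_interaction_space(move(t$receptor), move(t$ligand),
                                t$restraints, t$params$grid_spacing,
                                t$params$n_rotations, t$params$clash_dist)
  expect_equal(sc1$counts, sc2$counts)
})

test_that("halving the grid spacing scales clash-free counts by about 8", {
  sc2 <- scan_interaction_space(tiny_receptor, tiny_ligand, NULL,
                                grid_spacing = 2, n_rotations = 1,
                                clash_dist = 3, padding = 8)
  sc1 <- scan_interaction_space(tiny_receptor, tiny_ligand, NULL,
                                grid_spacing = 1, n_rotations = 1,
                                clash_dist = 3, padding = 8)
  ratio <- unname(sc1$counts["0"] / sc2$counts["0"])
  expect_gt(ratio, 8 * 0.8)
  expect_lt(ratio, 8 * 1.2)
})

test_that("rotation sets are deterministic, unit-orthogonal, identity at n=1", {
  expect_equal(rotation_set(1), list(diag(3)))
  rs <- rotation_set(24)
  expect_identical(rs, rotation_set(24))
  for (m in rs[c(1, 12, 24)]) {
    expect_equal(t(m) %*% m, diag(3), tolerance = 1e-12)
    expect_equal(det(m), 1, tolerance = 1e-12)
  }
})

test_that("symmetric restraints give unit propensity and an empty active set", {
  t <- gen_toy_structures(5, "symmetric")
  pr <- interaction_propensity(t$receptor, t$ligand, t$restraints,
                               contact_dist = 5,
                               grid_spacing = t$params$grid_spacing,
                               n_rotations = t$params$n_rotations,
                               clash_dist = t$params$clash_dist)
  expect_equal(pr$propensity$propensity, rep(1, nrow(pr$propensity)))
  expect_equal(nrow(pr$active), 0L)
  # mean propensity over contacted residues is 1 by construction
  expect_equal(mean(pr$propensity$propensity), 1, tolerance = 1e-12)
})

test_that("a planted binding patch dominates the active set", {
  # receptor bar; restraint pins the ligand near residue 5's end, so only
  # residues at that end can be enriched above the mean
  bar <- coarse_structure(
    data.frame(chain = "R", residue = 1:5, x = seq(0, 16, by = 4),
               y = 0, z = 0))
  lig <- coarse_structure(
    data.frame(chain = "L", residue = 1, x = 0, y = 0, z = 0))
  r <- distance_restraint("R", 5, "L", 1, 0, 6)
  pr <- interaction_propensity(bar, lig, r, contact_dist = 5,
                               grid_spacing = 2, n_rotations = 1,
                               clash_dist = 3)
  expect_true(all(pr$active$residue %in% 4:5))
  expect_error(
    interaction_propensity(bar, lig,
                           distance_restraint("R", 1, "L", 1, 0, 0.5),
                           grid_spacing = 2, n_rotations = 1,
                           clash_dist = 3),
    "relax")
})

test_that("the drop curve is cumulative, monotone, and duplicate-stable", {
  t <- gen_toy_structures(3, "two_lobe")
  dc <- restraint_drop_curve(t$receptor, t$ligand, t$restraints,
                             t$params$grid_spacing, t$params$n_rotations,
                             t$params$clash_dist)
  expect_true(all(diff(dc$accessible) <= 0))
  expect_equal(dc$source, c("none", "XL", "TAIL"))
  # step 0 equals the clash-free count
  sc <- scan_interaction_space(t$receptor, t$ligand, t$restraints,
                               t$params$grid_spacing, t$params$n_rotations,
                               t$params$clash_dist)
  expect_equal(dc$accessible[1], unname(sc$counts["0"]))
  # duplicating a restraint changes nothing downstream
  dup <- rbind(t$restraints, t$restraints[1, ])
  class(dup) <- c("restraint_set", "data.frame")
  dc2 <- restraint_drop_curve(t$receptor, t$ligand, dup,
                              t$params$grid_spacing, t$params$n_rotations,
                              t$params$clash_dist)
  expect_equal(dc2$accessible[4], dc2$accessible[3])
  # empty list: clash-free count only
  dc0 <- restraint_drop_curve(t$receptor, t$ligand, NULL,
                              t$params$grid_spacing, t$params$n_rotations,
                              t$params$clash_dist, padding = 15)
  expect_equal(nrow(dc0), 1L)
})

test_that("the degron-tail restraint causes the sharpest relative drop", {
  t <- gen_toy_structures(3, "two_lobe")
  dc <- restraint_drop_curve(t$receptor, t$ligand, t$restraints,
                             t$params$grid_spacing, t$params$n_rotations,
                             t$params$clash_dist)
  rel_drop <- 1 - dc$accessible[-1] / dc$accessible[-nrow(dc)]
  expect_equal(dc$source[which.max(rel_drop) + 1L], "TAIL")
  expect_gt(rel_drop[length(rel_drop)], max(rel_drop[-length(rel_drop)]))
})
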