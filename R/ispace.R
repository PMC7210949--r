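#' Coarse bead structure
#'
#' Calpha-bead representation of a rigid body: one bead per residue with
#' chain id, residue index and coordinates in Angstrom.
#'
#' @param beads data.frame with columns `chain`, `residue`, `x`, `y`, `z`.
#' @param radius uniform bead radius in Angstrom (informational).
#' @return object of class `coarse_structure`.
#' @export
coarse_structure <- function(beads, radius = 1.9) {
  req <- c("chain", "residue", "x", "y", "z")
  if (!all(req %in% names(beads)))
    stop("beads need columns: ", paste(req, collapse = ", "))
  if (nrow(beads) < 1L) stop("need at least one bead")
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")]))))
    stop("bead coordinates must be finite")
  structure(list(beads = as.data.frame(beads), radius = radius),
            class = "coarse_structure")
}

.bead_xyz <- function(s) unname(as.matrix(s$beads[, c("x", "y", "z")]))

#' Deterministic quasi-uniform rotation set
#'
#' `n` unit quaternions from the super-Fibonacci spiral, a deterministic
#' low-discrepancy covering of SO(3). `n = 1` returns the identity so that
#' translation-only scans are exact.
#'
#' @param n number of rotations (>= 1).
#' @return list of 3x3 rotation matrices.
#' @export
rotation_set <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("need n >= 1 rotations")
  if (n == 1L) return(list(diag(3)))
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041
  lapply(seq_len(n) - 1L, function(i) {
    s <- i + 0.5
    t <- s / n
    d <- 2 * pi * s
    r <- sqrt(t); R <- sqrt(1 - t)
    alpha <- d / phi; beta <- d / psi
    q <- c(r * sin(alpha), r * cos(alpha), R * sin(beta), R * cos(beta))
    .quat_to_mat(q)
  })
}

.quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Translation grid for the interaction-space scan
#'
#' Cubic grid of candidate ligand-center positions anchored to the receptor
#' frame: axes start at the receptor bounding-box minimum minus the
#' padding, step `grid_spacing`, and extend to the maximum plus padding.
#' Anchoring to the receptor's own bounding box makes the scan invariant
#' under rigid motion of the whole system.
#'
#' @param receptor a [coarse_structure()].
#' @param padding margin in Angstrom added on every side.
#' @param grid_spacing step in Angstrom.
#' @return matrix of grid centers, one row per point.
#' @export
placement_grid <- function(receptor, padding, grid_spacing) {
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  xyz <- .bead_xyz(receptor)
  ax <- lapply(1:3, function(k) {
    lo <- min(xyz[, k]) - padding
    hi <- max(xyz[, k]) + padding
    seq(lo, lo + grid_spacing * floor((hi - lo) / grid_spacing),
        by = grid_spacing)
  })
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  g
}

# Resolve restraint anchors against the two bodies. Each restraint must have
# one endpoint on the receptor and one on the ligand.
.resolve_anchors <- function(restraints, receptor, ligand) {
  find <- function(s, chain, resid)
    which(s$beads$chain == chain & s$beads$residue == resid)[1]
  n <- nrow(restraints)
  rec_i <- integer(n); lig_i <- integer(n)
  for (i in seq_len(n)) {
    ra <- find(receptor, restraints$chain_a[i], restraints$resid_a[i])
    la <- find(ligand,   restraints$chain_a[i], restraints$resid_a[i])
    rb <- find(receptor, restraints$chain_b[i], restraints$resid_b[i])
    lb <- find(ligand,   restraints$chain_b[i], restraints$resid_b[i])
    if (!is.na(ra) && !is.na(lb)) { rec_i[i] <- ra; lig_i[i] <- lb }
    else if (!is.na(rb) && !is.na(la)) { rec_i[i] <- rb; lig_i[i] <- la }
    else stop("restraint ", i, " does not bridge receptor and ligand anchors")
  }
  list(rec = rec_i, lig = lig_i)
}

# Enumerate all placements (grid x rotations): accessibility and restraint
# satisfaction. Ligand is rotated about its bead centroid, the centroid is
# placed on each grid point.
.enumerate_placements <- function(receptor, ligand, restraints = NULL,
                                  grid_spacing = 2, n_rotations = 576,
                                  clash_dist = 3, padding = NULL) {
  rec <- .bead_xyz(receptor)
  lig <- .bead_xyz(ligand)
  cen <- colMeans(lig)
  off0 <- sweep(lig, 2, cen)
  lig_radius <- if (nrow(lig) > 1L) max(sqrt(rowSums(off0^2))) else 0
  nres <- if (is.null(restraints)) 0L else nrow(restraints)
  if (is.null(padding)) {
    padding <- lig_radius + clash_dist +
      if (nres > 0L) max(restraints$upper) else 0
  }
  grid <- placement_grid(receptor, padding, grid_spacing)
  rots <- rotation_set(n_rotations)
  anch <- if (nres > 0L) .resolve_anchors(restraints, receptor, ligand) else NULL

  n_place <- nrow(grid) * length(rots)
  accessible <- logical(n_place)
  sat <- matrix(FALSE, n_place, nres)
  idx <- 0L
  for (rot in rots) {
    off <- off0 %*% t(rot)
    # placement clash-free iff every grid center keeps distance >= clash_dist
    # from all receptor beads shifted by -off_j
    mind2 <- rep(Inf, nrow(grid))
    for (j in seq_len(nrow(off))) {
      shifted <- sweep(rec, 2, off[j, ])
      for (r in seq_len(nrow(shifted))) {
        d2 <- (grid[, 1] - shifted[r, 1])^2 + (grid[, 2] - shifted[r, 2])^2 +
              (grid[, 3] - shifted[r, 3])^2
        mind2 <- pmin(mind2, d2)
      }
    }
    acc <- mind2 >= clash_dist^2
    rows <- idx + seq_len(nrow(grid))
    accessible[rows] <- acc
    if (nres > 0L) {
      for (k in seq_len(nres)) {
        target <- rec[anch$rec[k], ] - off[anch$lig[k], ]
        d2 <- (grid[, 1] - target[1])^2 + (grid[, 2] - target[2])^2 +
              (grid[, 3] - target[3])^2
        sat[rows, k] <- d2 >= restraints$lower[k]^2 & d2 <= restraints$upper[k]^2
      }
    }
    idx <- idx + nrow(grid)
  }
  list(accessible = accessible, sat = sat, grid = grid,
       n_rotations = length(rots), grid_spacing = grid_spacing,
       n_restraints = nres)
}

#' Accessible-interaction-space scan
#'
#' Exhaustively enumerates rigid placements of a ligand body around a
#' receptor body -- ligand centers on a cubic grid over the padded receptor
#' bounding box, crossed with a deterministic quasi-uniform rotation set --
#' and counts, for each number of distance restraints `k`, the clash-free
#' placements consistent with at least `k` restraints. The shape of
#' `counts[k]` against `k` quantifies how restraints shrink the accessible
#' interaction space.
#'
#' @param receptor,ligand [coarse_structure()] bodies.
#' @param restraints a `restraint_set` (possibly empty/NULL for a
#'   clash-only scan); each restraint must bridge the two bodies.
#' @param grid_spacing grid step, Angstrom (default 2).
#' @param n_rotations rotations (default 576; 1 = translation-only).
#' @param clash_dist minimal allowed inter-body bead distance, Angstrom
#'   (default 3).
#' @param padding grid margin override, Angstrom (default: ligand radius +
#'   clash distance + the largest restraint upper bound).
#' @return object of class `scan_result`: `counts` (named vector, k = 0..N),
#'   `n_placements`, `grid_spacing`, `n_rotations`, `volume_proxy`
#'   (`counts * grid_spacing^3 / n_rotations`, an accessible-volume proxy in
#'   cubic Angstrom).
#' @export
scan_interaction_space <- function(receptor, ligand, restraints = NULL,
                                   grid_spacing = 2, n_rotations = 576,
                                   clash_dist = 3, padding = NULL) {
  if (!is.null(restraints) && nrow(restraints) == 0L) restraints <- NULL
  en <- .enumerate_placements(receptor, ligand, restraints, grid_spacing,
                              n_rotations, clash_dist, padding)
  nres <- en$n_restraints
  nsat <- if (nres > 0L) rowSums(en$sat[en$accessible, , drop = FALSE])
          else integer(sum(en$accessible))
  counts <- vapply(0:nres, function(k) sum(nsat >= k), numeric(1))
  names(counts) <- as.character(0:nres)
  structure(list(counts = counts,
                 n_placements = length(en$accessible),
                 grid_spacing = grid_spacing,
                 n_rotations = en$n_rotations,
                 volume_proxy = counts * grid_spacing^3 / en$n_rotations),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d placements (grid %.2f A x %d rotations)\n",
              x$n_placements, x$grid_spacing, x$n_rotations))
  print(x$counts)
  invisible(x)
}

#' Per-residue interaction propensity
#'
#' Over the placements consistent with all restraints, counts how often
#' each receptor residue is contacted (any ligand bead within
#' `contact_dist`), normalizes by the mean over contacted residues, and
#' returns the residues with propensity strictly greater than 1 as the
#' active set (candidate interface residues for restraint-driven docking).
#'
#' @param receptor,ligand [coarse_structure()] bodies.
#' @param restraints non-empty `restraint_set`.
#' @param contact_dist contact cutoff, Angstrom (default 5).
#' @inheritParams scan_interaction_space
#' @return list: `propensity` (data.frame chain/residue/contacts/propensity
#'   over contacted residues), `active` (data.frame subset), `n_consistent`.
#' @export
interaction_propensity <- function(receptor, ligand, restraints,
                                   contact_dist = 5, grid_spacing = 2,
                                   n_rotations = 576, clash_dist = 3,
                                   padding = NULL) {
  if (is.null(restraints) || nrow(restraints) == 0L)
    stop("propensity needs at least one restraint")
  en <- .enumerate_placements(receptor, ligand, restraints, grid_spacing,
                              n_rotations, clash_dist, padding)
  ok <- en$accessible & rowSums(en$sat) == en$n_restraints
  if (!any(ok))
    stop("no clash-free placement satisfies all restraints; relax the restraints")
  rec <- .bead_xyz(receptor)
  lig <- .bead_xyz(ligand)
  cen <- colMeans(lig)
  off0 <- sweep(lig, 2, cen)
  rots <- rotation_set(en$n_rotations)
  ng <- nrow(en$grid)
  contacts <- numeric(nrow(rec))
  n_cons <- 0L
  for (ri in seq_along(rots)) {
    rows <- (ri - 1L) * ng + seq_len(ng)
    sel <- which(ok[rows])
    if (length(sel) == 0L) next
    off <- off0 %*% t(rots[[ri]])
    for (g in sel) {
      beads <- sweep(off, 2, en$grid[g, ], `+`)
      for (r in seq_len(nrow(rec))) {
        d2 <- (beads[, 1] - rec[r, 1])^2 + (beads[, 2] - rec[r, 2])^2 +
              (beads[, 3] - rec[r, 3])^2
        if (any(d2 <= contact_dist^2)) contacts[r] <- contacts[r] + 1
      }
      n_cons <- n_cons + 1L
    }
  }
  contacted <- contacts > 0
  if (!any(contacted))
    stop("no receptor residue contacted in any consistent placement; increase contact_dist")
  prop <- rep(NA_real_, length(contacts))
  prop[contacted] <- contacts[contacted] / mean(contacts[contacted])
  out <- data.frame(chain = receptor$beads$chain,
                    residue = receptor$beads$residue,
                    contacts = contacts, propensity = prop,
                    stringsAsFactors = FALSE)
  keep <- out[contacted, , drop = FALSE]
  list(propensity = keep,
       active = keep[keep$propensity > 1, , drop = FALSE],
       n_consistent = n_cons)
}

#' Accessible complexes versus number of restraints applied
#'
#' Applies an ordered restraint list cumulatively (crosslink restraints
#' first, the degron-tail restraint last) and reports the number of
#' clash-free placements consistent with all restraints applied so far --
#' the monotone non-increasing curve whose final-step drop measures the
#' impact of the tail restraint.
#'
#' @param receptor,ligand [coarse_structure()] bodies.
#' @param restraints ordered `restraint_set`.
#' @inheritParams scan_interaction_space
#' @return data.frame: `n_restraints` (0..N), `source` of the restraint
#'   added at each step (`"none"` for step 0), `accessible` count.
#' @export
restraint_drop_curve <- function(receptor, ligand, restraints,
                                 grid_spacing = 2, n_rotations = 576,
                                 clash_dist = 3, padding = NULL) {
  if (is.null(restraints) || nrow(restraints) == 0L) {
    sc <- scan_interaction_space(receptor, ligand, NULL, grid_spacing,
                                 n_rotations, clash_dist, padding)
    return(data.frame(n_restraints = 0L, source = "none",
                      accessible = unname(sc$counts["0"])))
  }
  en <- .enumerate_placements(receptor, ligand, restraints, grid_spacing,
                              n_rotations, clash_dist, padding)
  acc <- en$accessible
  counts <- numeric(nrow(restraints) + 1L)
  counts[1] <- sum(acc)
  cur <- acc
  for (k in seq_len(nrow(restraints))) {
    cur <- cur & en$sat[, k]
    counts[k + 1L] <- sum(cur)
  }
  data.frame(n_restraints = 0:nrow(restraints),
             source = c("none", restraints$source),
             accessible = counts, stringsAsFactors = FALSE)
}
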