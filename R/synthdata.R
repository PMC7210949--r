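# Seeded generators for every pipeline stage, each with planted ground
# truth. All generators restore the caller's RNG state and are byte-stable
# under a fixed seed.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# residues that cannot create KR / VGWPP / VKV motifs by accident
.SAFE_AA <- c("A", "D", "E", "G", "N", "Q", "S", "T", "L", "F", "H", "M", "Y")

#' Generate synthetic AUX/IAA-like sequences with planted motifs
#'
#' Random sequences assembled from five modules with planted KR dipeptide,
#' core degron (VGWPP-[VI]-[RG]-x(2)-R, both the V/R and I/G variants) and
#' VKV (PB1 start) motifs at drawn positions. The background alphabet
#' excludes K, R, V, W and P so each motif occurs exactly where planted and
#' segmentation recovers the truth spans by construction. Optionally emits
#' degron-free (non-canonical) records.
#'
#' @param seed integer seed.
#' @param n_canonical,n_noncanonical record counts.
#' @param tail_range integer range the degron-tail length is drawn from
#'   (default 0:60).
#' @param dir optional output directory; writes `sequences.fasta` and
#'   `truth.json`.
#' @return list: `records` (list of [protein_record()]), `truth` (per
#'   record: spans, kr_position, tail_len, canonical), `paths` when written.
#' @export
gen_sequences <- function(seed, n_canonical = 6L, n_noncanonical = 2L,
                          tail_range = 0:60, dir = NULL) {
  .with_seed(seed, {
    records <- list(); truth <- list()
    rnd <- function(n) paste(sample(.SAFE_AA, n, replace = TRUE), collapse = "")
    for (i in seq_len(n_canonical)) {
      di_body <- sample(5:30, 1); linker_len <- sample(5:40, 1)
      tail_len <- sample(tail_range, 1); pb1_body <- sample(30:80, 1)
      degron <- paste0("VGWPP",
                       sample(c("V", "I"), 1), sample(c("R", "G"), 1),
                       rnd(2), "R")
      seqstr <- paste0(rnd(di_body), "KR", rnd(linker_len), degron,
                       rnd(tail_len), "VKV", rnd(pb1_body))
      id <- sprintf("synthIAA%02d", i)
      records[[id]] <- protein_record(id, seqstr)
      di_end <- di_body + 2L
      deg_start <- di_end + linker_len + 1L
      deg_end <- deg_start + 9L
      pb1_start <- deg_end + tail_len + 1L
      spans <- list(DI = c(1L, di_end),
                    linker = c(di_end + 1L, deg_start - 1L),
                    degron = c(deg_start, deg_end))
      if (tail_len > 0L) spans$degron_tail <- c(deg_end + 1L, pb1_start - 1L)
      spans$PB1 <- c(pb1_start, nchar(seqstr))
      truth[[id]] <- list(spans = spans, kr_position = di_body + 1L,
                          tail_len = tail_len, canonical = TRUE)
    }
    for (i in seq_len(n_noncanonical)) {
      id <- sprintf("synthNC%02d", i)
      seqstr <- paste0(rnd(sample(40:120, 1)))
      records[[id]] <- protein_record(id, seqstr)
      truth[[id]] <- list(spans = list(), kr_position = NA, tail_len = NA,
                          canonical = FALSE)
    }
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fa <- file.path(dir, "sequences.fasta")
      writeLines(unlist(lapply(records, function(r)
        c(paste0(">", r$id), r$sequence))), fa)
      tj <- file.path(dir, "truth.json")
      jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
      paths <- c(fasta = fa, truth = tj)
    }
    list(records = records, truth = truth, paths = paths)
  })
}

#' Generate a synthetic saturation binding dataset
#'
#' Counts follow the one-site total + nonspecific model with multiplicative
#' mean-one lognormal noise at the stated coefficient of variation;
#' nonspecific controls follow the linear component with the same noise.
#'
#' @param seed integer seed.
#' @param kd_nM,bmax,ns generating truth (defaults: 20 nM, 1, 5e-4 per nM).
#' @param conc concentration design, nM (default 10 log-spaced 1-2000 nM).
#' @param cv multiplicative noise CV (default 0.10).
#' @param n_rep technical replicates (default 3).
#' @param dir optional output directory; writes `binding.csv` +
#'   `truth.json`.
#' @return list: `dataset` (a [binding_dataset()]), `truth`, `paths`.
#' @export
gen_binding <- function(seed, kd_nM = 20, bmax = 1, ns = 5e-4,
                        conc = default_concentrations(), cv = 0.10,
                        n_rep = 3L, dir = NULL) {
  .with_seed(seed, {
    mu_tot <- model_total(conc, kd_nM, bmax, ns)
    mu_ns <- ns * conc
    noise <- function(n) {
      if (cv == 0) return(rep(1, n))
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    tot <- matrix(rep(mu_tot, n_rep) * noise(length(conc) * n_rep),
                  ncol = n_rep)
    nsc <- matrix(rep(mu_ns, n_rep) * noise(length(conc) * n_rep),
                  ncol = n_rep)
    ds <- binding_dataset(conc, tot, nsc,
                          meta = list(generator = "gen_binding"))
    truth <- list(kd_nM = kd_nM, bmax = bmax, ns = ns, cv = cv)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      long <- data.frame(
        ligand_nM = rep(conc, times = n_rep),
        replicate = rep(seq_len(n_rep), each = length(conc)),
        total = as.vector(tot), nonspecific = as.vector(nsc))
      csv <- file.path(dir, "binding.csv")
      utils::write.csv(long, csv, row.names = FALSE)
      tj <- file.path(dir, "truth.json")
      jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
      paths <- c(csv = csv, truth = tj)
    }
    list(dataset = ds, truth = truth, paths = paths)
  })
}

#' Generate a replicated crosslink table with planted links
#'
#' Plants reproducible true links (present in at least `min_support`
#' replicates) and spurious decoy links (present in exactly one replicate).
#' Receptor endpoints are drawn from two sequence windows emulating the two
#' crosslinker-reactive clusters; ligand endpoints sit up- and downstream
#' of a nominal degron position.
#'
#' @param seed integer seed.
#' @param n_replicates number of independent experiments (default 3).
#' @param min_support reproducibility the true links must reach (default 2).
#' @param n_true,n_decoy planted link counts.
#' @param receptor,ligand protein ids used in the table.
#' @param cluster_windows list of two `c(start, end)` receptor windows.
#' @param ligand_degron nominal degron position on the ligand.
#' @param dir optional output directory; writes `xl.csv` + `truth.json`.
#' @return list: `table` (an `xl_table`), `truth` (true/decoy pair keys and
#'   windows), `paths`.
#' @export
gen_xl_table <- function(seed, n_replicates = 3L, min_support = 2L,
                         n_true = 8L, n_decoy = 6L,
                         receptor = "TIR1", ligand = "IAA7",
                         cluster_windows = list(c(140L, 229L), c(485L, 529L)),
                         ligand_degron = 80L, dir = NULL) {
  .with_seed(seed, {
    # same canonical unordered endpoint order as load_xl_table
    pair_key <- function(pa, ra, pb, rb) {
      if (pb < pa || (pb == pa && rb < ra)) paste(pb, rb, pa, ra, sep = "|")
      else paste(pa, ra, pb, rb, sep = "|")
    }
    draw_pair <- function() {
      w <- cluster_windows[[sample(length(cluster_windows), 1)]]
      rres <- sample(w[1]:w[2], 1)
      lres <- ligand_degron + sample(c(-60:-10, 10:60), 1)
      c(rres, max(lres, 1L))
    }
    pairs <- list(); seen <- character()
    while (length(pairs) < n_true + n_decoy) {
      p <- draw_pair()
      k <- paste(p, collapse = "|")
      if (!k %in% seen) { seen <- c(seen, k); pairs[[length(pairs) + 1L]] <- p }
    }
    rows <- list()
    truth_true <- character(); truth_decoy <- character()
    reps <- paste0("rep", seq_len(n_replicates))
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      if (i <= n_true) {
        k <- sample(min_support:n_replicates, 1)
        in_reps <- sample(reps, k)
        truth_true <- c(truth_true, pair_key(receptor, p[1], ligand, p[2]))
      } else {
        in_reps <- sample(reps, 1)
        truth_decoy <- c(truth_decoy, pair_key(receptor, p[1], ligand, p[2]))
      }
      for (r in in_reps) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein1 = receptor, residue1 = p[1],
          protein2 = ligand, residue2 = p[2],
          replicate = r, score = round(stats::runif(1, 70, 160), 1),
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df <- df[order(df$replicate, df$protein1, df$residue1, df$residue2), ]
    rownames(df) <- NULL
    tab <- load_xl_table(df)
    truth <- list(true_pairs = sort(truth_true),
                  decoy_pairs = sort(truth_decoy),
                  cluster_windows = cluster_windows,
                  n_replicates = n_replicates, min_support = min_support)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      csv <- file.path(dir, "xl.csv")
      utils::write.csv(df, csv, row.names = FALSE)
      tj <- file.path(dir, "truth.json")
      jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
      paths <- c(csv = csv, truth = tj)
    }
    list(table = tab, truth = truth, paths = paths)
  })
}

# naive reference census: triple loop over the identical placement set,
# independent of the vectorized scan path
.census_bruteforce <- function(receptor, ligand, restraints, grid_spacing,
                               n_rotations, clash_dist, padding = NULL) {
  rec <- .bead_xyz(receptor); lig <- .bead_xyz(ligand)
  cen <- colMeans(lig); off0 <- sweep(lig, 2, cen)
  lig_radius <- if (nrow(lig) > 1L) max(sqrt(rowSums(off0^2))) else 0
  nres <- if (is.null(restraints)) 0L else nrow(restraints)
  if (is.null(padding))
    padding <- lig_radius + clash_dist +
      if (nres > 0L) max(restraints$upper) else 0
  grid <- placement_grid(receptor, padding, grid_spacing)
  rots <- rotation_set(n_rotations)
  anch <- if (nres > 0L) .resolve_anchors(restraints, receptor, ligand) else NULL
  counts <- rep(0, nres + 1L)
  for (rot in rots) {
    off <- off0 %*% t(rot)
    for (g in seq_len(nrow(grid))) {
      beads <- sweep(off, 2, grid[g, ], `+`)
      clash <- FALSE
      for (j in seq_len(nrow(beads))) {
        for (r in seq_len(nrow(rec))) {
          if (sum((beads[j, ] - rec[r, ])^2) < clash_dist^2) { clash <- TRUE; break }
        }
        if (clash) break
      }
      if (clash) next
      ns <- 0L
      if (nres > 0L) {
        for (k in seq_len(nres)) {
          d <- sqrt(sum((rec[anch$rec[k], ] - beads[anch$lig[k], ])^2))
          if (d >= restraints$lower[k] && d <= restraints$upper[k]) ns <- ns + 1L
        }
      }
      for (k in 0:ns) counts[k + 1L] <- counts[k + 1L] + 1
    }
  }
  names(counts) <- as.character(0:nres)
  counts
}

#' Generate toy receptor/ligand structures with a known placement census
#'
#' Three scenarios, each small enough for exhaustive reference counting:
#' `"census"` -- a compact receptor and a 2-bead ligand with the brute-force
#' placement census stored as truth; `"two_lobe"` -- a receptor wall
#' splitting the accessible space into two lobes, with a permissive
#' crosslink restraint satisfied in both lobes and a degron-tail restraint
#' anchored off-wall that excludes one lobe entirely; `"symmetric"` -- a
#' mirror-symmetric receptor with symmetric restraints, under which every
#' contacted residue has interaction propensity exactly 1.
#'
#' @param seed integer seed (used for the census scenario's bead jitter).
#' @param scenario `"census"`, `"two_lobe"` or `"symmetric"`.
#' @param grid_spacing,n_rotations,clash_dist scan parameters the truth
#'   census is computed at (defaults 2 / 4 / 3; the toy bodies keep the
#'   placement count below ten thousand).
#' @param dir optional output directory; writes `receptor.pdb`,
#'   `ligand.pdb`, `restraints.tbl` (when the scenario has restraints) and
#'   `truth.json`.
#' @return list: `receptor`, `ligand` ([coarse_structure()]), `restraints`
#'   (possibly NULL), `params`, `truth` (census counts for the same
#'   placement set), `paths`.
#' @export
gen_toy_structures <- function(seed, scenario = c("census", "two_lobe",
                                                  "symmetric"),
                               grid_spacing = 2, n_rotations = 4,
                               clash_dist = 3, dir = NULL) {
  scenario <- match.arg(scenario)
  # single-bead ligands make rotations redundant; keep the placement set small
  if (scenario != "census") n_rotations <- 1L
  .with_seed(seed, {
    if (scenario == "census") {
      rb <- data.frame(chain = "R", residue = 1:4,
                       x = c(0, 2, 0, 1) + stats::runif(4, -0.3, 0.3),
                       y = c(0, 0, 2, 1) + stats::runif(4, -0.3, 0.3),
                       z = c(0, 0, 0, 2) + stats::runif(4, -0.3, 0.3))
      lb <- data.frame(chain = "L", residue = 1:2,
                       x = c(0, 2), y = c(0, 0), z = c(0, 0))
      restraints <- distance_restraint("R", 1, "L", 1, 0, 6)
    } else if (scenario == "two_lobe") {
      wall <- expand.grid(y = seq(-2, 2, by = 2), z = seq(-2, 2, by = 2))
      rb <- data.frame(chain = "R",
                       residue = seq_len(nrow(wall) + 1L),
                       x = c(rep(0, nrow(wall)), 6),
                       y = c(wall$y, 0), z = c(wall$z, 0))
      lb <- data.frame(chain = "L", residue = 1L, x = 0, y = 0, z = 0)
      center_res <- which(wall$y == 0 & wall$z == 0)[1]
      restraints <- rbind(
        distance_restraint("R", center_res, "L", 1, 0, 12, source = "XL"),
        distance_restraint("R", nrow(wall) + 1L, "L", 1, 0, 5,
                           source = "TAIL"))
      class(restraints) <- c("restraint_set", "data.frame")
    } else {
      rb <- data.frame(chain = "R", residue = 1:2,
                       x = c(-3, 3), y = c(0, 0), z = c(0, 0))
      lb <- data.frame(chain = "L", residue = 1L, x = 0, y = 0, z = 0)
      restraints <- rbind(
        distance_restraint("R", 1, "L", 1, 0, 10),
        distance_restraint("R", 2, "L", 1, 0, 10))
      class(restraints) <- c("restraint_set", "data.frame")
    }
    receptor <- coarse_structure(rb)
    ligand <- coarse_structure(lb)
    params <- list(grid_spacing = grid_spacing, n_rotations = n_rotations,
                   clash_dist = clash_dist)
    census <- .census_bruteforce(receptor, ligand, restraints, grid_spacing,
                                 n_rotations, clash_dist)
    truth <- list(census = as.list(census), scenario = scenario,
                  params = params)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      rp <- file.path(dir, "receptor.pdb"); lp <- file.path(dir, "ligand.pdb")
      write_pdb_ca(receptor, rp); write_pdb_ca(ligand, lp)
      tb <- file.path(dir, "restraints.tbl")
      write_tbl(restraints, tb)
      tj <- file.path(dir, "truth.json")
      jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
      paths <- c(receptor = rp, ligand = lp, tbl = tb, truth = tj)
    }
    list(receptor = receptor, ligand = ligand, restraints = restraints,
         params = params, truth = truth, paths = paths)
  })
}

#' Generate a synthetic effective-energy trajectory and decomposition
#'
#' The instantaneous energy follows
#' `plateau + transient * exp(-t / tau) + N(0, noise_sd)`: an equilibration
#' transient decaying onto a plateau, the shape of MM-GBSA effective-energy
#' time series. The per-residue decomposition table carries planted
#' hot-spots (side-chain contribution at or below the -1 kcal/mol
#' threshold, with margin) among neutral residues, and paired wild-type /
#' mutant post-equilibration series encode a planted alanine-scanning
#' energy shift.
#'
#' @param seed integer seed.
#' @param plateau,transient,tau_ps,noise_sd series parameters (kcal/mol,
#'   kcal/mol, ps, kcal/mol); defaults -45, 15, 1500, 2.
#' @param duration_ps,interval_ps sampling window (defaults 20000 / 10; the
#'   20 ns production window sampled every 10 ps, i.e. 2000 frames).
#' @param n_residues decomposition size; `hotspot_dg` the planted
#'   side-chain energies (kcal/mol, all <= -1).
#' @param ddg_true planted alanine-scanning shift, kcal/mol.
#' @param group_id trajectory label.
#' @param dir optional output directory; writes `trajectory.csv`,
#'   `decomposition.csv`, `cas.csv`, `truth.json`.
#' @return list: `trajectory` ([energy_trajectory()]), `decomposition`
#'   (data.frame), `wt`, `mut` (post-equilibration series), `truth`,
#'   `paths`.
#' @export
gen_energy <- function(seed, plateau = -45, transient = 15, tau_ps = 1500,
                       noise_sd = 2, duration_ps = 20000, interval_ps = 10,
                       n_residues = 30L,
                       hotspot_dg = c(-3.1, -2.2, -1.4), ddg_true = 2.5,
                       group_id = "group1", dir = NULL) {
  .with_seed(seed, {
    n <- sample_count(duration_ps, interval_ps)
    times <- seq_len(n) * interval_ps
    dg <- plateau + transient * exp(-times / tau_ps) +
      stats::rnorm(n, 0, noise_sd)
    traj <- energy_trajectory(times, dg, group_id)

    n_hot <- length(hotspot_dg)
    ids <- sprintf("RES%03d", seq_len(n_residues))
    hot_idx <- sort(sample(n_residues, n_hot))
    dg_sc <- stats::runif(n_residues, -0.6, 0.4)  # neutral background
    dg_sc[hot_idx] <- hotspot_dg
    decomp <- data.frame(residue_id = ids, chain = "A",
                         dg_sidechain = dg_sc,
                         dg_backbone = stats::runif(n_residues, -0.3, 0.3),
                         stringsAsFactors = FALSE)

    n_eq <- n %/% 2L
    wt <- plateau + stats::rnorm(n_eq, 0, noise_sd)
    mut <- plateau + ddg_true + stats::rnorm(n_eq, 0, noise_sd)

    truth <- list(plateau = plateau, transient = transient, tau_ps = tau_ps,
                  noise_sd = noise_sd,
                  hotspot_ids = ids[hot_idx], hotspot_dg = hotspot_dg,
                  ddg_true = ddg_true, n_frames = n)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      p1 <- file.path(dir, "trajectory.csv")
      utils::write.csv(data.frame(time_ps = times, dg_eff = dg), p1,
                       row.names = FALSE)
      p2 <- file.path(dir, "decomposition.csv")
      utils::write.csv(decomp, p2, row.names = FALSE)
      p3 <- file.path(dir, "cas.csv")
      utils::write.csv(data.frame(frame = seq_len(n_eq), wt = wt, mut = mut),
                       p3, row.names = FALSE)
      tj <- file.path(dir, "truth.json")
      jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
      paths <- c(trajectory = p1, decomposition = p2, cas = p3, truth = tj)
    }
    list(trajectory = traj, decomposition = decomp, wt = wt, mut = mut,
         truth = truth, paths = paths)
  })
}
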