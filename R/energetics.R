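#' Effective binding free-energy trajectory
#'
#' Per-frame effective binding free energies (MM-GBSA style) on a uniform
#' time grid.
#'
#' @param times frame times in ps, strictly increasing, uniformly spaced.
#' @param dg_eff effective energies, kcal/mol, one per frame.
#' @param group_id identifier of the simulation group/cluster.
#' @return object of class `energy_trajectory`.
#' @export
energy_trajectory <- function(times, dg_eff, group_id = "group1") {
  times <- as.numeric(times); dg_eff <- as.numeric(dg_eff)
  if (length(times) != length(dg_eff) || length(times) == 0L)
    stop("times and dg_eff must be non-empty, same length")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (diff(range(dt)) > 1e-9 * max(abs(dt)))
      stop("times must be uniformly spaced")
  }
  structure(list(times = times, dg_eff = dg_eff, group_id = group_id),
            class = "energy_trajectory")
}

#' Number of samples in a uniformly sampled window
#'
#' `duration / interval`, requiring the interval to divide the duration
#' (e.g. a 20,000 ps productive window sampled every 10 ps gives 2000
#' frames).
#'
#' @param duration_ps window length, ps.
#' @param interval_ps sampling interval, ps.
#' @param tol divisibility tolerance (default 1e-9, relative).
#' @return integer frame count.
#' @export
sample_count <- function(duration_ps, interval_ps, tol = 1e-9) {
  if (duration_ps <= 0 || interval_ps <= 0) stop("duration and interval must be positive")
  q <- duration_ps / interval_ps
  if (abs(q - round(q)) > tol * max(1, q))
    stop("interval does not divide duration")
  as.integer(round(q))
}

#' Accumulated (cumulative) mean of a trajectory
#'
#' `out[i] = mean(dg_eff[1..i])`: each position's mean over all previous
#' values including itself, the convergence diagnostic drawn over
#' instantaneous energies.
#'
#' @param traj an [energy_trajectory()] or numeric vector.
#' @return numeric vector, same length.
#' @export
accumulated_mean <- function(traj) {
  v <- if (inherits(traj, "energy_trajectory")) traj$dg_eff else as.numeric(traj)
  if (length(v) == 0L) stop("empty series")
  cumsum(v) / seq_along(v)
}

# SEM helpers: naive (independent frames) and block averaging for serially
# correlated frames.
.sem_naive <- function(v) stats::sd(v) / sqrt(length(v))
.sem_block <- function(v, block_len) {
  nb <- floor(length(v) / block_len)
  if (nb < 2L) return(NA_real_)
  bm <- vapply(seq_len(nb), function(b)
    mean(v[((b - 1L) * block_len + 1L):(b * block_len)]), numeric(1))
  stats::sd(bm) / sqrt(nb)
}

#' Post-equilibration statistics of a trajectory
#'
#' Mean, standard error and frame count over frames with `time >= t_eq`
#' (inclusive). Frames are treated as independent for the default SEM; a
#' block-averaging SEM is available for a more honest uncertainty under
#' serial correlation.
#'
#' @param traj an [energy_trajectory()].
#' @param t_eq_ps equilibration time, ps; must lie within the time range.
#' @param block_len optional block length (frames) for a block-averaged SEM.
#' @return list: `mean`, `sem`, `n`, and `sem_block` when requested.
#' @export
equilibrated_stats <- function(traj, t_eq_ps, block_len = NULL) {
  stopifnot(inherits(traj, "energy_trajectory"))
  if (t_eq_ps < min(traj$times) || t_eq_ps > max(traj$times))
    stop("t_eq outside the trajectory time range")
  v <- traj$dg_eff[traj$times >= t_eq_ps]
  out <- list(mean = mean(v),
              sem = if (length(v) > 1L) .sem_naive(v) else 0,
              n = length(v))
  if (!is.null(block_len)) out$sem_block <- .sem_block(v, block_len)
  out
}

#' Select the energetically most favorable group
#'
#' Among several trajectories (e.g. docking clusters simulated
#' independently) returns the group with the lowest post-equilibration mean
#' effective energy -- the most probable ensemble. Ties are broken by input
#' order with a warning.
#'
#' @param trajs list of [energy_trajectory()] objects (>= 2).
#' @param t_eq_ps equilibration time, ps.
#' @return list: `group_id`, `means` (named, all groups).
#' @export
select_group <- function(trajs, t_eq_ps) {
  if (length(trajs) < 2L) stop("need at least two groups")
  means <- vapply(trajs, function(tr) equilibrated_stats(tr, t_eq_ps)$mean,
                  numeric(1))
  names(means) <- vapply(trajs, `[[`, character(1), "group_id")
  best <- which(means == min(means))
  if (length(best) > 1L)
    warning("tie among groups: ", paste(names(means)[best], collapse = ", "),
            "; keeping the first")
  list(group_id = names(means)[best[1]], means = means)
}

#' Call hot-spot residues from a per-residue decomposition
#'
#' Hot-spots are residues whose side-chain energy contribution is at or
#' below the threshold (default -1.0 kcal/mol, inclusive). Returned sorted
#' by energy, most stabilizing first.
#'
#' @param table data.frame with columns `residue_id`, `dg_sidechain`
#'   (kcal/mol); `chain` and `dg_backbone` are carried through if present.
#' @param threshold kcal/mol (default -1.0).
#' @return data.frame subset of hot-spot rows, ordered by `dg_sidechain`.
#' @export
call_hotspots <- function(table, threshold = -1.0) {
  req <- c("residue_id", "dg_sidechain")
  if (!all(req %in% names(table)))
    stop("decomposition table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(table$residue_id))
    stop("duplicate residue ids in decomposition table")
  hs <- table[table$dg_sidechain <= threshold, , drop = FALSE]
  hs <- hs[order(hs$dg_sidechain), , drop = FALSE]
  rownames(hs) <- NULL
  hs
}

#' Computational alanine scanning entry
#'
#' Binding free-energy change upon alanine substitution:
#' `ddg = mean(mut) - mean(wt)` over paired post-equilibration windows,
#' with the SEMs propagated in quadrature.
#'
#' @param wt,mut numeric per-frame effective-energy series from the
#'   post-equilibration window (wild type and alanine mutant).
#' @param residue_id identifier of the mutated residue.
#' @param block_len optional block length for block-averaged SEMs.
#' @return list: `residue_id`, `ddg` (kcal/mol), `sem`.
#' @export
cas_ddg <- function(wt, mut, residue_id = NA_character_, block_len = NULL) {
  wt <- as.numeric(wt); mut <- as.numeric(mut)
  if (length(wt) == 0L || length(mut) == 0L) stop("empty energy series")
  sem_of <- function(v) {
    if (!is.null(block_len)) {
      s <- .sem_block(v, block_len)
      if (!is.na(s)) return(s)
    }
    if (length(v) > 1L) .sem_naive(v) else 0
  }
  list(residue_id = residue_id,
       ddg = mean(mut) - mean(wt),
       sem = sqrt(sem_of(wt)^2 + sem_of(mut)^2))
}
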