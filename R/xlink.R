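#' Load a crosslink identification table
#'
#' Reads a MeroX-export-like CSV with columns `protein1`, `residue1`,
#' `protein2`, `residue2`, `replicate` and optional `score`, and corrects
#' residue numbering to canonical coordinates by subtracting per-protein
#' N-terminal construct offsets. Duplicate identifications of the same
#' unordered residue pair within a replicate collapse to one row.
#'
#' @param file path to the CSV, or a data.frame with those columns.
#' @param offsets named integer vector/list, protein id -> extra N-terminal
#'   residues of the construct (missing proteins get 0).
#' @return data.frame of class `xl_table`: `protein_a`, `residue_a`,
#'   `protein_b`, `residue_b`, `replicate_id`, `score`, `valid` (FALSE when
#'   an offset-corrected index is non-positive). Endpoints are stored in
#'   canonical order (pair key is unordered).
#' @export
load_xl_table <- function(file, offsets = NULL) {
  df <- if (is.data.frame(file)) file
        else utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("protein1", "residue1", "protein2", "residue2", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("crosslink table is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$score)) df$score <- NA_real_
  off <- function(p) {
    if (is.null(offsets) || !p %in% names(offsets)) return(0L)
    o <- offsets[[p]]
    if (is.null(o) || is.na(o)) 0L else as.integer(o)
  }
  ra <- as.integer(df$residue1) - vapply(as.character(df$protein1), off, integer(1))
  rb <- as.integer(df$residue2) - vapply(as.character(df$protein2), off, integer(1))
  out <- data.frame(protein_a = as.character(df$protein1), residue_a = ra,
                    protein_b = as.character(df$protein2), residue_b = rb,
                    replicate_id = as.character(df$replicate),
                    score = as.numeric(df$score), stringsAsFactors = FALSE)
  # canonical unordered endpoint order
  swap <- out$protein_b < out$protein_a |
    (out$protein_b == out$protein_a & out$residue_b < out$residue_a)
  out[swap, c("protein_a", "residue_a", "protein_b", "residue_b")] <-
    out[swap, c("protein_b", "residue_b", "protein_a", "residue_a")]
  out$valid <- out$residue_a >= 1L & out$residue_b >= 1L
  key <- paste(out$protein_a, out$residue_a, out$protein_b, out$residue_b,
               out$replicate_id, sep = "|")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("xl_table", "data.frame")
  out
}

#' Build a crosslink network from a table
#'
#' Groups identifications by unique unordered residue pair and records the
#' replicate support set of each pair.
#'
#' @param tab an `xl_table` (or compatible data.frame).
#' @param replicates declared replicate ids; defaults to those present.
#' @return object of class `xl_network`: `links` (data.frame with one row
#'   per unique pair: endpoints, `n_support`, `support` comma-joined,
#'   `best_score`), `n_replicates`.
#' @export
xl_network <- function(tab, replicates = NULL) {
  tab <- tab[tab$valid %in% c(TRUE, NA) | is.null(tab$valid), , drop = FALSE]
  if (is.null(replicates)) replicates <- sort(unique(tab$replicate_id))
  if (!all(tab$replicate_id %in% replicates))
    stop("table contains replicate ids outside the declared set")
  key <- paste(tab$protein_a, tab$residue_a, tab$protein_b, tab$residue_b, sep = "|")
  sp <- split(seq_len(nrow(tab)), key)
  links <- do.call(rbind, lapply(sp, function(i) {
    reps <- sort(unique(tab$replicate_id[i]))
    data.frame(protein_a = tab$protein_a[i[1]], residue_a = tab$residue_a[i[1]],
               protein_b = tab$protein_b[i[1]], residue_b = tab$residue_b[i[1]],
               n_support = length(reps),
               support = paste(reps, collapse = ","),
               best_score = suppressWarnings(max(tab$score[i], na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  links$best_score[!is.finite(links$best_score)] <- NA_real_
  rownames(links) <- NULL
  structure(list(links = links, n_replicates = length(replicates),
                 replicates = replicates),
            class = "xl_network")
}

#' Filter crosslinks by replicate reproducibility
#'
#' Keeps residue pairs identified in at least `min_support` independent
#' experiments, the 2/3-or-3/4 style filter. Pairs supported by every
#' replicate are labelled `"solid"`, the rest `"dashed"`.
#'
#' @param net an [xl_network()].
#' @param min_support minimal replicate count (<= `net$n_replicates`).
#' @return an `xl_network` whose `links` carry a `support_class` column.
#' @export
replicate_filter <- function(net, min_support = 2L) {
  stopifnot(inherits(net, "xl_network"))
  if (min_support > net$n_replicates)
    stop("min_support exceeds the number of replicates")
  keep <- net$links$n_support >= min_support
  links <- net$links[keep, , drop = FALSE]
  links$support_class <- ifelse(links$n_support == net$n_replicates,
                                "solid", "dashed")
  rownames(links) <- NULL
  structure(list(links = links, n_replicates = net$n_replicates,
                 replicates = net$replicates),
            class = "xl_network")
}

#' Partition links into intra- and inter-protein classes
#'
#' @param net an [xl_network()].
#' @return the network with a `link_class` column (`"intra"` iff both
#'   endpoints are on the same protein, else `"inter"`).
#' @export
classify_links <- function(net) {
  stopifnot(inherits(net, "xl_network"))
  net$links$link_class <- ifelse(net$links$protein_a == net$links$protein_b,
                                 "intra", "inter")
  net
}

#' Single-linkage clustering of residue positions
#'
#' Groups sorted 1D residue positions into clusters: consecutive positions
#' join a cluster iff their gap is at most `max_gap`. Used to find
#' crosslinker-reactive residue patches on the receptor.
#'
#' @param positions non-empty integer vector of residue indices.
#' @param max_gap maximal gap (residues) within a cluster (default 30).
#' @return data.frame: `start`, `end`, `n_members`, `members`
#'   (comma-joined), one row per cluster, ordered by start.
#' @export
cluster_residues <- function(positions, max_gap = 30L) {
  if (length(positions) == 0L) stop("positions must be non-empty")
  p <- sort(unique(as.integer(positions)))
  grp <- cumsum(c(1L, as.integer(diff(p) > max_gap)))
  do.call(rbind, lapply(split(p, grp), function(m) {
    data.frame(start = min(m), end = max(m), n_members = length(m),
               members = paste(m, collapse = ","), stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Distance restraint between two structure anchors
#'
#' @param chain_a,resid_a,chain_b,resid_b anchor identities (Calpha atoms).
#' @param lower,upper distance bounds in Angstrom, `0 <= lower < upper`.
#' @param source `"XL"` (crosslink-derived) or `"TAIL"` (degron-tail
#'   polymer restraint).
#' @return one-row data.frame of class `restraint_set`.
#' @export
distance_restraint <- function(chain_a, resid_a, chain_b, resid_b,
                               lower, upper, source = "XL") {
  if (lower < 0 || lower >= upper) stop("need 0 <= lower < upper")
  out <- data.frame(chain_a = chain_a, resid_a = as.integer(resid_a),
                    chain_b = chain_b, resid_b = as.integer(resid_b),
                    lower = lower, upper = upper, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Convert filtered inter-protein crosslinks to distance restraints
#'
#' One restraint per resolvable inter-protein link: lower bound
#' `min_ca_ca` (default 0), upper bound the crosslinker-specific maximal
#' Calpha-Calpha distance. Endpoints are resolved to chains via
#' `chain_map`; links with an endpoint that has no coordinates (e.g.
#' residues in disordered regions absent from the model) are listed as
#' unresolved, not dropped silently. Where both endpoints have coordinates
#' the current Calpha-Calpha distance and a satisfied/violated flag are
#' reported.
#'
#' @param net a filtered, classified [xl_network()].
#' @param structures a `coarse_structure` (or bead data.frame, see
#'   [read_pdb_ca()]) holding all modelled chains.
#' @param chain_map named character vector, protein id -> chain id.
#' @param max_ca_ca upper bound in Angstrom (default 30, DSBU).
#' @param min_ca_ca lower bound in Angstrom (default 0).
#' @return list: `restraints` (a `restraint_set`), `report` (per-restraint
#'   current distance and `satisfied`), `unresolved` (data.frame of links
#'   whose endpoints lack coordinates).
#' @export
xl_to_restraints <- function(net, structures, chain_map,
                             max_ca_ca = 30, min_ca_ca = 0) {
  stopifnot(inherits(net, "xl_network"))
  links <- net$links
  if (is.null(links$link_class)) links <- classify_links(net)$links
  links <- links[links$link_class == "inter", , drop = FALSE]
  beads <- if (inherits(structures, "coarse_structure")) structures$beads else structures
  find_bead <- function(chain, resid) {
    i <- which(beads$chain == chain & beads$residue == resid)
    if (length(i) == 0L) NA_integer_ else i[1]
  }
  rows <- list(); reps <- list(); unres <- list()
  for (i in seq_len(nrow(links))) {
    ca <- chain_map[[links$protein_a[i]]]
    cb <- chain_map[[links$protein_b[i]]]
    if (is.null(ca) || is.null(cb)) {
      unres[[length(unres) + 1L]] <- links[i, , drop = FALSE]
      next
    }
    ia <- find_bead(ca, links$residue_a[i])
    ib <- find_bead(cb, links$residue_b[i])
    if (is.na(ia) || is.na(ib)) {
      unres[[length(unres) + 1L]] <- links[i, , drop = FALSE]
      next
    }
    r <- distance_restraint(ca, links$residue_a[i], cb, links$residue_b[i],
                            min_ca_ca, max_ca_ca, source = "XL")
    d <- sqrt(sum((as.numeric(beads[ia, c("x", "y", "z")]) -
                   as.numeric(beads[ib, c("x", "y", "z")]))^2))
    rows[[length(rows) + 1L]] <- r
    reps[[length(reps) + 1L]] <- data.frame(
      chain_a = ca, resid_a = links$residue_a[i],
      chain_b = cb, resid_b = links$residue_b[i],
      distance = d, satisfied = d >= min_ca_ca && d <= max_ca_ca)
  }
  restraints <- if (length(rows) > 0L) do.call(rbind, rows) else
    distance_restraint("A", 1, "B", 1, 0, 1)[0, , drop = FALSE]
  if (nrow(restraints) == 0L)
    warning("no resolvable inter-protein links; empty restraint set")
  class(restraints) <- c("restraint_set", "data.frame")
  list(restraints = restraints,
       report = if (length(reps) > 0L) do.call(rbind, reps) else NULL,
       unresolved = if (length(unres) > 0L) do.call(rbind, unres) else NULL)
}

# Mean residue mass used to convert tail length to peptide mass (Da/aa)
MEAN_RESIDUE_MASS <- 110

#' Degron-tail polymer distance restraint
#'
#' Converts the disordered degron-tail length into a distance restraint
#' between the core-degron anchor on the receptor-bound degron and the PB1
#' anchor: the peptide's theoretical Stokes radii in the compact (NF,
#' lower) and fully disordered (IDP, upper) states, scaled by a geometry
#' factor mapping a Stokes radius to an end-to-end distance bound (default
#' 2, end-to-end roughly twice the hydrodynamic radius).
#'
#' @param tail_len_aa tail length in residues (>= 1).
#' @param anchor_a,anchor_b `list(chain =, resid =)` anchors (degron end
#'   and PB1 start attachment points).
#' @param bands a [fold_class_bands()].
#' @param residue_mass mean residue mass, Da (default 110).
#' @param scale Stokes-radius-to-distance geometry factor (default 2).
#' @return a one-row `restraint_set` with `source = "TAIL"`.
#' @export
tail_restraint <- function(tail_len_aa, anchor_a, anchor_b,
                           bands = fold_class_bands(),
                           residue_mass = MEAN_RESIDUE_MASS, scale = 2) {
  tail_len_aa <- as.integer(tail_len_aa)
  if (is.na(tail_len_aa) || tail_len_aa < 1L)
    stop("tail_len_aa must be >= 1 (a zero-length tail carries no restraint)")
  mass <- tail_len_aa * residue_mass
  # for very short peptides (< ~4 aa) the compact-state law predicts the
  # larger radius; the bounds are the ordered pair either way
  rr <- sort(scale * theoretical_rs(mass, c("NF", "IDP"), bands))
  lower <- rr[1]; upper <- rr[2]
  distance_restraint(anchor_a$chain, anchor_a$resid,
                     anchor_b$chain, anchor_b$resid,
                     lower, upper, source = "TAIL")
}

#' Write restraints in the HADDOCK ambiguous-restraint dialect
#'
#' One `assign` statement per restraint,
#' `assign (segid A and resid i and name CA) (segid B and resid j and name
#' CA) d dminus dplus` with `d = upper`, `dminus = upper - lower`,
#' `dplus = 0`. Output ordering is byte-stable (sorted by chain then
#' residue); parameters are logged in `!` comment headers.
#'
#' @param restraints a non-empty `restraint_set`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_tbl <- function(restraints, path) {
  if (nrow(restraints) == 0L) stop("empty restraint set")
  o <- order(restraints$chain_a, restraints$resid_a,
             restraints$chain_b, restraints$resid_b)
  r <- restraints[o, , drop = FALSE]
  lines <- c(
    "! distance restraints (Angstrom); d dminus dplus = upper, upper-lower, 0",
    sprintf("! %d restraints (%s)", nrow(r),
            paste(sprintf("%s:%d", names(table(r$source)), table(r$source)),
                  collapse = ", ")),
    sprintf(
      "assign (segid %s and resid %d and name CA) (segid %s and resid %d and name CA) %.1f %.1f %.1f",
      r$chain_a, r$resid_a, r$chain_b, r$resid_b,
      r$upper, r$upper - r$lower, 0))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a restraint file written by [write_tbl()]
#'
#' @param path file path.
#' @return a `restraint_set` (source column is `"XL"` for all rows; the
#'   dialect does not carry provenance).
#' @export
read_tbl <- function(path) {
  lines <- grep("^assign", readLines(path), value = TRUE)
  pat <- paste0("^assign \\(segid (\\S+) and resid (\\d+) and name CA\\) ",
                "\\(segid (\\S+) and resid (\\d+) and name CA\\) ",
                "([0-9.]+) ([0-9.]+) ([0-9.]+)$")
  m <- regmatches(lines, regexec(pat, lines))
  if (any(lengths(m) == 0L)) stop("unparseable assign statement")
  out <- do.call(rbind, lapply(m, function(g) {
    upper <- as.numeric(g[6]); dminus <- as.numeric(g[7])
    distance_restraint(g[2], as.integer(g[3]), g[4], as.integer(g[5]),
                       upper - dminus, upper)
  }))
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Flat table for circular crosslink maps
#'
#' One row per link with endpoint coordinates, intra/inter class and
#' replicate support class, suitable for circos-style rendering.
#'
#' @param net a filtered [xl_network()] (support classes are computed if
#'   absent, as is the intra/inter partition).
#' @return data.frame: `protein_a`, `res_a`, `protein_b`, `res_b`, `class`,
#'   `support_class`.
#' @export
export_circular_map <- function(net) {
  stopifnot(inherits(net, "xl_network"))
  if (is.null(net$links$link_class)) net <- classify_links(net)
  l <- net$links
  if (is.null(l$support_class))
    l$support_class <- ifelse(l$n_support == net$n_replicates, "solid", "dashed")
  data.frame(protein_a = l$protein_a, res_a = l$residue_a,
             protein_b = l$protein_b, res_b = l$residue_b,
             class = l$link_class, support_class = l$support_class,
             stringsAsFactors = FALSE)
}

#' Crosslinker-reactive residue check
#'
#' DSBU reacts with K, S, T, Y side chains and protein N-termini. Endpoints
#' outside this vocabulary are reported with a warning (upstream spectral
#' identification normally enforces it already).
#'
#' @param net an [xl_network()].
#' @param sequences named character vector of protein sequences.
#' @return data.frame of offending endpoints (empty when all reactive).
#' @export
check_reactive_residues <- function(net, sequences) {
  l <- net$links
  chk <- function(p, r) {
    s <- sequences[[p]]
    if (is.null(s) || r < 1L || r > nchar(s)) return(NA)
    aa <- substr(s, r, r)
    aa %in% c("K", "S", "T", "Y") || r == 1L
  }
  bad <- list()
  for (i in seq_len(nrow(l))) {
    for (side in c("a", "b")) {
      p <- l[[paste0("protein_", side)]][i]; r <- l[[paste0("residue_", side)]][i]
      ok <- chk(p, r)
      if (isFALSE(ok))
        bad[[length(bad) + 1L]] <- data.frame(protein = p, residue = r,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- if (length(bad)) unique(do.call(rbind, bad)) else
    data.frame(protein = character(), residue = integer())
  if (nrow(out) > 0L)
    warning(nrow(out), " crosslink endpoints on non-reactive residues")
  out
}
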