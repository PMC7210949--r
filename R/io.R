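#' Read a multi-record FASTA file
#'
#' Standard multi-FASTA (any wrap width); the first whitespace-delimited
#' token of each description line is the record id. Numbering offsets for
#' specific records can be attached on the fly.
#'
#' @param path FASTA file.
#' @param offsets optional named vector/list of N-terminal numbering
#'   offsets per record id.
#' @return named list of [protein_record()] objects.
#' @export
read_fasta <- function(path, offsets = NULL) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  if (length(fa) == 0L) stop("no FASTA records in ", path)
  recs <- lapply(names(fa), function(id) {
    off <- if (!is.null(offsets) && id %in% names(offsets))
      offsets[[id]] else 0L
    protein_record(id, as.character(fa[[id]]), offset = off)
  })
  stats::setNames(recs, names(fa))
}

#' Read a per-residue disorder profile
#'
#' Accepts 2-column position/score TSV or IUPred-style 3-column output
#' (position, residue, score) with `#` header lines. Scores must lie in
#' \[0, 1\] and positions must be 1..n contiguous.
#'
#' @param path TSV file.
#' @return numeric score vector, one per residue.
#' @export
read_disorder_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty disorder profile: ", path)
  parts <- strsplit(trimws(lines), "[\t ]+")
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1L || !ncol %in% c(2L, 3L))
    stop("disorder profile must have 2 (pos, score) or 3 (pos, aa, score) columns")
  pos <- as.integer(vapply(parts, `[[`, character(1), 1L))
  score <- as.numeric(vapply(parts, `[[`, character(1), ncol))
  if (any(is.na(pos)) || any(is.na(score))) stop("unparseable disorder profile")
  if (!identical(pos, seq_along(pos))) stop("positions must be contiguous from 1")
  if (any(score < 0) || any(score > 1)) stop("scores must lie in [0, 1]")
  score
}

#' Read Calpha beads from a PDB file
#'
#' Extracts Calpha atoms from ATOM records (HETATM ignored, first altloc
#' kept) into a coarse bead structure; chain and residue numbering are
#' preserved. Residues present in the file without a Calpha atom are
#' skipped with a warning.
#'
#' @param path PDB file.
#' @return a [coarse_structure()].
#' @export
read_pdb_ca <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  ca <- at[at$elety == "CA" & (is.na(at$alt) | at$alt %in% c("", "A")), ,
           drop = FALSE]
  if (nrow(ca) == 0L) stop("no Calpha atoms in ", path)
  all_res <- unique(paste(at$chain, at$resno))
  ca_res <- unique(paste(ca$chain, ca$resno))
  missing <- setdiff(all_res, ca_res)
  if (length(missing) > 0L)
    warning(length(missing), " residues without a Calpha atom skipped")
  coarse_structure(data.frame(
    chain = as.character(ca$chain), residue = as.integer(ca$resno),
    x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE))
}

#' Write a coarse structure as a minimal PDB file
#'
#' One Calpha ATOM record per bead (residue type ALA, fixed-format
#' columns); deterministic output for identical input.
#'
#' @param structure a [coarse_structure()] (or bead data.frame).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pdb_ca <- function(structure, path) {
  beads <- if (inherits(structure, "coarse_structure")) structure$beads
           else structure
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(beads)), substr(beads$chain, 1, 1), beads$residue,
    beads$x, beads$y, beads$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated bundle of thresholds, paths and the seed shared by the
#' pipeline stages. Residue numbering is 1-based inclusive everywhere;
#' distances are in Angstrom, energies kcal/mol, concentrations nM, times
#' ps.
#'
#' @param disorder_lo,disorder_hi disorder category thresholds (0.4 / 0.6).
#' @param hotspot_threshold side-chain energy cutoff, kcal/mol (-1.0).
#' @param cluster_max_gap residue-cluster gap, residues (30).
#' @param max_ca_ca crosslinker Calpha-Calpha bound, Angstrom (30, DSBU).
#' @param sec_tolerance fold-class band half-width (0.10).
#' @param min_support crosslink replicate filter (2).
#' @param t_eq_ps equilibration time, ps (10000).
#' @param seed integer seed.
#' @param paths named list of input paths used by [run_pipeline()]:
#'   `fasta`, `disorder` (named per record), `xl`, `receptor_pdb`,
#'   `ligand_pdb`, `trajectory`, `decomposition`; only stages whose inputs
#'   are present run.
#' @param out_dir report directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(disorder_lo = 0.4, disorder_hi = 0.6,
                            hotspot_threshold = -1.0, cluster_max_gap = 30L,
                            max_ca_ca = 30, sec_tolerance = 0.10,
                            min_support = 2L, t_eq_ps = 10000,
                            seed = 1L, paths = list(), out_dir = ".") {
  if (disorder_lo < 0 || disorder_hi > 1 || disorder_lo > disorder_hi)
    stop("disorder thresholds must satisfy 0 <= lo <= hi <= 1")
  if (hotspot_threshold > 0) stop("hotspot threshold must be <= 0 kcal/mol")
  if (max_ca_ca <= 0 || sec_tolerance < 0 || sec_tolerance >= 1)
    stop("invalid max_ca_ca or sec_tolerance")
  structure(list(disorder_lo = disorder_lo, disorder_hi = disorder_hi,
                 hotspot_threshold = hotspot_threshold,
                 cluster_max_gap = as.integer(cluster_max_gap),
                 max_ca_ca = max_ca_ca, sec_tolerance = sec_tolerance,
                 min_support = as.integer(min_support), t_eq_ps = t_eq_ps,
                 seed = as.integer(seed), paths = paths, out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file whose keys mirror
#'   [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, cfg[intersect(names(cfg), known)])
}

#' Run the configured pipeline stages
#'
#' Executes, for each stage whose inputs are configured: sequence
#' annotation (FASTA + disorder profiles -> domain spans, disorder
#' fractions, lysine inventory), crosslink filtering and restraint
#' generation (crosslink CSV + receptor structure -> filtered network,
#' clusters, restraint file), interaction-space scan (receptor + ligand +
#' restraints -> counts curve), and energetics post-processing (trajectory
#' + decomposition CSVs -> equilibrated statistics, hot-spots). Reports are
#' written as deterministic JSON and TSV files under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return list of per-stage results (also serialized to
#'   `report.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$paths
  need <- function(path, stage) {
    if (!file.exists(path))
      stop(sprintf("stage '%s': input not found: %s", stage, path))
    path
  }
  report <- list()
  timings <- list()
  clock <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(code)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[%s] done in %.2fs", stage, timings[[stage]]))
    res
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(p$fasta)) {
    report$annotate <- clock("annotate", {
      recs <- read_fasta(need(p$fasta, "annotate"))
      lapply(recs, function(r) {
        ann <- segment_domains(r)
        out <- list(id = r$id, n_res = nchar(r$sequence),
                    canonical = ann$canonical, spans = ann$spans,
                    kr_position = ann$kr_position,
                    tail_len = if (ann$canonical) degron_tail_length(ann) else NA,
                    lysines = lysine_positions(r))
        if (!is.null(p$disorder) && !is.null(p$disorder[[r$id]])) {
          sc <- read_disorder_tsv(need(p$disorder[[r$id]], "annotate"))
          out$disorder_fractions <- classify_disorder(
            sc, config$disorder_lo, config$disorder_hi)$fractions
        }
        out
      })
    })
  }

  if (!is.null(p$xl)) {
    report$xl <- clock("xl", {
      tab <- load_xl_table(need(p$xl, "xl"))
      net <- classify_links(replicate_filter(xl_network(tab),
                                             config$min_support))
      inter <- net$links[net$links$link_class == "inter", , drop = FALSE]
      clusters <- if (nrow(inter) > 0L)
        cluster_residues(inter$residue_a, config$cluster_max_gap) else NULL
      utils::write.table(export_circular_map(net),
                         file.path(config$out_dir, "xl_map.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(n_links = nrow(net$links), n_inter = nrow(inter),
           clusters = clusters)
    })
  }

  if (!is.null(p$receptor_pdb) && !is.null(p$ligand_pdb) && !is.null(p$tbl)) {
    report$scan <- clock("scan", {
      rec <- read_pdb_ca(need(p$receptor_pdb, "scan"))
      lig <- read_pdb_ca(need(p$ligand_pdb, "scan"))
      restraints <- read_tbl(need(p$tbl, "scan"))
      sc <- scan_interaction_space(rec, lig, restraints,
                                   grid_spacing = 2, n_rotations = 4)
      utils::write.table(
        data.frame(k = names(sc$counts), count = as.numeric(sc$counts)),
        file.path(config$out_dir, "scan_counts.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      list(counts = as.list(sc$counts), n_placements = sc$n_placements)
    })
  }

  if (!is.null(p$trajectory)) {
    report$energetics <- clock("energetics", {
      tr <- utils::read.csv(need(p$trajectory, "energetics"))
      traj <- energy_trajectory(tr$time_ps, tr$dg_eff)
      st <- equilibrated_stats(traj, config$t_eq_ps)
      out <- list(mean = st$mean, sem = st$sem, n = st$n)
      if (!is.null(p$decomposition)) {
        dec <- utils::read.csv(need(p$decomposition, "energetics"),
                               stringsAsFactors = FALSE)
        out$hotspots <- call_hotspots(dec, config$hotspot_threshold)$residue_id
      }
      out
    })
  }

  report$timings <- timings
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
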