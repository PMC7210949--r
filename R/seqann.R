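#' Protein sequence record
#'
#' Container for one AUX/IAA (or other) protein sequence together with an
#' N-terminal numbering offset. Some expression constructs carry extra
#' residues at the N-terminus relative to canonical numbering (e.g. 5 for
#' IAA7, 2 for IAA12); the offset is subtracted when exchanging residue
#' indices with external tables such as crosslink identifications.
#'
#' @param id record identifier.
#' @param sequence amino-acid string, 1-letter code. The 20 standard letters
#'   are accepted; `X` is allowed but flagged via an attribute.
#' @param offset non-negative integer count of extra N-terminal residues
#'   relative to canonical numbering.
#' @return an object of class `protein_record` with fields `id`, `sequence`,
#'   `offset` and logical attribute `has_x`.
#' @export
protein_record <- function(id, sequence, offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) == 0L) stop("sequence must be non-empty")
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L) stop("offset must be a non-negative integer")
  aa <- strsplit(sequence, "")[[1]]
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(unique(aa), c(standard, "X"))
  if (length(bad) > 0L)
    stop("non-standard residue letters: ", paste(bad, collapse = ", "))
  rec <- structure(
    list(id = id, sequence = sequence, offset = offset),
    class = "protein_record")
  attr(rec, "has_x") <- any(aa == "X")
  rec
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa, offset %d\n",
              x$id, nchar(x$sequence), x$offset))
  invisible(x)
}

# Core degron: VGWPP-[VI]-[RG]-x(2)-R, a 10-residue match.
DEGRON_REGEX <- "VGWPP[VI][RG]..R"
PB1_START_MOTIF <- "VKV"

#' Segment an AUX/IAA sequence into its five modules
#'
#' Splits a sequence into DI, linker, core degron, degron tail and PB1
#' domain. The core degron is located by the family consensus
#' `VGWPP-[VI]-[RG]-x(2)-R` (10 residues); DI runs from residue 1 through
#' the first KR dipeptide upstream of the degron; the linker connects KR and
#' degron; the PB1 domain starts at the first VKV motif at or after the
#' degron end; the degron tail is the stretch in between. When the degron or
#' the VKV motif is absent the annotation is non-canonical and spans are
#' partial.
#'
#' @param rec a [protein_record()].
#' @param degron_extension residues prepended to the regex match for display
#'   parity with the commonly drawn 13-aa degron (default 0: the pure regex
#'   span). The extension never eats into the DI span.
#' @return an object of class `domain_annotation`: list with `spans` (named
#'   list of `c(start, end)` 1-based inclusive), `kr_position` (start of the
#'   KR dipeptide or `NA`), `canonical` flag, `n_res`, and `warnings`
#'   (character vector, e.g. multiple degron matches).
#' @export
segment_domains <- function(rec, degron_extension = 0L) {
  stopifnot(inherits(rec, "protein_record"))
  n <- nchar(rec$sequence)
  warnings <- character()
  spans <- list()

  m <- gregexpr(DEGRON_REGEX, rec$sequence, perl = TRUE)[[1]]
  canonical <- m[1] != -1L
  kr_position <- NA_integer_

  if (!canonical) {
    ann <- structure(list(spans = spans, kr_position = kr_position,
                          canonical = FALSE, n_res = n, warnings = warnings),
                     class = "domain_annotation")
    return(ann)
  }
  if (length(m) > 1L) {
    warnings <- c(warnings, sprintf(
      "%d degron matches; using the first at %d", length(m), m[1]))
  }
  deg_start <- as.integer(m[1])
  deg_len <- attr(m, "match.length")[1]
  deg_end <- deg_start + deg_len - 1L

  # KR dipeptide: first occurrence strictly upstream of the degron start
  upstream <- substr(rec$sequence, 1L, deg_start - 1L)
  kr <- regexpr("KR", upstream, fixed = TRUE)
  if (kr != -1L) kr_position <- as.integer(kr)

  ext <- min(as.integer(degron_extension),
             deg_start - (if (is.na(kr_position)) 1L else kr_position + 2L))
  ext <- max(ext, 0L)
  deg_start <- deg_start - ext

  if (!is.na(kr_position)) {
    spans$DI <- c(1L, kr_position + 1L)  # through the KR dipeptide
    if (kr_position + 2L <= deg_start - 1L)
      spans$linker <- c(kr_position + 2L, deg_start - 1L)
  } else {
    # no KR upstream: DI empty, linker starts at 1
    if (deg_start > 1L) spans$linker <- c(1L, deg_start - 1L)
  }
  spans$degron <- c(deg_start, deg_end)

  # PB1: first VKV at/after the degron end
  tailseq <- substr(rec$sequence, deg_end + 1L, n)
  vkv <- regexpr(PB1_START_MOTIF, tailseq, fixed = TRUE)
  if (vkv != -1L) {
    pb1_start <- deg_end + as.integer(vkv)
    if (pb1_start > deg_end + 1L)
      spans$degron_tail <- c(deg_end + 1L, pb1_start - 1L)
    spans$PB1 <- c(pb1_start, n)
  } else {
    canonical <- FALSE
    warnings <- c(warnings, "no VKV motif after degron; PB1 span absent")
    if (deg_end < n) spans$degron_tail <- c(deg_end + 1L, n)
  }

  structure(list(spans = spans, kr_position = kr_position,
                 canonical = canonical, n_res = n, warnings = warnings),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("<domain_annotation> %d aa, %s\n", x$n_res,
              if (x$canonical) "canonical" else "non-canonical"))
  for (nm in names(x$spans))
    cat(sprintf("  %-12s %d-%d\n", nm, x$spans[[nm]][1], x$spans[[nm]][2]))
  invisible(x)
}

#' Classify per-residue disorder scores
#'
#' Thresholds a disorder-probability profile into ordered (< `lo`),
#' intermediate (`lo`..`hi`, closed interval) and disordered (> `hi`)
#' residues, and returns the composition fractions.
#'
#' @param scores numeric vector of per-residue disorder probabilities in
#'   \[0, 1\].
#' @param lo,hi thresholds (defaults 0.4 and 0.6).
#' @param span optional `c(start, end)` restricting the classification to a
#'   sub-span (e.g. excluding the PB1 domain).
#' @return list with `category` (factor vector, levels ordered /
#'   intermediate / disordered) and `fractions` (named numeric, sums to 1).
#' @export
classify_disorder <- function(scores, lo = 0.4, hi = 0.6, span = NULL) {
  stopifnot(is.numeric(scores))
  if (length(scores) == 0L) stop("empty disorder profile")
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("disorder scores must lie in [0, 1]")
  if (lo > hi) stop("lo must be <= hi")
  if (!is.null(span)) {
    span <- as.integer(span)
    if (span[1] < 1L || span[2] > length(scores) || span[1] > span[2])
      stop("span out of range")
    scores <- scores[span[1]:span[2]]
  }
  lv <- c("ordered", "intermediate", "disordered")
  cat_chr <- ifelse(scores > hi, "disordered",
                    ifelse(scores < lo, "ordered", "intermediate"))
  category <- factor(cat_chr, levels = lv)
  fractions <- as.numeric(table(category)) / length(category)
  names(fractions) <- lv
  list(category = category, fractions = fractions)
}

# Kyte-Doolittle hydropathy index (J Mol Biol 157:105, standard scale)
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean of Kyte-Doolittle residue hydropathy values, the
#' ProtScale-style profile. Near the termini the window shrinks so the
#' output has one value per residue. `X` residues contribute 0.
#'
#' @param rec a [protein_record()] or a plain sequence string.
#' @param window odd window width (default 9, the ProtScale default).
#' @return numeric vector, length = sequence length.
#' @export
hydropathy_profile <- function(rec, window = 9L) {
  seqstr <- if (inherits(rec, "protein_record")) rec$sequence else toupper(rec)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be a positive odd integer")
  aa <- strsplit(seqstr, "")[[1]]
  vals <- KYTE_DOOLITTLE[aa]
  vals[is.na(vals)] <- 0  # X
  n <- length(vals)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(vals[lo:hi])
  }, numeric(1))
}

#' Map residue positions onto domain modules
#'
#' Assigns each position (e.g. a mapped ubiquitylation site) to its
#' containing module of a [segment_domains()] annotation; span ends are
#' inclusive. Positions outside the sequence or outside any span are flagged,
#' not dropped.
#'
#' @param positions integer vector of 1-based residue indices.
#' @param ann a `domain_annotation`.
#' @return list with `assignment` (data.frame: position, module; module is
#'   `"out_of_range"` when beyond the sequence, `"unassigned"` when inside
#'   the sequence but in no span) and `per_domain_counts` (named integer over
#'   the annotation's modules).
#' @export
map_sites <- function(positions, ann) {
  stopifnot(inherits(ann, "domain_annotation"))
  positions <- as.integer(positions)
  module <- vapply(positions, function(p) {
    if (is.na(p) || p < 1L || p > ann$n_res) return("out_of_range")
    for (nm in names(ann$spans)) {
      sp <- ann$spans[[nm]]
      if (p >= sp[1] && p <= sp[2]) return(nm)
    }
    "unassigned"
  }, character(1))
  counts <- vapply(names(ann$spans),
                   function(nm) sum(module == nm), integer(1))
  list(assignment = data.frame(position = positions, module = module,
                               stringsAsFactors = FALSE),
       per_domain_counts = counts)
}

#' Lysine inventory of a sequence
#'
#' All K positions (1-based), the candidate ubiquitin-acceptor sites.
#'
#' @param rec a [protein_record()] or sequence string.
#' @return integer vector of positions.
#' @export
lysine_positions <- function(rec) {
  seqstr <- if (inherits(rec, "protein_record")) rec$sequence else toupper(rec)
  which(strsplit(seqstr, "")[[1]] == "K")
}

#' Degron tail length in residues
#'
#' Number of residues between the core degron end and the PB1 start:
#' `PB1.start - degron.end - 1`. Zero when the degron abuts the VKV motif.
#'
#' @param ann a canonical `domain_annotation`.
#' @return integer length (>= 0).
#' @export
degron_tail_length <- function(ann) {
  stopifnot(inherits(ann, "domain_annotation"))
  if (!ann$canonical) stop("degron tail length requires a canonical annotation")
  ann$spans$PB1[1] - ann$spans$degron[2] - 1L
}
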