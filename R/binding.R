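#' One-site total binding model
#'
#' Total counts expected in a saturation radioligand binding assay:
#' specific one-site binding plus a linear nonspecific component,
#' `bmax * x / (kd + x) + ns * x`. Free ligand is approximated by added
#' ligand (no depletion correction), as in the assay design.
#'
#' @param x free ligand concentration(s), nM (>= 0).
#' @param kd dissociation constant, nM (> 0).
#' @param bmax maximal specific binding, counts (> 0).
#' @param ns nonspecific slope, counts per nM (>= 0).
#' @return expected total counts.
#' @export
model_total <- function(x, kd, bmax, ns = 0) {
  if (any(x < 0)) stop("concentrations must be >= 0")
  if (kd <= 0 || bmax <= 0 || ns < 0) stop("invalid parameters: need kd > 0, bmax > 0, ns >= 0")
  bmax * x / (kd + x) + ns * x
}

#' Assemble a saturation binding dataset
#'
#' @param ligand_nM strictly positive concentrations (one per row of the
#'   count matrices), sorted ascending.
#' @param total_counts matrix, concentrations x replicates, total binding.
#' @param nonspecific_counts same shape, hot + excess cold ligand controls.
#' @param meta optional list of identifiers (receptor, target, ...).
#' @return object of class `binding_dataset`.
#' @export
binding_dataset <- function(ligand_nM, total_counts, nonspecific_counts,
                            meta = list()) {
  ligand_nM <- as.numeric(ligand_nM)
  total_counts <- as.matrix(total_counts)
  nonspecific_counts <- as.matrix(nonspecific_counts)
  if (any(ligand_nM <= 0)) stop("ligand concentrations must be positive")
  if (is.unsorted(ligand_nM, strictly = TRUE)) stop("concentrations must be sorted, distinct")
  if (length(unique(ligand_nM)) < 5L) stop("need >= 5 distinct concentrations")
  if (nrow(total_counts) != length(ligand_nM) ||
      !all(dim(total_counts) == dim(nonspecific_counts)))
    stop("count matrices must be concentrations x replicates, same shape")
  if (any(total_counts < 0) || any(nonspecific_counts < 0))
    stop("counts must be >= 0")
  structure(list(ligand_nM = ligand_nM, total_counts = total_counts,
                 nonspecific_counts = nonspecific_counts, meta = meta),
            class = "binding_dataset")
}

# Deterministic initial values: kd0 = concentration at half-max specific
# signal, ns0 from the nonspecific controls (through-origin slope), bmax0
# from the specific plateau.
.binding_start <- function(ds) {
  x <- ds$ligand_nM
  tot <- rowMeans(ds$total_counts)
  nsc <- rowMeans(ds$nonspecific_counts)
  ns0 <- max(sum(nsc * x) / sum(x * x), 0)
  spec <- pmax(tot - ns0 * x, 0)
  smax <- max(spec)
  if (smax <= 0) return(list(kd = stats::median(x), bmax = max(tot, 1e-6), ns = ns0))
  kd0 <- x[which.min(abs(spec - smax / 2))]
  list(kd = max(kd0, min(x) / 10), bmax = smax, ns = ns0)
}

#' Fit the one-site total + nonspecific binding model
#'
#' Nonlinear least squares (Levenberg-Marquardt) for `kd`, `bmax` and the
#' nonspecific slope. Two modes: `"joint"` fits total and nonspecific count
#' tables simultaneously with a shared `ns` (the Prism-style preset);
#' `"pinned-ns"` first pins `ns` by a through-origin linear fit of the
#' nonspecific controls, then fits `kd` and `bmax` on the totals.
#' Scintillation-count noise is predominantly multiplicative, so the
#' default weighting is relative (1 / predicted^2, applied in a second
#' stage after an unweighted pass); `weighting = "none"` gives the plain
#' unweighted fit. Non-convergence is reported via `converged = FALSE`
#' with the last iterate, never as an error.
#'
#' @param ds a [binding_dataset()].
#' @param mode `"joint"` or `"pinned-ns"`.
#' @param weighting `"relative"` (default) or `"none"`.
#' @return object of class `binding_fit`: `kd_nM`, `bmax`, `ns_slope`,
#'   `se_kd`, `converged`, `residual_ss`, `mode`, `n_obs`.
#' @export
fit_one_site <- function(ds, mode = c("joint", "pinned-ns"),
                         weighting = c("relative", "none")) {
  stopifnot(inherits(ds, "binding_dataset"))
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  start <- .binding_start(ds)
  x <- ds$ligand_nM
  nrep <- ncol(ds$total_counts)
  xl <- rep(x, nrep)

  mk_fit <- function(dat, start, lower, formula) {
    pass1 <- tryCatch(minpack.lm::nlsLM(
      formula, data = dat, start = start, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(pass1) || weighting == "none") return(pass1)
    dat$.w <- 1 / pmax(stats::fitted(pass1), .Machine$double.eps)^2
    tryCatch(minpack.lm::nlsLM(
      formula, data = dat, start = as.list(stats::coef(pass1)),
      lower = lower, weights = .w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) pass1)
  }

  if (mode == "joint") {
    dat <- data.frame(
      x = c(xl, xl),
      y = c(as.vector(ds$total_counts), as.vector(ds$nonspecific_counts)),
      is_total = rep(c(1, 0), each = length(xl)))
    fit <- mk_fit(dat, start, c(kd = 1e-9, bmax = 1e-12, ns = 0),
                  y ~ is_total * bmax * x / (kd + x) + ns * x)
    ns_fixed <- NULL
  } else {
    nsc <- rowMeans(ds$nonspecific_counts)
    ns_fixed <- max(sum(nsc * x) / sum(x * x), 0)
    dat <- data.frame(x = xl, y = as.vector(ds$total_counts))
    fit <- mk_fit(dat, start[c("kd", "bmax")], c(kd = 1e-9, bmax = 1e-12),
                  y ~ bmax * x / (kd + x) + ns_fixed * x)
  }

  if (is.null(fit)) {
    return(structure(list(kd_nM = start$kd, bmax = start$bmax,
                          ns_slope = if (mode == "joint") start$ns else ns_fixed,
                          se_kd = NA_real_, converged = FALSE,
                          residual_ss = NA_real_, mode = mode,
                          n_obs = nrow(dat)),
                     class = "binding_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  structure(list(kd_nM = unname(cf["kd"]), bmax = unname(cf["bmax"]),
                 ns_slope = if (mode == "joint") unname(cf["ns"]) else ns_fixed,
                 se_kd = unname(se["kd"]),
                 converged = isTRUE(fit$convInfo$isConv),
                 residual_ss = sum(stats::residuals(fit)^2),
                 mode = mode, n_obs = nrow(dat)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> Kd = %.3g nM (SE %.3g), Bmax = %.3g, NS = %.3g/nM [%s, %s]\n",
              x$kd_nM, x$se_kd, x$bmax, x$ns_slope, x$mode,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Normalize a specific-binding curve to its maximum
#'
#' Presentation-only rescaling so the largest value maps to exactly 1.
#'
#' @param curve numeric vector with at least one positive value.
#' @return values in \[min/max, 1\].
#' @export
normalize_relative <- function(curve) {
  if (!any(curve > 0)) stop("normalization needs at least one positive value")
  curve / max(curve)
}

#' Default saturation-binding concentration design
#'
#' 10 log-spaced concentrations between 1 and 2000 nM, the design used for
#' the simulate-and-refit experiments.
#'
#' @param n number of concentrations.
#' @param from,to range in nM.
#' @return numeric vector, nM.
#' @export
default_concentrations <- function(n = 10L, from = 1, to = 2000) {
  exp(seq(log(from), log(to), length.out = n))
}
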