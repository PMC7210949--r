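#' Power-law coefficients for fold-class Stokes radii
#'
#' Hydrodynamic conformational classes obey log-log scaling laws between
#' Stokes radius and molecular mass, `log10(Rs/A) = a + b * log10(M/Da)`,
#' with class-specific coefficients established on reference protein sets
#' (Uversky-type laws): natively folded (NF), molten globule (MG), premolten
#' globule (PMG) and fully unfolded / intrinsically disordered (IDP). Two
#' IDP coefficient sets are in circulation, calibrated on urea- or
#' GdmCl-unfolded proteins; `idp_set` selects one (default `"urea"`, the
#' more expanded law, a conservative outer bound for disordered chains).
#'
#' @param tolerance fractional band half-width around the theoretical radius
#'   used by [classify_fold()] (default 0.10, i.e. 10\% outer limits).
#' @param idp_set `"urea"` or `"gdmcl"`.
#' @return object of class `fold_class_bands`: list with `coef` (data.frame
#'   class/a/b) and `tolerance`.
#' @export
fold_class_bands <- function(tolerance = 0.10, idp_set = c("urea", "gdmcl")) {
  idp_set <- match.arg(idp_set)
  idp <- switch(idp_set,
                urea  = c(a = -0.649, b = 0.521),
                gdmcl = c(a = -0.549, b = 0.493))
  coef <- data.frame(
    class = c("NF", "MG", "PMG", "IDP"),
    a = c(-0.254, -0.053, -0.239, idp[["a"]]),
    b = c( 0.369,  0.334,  0.392, idp[["b"]]),
    stringsAsFactors = FALSE)
  if (!is.numeric(tolerance) || tolerance < 0 || tolerance >= 1)
    stop("tolerance must be in [0, 1)")
  structure(list(coef = coef, tolerance = tolerance, idp_set = idp_set),
            class = "fold_class_bands")
}

#' Theoretical Stokes radius of a fold class
#'
#' Evaluates the class power law `Rs = 10^(a + b * log10(M))`.
#'
#' @param mass molecular mass in Da (may be a vector).
#' @param cls one of `"NF"`, `"MG"`, `"PMG"`, `"IDP"`.
#' @param bands a [fold_class_bands()] object.
#' @return Stokes radius in Angstrom.
#' @export
theoretical_rs <- function(mass, cls, bands = fold_class_bands()) {
  stopifnot(inherits(bands, "fold_class_bands"))
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("mass must be positive")
  i <- match(cls, bands$coef$class)
  if (any(is.na(i))) stop("unknown fold class: ", paste(cls[is.na(i)], collapse = ", "))
  10^(bands$coef$a[i] + bands$coef$b[i] * log10(mass))
}

#' Classify a measured Stokes radius into a fold class
#'
#' Each class contributes a band `[Rs_theo * (1 - tol), Rs_theo * (1 + tol)]`
#' around its theoretical radius at the given mass. The measurement is
#' assigned to the band that contains it; with several containing bands
#' (neighbouring bands overlap over part of the protein mass range) the
#' class with the nearest center wins and every consistent class is
#' reported; with none, the nearest class is returned flagged as outside
#' all bands.
#'
#' @param rs_measured measured Stokes radius in Angstrom.
#' @param mass molecular mass in Da.
#' @param bands a [fold_class_bands()] object.
#' @return list: `class`, `margin` (relative distance
#'   `|rs - rs_theo| / rs_theo` to the assigned class center),
#'   `inside_band` flag, `consistent` (all classes whose band contains the
#'   measurement), and `theoretical` (named radii for all classes).
#' @export
classify_fold <- function(rs_measured, mass, bands = fold_class_bands()) {
  stopifnot(inherits(bands, "fold_class_bands"))
  if (!is.finite(rs_measured) || rs_measured <= 0) stop("rs_measured must be positive")
  theo <- vapply(bands$coef$class, function(cl) theoretical_rs(mass, cl, bands),
                 numeric(1))
  rel <- abs(rs_measured - theo) / theo
  inside <- rel <= bands$tolerance
  pick <- if (any(inside)) {
    cand <- which(inside)
    cand[which.min(rel[cand])]
  } else which.min(rel)
  list(class = bands$coef$class[pick],
       margin = unname(rel[pick]),
       inside_band = any(inside),
       consistent = bands$coef$class[inside],
       theoretical = theo)
}

#' Calibrate a size-exclusion column
#'
#' Least-squares line of `log10(Rs)` against elution volume (the common
#' Laurent-Killander-style linearization); larger particles elute earlier,
#' so the slope is negative on a sane calibration. A `Kav`-based x-axis is
#' available when the column void and total volumes are known.
#'
#' @param standards data.frame with columns `name`, `rs_angstrom`,
#'   `elution_ml` (at least 3 rows).
#' @param xaxis `"volume"` (default) or `"kav"`; for `"kav"` supply `v0` and
#'   `vt` (mL).
#' @param v0,vt void and total column volume (mL), only for `xaxis = "kav"`.
#' @return object of class `sec_calibration`: `slope`, `intercept`,
#'   `r_squared`, `residual_sd`, `n`, `xaxis`, plus the `lm` fit.
#' @export
calibrate_sec <- function(standards, xaxis = c("volume", "kav"),
                          v0 = NULL, vt = NULL) {
  xaxis <- match.arg(xaxis)
  req <- c("rs_angstrom", "elution_ml")
  if (!all(req %in% names(standards)))
    stop("standards must have columns: ", paste(req, collapse = ", "))
  if (nrow(standards) < 3L) stop("need at least 3 calibration standards")
  if (any(standards$rs_angstrom <= 0) || any(standards$elution_ml <= 0))
    stop("radii and elution volumes must be positive")
  x <- if (xaxis == "kav") {
    if (is.null(v0) || is.null(vt)) stop("kav axis needs v0 and vt")
    (standards$elution_ml - v0) / (vt - v0)
  } else standards$elution_ml
  if (diff(range(x)) < .Machine$double.eps^0.5)
    stop("degenerate calibration: all elution positions identical")
  y <- log10(standards$rs_angstrom)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact lines trip the perfect-fit note
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 residual_sd = sm$sigma,
                 n = nrow(standards), xaxis = xaxis, v0 = v0, vt = vt,
                 fit = fit),
            class = "sec_calibration")
}

#' Stokes radius from an elution volume
#'
#' Inverts a [calibrate_sec()] calibration for a sample's retention volume.
#'
#' @param cal a `sec_calibration`.
#' @param elution_ml retention volume(s) in mL.
#' @return Stokes radius in Angstrom.
#' @export
stokes_from_elution <- function(cal, elution_ml) {
  stopifnot(inherits(cal, "sec_calibration"))
  x <- if (cal$xaxis == "kav") (elution_ml - cal$v0) / (cal$vt - cal$v0)
       else elution_ml
  10^(cal$intercept + cal$slope * x)
}
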