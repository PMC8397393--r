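# Physical constants
AVOGADRO <- 6.02214076e23  # mol^-1
P33_HALF_LIFE_DAYS <- 25.35
MEAN_BP_MASS <- 650        # g/mol per base pair, standard dsDNA average

#' Correct scintillation counts for radioactive decay
#'
#' Rescales measured counts back to the activity at labelling time:
#' `cpm * 2^(elapsed / half_life)`.
#'
#' @param cpm Measured counts per minute.
#' @param elapsed Days elapsed since the reference activity (>= 0).
#' @param half_life Isotope half-life in days (default 25.35, 33P).
#' @return Decay-corrected counts.
#' @export
decay_correct <- function(cpm, elapsed, half_life = P33_HALF_LIFE_DAYS) {
  if (any(elapsed < 0)) stop("`elapsed` must be >= 0", call. = FALSE)
  if (half_life <= 0) stop("`half_life` must be > 0", call. = FALSE)
  cpm * 2^(elapsed / half_life)
}

#' Convert DNA mass concentration to molarity
#'
#' @param ng_ml Concentration in ng/mL.
#' @param length_bp Fragment length in base pairs (>= 1).
#' @param bp_mass Mean molar mass per base pair, g/mol (default 650).
#' @return Concentration in nM.
#' @examples
#' mass_to_molar(100, 688)  # ~0.2236 nM
#' @export
mass_to_molar <- function(ng_ml, length_bp, bp_mass = MEAN_BP_MASS) {
  if (any(length_bp < 1)) stop("`length_bp` must be >= 1", call. = FALSE)
  # ng/mL -> g/L (1e-9 * 1e3), / (g/mol) -> mol/L, * 1e9 -> nM
  ng_ml * 1e-6 / (length_bp * bp_mass) * 1e9
}

#' Convert DNA molarity to mass concentration
#'
#' Inverse of [mass_to_molar()].
#' @param nM Concentration in nM.
#' @inheritParams mass_to_molar
#' @return Concentration in ng/mL.
#' @export
molar_to_mass <- function(nM, length_bp, bp_mass = MEAN_BP_MASS) {
  nM * (length_bp * bp_mass) / 1e3
}

#' Construct a binding dataset
#'
#' Free vs bound ligand concentrations from a saturation binding assay,
#' both in nM.
#'
#' @param free Free DNA concentrations, nM.
#' @param bound Bound DNA concentrations, nM.
#' @param replicate Optional replicate ids.
#' @return A `binding_dataset` data.frame with columns `free`, `bound`,
#'   `replicate`.
#' @export
binding_dataset <- function(free, bound, replicate = NULL) {
  free <- as.numeric(free)
  bound <- as.numeric(bound)
  if (length(free) != length(bound)) {
    stop("`free` and `bound` must have equal length", call. = FALSE)
  }
  if (any(free < 0) || any(bound < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (is.null(replicate)) replicate <- rep(1L, length(free))
  structure(
    data.frame(free = free, bound = bound, replicate = replicate),
    class = c("binding_dataset", "data.frame")
  )
}

#' Fit a saturation binding isotherm
#'
#' `method = "langmuir"` fits `B = Bmax * F / (Kd + F)` by nonlinear least
#' squares (port algorithm, positivity-bounded, started at
#' `Bmax0 = 1.2 * max(B)`, `Kd0 = median(F)`). `method = "scatchard"` fits
#' ordinary least squares of `B/F` against `B`; the slope is `-1/Kd` and
#' the intercept `Bmax/Kd`, with parameter standard errors propagated from
#' the coefficient covariance by the delta method. Points with `F = 0` are
#' dropped from the Scatchard fit with a warning.
#'
#' @param data A [binding_dataset()] or data.frame with columns `free` and
#'   `bound` (nM).
#' @param method `"langmuir"` (default) or `"scatchard"`.
#' @return A `binding_fit` object: list with `Kd`, `Kd_se`, `Bmax`,
#'   `Bmax_se` (nM), `method`, `residuals`, `fitted`, `n`.
#' @export
fit_binding <- function(data, method = c("langmuir", "scatchard")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), all(c("free", "bound") %in% names(data)))
  Fc <- data$free
  B <- data$bound
  if (length(unique(Fc)) < 4L) {
    stop("need at least 4 distinct free concentrations", call. = FALSE)
  }
  if (method == "langmuir") {
    df <- data.frame(Fc = Fc, B = B)
    start <- list(Bmax = max(B) * 1.2, Kd = stats::median(Fc))
    fit <- tryCatch(
      stats::nls(B ~ Bmax * Fc / (Kd + Fc), data = df, start = start,
                 algorithm = "port", lower = c(Bmax = 1e-12, Kd = 1e-12)),
      error = function(e) {
        stop("langmuir fit did not converge (start Bmax=",
             signif(start$Bmax, 4), ", Kd=", signif(start$Kd, 4), "): ",
             conditionMessage(e), call. = FALSE)
      }
    )
    sm <- summary(fit)
    co <- sm$coefficients
    out <- list(Kd = co["Kd", "Estimate"], Kd_se = co["Kd", "Std. Error"],
                Bmax = co["Bmax", "Estimate"],
                Bmax_se = co["Bmax", "Std. Error"],
                method = "langmuir_nls",
                residuals = as.numeric(stats::residuals(fit)),
                fitted = as.numeric(stats::fitted(fit)), n = length(B))
  } else {
    keep <- Fc > 0
    if (any(!keep)) {
      warning("dropping ", sum(!keep), " point(s) with free = 0 from the ",
              "Scatchard fit", call. = FALSE)
    }
    Fc <- Fc[keep]; B <- B[keep]
    y <- B / Fc
    fit <- stats::lm(y ~ B)
    sl <- stats::coef(fit)[["B"]]
    ic <- stats::coef(fit)[["(Intercept)"]]
    if (sl >= 0) {
      stop("Scatchard slope is non-negative; data do not describe ",
           "saturable binding", call. = FALSE)
    }
    # noiseless validation data triggers the perfect-fit warning; the SEs
    # (0 to machine precision) are still what we want to report
    V <- withCallingHandlers(
      stats::vcov(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    Kd <- -1 / sl
    Bmax <- -ic / sl
    # delta method: Kd = -1/sl, Bmax = -ic/sl
    gK <- c(0, 1 / sl^2)
    gB <- c(-1 / sl, ic / sl^2)
    out <- list(Kd = Kd, Kd_se = sqrt(drop(t(gK) %*% V %*% gK)),
                Bmax = Bmax, Bmax_se = sqrt(drop(t(gB) %*% V %*% gB)),
                method = "scatchard_ols",
                residuals = as.numeric(stats::residuals(fit)),
                fitted = as.numeric(stats::fitted(fit)), n = length(B))
  }
  structure(out, class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit %s> Kd = %.4g +/- %.2g nM, Bmax = %.4g +/- %.2g nM (n = %d)\n",
              x$method, x$Kd, x$Kd_se, x$Bmax, x$Bmax_se, x$n))
  invisible(x)
}

#' Bound DNA molecules per cell
#'
#' Converts a maximum binding concentration into a per-cell molecule count:
#' `Bmax (mol/L) * N_A / cells per litre`, rounded to the nearest integer.
#'
#' @param bmax_nM Maximum binding concentration, nM.
#' @param cells_per_ml Cell density, cells/mL.
#' @return Molecules per cell (integer-valued numeric).
#' @examples
#' molecules_per_cell(2.2, 1e8)  # ~13,249
#' @export
molecules_per_cell <- function(bmax_nM, cells_per_ml) {
  if (any(cells_per_ml <= 0)) stop("`cells_per_ml` must be > 0", call. = FALSE)
  round(bmax_nM * 1e-9 * AVOGADRO / (cells_per_ml * 1e3))
}

#' Cell and DNA-footprint geometry
#'
#' @param diameter_um Cell (cylinder) diameter, um.
#' @param length_um Cell length, um.
#' @param footprint_nm DNA footprint `c(width, length)` in nm.
#' @param cells_per_ml Optional cell density, cells/mL.
#' @return A `cell_geometry` list.
#' @export
cell_geometry <- function(diameter_um = 1, length_um = 2,
                          footprint_nm = c(2, 234), cells_per_ml = 1e8) {
  stopifnot(diameter_um > 0, length_um > 0, all(footprint_nm > 0),
            length(footprint_nm) == 2L)
  structure(list(diameter_um = diameter_um, length_um = length_um,
                 footprint_nm = footprint_nm, cells_per_ml = cells_per_ml),
            class = "cell_geometry")
}

#' Fraction of the cell surface covered by bound DNA
#'
#' The cell is modelled as a cylinder; only the lateral surface
#' `pi * d * L` counts (end caps excluded). Coverage may exceed 1 and is
#' reported as-is with a warning.
#'
#' @param geometry A [cell_geometry()].
#' @param n_molecules Number of bound DNA molecules (>= 0).
#' @return Coverage fraction.
#' @examples
#' coverage_fraction(cell_geometry(), 13250)  # > 0.9
#' @export
coverage_fraction <- function(geometry, n_molecules) {
  stopifnot(inherits(geometry, "cell_geometry"), n_molecules >= 0)
  area_nm2 <- pi * (geometry$diameter_um * 1e3) * (geometry$length_um * 1e3)
  footprint <- prod(geometry$footprint_nm)
  frac <- n_molecules * footprint / area_nm2
  if (frac > 1) warning("coverage fraction exceeds 1 (", signif(frac, 3),
                        "); molecules would overlap", call. = FALSE)
  frac
}

#' Contour length of a DNA fragment
#'
#' @param length_bp Fragment length, base pairs (>= 1).
#' @param rise_per_bp Helical rise per base pair, nm (default 0.34, B-DNA).
#' @return Contour length, nm.
#' @examples
#' contour_length(688)  # ~234 nm
#' @export
contour_length <- function(length_bp, rise_per_bp = 0.34) {
  if (any(length_bp < 1)) stop("`length_bp` must be >= 1", call. = FALSE)
  length_bp * rise_per_bp
}

#' Free eDNA expressed as a fraction of the cell population
#'
#' Divides the eDNA mass per mL by the mass of one genome, then by the cell
#' density: the number of genome-equivalents of free DNA per cell.
#'
#' @param edna_ng_ml Free eDNA concentration, ng/mL.
#' @param genome_bp Genome size, base pairs.
#' @param cells_per_ml Cell density, cells/mL.
#' @param bp_mass Mean molar mass per base pair, g/mol (default 650).
#' @return Fraction (genome equivalents per cell).
#' @examples
#' edna_population_fraction(60, 6e6, 1e9)  # ~0.0093, i.e. ~1%
#' @export
edna_population_fraction <- function(edna_ng_ml, genome_bp, cells_per_ml,
                                     bp_mass = MEAN_BP_MASS) {
  stopifnot(edna_ng_ml >= 0, genome_bp > 0, cells_per_ml > 0, bp_mass > 0)
  genome_mass_g <- genome_bp * bp_mass / AVOGADRO
  (edna_ng_ml * 1e-9 / genome_mass_g) / cells_per_ml
}
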