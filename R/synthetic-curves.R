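# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. Generators are pure functions of
# (recipe, seed).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

KT_PN_NM <- 4.11  # thermal energy at 297 K, pN nm

#' Recipe for synthetic force curves
#'
#' Describes a family of AFM force-distance curves with analytic ground
#' truth: Gaussian baseline noise, an optional linear drift, a constant
#' compliance contact region crossing zero force at `z = 0`, an optional
#' jump-to-contact on approach, and a list of rupture events on retraction.
#'
#' @param baseline_sd Baseline noise sd, pN (>= 0; default 5 makes event
#'   detection nontrivial without drowning rupture forces).
#' @param drift_slope Linear baseline drift, pN/nm (default 0).
#' @param compliance_slope Contact-region stiffness, pN/nm (default 50).
#' @param contact_depth Indentation depth represented in the trace, nm
#'   (z runs from `-contact_depth`; default 2).
#' @param jump_to_contact `NULL`, or `list(distance = nm, depth = pN)` for
#'   the approach snap-in.
#' @param repulsion `NULL`, or `list(onset = nm, amplitude = pN)`: an
#'   exponentially decaying repulsive tail on approach.
#' @param ruptures List of rupture events for the retraction, each
#'   `list(position = nm, force = pN, model = "linear_ramp"|"rect"|"wlc",
#'   width = nm (rect), persistence = nm (wlc), start = nm (optional))`.
#'   Ramps load from `start` (default: the previous rupture position, or
#'   0) and detach instantaneously at `position`.
#' @param scale_sdlog Per-curve lognormal spread (sdlog) applied to all
#'   rupture forces, mean-one so expected work matches the recipe
#'   (default 0: identical curves).
#' @param scale_min Lower bound on the per-curve scale (default 0). Presets
#'   use it to keep every scripted rupture above the noise floor, where an
#'   "event" is physically meaningful.
#' @param no_binding_fraction Fraction of curves drawn with no ruptures at
#'   all (default 0).
#' @param force_range Instrument force range, pN; a rupture deeper than
#'   this is a recipe error (default 20000).
#' @param n_points Points per segment (default 1024).
#' @param z_range Maximum piezo distance, nm (default 500, a typical
#'   force distance).
#' @param spring_constant Cantilever spring constant, pN/nm (default 40).
#' @param seed Default seed for [gen_force_curves()].
#' @return A `curve_recipe` list.
#' @seealso [curve_recipe_preset()] for cation-condition presets.
#' @export
curve_recipe <- function(baseline_sd = 5, drift_slope = 0,
                         compliance_slope = 50, contact_depth = 2,
                         jump_to_contact = NULL, repulsion = NULL,
                         ruptures = list(), scale_sdlog = 0, scale_min = 0,
                         no_binding_fraction = 0, force_range = 20000,
                         n_points = 1024L, z_range = 500,
                         spring_constant = 40, seed = 1L) {
  stopifnot(baseline_sd >= 0, compliance_slope > 0, contact_depth > 0,
            n_points >= 64L, z_range > 0,
            no_binding_fraction >= 0, no_binding_fraction <= 1)
  for (r in ruptures) {
    stopifnot(is.list(r), !is.null(r$position), !is.null(r$force))
    if (r$position <= 0 || r$position > z_range) {
      stop("rupture position ", r$position, " nm outside (0, z_range]",
           call. = FALSE)
    }
    if (r$force > force_range) {
      stop("rupture force ", r$force, " pN exceeds the force range (",
           force_range, " pN)", call. = FALSE)
    }
    if (identical(r$model, "wlc") &&
        (is.null(r$persistence) || r$persistence <= 0)) {
      stop("wlc rupture needs a positive persistence length", call. = FALSE)
    }
  }
  if (length(ruptures) >= 1L) {
    pos <- vapply(ruptures, `[[`, numeric(1), "position")
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("rupture positions must be strictly increasing", call. = FALSE)
    }
    prev <- 0
    for (r in ruptures) {
      start <- if (is.null(r$start)) prev else r$start
      if (start < prev || start >= r$position) {
        stop("rupture start ", start, " nm must lie in [previous position, ",
             "position)", call. = FALSE)
      }
      prev <- r$position
    }
  }
  if (!is.null(jump_to_contact)) {
    stopifnot(jump_to_contact$distance > 0, jump_to_contact$depth > 0)
  }
  structure(as.list(environment()), class = "curve_recipe")
}

#' Preset curve recipes for the measured cation conditions
#'
#' Calcium presets show a single deep pull-off whose mean work matches the
#' measured scale (34 aJ at 1 mM, 138 aJ at 10 mM) plus a jump-to-contact
#' whose distance tracks the observed repulsion onsets (14.6 and 44.3 nm).
#' Sodium presets show several small ruptures, no snap-in, and a sizeable
#' no-binding fraction, with mean works near the measured 1 aJ (2 mM) and
#' 0.14 aJ (20 mM).
#'
#' @param condition One of `"ca_1mM"`, `"ca_10mM"`, `"na_2mM"`, `"na_20mM"`.
#' @param ... Overrides passed on to [curve_recipe()].
#' @return A `curve_recipe`.
#' @export
curve_recipe_preset <- function(condition = c("ca_1mM", "ca_10mM",
                                              "na_2mM", "na_20mM"), ...) {
  condition <- match.arg(condition)
  args <- switch(condition,
    ca_1mM = list(
      ruptures = list(list(position = 170, force = 400,
                           model = "linear_ramp")),
      jump_to_contact = list(distance = 14.6, depth = 200),
      repulsion = list(onset = 14.6, amplitude = 40),
      scale_sdlog = 0.42, scale_min = 0.15, no_binding_fraction = 0),
    ca_10mM = list(
      ruptures = list(list(position = 300, force = 920,
                           model = "linear_ramp")),
      jump_to_contact = list(distance = 44.3, depth = 300),
      repulsion = list(onset = 44.3, amplitude = 40),
      scale_sdlog = 0.42, scale_min = 0.15, no_binding_fraction = 0),
    na_2mM = list(
      ruptures = list(
        list(position = 10, force = 60, model = "linear_ramp"),
        list(position = 24, force = 80, model = "linear_ramp", start = 14),
        list(position = 43, force = 70, model = "linear_ramp", start = 28)),
      scale_sdlog = 0.3, scale_min = 0.5, no_binding_fraction = 0.3),
    na_20mM = list(
      ruptures = list(
        list(position = 8, force = 40, model = "linear_ramp"),
        list(position = 22, force = 30, model = "linear_ramp", start = 12)),
      scale_sdlog = 0.3, scale_min = 0.5, no_binding_fraction = 0.5)
  )
  do.call(curve_recipe, utils::modifyList(args, list(...)))
}

# WLC force, pN, at extension x for persistence Lp and contour Lc (nm).
wlc_force <- function(x, Lp, Lc) {
  t <- x / Lc
  (KT_PN_NM / Lp) * (1 / (4 * (1 - t)^2) - 0.25 + t)
}

# Analytic integral of wlc_force from 0 to x, pN nm.
wlc_work <- function(x, Lp, Lc) {
  (KT_PN_NM / Lp) *
    (Lc / (4 * (1 - x / Lc)) - Lc / 4 - x / 4 + x^2 / (2 * Lc))
}

# Solve the contour length so that the WLC force at extension X equals f.
wlc_contour_for <- function(X, f, Lp) {
  g <- function(Lc) wlc_force(X, Lp, Lc) - f
  stats::uniroot(g, lower = X * 1.0001, upper = X * 1e3, tol = 1e-10)$root
}

# Noise-free adhesive force contribution of one rupture on grid z, plus its
# analytic area (pN nm) and minimum force. `start` is the anchor of the
# ramp/wlc extension.
rupture_profile <- function(z, r, start, scale) {
  f <- r$force * scale
  model <- if (is.null(r$model)) "linear_ramp" else r$model
  out <- numeric(length(z))
  if (model == "linear_ramp") {
    span <- r$position - start
    sel <- z > start & z <= r$position
    out[sel] <- -f * (z[sel] - start) / span
    area <- f * span / 2
  } else if (model == "rect") {
    w <- r$width
    stopifnot(!is.null(w), w > 0)
    sel <- z > r$position - w & z <= r$position
    out[sel] <- -f
    area <- f * w
  } else if (model == "wlc") {
    X <- r$position - start
    Lc <- wlc_contour_for(X, f, r$persistence)
    sel <- z > start & z <= r$position
    out[sel] <- -wlc_force(z[sel] - start, r$persistence, Lc)
    area <- wlc_work(X, r$persistence, Lc)
  } else {
    stop("unknown rupture model: ", model, call. = FALSE)
  }
  list(force = out, area = area, f_min = f)
}

#' Generate synthetic force curves with ground truth
#'
#' Each curve comprises an approach and a retraction segment on a common z
#' grid from `-contact_depth` to `z_range`. The constant-compliance line
#' crosses zero force exactly at `z = 0`, so generated curves are aligned
#' by construction. Ground truth (adhesion force, work, event count,
#' onsets) is computed analytically from the recipe, never by running the
#' analysis under test.
#'
#' @param recipe A [curve_recipe()].
#' @param n_curves Number of curves to generate.
#' @param seed Seed (defaults to `recipe$seed`).
#' @return List with `curves` (length `2 * n_curves`; approach and retract
#'   [force_curve()]s with ids `c###_approach` / `c###_retract`) and
#'   `truth`, a data.frame with one row per curve: `id`, `binding`,
#'   `work_aJ`, `f_adh_pN`, `n_events`, `onset_nm`, `jtc_nm`.
#' @export
gen_force_curves <- function(recipe, n_curves = 150L, seed = recipe$seed) {
  stopifnot(inherits(recipe, "curve_recipe"), n_curves >= 1L)
  with_seed(seed, {
    z <- seq(-recipe$contact_depth, recipe$z_range,
             length.out = recipe$n_points)
    compliance <- ifelse(z < 0, -recipe$compliance_slope * z, 0)
    curves <- vector("list", 2L * n_curves)
    truth <- vector("list", n_curves)
    for (i in seq_len(n_curves)) {
      id <- sprintf("c%03d", i)
      scale <- if (recipe$scale_sdlog > 0) {
        max(exp(stats::rnorm(1, -recipe$scale_sdlog^2 / 2,
                             recipe$scale_sdlog)),
            recipe$scale_min)
      } else 1
      binding <- length(recipe$ruptures) > 0L &&
        stats::runif(1) >= recipe$no_binding_fraction

      base_r <- recipe$drift_slope * z +
        stats::rnorm(length(z), 0, recipe$baseline_sd)
      f_ret <- base_r + compliance
      area <- 0; f_adh <- 0; n_ev <- 0L; onset <- NA_real_
      if (binding) {
        start <- 0
        for (r in recipe$ruptures) {
          if (!is.null(r$start)) start <- r$start
          rp <- rupture_profile(z, r, start, scale)
          f_ret <- f_ret + rp$force
          area <- area + rp$area
          f_adh <- max(f_adh, rp$f_min)
          start <- r$position
        }
        n_ev <- length(recipe$ruptures)
        onset <- max(vapply(recipe$ruptures, `[[`, numeric(1), "position"))
      }

      base_a <- recipe$drift_slope * z +
        stats::rnorm(length(z), 0, recipe$baseline_sd)
      f_app <- base_a + compliance
      jtc <- NA_real_
      if (!is.null(recipe$repulsion)) {
        lam <- recipe$repulsion$onset / 1.2
        f_app <- f_app + ifelse(z >= 0,
                                recipe$repulsion$amplitude * exp(-z / lam), 0)
      }
      if (!is.null(recipe$jump_to_contact)) {
        d <- recipe$jump_to_contact$distance
        f_app <- f_app + ifelse(z >= 0 & z <= d,
                                -recipe$jump_to_contact$depth, 0)
        jtc <- d
      }

      curves[[2L * i - 1L]] <- force_curve(
        z, f_app, segment = "approach",
        spring_constant = recipe$spring_constant,
        id = paste0(id, "_approach"))
      curves[[2L * i]] <- force_curve(
        z, f_ret, segment = "retract",
        spring_constant = recipe$spring_constant,
        id = paste0(id, "_retract"))
      curves[[2L * i - 1L]]$aligned <- TRUE
      curves[[2L * i]]$aligned <- TRUE
      truth[[i]] <- data.frame(
        id = id, binding = binding, work_aJ = area / 1000,
        f_adh_pN = f_adh, n_events = if (binding) n_ev else 0L,
        onset_nm = onset, jtc_nm = jtc, stringsAsFactors = FALSE)
    }
    list(curves = curves, truth = do.call(rbind, truth))
  })
}
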