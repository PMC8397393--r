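#' Estimate the non-interacting baseline of a force curve
#'
#' The baseline is taken over the farthest `window_fraction` of points by
#' piezo distance, where the tip is distant from the surface and no
#' interaction is evident.
#'
#' @param curve A [force_curve()].
#' @param window_fraction Fraction of points (from the far end) used for the
#'   baseline, in (0, 0.5]. Default 0.25.
#' @return An object of class `afm_baseline`: list with `mean` (pN), `sd`
#'   (pN) and `window` (`c(z_lo, z_hi)` in nm).
#' @export
estimate_baseline <- function(curve, window_fraction = 0.25) {
  stopifnot(inherits(curve, "force_curve"))
  if (window_fraction <= 0 || window_fraction > 0.5) {
    stop("`window_fraction` must be in (0, 0.5]", call. = FALSE)
  }
  n <- length(curve$z)
  nw <- floor(n * window_fraction)
  if (nw < 8L) {
    stop("baseline window has ", nw, " points; need at least 8", call. = FALSE)
  }
  idx <- seq.int(n - nw + 1L, n)  # z is sorted ascending: far end is the tail
  f <- curve$force[idx]
  structure(
    list(mean = mean(f), sd = stats::sd(f),
         window = c(curve$z[idx[1L]], curve$z[n])),
    class = "afm_baseline"
  )
}

#' @export
print.afm_baseline <- function(x, ...) {
  cat(sprintf("<afm_baseline> mean %.4g pN, sd %.4g pN, window [%.4g, %.4g] nm\n",
              x$mean, x$sd, x$window[1], x$window[2]))
  invisible(x)
}

# Locate the constant-compliance (contact) region: the contiguous run of
# points at the near end of the trace whose baseline-subtracted force stays
# above +m*sd. Returns integer indices or NULL when the curve never contacts.
find_compliance_region <- function(z, f, sd, m = 3) {
  thr <- m * sd
  above <- f > thr
  if (!above[1L]) return(NULL)
  end <- which(!above)[1L]
  idx <- if (is.na(end)) seq_along(z) else seq_len(end - 1L)
  if (length(idx) < 4L) return(NULL)
  idx
}

#' Align a force curve vertically and horizontally
#'
#' Vertical alignment subtracts the baseline mean from all forces.
#' Horizontal alignment fits a least-squares line to the steepest contiguous
#' 20% of the constant-compliance region and shifts `z` so that this line
#' crosses zero force at `z = 0`. Curves with no detectable compliance
#' region (no contact) receive the vertical alignment only and are flagged
#' with `contact = FALSE`.
#'
#' @param curve A [force_curve()].
#' @param baseline An [estimate_baseline()] result; computed with defaults
#'   when `NULL`.
#' @param m Multiplier on the baseline sd used to delimit the compliance
#'   region (default 3).
#' @param compliance_fraction Fraction of the compliance region, chosen as
#'   the steepest contiguous window, used for the regression (default 0.2).
#' @return The aligned `force_curve` with `aligned = TRUE` and
#'   `contact = TRUE/FALSE`. Alignment is idempotent on noiseless data.
#' @export
align_curve <- function(curve, baseline = NULL, m = 3,
                        compliance_fraction = 0.2) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(baseline)) baseline <- estimate_baseline(curve)
  f <- curve$force - baseline$mean
  z <- curve$z
  comp <- find_compliance_region(z, f, baseline$sd, m = m)
  if (is.null(comp)) {
    out <- curve
    out$force <- f
    out$aligned <- TRUE
    out$contact <- FALSE
    return(out)
  }
  # steepest contiguous window within the compliance run
  nwin <- max(3L, ceiling(length(comp) * compliance_fraction))
  nwin <- min(nwin, length(comp))
  best <- NULL
  best_slope <- -Inf
  for (s in seq_len(length(comp) - nwin + 1L)) {
    w <- comp[s:(s + nwin - 1L)]
    sl <- abs(stats::cov(z[w], f[w]) / stats::var(z[w]))
    if (is.finite(sl) && sl > best_slope) {
      best_slope <- sl
      best <- w
    }
  }
  fit <- stats::lm.fit(cbind(1, z[best]), f[best])
  a <- fit$coefficients[1L]
  b <- fit$coefficients[2L]
  out <- curve
  out$force <- f
  if (is.finite(b) && b != 0) {
    z0 <- -a / b                 # compliance line crosses F = 0 here
    out$z <- z - z0
    out$contact <- TRUE
  } else {
    out$contact <- FALSE
  }
  out$aligned <- TRUE
  out
}

#' Detect the onset of tip-surface interaction
#'
#' Scanning from far to near, returns the piezo distance of the first point
#' of the first run of at least `k` consecutive points whose force deviates
#' from the baseline mean by more than `m` standard deviations.
#'
#' @param curve An aligned [force_curve()].
#' @param baseline An [estimate_baseline()] result (its `sd` sets the
#'   threshold; its `mean` is 0 after alignment).
#' @param k Run length (default 4).
#' @param m Threshold multiplier (default 3).
#' @return Onset distance in nm, or `NA_real_` when no qualifying run exists.
#' @export
detect_onset <- function(curve, baseline = NULL, k = 4L, m = 3) {
  stopifnot(inherits(curve, "force_curve"))
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (m <= 0) stop("`m` must be > 0", call. = FALSE)
  if (is.null(baseline)) baseline <- estimate_baseline(curve)
  if (baseline$sd <= 0) stop("baseline sd must be > 0 for onset detection",
                             call. = FALSE)
  mu <- if (isTRUE(curve$aligned)) 0 else baseline$mean
  out_of_band <- abs(curve$force - mu) > m * baseline$sd
  # far-to-near scan: reverse so index 1 is the farthest point
  x <- rev(out_of_band)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0L) return(NA_real_)
  first <- starts[hit[1L]]               # first point of the run, scan order
  rev(curve$z)[first]
}

#' Adhesion force of a retraction curve
#'
#' The magnitude of the global force minimum; 0 when the curve never drops
#' below the zero-force line. Ties resolve to the smallest `z`.
#'
#' @param retraction An aligned retraction [force_curve()].
#' @return Adhesion force in pN (non-negative).
#' @export
adhesion_force <- function(retraction) {
  stopifnot(inherits(retraction, "force_curve"))
  max(0, -min(retraction$force))
}

#' Work of adhesion of a retraction curve
#'
#' Trapezoidal integral of the area between the curve and the zero-force
#' line over its sub-zero excursions: `W = -integral(min(F, 0)) dz`,
#' reported in aJ (1 aJ = 1000 pN nm). Positive-force regions contribute
#' nothing via the clamp.
#'
#' @param retraction An aligned retraction [force_curve()].
#' @param z_max Optional upper integration limit in nm (default `Inf`, the
#'   whole trace). The batch pipeline passes the detected interaction onset
#'   here so that far-field noise does not accumulate into the integral.
#' @return Work in aJ (non-negative).
#' @export
work_of_adhesion <- function(retraction, z_max = Inf) {
  stopifnot(inherits(retraction, "force_curve"))
  keep <- retraction$z <= z_max
  z <- retraction$z[keep]
  f <- pmin(retraction$force[keep], 0)
  if (length(z) < 2L) return(0)
  area <- sum(diff(z) * (f[-1L] + f[-length(f)]) / 2)
  max(0, -area) / 1000
}

#' Count rupture events on a retraction curve
#'
#' Hysteresis event detector, scanning from the surface outward, applied
#' to a lightly smoothed trace (running mean over `smooth_points` points;
#' smoothing suppresses threshold chatter where a slow ramp crosses the
#' noise band). An event arms when `min_points` consecutive points lie
#' below `-m * sd` (the run requirement keeps isolated noise spikes from
#' registering); while armed, the running event depth is the deepest force
#' seen. The event releases when the force recovers by at least
#' `release_fraction` of that depth for `min_points` consecutive points
#' (or the trace ends). Events whose minima are closer than
#' `min_separation` are merged into the deeper one.
#'
#' @param retraction An aligned retraction [force_curve()].
#' @param baseline An [estimate_baseline()] result.
#' @param min_separation Minimum z spacing between distinct event minima,
#'   nm (default 2).
#' @param release_fraction Required fractional force recovery (relative to
#'   the event depth) that ends an event (default 0.5).
#' @param m Depth threshold multiplier on the baseline sd (default 3).
#' @param min_points Consecutive points required to arm or release an
#'   event (default 3).
#' @param smooth_points Running-mean window, points (default 5; 1 disables
#'   smoothing).
#' @return Integer event count (0 for curves never below the threshold).
#' @export
count_events <- function(retraction, baseline = NULL, min_separation = 2,
                         release_fraction = 0.5, m = 3, min_points = 3L,
                         smooth_points = 5L) {
  stopifnot(inherits(retraction, "force_curve"))
  if (is.null(baseline)) baseline <- estimate_baseline(retraction)
  if (release_fraction <= 0 || release_fraction > 1) {
    stop("`release_fraction` must be in (0, 1]", call. = FALSE)
  }
  thr <- m * baseline$sd
  z <- retraction$z
  f <- retraction$force
  if (smooth_points > 1L) {
    sm <- as.numeric(stats::filter(f, rep(1 / smooth_points, smooth_points),
                                   sides = 2))
    f <- ifelse(is.na(sm), f, sm)
  }
  n <- length(f)
  minima_z <- numeric(0)
  minima_f <- numeric(0)
  in_event <- FALSE
  run_in <- 0L
  run_out <- 0L
  depth <- 0
  zmin <- NA_real_
  fmin <- 0
  for (i in seq_len(n)) {
    if (!in_event) {
      run_in <- if (f[i] < -thr) run_in + 1L else 0L
      if (run_in >= min_points) {
        in_event <- TRUE
        run_out <- 0L
        j0 <- i - run_in + 1L
        fmin <- min(f[j0:i])
        zmin <- z[j0:i][which.min(f[j0:i])]
        depth <- -fmin
      }
    } else {
      if (f[i] < fmin) {
        fmin <- f[i]
        zmin <- z[i]
        depth <- -fmin
      }
      released <- f[i] >= fmin + release_fraction * depth
      run_out <- if (released) run_out + 1L else 0L
      if (run_out >= min_points) {
        minima_z <- c(minima_z, zmin)
        minima_f <- c(minima_f, fmin)
        in_event <- FALSE
        run_in <- 0L
      }
    }
  }
  if (in_event) {
    minima_z <- c(minima_z, zmin)
    minima_f <- c(minima_f, fmin)
  }
  if (length(minima_z) == 0L) return(0L)
  # merge events whose minima are closer than min_separation (keep deeper)
  ord <- order(minima_f)
  keep_z <- numeric(0)
  for (i in ord) {
    if (all(abs(minima_z[i] - keep_z) >= min_separation) ||
        length(keep_z) == 0L) {
      keep_z <- c(keep_z, minima_z[i])
    }
  }
  length(keep_z)
}

#' Jump-to-contact distance on an approach curve
#'
#' Scanning from far to near, the first point where the force drops below
#' `-m * sd` and the local force gradient toward the surface exceeds
#' `snap_slope` marks the attractive snap of the tip to the surface. The
#' reported distance is the last stable point before the snap.
#'
#' @param approach An aligned approach [force_curve()].
#' @param baseline An [estimate_baseline()] result.
#' @param m Threshold multiplier (default 3).
#' @param snap_slope Minimum force gradient `dF/dz` across the snap, pN/nm
#'   (default 10).
#' @param min_points Consecutive sub-threshold points (at and inside the
#'   candidate) required for the attractive well to qualify, keeping
#'   single-point noise coincidences from registering as a snap (default 3).
#' @return Jump-to-contact distance in nm, or `NA_real_` when no snap-in is
#'   present (typical of monotone repulsive approaches).
#' @export
jump_to_contact <- function(approach, baseline = NULL, m = 3, snap_slope = 10,
                            min_points = 3L) {
  stopifnot(inherits(approach, "force_curve"))
  if (is.null(baseline)) baseline <- estimate_baseline(approach)
  z <- approach$z
  f <- approach$force
  n <- length(z)
  thr <- m * baseline$sd
  below <- f < -thr
  # consecutive sub-threshold run ending at each point (well interior)
  runlen <- Reduce(function(acc, b) if (b) acc + 1L else 0L, below,
                   accumulate = TRUE)
  # forward difference toward larger z at each point
  slope <- c((f[-1L] - f[-n]) / (z[-1L] - z[-n]), NA_real_)
  hit <- which(below & slope > snap_slope & runlen >= min_points)
  if (length(hit) == 0L) return(NA_real_)
  i <- max(hit)  # farthest from the surface = first met scanning far-to-near
  if (i < n) z[i + 1L] else z[i]
}

#' Analyze a batch of force curves
#'
#' Runs the full single-curve pipeline: baseline estimation, vertical and
#' horizontal alignment, onset detection, adhesion force, work of adhesion,
#' event census on retractions, and jump-to-contact on approaches. The work
#' integral is restricted to the detected interaction region (z at or below
#' the onset); a retraction with no detected onset is scored as
#' non-binding with zero work and zero events.
#'
#' @param curves A list of [force_curve()] objects (approach and/or retract
#'   segments; metrics are per input curve).
#' @param window_fraction,k,m,min_separation,release_fraction,snap_slope
#'   Analysis parameters; see the individual stage functions.
#' @return A data.frame with one row per curve: `id`, `segment`, `contact`,
#'   `F_adh_pN`, `W_adh_aJ`, `n_events`, `onset_z_nm`,
#'   `jump_to_contact_z_nm`, `interaction_range_nm`.
#' @export
analyze_curves <- function(curves, window_fraction = 0.25, k = 4L, m = 3,
                           min_separation = 2, release_fraction = 0.5,
                           snap_slope = 10) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    stopifnot(inherits(cv, "force_curve"))
    bl <- estimate_baseline(cv, window_fraction)
    al <- align_curve(cv, bl, m = m)
    onset <- detect_onset(al, bl, k = k, m = m)
    row <- data.frame(
      id = if (is.null(cv$id)) sprintf("curve%03d", i) else as.character(cv$id),
      segment = cv$segment, contact = isTRUE(al$contact),
      F_adh_pN = NA_real_, W_adh_aJ = NA_real_, n_events = NA_integer_,
      onset_z_nm = onset, jump_to_contact_z_nm = NA_real_,
      interaction_range_nm = if (is.na(onset)) 0 else onset,
      stringsAsFactors = FALSE
    )
    if (cv$segment == "retract") {
      n_ev <- if (is.na(onset)) 0L else {
        count_events(al, bl, min_separation = min_separation,
                     release_fraction = release_fraction, m = m)
      }
      row$n_events <- n_ev
      if (n_ev == 0L) {
        # no rupture event: non-binding curve, zero adhesion by definition
        # (keeps W > 0 implying n_events >= 1)
        row$F_adh_pN <- 0
        row$W_adh_aJ <- 0
      } else {
        row$F_adh_pN <- adhesion_force(al)
        row$W_adh_aJ <- work_of_adhesion(al, z_max = onset)
      }
    } else {
      row$jump_to_contact_z_nm <- jump_to_contact(al, bl, m = m,
                                                  snap_slope = snap_slope)
    }
    row
  })
  do.call(rbind, rows)
}

#' Summarize a set of per-curve adhesion metrics
#'
#' @param metrics A data.frame as returned by [analyze_curves()] (retraction
#'   rows are used for force/work/event statistics; approach rows for
#'   jump-to-contact).
#' @return An object of class `curve_set_summary`: data.frame of
#'   `metric`, `mean`, `sd`, `se`, `n` with the no-binding fraction (share
#'   of retractions with zero work) as attribute `no_binding_fraction`.
#' @export
summarize_curves <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1L)
  cols <- c(F_adh_pN = "F_adh_pN", W_adh_aJ = "W_adh_aJ",
            n_events = "n_events", onset_z_nm = "onset_z_nm",
            jump_to_contact_z_nm = "jump_to_contact_z_nm")
  rows <- lapply(names(cols), function(nm) {
    x <- metrics[[cols[[nm]]]]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) {
      return(data.frame(metric = nm, mean = NA_real_, sd = NA_real_,
                        se = NA_real_, n = 0L, stringsAsFactors = FALSE))
    }
    s <- if (n > 1L) stats::sd(x) else 0
    data.frame(metric = nm, mean = mean(x), sd = s, se = s / sqrt(n), n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  w <- metrics$W_adh_aJ[metrics$segment == "retract"]
  w <- w[!is.na(w)]
  attr(out, "no_binding_fraction") <- if (length(w)) mean(w == 0) else NA_real_
  class(out) <- c("curve_set_summary", "data.frame")
  out
}

#' @export
print.curve_set_summary <- function(x, ...) {
  cat("<curve_set_summary>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("no-binding fraction: %.3f\n", attr(x, "no_binding_fraction")))
  invisible(x)
}
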