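# Fixture builders shared across the suite. All fixtures are constructed
# in code; no data files.

# A noiseless curve with a linear compliance region (slope `stiffness`
# crossing F = 0 at z = 0) and optional extra force added on top.
make_contact_curve <- function(z = seq(-5, 100, length.out = 256),
                               stiffness = 100, extra = 0) {
  f <- ifelse(z < 0, -stiffness * z, 0) + extra
  force_curve(z, f, segment = "retract")
}

# Piecewise-linear retraction through the given (z, F) vertices, sampled
# so every vertex is on the grid (trapezoid integration is then exact).
make_polyline_curve <- function(zv, fv, points_per_seg = 16L) {
  z <- numeric(0)
  f <- numeric(0)
  for (i in seq_len(length(zv) - 1L)) {
    zz <- seq(zv[i], zv[i + 1L], length.out = points_per_seg)
    ff <- seq(fv[i], fv[i + 1L], length.out = points_per_seg)
    if (i > 1L) { zz <- zz[-1L]; ff <- ff[-1L] }
    z <- c(z, zz)
    f <- c(f, ff)
  }
  force_curve(z, f, segment = "retract")
}

# Baseline object with known parameters (bypasses estimation).
fixed_baseline <- function(mean = 0, sd = 1, window = c(0, 1)) {
  structure(list(mean = mean, sd = sd, window = window),
            class = "afm_baseline")
}

# One-frame trajectory from explicit atom positions/roles.
make_frame_traj <- function(pos, role, charge = NULL, element = NULL,
                            box = c(50, 50, 50), nframes = 1L, dt = 50) {
  n <- nrow(pos)
  if (is.null(charge)) {
    charge <- ifelse(role == "cation", 2, ifelse(role == "other", 0, -1))
  }
  if (is.null(element)) {
    element <- c(cation = "Ca", phosphate_O = "OP", silica_O = "OS",
                 other = "X")[role]
  }
  md_trajectory(rep(list(pos), nframes), element, charge, role, box,
                frame_interval = dt, surface_ref_z = 0)
}
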