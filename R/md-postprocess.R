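#' Perpendicular charge-density profile
#'
#' Charge-weighted histogram of atom heights above the silica surface
#' reference plane, averaged over frames. Heights are wrapped by the
#' minimum-image convention into `[-lz/2, lz/2)`, so the profile integral
#' (sum of bin value times bin width) equals the total charge of the
#' selection exactly.
#'
#' @param traj An [md_trajectory()].
#' @param selection Atom selection: a role name (e.g. `"cation"`), element
#'   name, logical mask or index vector.
#' @param bin_width Bin width, Angstrom (default 0.25).
#' @return A `density_profile` data.frame with columns `z_lo`, `z_hi`,
#'   `z_mid` (Angstrom above the surface plane) and `charge_density`
#'   (e/Angstrom, per-frame average).
#' @export
charge_density <- function(traj, selection, bin_width = 0.25) {
  stopifnot(inherits(traj, "md_trajectory"), bin_width > 0)
  idx <- resolve_selection(traj, selection)
  lz <- traj$box[3L]
  edges <- seq(-lz / 2, lz / 2, by = bin_width)
  if (max(edges) < lz / 2) edges <- c(edges, max(edges) + bin_width)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  q <- traj$charge[idx]
  for (fr in traj$frames) {
    dz <- min_image(fr[idx, 3L] - traj$surface_ref_z, lz)
    bin <- pmin(pmax(floor((dz + lz / 2) / bin_width) + 1L, 1L), nb)
    acc <- acc + as.numeric(tapply(q, factor(bin, levels = seq_len(nb)), sum,
                                   default = 0))
  }
  dens <- acc / (length(traj$frames) * bin_width)
  structure(
    data.frame(z_lo = edges[-length(edges)], z_hi = edges[-1L],
               z_mid = (edges[-length(edges)] + edges[-1L]) / 2,
               charge_density = dens),
    class = c("density_profile", "data.frame")
  )
}

#' Profile integral (total charge of the selection)
#' @param profile A [charge_density()] result.
#' @return Total charge, e.
#' @export
profile_total_charge <- function(profile) {
  sum(profile$charge_density * (profile$z_hi - profile$z_lo))
}

#' Per-frame centre-of-mass separation along the surface normal
#'
#' @param traj An [md_trajectory()].
#' @param group_a,group_b Atom selections (see [charge_density()]).
#' @param masses Optional per-atom masses for mass weighting; equal weights
#'   when `NULL`.
#' @return Numeric vector, one `|z_a - z_b|` per frame, in nm
#'   (minimum image along z).
#' @export
com_separation <- function(traj, group_a, group_b, masses = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  ia <- resolve_selection(traj, group_a)
  ib <- resolve_selection(traj, group_b)
  wa <- if (is.null(masses)) rep(1, length(ia)) else masses[ia]
  wb <- if (is.null(masses)) rep(1, length(ib)) else masses[ib]
  lz <- traj$box[3L]
  vapply(traj$frames, function(fr) {
    za <- sum(fr[ia, 3L] * wa) / sum(wa)
    zb <- sum(fr[ib, 3L] * wb) / sum(wb)
    abs(min_image(za - zb, lz)) / 10
  }, numeric(1))
}

#' Solvation-shell cutoffs for a cation-oxygen pair
#'
#' The first- and second-shell cutoff radii are the first and second minima
#' of the cation-oxygen radial distribution function. Defaults are typical
#' RDF minima for Na-O (3.2 / 5.6 Angstrom) and Ca-O (3.0 / 5.2 Angstrom);
#' use [pair_rdf()] to derive values from a specific trajectory.
#'
#' @param cation `"Na"` or `"Ca"` (sets default cutoffs), or any label with
#'   explicit `r1`, `r2`.
#' @param r1 First-shell cutoff, Angstrom.
#' @param r2 Second-shell cutoff, Angstrom (> r1).
#' @return A `shell_spec` list.
#' @export
shell_spec <- function(cation = c("Na", "Ca"), r1 = NULL, r2 = NULL) {
  if (is.null(r1) || is.null(r2)) {
    cation <- match.arg(cation)
    defaults <- list(Na = c(3.2, 5.6), Ca = c(3.0, 5.2))[[cation]]
    if (is.null(r1)) r1 <- defaults[1L]
    if (is.null(r2)) r2 <- defaults[2L]
  }
  if (!(r1 > 0 && r2 > r1)) stop("need 0 < r1 < r2", call. = FALSE)
  structure(list(cation = as.character(cation)[1L], r1 = r1, r2 = r2),
            class = "shell_spec")
}

#' Classify an oxygen atom into a cation's solvation shell
#'
#' First shell: distance `<= r1` (closed upper bound); second shell:
#' `r1 <` distance `<= r2`; otherwise `"none"`. Distances use the periodic
#' minimum image when `box` is given.
#'
#' @param cation_pos Length-3 cation position, Angstrom.
#' @param oxygen_pos Length-3 position or n x 3 matrix of oxygen positions.
#' @param spec A [shell_spec()].
#' @param box Optional box lengths for periodic wrapping.
#' @return Character vector of `"1st"`, `"2nd"` or `"none"`.
#' @export
classify_shell <- function(cation_pos, oxygen_pos, spec, box = NULL) {
  stopifnot(inherits(spec, "shell_spec"))
  if (is.null(dim(oxygen_pos))) oxygen_pos <- matrix(oxygen_pos, ncol = 3L)
  d <- if (is.null(box)) {
    sqrt(rowSums(sweep(oxygen_pos, 2L, cation_pos)^2))
  } else {
    min_image_dist(cation_pos, oxygen_pos, box)
  }
  ifelse(d <= spec$r1, "1st", ifelse(d <= spec$r2, "2nd", "none"))
}

#' Find cation bridges in one frame
#'
#' A bridge is an O(phosphate)-cation-O(silica) triplet in which the cation
#' holds both oxygens within its second solvation shell. Each triplet is
#' labelled by the shell pair `"<phosphate shell>-<silica shell>"`.
#'
#' @param traj An [md_trajectory()].
#' @param frame Frame index.
#' @param spec A [shell_spec()].
#' @return A data.frame with columns `cation`, `phosphate_O`, `silica_O`
#'   (atom indices) and `shell_pair`; zero rows when no bridge is present.
#' @export
find_bridges <- function(traj, frame = 1L, spec) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(spec, "shell_spec"))
  pos <- traj$frames[[frame]]
  ications <- which(traj$role == "cation")
  ip <- which(traj$role == "phosphate_O")
  is <- which(traj$role == "silica_O")
  out <- list()
  for (ic in ications) {
    if (length(ip) == 0L || length(is) == 0L) break
    sp <- classify_shell(pos[ic, ], pos[ip, , drop = FALSE], spec, traj$box)
    ss <- classify_shell(pos[ic, ], pos[is, , drop = FALSE], spec, traj$box)
    jp <- which(sp != "none")
    js <- which(ss != "none")
    if (length(jp) == 0L || length(js) == 0L) next
    grid <- expand.grid(p = jp, s = js)
    out[[length(out) + 1L]] <- data.frame(
      cation = ic, phosphate_O = ip[grid$p], silica_O = is[grid$s],
      shell_pair = paste(sp[grid$p], ss[grid$s], sep = "-"),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(cation = integer(0), phosphate_O = integer(0),
                      silica_O = integer(0), shell_pair = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

SHELL_PAIRS <- c("1st-1st", "1st-2nd", "2nd-1st", "2nd-2nd")

#' Census of cation bridges by shell pair and lifetime
#'
#' Tracks each O(phosphate)-cation-O(silica) triplet identity across
#' frames. A triplet's lifetime is its longest contiguous run of frames
#' (a disappearance longer than `gap` frames ends the run; default 0, i.e.
#' strict continuity) times the frame interval. Each unique triplet is
#' counted under a threshold `T` if its lifetime is at least `T`, in the
#' shell-pair row given by its modal label over the run.
#'
#' @param traj An [md_trajectory()].
#' @param spec A [shell_spec()].
#' @param thresholds Lifetime thresholds, ps (default `c(50, 200, 500)`).
#' @param gap Number of consecutive absent frames tolerated inside a run
#'   (default 0).
#' @return A `bridge_census` object: 4 x length(thresholds) integer matrix
#'   (rows `1st-1st`, `1st-2nd`, `2nd-1st`, `2nd-2nd`).
#' @export
bridge_census <- function(traj, spec, thresholds = c(50, 200, 500), gap = 0L) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(spec, "shell_spec"))
  thresholds <- sort(thresholds)
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (traj$frame_interval > min(thresholds)) {
    stop("frame interval (", traj$frame_interval,
         " ps) is too coarse for the ", min(thresholds), " ps threshold",
         call. = FALSE)
  }
  nf <- n_frames(traj)
  # presence[[key]] = integer frame indices; labels[[key]] = shell pairs
  presence <- list()
  labels <- list()
  for (f in seq_len(nf)) {
    br <- find_bridges(traj, f, spec)
    if (nrow(br) == 0L) next
    keys <- paste(br$cation, br$phosphate_O, br$silica_O, sep = ":")
    for (j in seq_along(keys)) {
      k <- keys[j]
      presence[[k]] <- c(presence[[k]], f)
      labels[[k]] <- c(labels[[k]], br$shell_pair[j])
    }
  }
  counts <- matrix(0L, nrow = length(SHELL_PAIRS), ncol = length(thresholds),
                   dimnames = list(SHELL_PAIRS, paste0(thresholds, "ps")))
  for (k in names(presence)) {
    fs <- presence[[k]]
    lb <- labels[[k]]
    # split into runs allowing `gap` missing frames
    brk <- which(diff(fs) > gap + 1L)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(fs))
    run_len <- vapply(seq_along(starts),
                      function(i) length(starts[i]:ends[i]), integer(1))
    best <- which.max(run_len)
    run_idx <- starts[best]:ends[best]
    lifetime <- length(run_idx) * traj$frame_interval
    pair_tab <- table(lb[run_idx])
    pair <- names(pair_tab)[which.max(pair_tab)]
    if (!pair %in% SHELL_PAIRS) next
    hit <- thresholds <= lifetime
    counts[pair, hit] <- counts[pair, hit] + 1L
  }
  structure(counts, class = c("bridge_census", class(counts)),
            thresholds = thresholds)
}

#' @export
print.bridge_census <- function(x, ...) {
  cat("<bridge_census> unique complexes by shell pair and lifetime:\n")
  print(unclass(x))
  invisible(x)
}

#' Cation-oxygen radial distribution function
#'
#' Auxiliary routine for deriving [shell_spec()] cutoffs from a trajectory:
#' the number density of selection-b atoms around selection-a atoms,
#' normalised by the ideal-gas expectation in the periodic box.
#'
#' @param traj An [md_trajectory()].
#' @param sel_a,sel_b Atom selections (centres / neighbours).
#' @param r_max Maximum radius, Angstrom.
#' @param dr Bin width, Angstrom.
#' @return Data.frame with `r` (bin centre) and `g` (RDF value).
#' @export
pair_rdf <- function(traj, sel_a, sel_b, r_max = 8, dr = 0.1) {
  stopifnot(inherits(traj, "md_trajectory"), r_max > 0, dr > 0)
  ia <- resolve_selection(traj, sel_a)
  ib <- resolve_selection(traj, sel_b)
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  for (fr in traj$frames) {
    for (i in ia) {
      d <- min_image_dist(fr[i, ], fr[ib, , drop = FALSE], traj$box)
      d <- d[d > 1e-9 & d < r_max]
      if (length(d)) {
        acc <- acc + tabulate(pmin(floor(d / dr) + 1L, nb), nbins = nb)
      }
    }
  }
  rho <- length(ib) / prod(traj$box)
  shell_vol <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  norm <- length(ia) * length(traj$frames) * rho * shell_vol
  data.frame(r = (edges[-1L] + edges[-length(edges)]) / 2, g = acc / norm)
}

#' Construct a binding-energy profile
#'
#' Final configurational energies of a series of simulations against the
#' DNA-slab centre-of-mass separation, shifted so the minimum is zero.
#'
#' @param separation_nm Centre-of-mass separations, nm.
#' @param energy Configurational energies, kJ/mol (any common offset).
#' @return An `energy_profile` data.frame with `separation_nm` and
#'   `energy` (kJ/mol, minimum at 0), sorted by separation.
#' @export
energy_profile <- function(separation_nm, energy) {
  stopifnot(length(separation_nm) == length(energy), length(energy) >= 1L)
  ord <- order(separation_nm)
  structure(
    data.frame(separation_nm = separation_nm[ord],
               energy = energy[ord] - min(energy)),
    class = c("energy_profile", "data.frame")
  )
}

#' Extract the binding energy barrier from an energy profile
#'
#' The far-field reference is the mean energy over points within
#' `far_field_window` nm of the largest separation; the barrier is the
#' profile maximum minus the far-field level, floored at zero. Invariant
#' under a common energy offset.
#'
#' @param profile An [energy_profile()] (or data.frame with
#'   `separation_nm`, `energy`).
#' @param far_field_window Width of the far-field averaging window, nm
#'   (default 0.5).
#' @return List with `barrier` and `far_field`, kJ/mol.
#' @export
energy_barrier <- function(profile, far_field_window = 0.5) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 3L,
            far_field_window > 0)
  e <- profile$energy - min(profile$energy)
  s <- profile$separation_nm
  far <- e[s >= max(s) - far_field_window]
  if (length(far) == 0L) stop("far-field window covers no points",
                              call. = FALSE)
  far_field <- mean(far)
  list(barrier = max(0, max(e) - far_field), far_field = far_field)
}

#' Convert a per-cell binding energy to an interfacial energy density
#'
#' @param energy_kj_mol Binding energy per simulation cell, kJ/mol.
#' @param area_A2 Interfacial area of the cell, Angstrom^2.
#' @return Energy density, mJ/m^2.
#' @examples
#' adhesion_energy_density(800, 49.0 * 39.5)  # ~69 mJ/m^2
#' @export
adhesion_energy_density <- function(energy_kj_mol, area_A2) {
  if (any(area_A2 <= 0)) stop("`area_A2` must be > 0", call. = FALSE)
  energy_kj_mol * 1e3 / AVOGADRO / (area_A2 * 1e-20) * 1e3
}

#' Number of silanol deprotonations needed for a target surface charge
#'
#' @param sigma Surface charge density, e/nm^2.
#' @param lx,ly Lateral cell dimensions, Angstrom.
#' @return Nearest-integer number of protons removed per surface.
#' @examples
#' deprotonation_count(0.835, 49.0, 39.5)  # 16
#' @export
deprotonation_count <- function(sigma, lx, ly) {
  stopifnot(sigma >= 0, lx > 0, ly > 0)
  round(sigma * lx * ly / 100)  # lx*ly A^2 -> nm^2
}

#' Number of cations neutralizing a net charge
#'
#' @param net_charge Net charge to neutralize, e (sign ignored).
#' @param valence Cation valence, 1 or 2.
#' @return Integer cation count.
#' @examples
#' neutralizing_cations(-38, 1)  # 38 Na+
#' neutralizing_cations(-38, 2)  # 19 Ca2+
#' @export
neutralizing_cations <- function(net_charge, valence) {
  if (!valence %in% c(1L, 2L)) stop("`valence` must be 1 or 2", call. = FALSE)
  q <- abs(net_charge)
  if (q %% valence != 0) {
    stop("net charge ", net_charge, " is not divisible by valence ", valence,
         "; no integer cation count exists", call. = FALSE)
  }
  q / valence
}
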