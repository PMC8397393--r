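#' Recipe for a toy slab + cation + polymer trajectory
#'
#' A stylised silica slab (a lateral grid of Si sites with silica oxygens
#' above them), a polymer strand carrying phosphate oxygens parallel to
#' the surface, and mobile cations whose heights follow a prescribed
#' space-charge-layer model. Scripted bridge events place an
#' O(phosphate)-cation-O(silica) triplet at the midpoints of the requested
#' solvation-shell annuli for a chosen time window and keep the partners
#' well separated otherwise, so the bridge census has an exact analytic
#' truth. Atom species are force-field-style labels (`Si`, `OS` silica
#' oxygen, `OP` phosphate oxygen, plus the cation element): element
#' symbols alone cannot distinguish the two oxygen roles.
#'
#' @param box Box lengths `c(lx, ly, lz)`, Angstrom; z is the surface
#'   normal (default `c(49, 39.5, 80)`, the lateral cell of the reference
#'   slab).
#' @param slab_z Height of the top Si plane, Angstrom (default 4).
#' @param cation Cation species: `list(element, valence)` (default Ca2+).
#' @param n_cations Number of free cations (default 19, the count that
#'   neutralises the -38 e cell with divalent ions).
#' @param layer Space-charge-layer model for cation heights above the
#'   slab: `list(model = "gaussian", center, width)` (default center 2.2,
#'   width 0.35: an organised divalent layer) or
#'   `list(model = "uniform", range = c(lo, hi))` (e.g. `c(1, 3.5)` for a
#'   diffuse monovalent layer).
#' @param n_phosphate Phosphate oxygens on the polymer strand (default 22).
#' @param com_offset_nm Height of the polymer strand above the slab plane,
#'   nm (default 3.6, the preferred bound-state separation).
#' @param scripted_bridges Data.frame with columns `start_ps`,
#'   `duration_ps`, `shell_pair` (one of `"1st-1st"`, `"1st-2nd"`,
#'   `"2nd-1st"`, `"2nd-2nd"`; phosphate shell first) and optionally
#'   `triplet` (integer id; windows of the same triplet must not overlap).
#' @param shell A [shell_spec()]; defaults to the cation element's cutoffs.
#' @param frame_interval Frame spacing, ps (default 10).
#' @param n_frames Number of frames (default 200, i.e. 2 ns).
#' @param seed Default seed for [gen_toy_trajectory()].
#' @return A `trajectory_recipe` list.
#' @export
trajectory_recipe <- function(box = c(49, 39.5, 80), slab_z = 4,
                              cation = list(element = "Ca", valence = 2),
                              n_cations = 19L,
                              layer = list(model = "gaussian", center = 2.2,
                                           width = 0.35),
                              n_phosphate = 22L, com_offset_nm = 3.6,
                              scripted_bridges = NULL, shell = NULL,
                              frame_interval = 10, n_frames = 200L,
                              seed = 1L) {
  stopifnot(length(box) == 3L, all(box > 0), slab_z > 0, n_cations >= 0,
            n_phosphate >= 1L, frame_interval > 0, n_frames >= 1L)
  if (!layer$model %in% c("gaussian", "uniform")) {
    stop("layer$model must be 'gaussian' or 'uniform'", call. = FALSE)
  }
  if (is.null(shell)) shell <- shell_spec(cation$element)
  total_ps <- n_frames * frame_interval
  if (!is.null(scripted_bridges)) {
    sb <- scripted_bridges
    stopifnot(all(c("start_ps", "duration_ps", "shell_pair") %in% names(sb)))
    if (!all(sb$shell_pair %in% SHELL_PAIRS)) {
      stop("shell_pair must be one of: ", paste(SHELL_PAIRS, collapse = ", "),
           call. = FALSE)
    }
    if (any(sb$start_ps < 0) || any(sb$start_ps + sb$duration_ps > total_ps)) {
      stop("scripted bridge windows must lie within the simulated time (0-",
           total_ps, " ps)", call. = FALSE)
    }
    if (is.null(sb$triplet)) sb$triplet <- seq_len(nrow(sb))
    for (tid in unique(sb$triplet)) {
      w <- sb[sb$triplet == tid, ]
      if (nrow(w) > 1L) {
        w <- w[order(w$start_ps), ]
        if (any(w$start_ps[-1L] < (w$start_ps + w$duration_ps)[-nrow(w)])) {
          stop("overlapping scripted windows for triplet ", tid,
               call. = FALSE)
        }
      }
    }
    scripted_bridges <- sb
  }
  structure(as.list(environment()), class = "trajectory_recipe")
}

# Distance placed inside a shell: the midpoint of the shell annulus.
shell_mid_distance <- function(shell_label, spec) {
  if (shell_label == "1st") spec$r1 / 2 else (spec$r1 + spec$r2) / 2
}

#' Generate a toy trajectory with scripted ground truth
#'
#' @param recipe A [trajectory_recipe()].
#' @param seed Seed (defaults to `recipe$seed`).
#' @return List with `traj` (an [md_trajectory()]), and `truth`:
#'   `census` (the analytic bridge-census matrix at 50/200/500 ps),
#'   `layer_center` (Angstrom above the slab plane) and `com_nm` (the
#'   scripted slab-polymer separation). Truth is computed from the recipe
#'   alone, never by running the analyses under test.
#' @export
gen_toy_trajectory <- function(recipe, seed = recipe$seed) {
  stopifnot(inherits(recipe, "trajectory_recipe"))
  with_seed(seed, {
    box <- recipe$box
    spec <- recipe$shell
    sb <- recipe$scripted_bridges
    n_scripted <- if (is.null(sb)) 0L else length(unique(sb$triplet))

    # --- static scaffold ------------------------------------------------
    # slab: Si grid at z = slab_z; silica oxygens 0.7 A above each Si.
    gx <- seq(2, box[1] - 2, by = 5)
    gy <- seq(2, box[2] - 2, by = 5)
    si_xy <- as.matrix(expand.grid(x = gx, y = gy))
    n_si <- nrow(si_xy)
    # grid oxygens in the far lateral zone carry the silica_O role; those
    # nearer the polymer/bridge strip stay "other" so free cations settling
    # on the slab cannot form unscripted bridges.
    grid_o_role <- ifelse(si_xy[, 1] >= 20, "silica_O", "other")

    # polymer strand: phosphate oxygens along y at x = 5
    poly_y <- seq(1, box[2] - 1, length.out = recipe$n_phosphate)
    poly_z <- recipe$slab_z + recipe$com_offset_nm * 10

    # dedicated bridge sites at x = 12, spaced along y
    if (n_scripted > 0L) {
      bridge_y <- seq(3, box[2] - 3, length.out = max(n_scripted, 2L))[
        seq_len(n_scripted)]
      if (n_scripted > 1L && min(diff(bridge_y)) <= spec$r2) {
        stop("too many scripted triplets for the box: bridge sites would ",
             "fall within one another's shells", call. = FALSE)
      }
    }

    element <- c(rep("Si", n_si), rep("OS", n_si), rep("OP",
                 recipe$n_phosphate),
                 if (n_scripted) rep("OS", n_scripted),
                 if (n_scripted) rep("OP", n_scripted),
                 rep(recipe$cation$element, recipe$n_cations + n_scripted))
    charge <- c(rep(2.4, n_si), rep(-1.2, n_si),
                rep(-0.8, recipe$n_phosphate),
                if (n_scripted) rep(-1.2, n_scripted),
                if (n_scripted) rep(-0.8, n_scripted),
                rep(recipe$cation$valence, recipe$n_cations + n_scripted))
    role <- c(rep("other", n_si), grid_o_role,
              rep("phosphate_O", recipe$n_phosphate),
              if (n_scripted) rep("silica_O", n_scripted),
              if (n_scripted) rep("phosphate_O", n_scripted),
              rep("cation", recipe$n_cations + n_scripted))
    i_bridge_sO <- if (n_scripted) 2L * n_si + recipe$n_phosphate +
      seq_len(n_scripted) else integer(0)
    i_bridge_pO <- if (n_scripted) 2L * n_si + recipe$n_phosphate +
      n_scripted + seq_len(n_scripted) else integer(0)
    i_free_cat <- 2L * n_si + recipe$n_phosphate + 2L * n_scripted +
      seq_len(recipe$n_cations)
    i_bridge_cat <- 2L * n_si + recipe$n_phosphate + 2L * n_scripted +
      recipe$n_cations + seq_len(n_scripted)
    n_atoms <- 2L * n_si + recipe$n_phosphate + 2L * n_scripted +
      recipe$n_cations + n_scripted

    draw_layer_z <- function(n) {
      dz <- if (recipe$layer$model == "gaussian") {
        stats::rnorm(n, recipe$layer$center, recipe$layer$width)
      } else {
        stats::runif(n, recipe$layer$range[1], recipe$layer$range[2])
      }
      recipe$slab_z + pmin(pmax(dz, 0.1), box[3] - recipe$slab_z - 0.1)
    }

    free_x <- stats::runif(recipe$n_cations, 20, box[1] - 2)
    free_y <- stats::runif(recipe$n_cations, 1, box[2] - 1)

    base <- matrix(0, nrow = n_atoms, ncol = 3L)
    base[seq_len(n_si), ] <- cbind(si_xy, recipe$slab_z)
    base[n_si + seq_len(n_si), ] <- cbind(si_xy, recipe$slab_z + 0.7)
    base[2L * n_si + seq_len(recipe$n_phosphate), ] <-
      cbind(5, poly_y, poly_z)
    if (n_scripted) {
      base[i_bridge_sO, ] <- cbind(12, bridge_y, recipe$slab_z + 0.7)
      # parked positions, reset per frame below
      base[i_bridge_pO, ] <- cbind(5, bridge_y, poly_z)
      base[i_bridge_cat, ] <- cbind(35, bridge_y, recipe$slab_z + 2)
    }

    times <- (seq_len(recipe$n_frames) - 1L) * recipe$frame_interval
    frames <- vector("list", recipe$n_frames)
    for (fidx in seq_len(recipe$n_frames)) {
      pos <- base
      pos[i_free_cat, 1L] <- free_x
      pos[i_free_cat, 2L] <- free_y
      pos[i_free_cat, 3L] <- draw_layer_z(recipe$n_cations)
      if (n_scripted) {
        pos[i_bridge_cat, 3L] <- draw_layer_z(n_scripted)
        t <- times[fidx]
        for (r in seq_len(nrow(sb))) {
          on <- t >= sb$start_ps[r] & t < sb$start_ps[r] + sb$duration_ps[r]
          if (!on) next
          tid <- sb$triplet[r]
          parts <- strsplit(sb$shell_pair[r], "-", fixed = TRUE)[[1L]]
          d_p <- shell_mid_distance(parts[1L], spec)
          d_s <- shell_mid_distance(parts[2L], spec)
          s_pos <- base[i_bridge_sO[tid], ]
          c_pos <- s_pos + c(0, 0, d_s)
          pos[i_bridge_cat[tid], ] <- c_pos
          pos[i_bridge_pO[tid], ] <- c_pos + c(0, 0, d_p)
        }
      }
      frames[[fidx]] <- pos
    }

    traj <- md_trajectory(frames, element, charge, role, box,
                          frame_interval = recipe$frame_interval)

    # --- analytic truth -------------------------------------------------
    thresholds <- c(50, 200, 500)
    census <- matrix(0L, nrow = length(SHELL_PAIRS),
                     ncol = length(thresholds),
                     dimnames = list(SHELL_PAIRS, paste0(thresholds, "ps")))
    if (n_scripted) {
      for (tid in unique(sb$triplet)) {
        w <- sb[sb$triplet == tid, ]
        lifetimes <- vapply(seq_len(nrow(w)), function(r) {
          sum(times >= w$start_ps[r] &
                times < w$start_ps[r] + w$duration_ps[r]) *
            recipe$frame_interval
        }, numeric(1))
        best <- which.max(lifetimes)
        pair <- w$shell_pair[best]
        hit <- thresholds <= lifetimes[best]
        census[pair, hit] <- census[pair, hit] + 1L
      }
    }
    layer_center <- if (recipe$layer$model == "gaussian") {
      recipe$layer$center
    } else {
      mean(recipe$layer$range)
    }
    list(traj = traj,
         truth = list(census = census, layer_center = layer_center,
                      com_nm = recipe$com_offset_nm))
  })
}
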