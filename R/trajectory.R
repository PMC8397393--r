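#' Construct an MD trajectory
#'
#' Ordered frames of typed, charged particles in an orthorhombic periodic
#' box with a silica-surface reference plane. The third coordinate (z) is
#' the surface normal.
#'
#' @param frames List of numeric n x 3 position matrices, Angstrom. All
#'   frames must share atom count and order.
#' @param element Character vector of species labels, length n.
#' @param charge Numeric per-atom charges, e.
#' @param role Character per-atom roles, each one of `"cation"`,
#'   `"phosphate_O"`, `"silica_O"`, `"other"`.
#' @param box Box lengths `c(lx, ly, lz)` in Angstrom.
#' @param frame_interval Time between frames, ps (> 0).
#' @param surface_ref_z Reference z of the silica surface, Angstrom. When
#'   `NULL`, computed as the mean z of the topmost Si atoms (those within
#'   1 Angstrom of the highest Si) in the first frame, or 0 if there are
#'   no Si atoms.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(frames, element, charge, role, box,
                          frame_interval = 1, surface_ref_z = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  n <- nrow(frames[[1L]])
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!is.matrix(fr) || ncol(fr) != 3L) {
      stop("frame ", i, " is not an n x 3 matrix", call. = FALSE)
    }
    if (nrow(fr) != n) {
      stop("atom-count mismatch at frame ", i, ": ", nrow(fr), " vs ", n,
           call. = FALSE)
    }
  }
  stopifnot(length(element) == n, length(charge) == n, length(role) == n)
  bad <- setdiff(unique(role), c("cation", "phosphate_O", "silica_O", "other"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stopifnot(length(box) == 3L, all(box > 0), frame_interval > 0)
  if (is.null(surface_ref_z)) {
    surface_ref_z <- surface_reference_z(frames[[1L]], element)
  }
  structure(
    list(frames = frames, element = as.character(element),
         charge = as.numeric(charge), role = as.character(role),
         box = as.numeric(box), frame_interval = frame_interval,
         surface_ref_z = surface_ref_z),
    class = "md_trajectory"
  )
}

# Mean z of the topmost Si layer (atoms within `slice` Angstrom of the
# highest Si in the frame); 0 when there are no Si atoms.
surface_reference_z <- function(positions, element, slice = 1) {
  zsi <- positions[element == "Si", 3L]
  if (length(zsi) == 0L) return(0)
  mean(zsi[zsi >= max(zsi) - slice])
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d frames x %d atoms, box %.1f x %.1f x %.1f A, dt %.3g ps, surface z = %.3g A\n",
    length(x$frames), length(x$element), x$box[1], x$box[2], x$box[3],
    x$frame_interval, x$surface_ref_z))
  tab <- table(x$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An [md_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

# Resolve a selection to integer atom indices. Accepts a role name, an
# element name, a logical mask or an integer index vector.
resolve_selection <- function(traj, selection) {
  if (is.character(selection) && length(selection) == 1L) {
    idx <- which(traj$role == selection)
    if (length(idx) == 0L) idx <- which(traj$element == selection)
  } else if (is.logical(selection)) {
    idx <- which(selection)
  } else {
    idx <- as.integer(selection)
  }
  if (length(idx) == 0L) {
    stop("selection matches no atoms", call. = FALSE)
  }
  idx
}

# Minimum-image displacement for scalar coordinates under box length L.
min_image <- function(d, L) d - L * round(d / L)

# Minimum-image distance between one point and a matrix of points.
min_image_dist <- function(p, q, box) {
  d <- sweep(q, 2L, p)
  for (k in 1:3) d[, k] <- min_image(d[, k], box[k])
  sqrt(rowSums(d * d))
}
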