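#' Construct a force curve
#'
#' A single approach or retraction trace from an AFM force-distance
#' experiment: piezo displacement `z` (nm, positive away from the surface)
#' against cantilever force `force` (pN), plus probe metadata.
#'
#' @param z Numeric vector of piezo displacements in nm. Sorted ascending on
#'   construction.
#' @param force Numeric vector of forces in pN, same length as `z`.
#' @param segment Either `"approach"` or `"retract"`.
#' @param spring_constant Cantilever spring constant in pN/nm (default 40,
#'   a typical soft contact-mode lever).
#' @param speed Piezo speed in um/s.
#' @param id Optional curve identifier.
#' @return An object of class `force_curve`: a list with elements `z`,
#'   `force`, `segment`, `spring_constant`, `speed`, `id`, and alignment
#'   bookkeeping fields `aligned` (logical) and `contact` (logical or `NA`,
#'   set by [align_curve()]).
#' @examples
#' fc <- force_curve(z = seq(0, 100, length.out = 64), force = rnorm(64, sd = 5))
#' fc
#' @export
force_curve <- function(z, force, segment = c("retract", "approach"),
                        spring_constant = 40, speed = 0.99, id = NULL) {
  segment <- match.arg(segment)
  z <- as.numeric(z)
  force <- as.numeric(force)
  if (length(z) != length(force)) {
    stop("`z` and `force` must have equal length", call. = FALSE)
  }
  if (length(z) < 16L) {
    stop("a force curve needs at least 16 points, got ", length(z),
         call. = FALSE)
  }
  if (any(!is.finite(z)) || any(!is.finite(force))) {
    stop("`z` and `force` must be finite", call. = FALSE)
  }
  if (spring_constant <= 0) stop("`spring_constant` must be > 0", call. = FALSE)
  ord <- order(z)
  structure(
    list(z = z[ord], force = force[ord], segment = segment,
         spring_constant = spring_constant, speed = speed, id = id,
         aligned = FALSE, contact = NA),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve%s> %s segment, %d points, z [%.3g, %.3g] nm, F [%.3g, %.3g] pN%s\n",
    if (is.null(x$id)) "" else paste0(" ", x$id),
    x$segment, length(x$z), min(x$z), max(x$z), min(x$force), max(x$force),
    if (isTRUE(x$aligned)) ", aligned" else ""
  ))
  invisible(x)
}

#' @export
length.force_curve <- function(x) length(x$z)

#' @export
as.data.frame.force_curve <- function(x, ...) {
  data.frame(z = x$z, force = x$force, segment = x$segment,
             stringsAsFactors = FALSE)
}
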