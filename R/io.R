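# Dialect by extension: .tsv/.txt -> tab, .csv -> comma.
infer_dialect <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect != "auto") return(dialect)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
}

read_delim_checked <- function(path, dialect, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("format error: missing column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  df
}

as_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop("parse error: non-numeric value '", x[bad[1L]], "' in column '",
         col, "', data row ", bad[1L], " of ", path, call. = FALSE)
  }
  out
}

#' Read force curves from a delimited text file
#'
#' Expected columns: `distance_nm` (or `distance_um`), `force_pN` (or
#' `force_nN`), `segment` (`approach`/`retract`), and optionally
#' `curve_id`. One [force_curve()] is returned per (curve id, segment),
#' with units converted to nm/pN and rows sorted by distance.
#'
#' @param path File path (`.tsv`/`.txt` tab-separated, `.csv`
#'   comma-separated).
#' @param dialect `"auto"` (by extension, default), `"tsv"` or `"csv"`.
#' @param spring_constant Spring constant attached to each curve, pN/nm.
#' @return List of [force_curve()] objects.
#' @export
read_force_curves <- function(path, dialect = "auto", spring_constant = 40) {
  dialect <- infer_dialect(path, dialect)
  df <- read_delim_checked(path, dialect, required = "segment")
  if ("distance_nm" %in% names(df)) {
    z <- as_numeric_col(df$distance_nm, "distance_nm", path)
  } else if ("distance_um" %in% names(df)) {
    z <- as_numeric_col(df$distance_um, "distance_um", path) * 1e3
  } else {
    stop("format error: missing column(s) distance_nm in ", path,
         call. = FALSE)
  }
  if ("force_pN" %in% names(df)) {
    f <- as_numeric_col(df$force_pN, "force_pN", path)
  } else if ("force_nN" %in% names(df)) {
    f <- as_numeric_col(df$force_nN, "force_nN", path) * 1e3
  } else {
    stop("format error: missing column(s) force_pN in ", path, call. = FALSE)
  }
  seg <- df$segment
  bad <- setdiff(unique(seg), c("approach", "retract"))
  if (length(bad)) {
    stop("format error: unknown segment label(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  id <- if ("curve_id" %in% names(df)) df$curve_id else "curve001"
  key <- paste(id, seg, sep = "\r")
  lapply(split(seq_along(z), factor(key, levels = unique(key))), function(i) {
    force_curve(z[i], f[i], segment = seg[i[1L]],
                spring_constant = spring_constant, id = id[i[1L]])
  })
}

#' Write force curves to a delimited text file
#'
#' @param curves List of [force_curve()] objects.
#' @param path Output path; the extension picks the dialect.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_force_curves <- function(curves, path, dialect = "auto") {
  dialect <- infer_dialect(path, dialect)
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    data.frame(
      curve_id = if (is.null(cv$id)) sprintf("curve%03d", i) else cv$id,
      segment = cv$segment, distance_nm = cv$z, force_pN = cv$force,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  sep <- if (dialect == "csv") "," else "\t"
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build result records
#'
#' The common currency of the command-line pipeline: one row per
#' (stage, input, metric) with value, unit and optional uncertainty.
#'
#' @param stage Stage name (e.g. `"curves"`, `"binding"`, `"md"`).
#' @param id Input identifier.
#' @param metric Metric name.
#' @param value Numeric value.
#' @param unit Unit string.
#' @param uncertainty Optional standard error.
#' @return A `result_record` data.frame.
#' @export
result_record <- function(stage, id, metric, value, unit,
                          uncertainty = NA_real_) {
  structure(
    data.frame(stage = stage, id = id, metric = metric,
               value = as.numeric(value), unit = unit,
               uncertainty = as.numeric(uncertainty),
               stringsAsFactors = FALSE),
    class = c("result_record", "data.frame")
  )
}

RESULT_FIELDS <- c("stage", "id", "metric", "value", "unit", "uncertainty")

#' Write result records to JSON or CSV
#'
#' Field order is fixed and numbers are written at full precision, so a
#' write-read cycle is the identity (to 1e-9 relative on numerics).
#'
#' @param records A data.frame of result records (see [result_record()]).
#' @param path Output path.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  records <- records[, RESULT_FIELDS]
  if (format == "json") {
    jsonlite::write_json(records, path, digits = NA, na = "null",
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(
      format(records, digits = 15, trim = TRUE, scientific = FALSE),
      path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read result records written by [write_results()]
#'
#' @param path File path.
#' @param format `"auto"`, `"json"` or `"csv"`.
#' @return A `result_record` data.frame.
#' @export
read_results <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    df <- jsonlite::fromJSON(path)
    df$value <- as.numeric(df$value)
    if (is.null(df$uncertainty)) df$uncertainty <- NA_real_
    df$uncertainty <- as.numeric(df$uncertainty)
  } else {
    raw <- read_delim_checked(path, "csv", required = RESULT_FIELDS)
    df <- raw
    df$value <- as_numeric_col(raw$value, "value", path)
    df$uncertainty <- suppressWarnings(as.numeric(raw$uncertainty))
  }
  structure(df[, RESULT_FIELDS], class = c("result_record", "data.frame"))
}

#' Default run configuration
#'
#' All tunable analysis parameters with their units and defaults:
#' `seed`; baseline `window_fraction`; onset run length `k` and multiplier
#' `m`; event `min_separation` (nm) and `release_fraction`; `snap_slope`
#' (pN/nm); shell cutoffs `r1`/`r2` (Angstrom); `lifetime_thresholds`
#' (ps); density `bin_width` (Angstrom).
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(seed = 1L, window_fraction = 0.25, k = 4L, m = 3,
       min_separation = 2, release_fraction = 0.5, snap_slope = 10,
       shell = list(cation = "Ca", r1 = 3.0, r2 = 5.2),
       lifetime_thresholds = c(50, 200, 500), bin_width = 0.25)
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys take the [default_config()]
#' values; invariants (k >= 1, m > 0, ascending positive lifetime
#' thresholds, r1 < r2) are validated.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Named list of parameters.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg <- utils::modifyList(cfg, user)
  }
  if (cfg$k < 1L) stop("config: k must be >= 1", call. = FALSE)
  if (cfg$m <= 0) stop("config: m must be > 0", call. = FALSE)
  lt <- cfg$lifetime_thresholds
  if (any(lt <= 0) || is.unsorted(lt, strictly = TRUE)) {
    stop("config: lifetime thresholds must be positive and ascending",
         call. = FALSE)
  }
  if (!(cfg$shell$r1 > 0 && cfg$shell$r2 > cfg$shell$r1)) {
    stop("config: shell cutoffs need 0 < r1 < r2", call. = FALSE)
  }
  cfg
}

#' Read a species map
#'
#' YAML mapping from species label to `{charge, role}`, e.g.
#' `Ca: {charge: 2, role: cation}`.
#'
#' @param path YAML file path.
#' @return Data.frame with columns `species`, `charge`, `role`.
#' @export
read_species_map <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(names(raw), function(sp) {
    e <- raw[[sp]]
    if (is.null(e$charge) || is.null(e$role)) {
      stop("species map entry '", sp, "' needs charge and role",
           call. = FALSE)
    }
    data.frame(species = sp, charge = as.numeric(e$charge),
               role = as.character(e$role), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj An [md_trajectory()].
#' @param path Output path.
#' @param digits Coordinate decimals (default 4; round trips to 1e-3 A).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 4) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(traj$element)
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d t= %.6g ps", i,
                       (i - 1) * traj$frame_interval), con)
    writeLines(sprintf(fmt, traj$element, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file (all frames must share atom count and order).
#' @param species_map Data.frame from [read_species_map()], or a named
#'   list of `list(charge, role)` entries.
#' @param box Box lengths `c(lx, ly, lz)`, Angstrom.
#' @param frame_interval Frame spacing, ps.
#' @param surface_ref_z Optional surface reference height.
#' @return An [md_trajectory()].
#' @export
read_xyz_trajectory <- function(path, species_map, box, frame_interval = 1,
                                surface_ref_z = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  frames <- list()
  element <- NULL
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("format error: bad atom count at line ", i,
                       call. = FALSE)
    fidx <- fidx + 1L
    if (i + 1L + n > length(lines)) {
      stop("format error: truncated frame ", fidx, call. = FALSE)
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    el <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(element)) {
      element <- el
    } else if (length(el) != length(element)) {
      stop("format error: atom-count mismatch at frame ", fidx,
           call. = FALSE)
    }
    frames[[fidx]] <- unname(xyz)
    i <- i + 2L + n
  }
  apply_species_map(frames, element, species_map, box, frame_interval,
                    surface_ref_z)
}

apply_species_map <- function(frames, element, species_map, box,
                              frame_interval, surface_ref_z) {
  if (is.data.frame(species_map)) {
    map <- stats::setNames(
      lapply(seq_len(nrow(species_map)), function(i) {
        list(charge = species_map$charge[i], role = species_map$role[i])
      }), species_map$species)
  } else {
    map <- species_map
  }
  absent <- setdiff(unique(element), names(map))
  if (length(absent)) {
    stop("configuration error: species absent from map: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  charge <- vapply(element, function(e) map[[e]]$charge, numeric(1))
  role <- vapply(element, function(e) map[[e]]$role, character(1))
  md_trajectory(frames, element, unname(charge), unname(role), box,
                frame_interval = frame_interval,
                surface_ref_z = surface_ref_z)
}

#' Write a trajectory as a multi-MODEL PDB
#'
#' @inheritParams write_xyz_trajectory
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1",
                     traj$box[1], traj$box[2], traj$box[3]), con)
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s MOL A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(fr)), substr(traj$element, 1, 4), fr[, 1], fr[, 2],
      fr[, 3], substr(traj$element, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-MODEL PDB trajectory
#'
#' Atom species are taken from the PDB atom-name field (columns 13-16).
#'
#' @inheritParams read_xyz_trajectory
#' @return An [md_trajectory()].
#' @export
read_pdb_trajectory <- function(path, species_map, box, frame_interval = 1,
                                surface_ref_z = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  frames <- list()
  element <- NULL
  cur <- NULL
  cur_el <- character(0)
  fidx <- 0L
  flush_model <- function() {
    if (is.null(cur) || nrow(cur) == 0L) return()
    fidx <<- fidx + 1L
    if (is.null(element)) {
      element <<- cur_el
    } else if (length(cur_el) != length(element)) {
      stop("format error: atom-count mismatch at frame ", fidx,
           call. = FALSE)
    }
    frames[[fidx]] <<- cur
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "MODEL ") {
      cur <- matrix(numeric(0), ncol = 3L)
      cur_el <- character(0)
    } else if (tag == "ENDMDL") {
      flush_model()
      cur <- NULL
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      if (is.null(cur)) { cur <- matrix(numeric(0), ncol = 3L) }
      xyz <- as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                          substr(ln, 47, 54)))
      if (any(is.na(xyz))) {
        stop("format error: bad coordinates in record: ", ln, call. = FALSE)
      }
      cur <- rbind(cur, xyz)
      cur_el <- c(cur_el, trimws(substr(ln, 13, 16)))
    }
  }
  flush_model()  # tolerate a final MODEL without ENDMDL
  if (length(frames) == 0L) stop("no MODEL records found in ", path,
                                 call. = FALSE)
  frames <- lapply(frames, function(m) {
    dimnames(m) <- NULL
    m
  })
  apply_species_map(frames, element, species_map, box, frame_interval,
                    surface_ref_z)
}
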