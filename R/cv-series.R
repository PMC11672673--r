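# Collective-variable time series container and I/O.

#' Collective-variable time series
#'
#' @param values numeric samples: dihedral angles in degrees (circular) or
#'   distances in nm (linear); >= 2 samples
#' @param frame_dt time between samples (ps)
#' @param circular is the variable an angle? Circular series are wrapped to
#'   (-180, 180].
#' @param replica_id identifier of the replica the series came from
#' @return Object of class `cv_series`.
#' @export
cv_series <- function(values, frame_dt, circular = FALSE,
                      replica_id = NA_integer_) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (anyNA(values)) stop("NA values in series", call. = FALSE)
  stopifnot(is.numeric(frame_dt), frame_dt > 0)
  if (circular) values <- wrap_angle(values)
  structure(list(values = values, frame_dt = frame_dt, circular = circular,
                 replica_id = replica_id),
            class = "cv_series")
}

#' Wrap angles to (-180, 180] degrees
#'
#' @param theta angles in degrees
#' @return Wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- theta %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("CV series: %d samples, frame_dt = %g ps, %s%s\n",
              length(x$values), x$frame_dt,
              if (x$circular) "circular (deg)" else "linear",
              if (is.na(x$replica_id)) "" else
                paste0(", replica ", x$replica_id)))
  invisible(x)
}

#' Read a GROMACS XVG table
#'
#' Skips `@` and `#` header lines and parses the remaining whitespace
#' -separated numeric columns.
#'
#' @param path XVG file path
#' @return Numeric matrix (one row per data line).
#' @export
read_xvg <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[!grepl("^\\s*[@#]", lines) &
                        nzchar(trimws(lines))]
  if (length(data_lines) == 0L) {
    stop("parse error in ", path, ": no data lines", call. = FALSE)
  }
  parsed <- lapply(strsplit(trimws(data_lines), "[[:space:]]+"), as.numeric)
  ncols <- lengths(parsed)
  if (length(unique(ncols)) != 1L || anyNA(unlist(parsed))) {
    bad <- which(ncols != ncols[1] | vapply(parsed, anyNA, logical(1)))[1]
    stop("parse error in ", path, " at data line ", bad, call. = FALSE)
  }
  do.call(rbind, parsed)
}

#' Read a collective-variable series from XVG or CSV
#'
#' XVG: first column is time (ps), second the value. CSV: columns
#' `time_ps` and `value`, or a single `value` column (then `frame_dt` is
#' required).
#'
#' @param path file path (`.xvg` or `.csv`)
#' @param circular is the variable an angle?
#' @param frame_dt frame spacing (ps); inferred from the time column if
#'   absent
#' @param replica_id replica identifier
#' @return A [cv_series()].
#' @export
read_cv_series <- function(path, circular = FALSE, frame_dt = NULL,
                           replica_id = NA_integer_) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xvg") {
    m <- read_xvg(path)
    if (ncol(m) < 2L) stop("parse error in ", path,
                           ": need time and value columns", call. = FALSE)
    tvec <- m[, 1]
    vals <- m[, 2]
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if ("value" %in% names(df)) {
      vals <- df$value
      tvec <- if ("time_ps" %in% names(df)) df$time_ps else NULL
    } else {
      stop("parse error in ", path, ": no 'value' column", call. = FALSE)
    }
  }
  if (is.null(frame_dt)) {
    if (is.null(tvec) || length(tvec) < 2L) {
      stop("frame_dt not given and no time column in ", path, call. = FALSE)
    }
    frame_dt <- stats::median(diff(tvec))
  }
  cv_series(vals, frame_dt, circular = circular, replica_id = replica_id)
}
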