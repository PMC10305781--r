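#' Construct a motion trace
#'
#' A `motion_trace` holds uniformly sampled 3D marker trajectories in
#' millimetres, in a right-handed coordinate frame, with time in seconds from
#' a shared zero.
#'
#' @param time numeric vector of frame times (s), uniformly spaced.
#' @param markers named list of n-by-3 numeric matrices (columns x, y, z in mm),
#'   one per marker, all with `length(time)` rows.
#' @param rate sampling rate in Hz; defaults to the rate implied by `time`.
#' @return an object of class `motion_trace`.
#' @export
motion_trace <- function(time, markers, rate = NULL) {
  stopifnot(is.numeric(time), is.list(markers), length(names(markers)) == length(markers))
  n <- length(time)
  if (n > 1L && !is_uniform(time)) stop("non-uniform timestamps in motion trace")
  for (nm in names(markers)) {
    m <- markers[[nm]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != n)
      stop("marker '", nm, "' must be an n-by-3 matrix matching the time base")
    markers[[nm]] <- unname(m)
  }
  if (is.null(rate)) rate <- if (n > 1L) 1 / (time[2L] - time[1L]) else NA_real_
  structure(list(time = as.numeric(time), markers = markers, rate = rate),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames @ %g Hz, %d markers: %s\n",
              length(x$time), x$rate, length(x$markers),
              paste(names(x$markers), collapse = ", ")))
  invisible(x)
}

n_frames <- function(trace) length(trace$time)

require_markers <- function(trace, needed) {
  missing <- setdiff(needed, names(trace$markers))
  if (length(missing))
    stop("required marker(s) missing from trace: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Write a motion trace to marker TSV
#'
#' The dialect is a plain tab-separated text format modelled on optical-capture
#' exports: four header lines (`MARKER_TSV`, `FREQUENCY`, `NO_OF_FRAMES`,
#' `MARKER_NAMES`), a column-header row, then one row per frame with the frame
#' index followed by x/y/z per marker in mm. Missing samples are written as the
#' sentinel `NULL`. Coordinates are written with 17 significant digits so the
#' round trip through [read_motion()] is bit-exact.
#'
#' @param trace a [motion_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  n <- n_frames(trace)
  nm <- names(trace$markers)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MARKER_TSV\t1",
    sprintf("FREQUENCY\t%s", format(trace$rate, digits = 17)),
    sprintf("NO_OF_FRAMES\t%d", n),
    paste(c("MARKER_NAMES", nm), collapse = "\t"),
    paste(c("frame", as.vector(t(outer(nm, c("_x", "_y", "_z"), paste0)))), collapse = "\t")
  ), con)
  if (n > 0L) {
    body <- do.call(cbind, lapply(trace$markers, identity))
    txt <- matrix(sprintf("%.17g", body), nrow = n)
    txt[!is.finite(body)] <- "NULL"
    writeLines(paste(seq_len(n) - 1L, apply(txt, 1L, paste, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a motion trace from marker TSV
#'
#' @param path file in the dialect written by [write_motion()].
#' @return a [motion_trace()]; gap frames read back as `NA` (downstream
#'   kinematics reject non-finite coordinates).
#' @export
read_motion <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5L) stop("malformed marker TSV header (fewer than 5 lines): ", path)
  hdr <- strsplit(lines[1:5], "\t", fixed = TRUE)
  if (hdr[[1L]][1L] != "MARKER_TSV") stop("line 1: missing MARKER_TSV magic")
  if (hdr[[2L]][1L] != "FREQUENCY") stop("line 2: missing FREQUENCY")
  rate <- as.numeric(hdr[[2L]][2L])
  if (!is.finite(rate) || rate <= 0) stop("line 2: bad FREQUENCY value")
  if (hdr[[3L]][1L] != "NO_OF_FRAMES") stop("line 3: missing NO_OF_FRAMES")
  nf <- as.integer(hdr[[3L]][2L])
  if (hdr[[4L]][1L] != "MARKER_NAMES") stop("line 4: missing MARKER_NAMES")
  nm <- hdr[[4L]][-1L]
  if (!length(nm)) stop("line 4: no marker names declared")
  expected_cols <- c("frame", as.vector(t(outer(nm, c("_x", "_y", "_z"), paste0))))
  if (!identical(hdr[[5L]], expected_cols)) {
    got <- hdr[[5L]][-1L]
    miss <- setdiff(expected_cols[-1L], got)
    if (length(miss)) stop("line 5: missing marker column(s): ", paste(miss, collapse = ", "))
    stop("line 5: column header does not match declared markers")
  }
  body <- lines[-(1:5)]
  body <- body[nzchar(body)]
  if (length(body) != nf)
    stop("declared NO_OF_FRAMES (", nf, ") does not match body rows (", length(body), ")")
  markers <- stats::setNames(rep(list(matrix(numeric(0), 0L, 3L)), length(nm)), nm)
  if (nf > 0L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    ncol_exp <- 1L + 3L * length(nm)
    bad <- which(lengths(parts) != ncol_exp)
    if (length(bad)) stop("line ", 5L + bad[1L], ": expected ", ncol_exp,
                          " columns, got ", lengths(parts)[bad[1L]])
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))), nrow = ncol_exp)
    vals <- t(m[-1L, , drop = FALSE])
    for (i in seq_along(nm))
      markers[[i]] <- vals[, (3L * i - 2L):(3L * i), drop = FALSE]
  }
  motion_trace(time = (seq_len(nf) - 1L) / rate, markers = markers, rate = rate)
}
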