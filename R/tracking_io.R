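# Tracking-table construction, validation, calibration and the velocity matrix.

new_tracking_table <- function(df, group, trial, condition, units, fps) {
  structure(
    df,
    group = group, trial = trial, condition = condition,
    units = units, fps = fps,
    class = c("tracking_table", "data.frame")
  )
}

validate_tracking_table <- function(df, path = "<tracking table>", min_frames = 150L) {
  if (!"frame" %in% names(df)) {
    stop(sprintf("%s: missing `frame` column", path), call. = FALSE)
  }
  coord_cols <- setdiff(names(df), "frame")
  xs <- grep("^id[0-9]+_x$", coord_cols, value = TRUE)
  ys <- grep("^id[0-9]+_y$", coord_cols, value = TRUE)
  if (length(xs) == 0L || length(xs) != length(ys) ||
      length(coord_cols) != length(xs) + length(ys)) {
    stop(sprintf("%s: coordinate columns must come in idN_x/idN_y pairs", path),
         call. = FALSE)
  }
  if (nrow(df) < min_frames) {
    stop(sprintf("%s: insufficient frames (%d < %d)", path, nrow(df), min_frames),
         call. = FALSE)
  }
  d <- diff(df$frame)
  if (any(d != 1)) {
    at <- which(d != 1)[1]
    stop(sprintf("%s: frame gap at row %d (frame %s -> %s)", path, at + 1L,
                 df$frame[at], df$frame[at + 1L]), call. = FALSE)
  }
  for (cc in coord_cols) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-finite coordinate in column `%s`, row %d", path, cc, bad[1]),
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a tracking-coordinate CSV
#'
#' Reads one group-trial of multi-animal tracking coordinates in the dialect
#' `frame,id0_x,id0_y,...,idN_x,idN_y` (0-based frames, video convention:
#' origin top-left, y increasing downward). Metadata (group, trial, condition,
#' units, fps) comes from a `manifest.json` sidecar in the same directory (as
#' written by [write_fixture()]) or from the `meta` argument. The table is
#' validated: frame indices must be gap-free, at least 150 frames must cover
#' the analysis window and all coordinates must be finite.
#'
#' @param path Path to the CSV file.
#' @param meta Optional named list overriding the sidecar: `group`, `trial`,
#'   `condition`, `units` ("px" or "cm"), `fps`, optionally `pixels_per_cm`.
#' @param min_frames Minimum frames required (3 intervals x 10 s x 5 fps).
#' @return A `tracking_table` (data.frame with metadata attributes).
#' @export
read_tracking <- function(path, meta = NULL, min_frames = 150L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(meta)) {
    mpath <- file.path(dirname(path), "manifest.json")
    if (!file.exists(mpath)) {
      stop(sprintf("%s: no metadata - provide `meta` or a manifest.json sidecar", path),
           call. = FALSE)
    }
    man <- jsonlite::read_json(mpath)
    hit <- Filter(function(f) identical(f$file, basename(path)), man$files)
    if (length(hit) == 0L) {
      stop(sprintf("%s: not listed in manifest.json", path), call. = FALSE)
    }
    meta <- hit[[1]]
  }
  for (f in c("group", "trial", "units", "fps")) {
    if (is.null(meta[[f]])) stop(sprintf("%s: metadata field `%s` missing", path, f),
                                 call. = FALSE)
  }
  if (!meta$units %in% c("px", "cm")) {
    stop(sprintf("%s: units must be 'px' or 'cm'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  validate_tracking_table(df, path = path, min_frames = min_frames)
  tab <- new_tracking_table(
    df, group = meta$group, trial = meta$trial,
    condition = meta$condition %||% NA_character_,
    units = meta$units, fps = meta$fps
  )
  if (!is.null(meta$pixels_per_cm)) attr(tab, "pixels_per_cm") <- meta$pixels_per_cm
  tab
}

#' Pixel-to-centimetre calibration
#'
#' Builds a calibration from either a known pixel scale or a measured pixel
#' span of the tank's inner long side (20.0-20.5 cm in this assay).
#'
#' @param pixels_per_cm Pixels per centimetre (positive), or NULL to derive it.
#' @param pixels_span Measured pixel length of the reference side.
#' @param source_length_cm True length of the reference side in cm.
#' @return A list of class `calibration_spec`.
#' @examples
#' calibration_spec(pixels_span = 400, source_length_cm = 20.0) # 20 px/cm
#' @export
calibration_spec <- function(pixels_per_cm = NULL, pixels_span = NULL,
                             source_length_cm = NULL) {
  if (is.null(pixels_per_cm)) {
    if (is.null(pixels_span) || is.null(source_length_cm)) {
      stop("provide `pixels_per_cm` or both `pixels_span` and `source_length_cm`",
           call. = FALSE)
    }
    if (source_length_cm <= 0) stop("`source_length_cm` must be positive", call. = FALSE)
    pixels_per_cm <- pixels_span / source_length_cm
  }
  if (!is.numeric(pixels_per_cm) || length(pixels_per_cm) != 1L ||
      !is.finite(pixels_per_cm) || pixels_per_cm <= 0) {
    stop("`pixels_per_cm` must be a positive number", call. = FALSE)
  }
  if (!is.null(source_length_cm) &&
      (source_length_cm < 20.0 || source_length_cm > 20.5)) {
    warning("`source_length_cm` outside the tank's nominal 20.0-20.5 cm range")
  }
  structure(list(pixels_per_cm = pixels_per_cm,
                 source_length_cm = source_length_cm),
            class = "calibration_spec")
}

#' Convert a tracking table from pixels to centimetres
#'
#' Divides every coordinate by `cal$pixels_per_cm` and flips the unit flag.
#' Calling it on a table already in cm is a warning no-op (idempotent).
#'
#' @param table A `tracking_table`.
#' @param cal A [calibration_spec()].
#' @return The table in cm units.
#' @export
calibrate <- function(table, cal) {
  stopifnot(inherits(table, "tracking_table"))
  if (!inherits(cal, "calibration_spec")) cal <- do.call(calibration_spec, as.list(cal))
  units <- attr(table, "units")
  if (units == "cm") {
    warning("table already in cm; calibrate() is a no-op")
    return(table)
  }
  coord_cols <- setdiff(names(table), "frame")
  out <- table
  for (cc in coord_cols) out[[cc]] <- out[[cc]] / cal$pixels_per_cm
  attr(out, "units") <- "cm"
  out
}

#' Per-individual raw swimming speed
#'
#' Speed at frame i is the Euclidean displacement from frame i-1 to i times
#' the frame rate (cm/s). The first frame's speed is duplicated from frame 2
#' so the series keeps one value per frame.
#'
#' @param table A `tracking_table` in cm units.
#' @return Numeric matrix, one row per individual (rownames `id0`, `id1`,
#'   ...), one column per frame.
#' @examples
#' # a fish moving 0.2 cm between consecutive frames at 5 fps swims 1 cm/s
#' @export
compute_speed <- function(table) {
  stopifnot(inherits(table, "tracking_table"))
  if (attr(table, "units") != "cm") {
    stop("coordinates are in pixels: calibrate first", call. = FALSE)
  }
  fps <- attr(table, "fps")
  xs <- grep("^id[0-9]+_x$", names(table), value = TRUE)
  ids <- sub("_x$", "", xs)
  n <- nrow(table)
  out <- matrix(NA_real_, nrow = length(ids), ncol = n,
                dimnames = list(ids, NULL))
  for (j in seq_along(ids)) {
    dx <- diff(table[[paste0(ids[j], "_x")]])
    dy <- diff(table[[paste0(ids[j], "_y")]])
    sp <- sqrt(dx^2 + dy^2) * fps
    out[j, ] <- c(sp[1], sp)
  }
  out
}

#' Trailing moving average of a speed series
#'
#' Smooths with a trailing window; the first `window - 1` entries average over
#' all frames available so far (partial windows), so the series keeps its
#' length and interval boundaries stay exact.
#'
#' @param raw Numeric vector or matrix (rows smoothed independently).
#' @param window Window size in frames (>= 1).
#' @return Smoothed object of the same shape.
#' @examples
#' smooth_speed(c(0, 0, 0, 0, 5), window = 5) # last entry 1.0
#' @export
smooth_speed <- function(raw, window = 5) {
  if (!is_count(window)) stop("`window` must be a positive integer", call. = FALSE)
  smooth_vec <- function(x) {
    n <- length(x)
    w <- min(window, n)
    cs <- cumsum(x)
    full <- if (n >= w) (cs[w:n] - c(0, cs)[(w:n) - w + 1L]) / w else numeric(0)
    head_part <- if (w > 1L) cs[seq_len(w - 1L)] / seq_len(w - 1L) else numeric(0)
    c(head_part, full)
  }
  if (is.matrix(raw)) {
    out <- t(apply(raw, 1L, smooth_vec))
    dimnames(out) <- dimnames(raw)
    out
  } else {
    smooth_vec(raw)
  }
}

#' Assemble the smoothed velocity matrix for an experiment
#'
#' Calibrates pixel tables as needed, computes per-individual speeds, applies
#' the trailing moving average and stacks one row per individual-trial,
#' ordered by (group, trial, individual). The familiar design (17 groups x 6
#' individuals x 10 trials) yields a 1020 x 150 matrix; interval boundaries
#' are frames \[1,50\], \[51,100\], \[101,150\] (before/during/after LS).
#'
#' @param tables List of `tracking_table` objects.
#' @param cal Optional [calibration_spec()]; required if any table is in px
#'   and carries no `pixels_per_cm` attribute.
#' @param window Moving-average window (frames).
#' @param n_frames Number of frames retained per trial (3 x 10 s x 5 fps).
#' @return A `velocity_matrix`: list with `speeds` (matrix, cm/s) and `info`
#'   (data.frame: group, trial, individual, condition).
#' @export
build_velocity_matrix <- function(tables, cal = NULL, window = 5, n_frames = 150L) {
  if (length(tables) == 0L) stop("`tables` must be non-empty", call. = FALSE)
  meta <- data.frame(
    group = vapply(tables, function(t) as.character(attr(t, "group")), ""),
    trial = vapply(tables, function(t) as.numeric(attr(t, "trial")), 0),
    stringsAsFactors = FALSE
  )
  ord <- order(meta$group, meta$trial)
  tables <- tables[ord]

  n_ind_by_group <- list()
  rows <- list()
  info <- list()
  for (tab in tables) {
    validate_tracking_table(as.data.frame(tab), min_frames = n_frames)
    if (attr(tab, "units") == "px") {
      this_cal <- cal
      if (is.null(this_cal) && !is.null(attr(tab, "pixels_per_cm"))) {
        this_cal <- calibration_spec(pixels_per_cm = attr(tab, "pixels_per_cm"))
      }
      if (is.null(this_cal)) {
        stop("pixel-unit table without a calibration: pass `cal`", call. = FALSE)
      }
      tab <- calibrate(tab, this_cal)
    }
    g <- as.character(attr(tab, "group"))
    sp <- compute_speed(tab)[, seq_len(n_frames), drop = FALSE]
    n_ind <- nrow(sp)
    prev <- n_ind_by_group[[g]]
    if (!is.null(prev) && prev != n_ind) {
      stop(sprintf("group %s: heterogeneous individual counts across trials (%d vs %d)",
                   g, prev, n_ind), call. = FALSE)
    }
    n_ind_by_group[[g]] <- n_ind
    sm <- smooth_speed(sp, window = window)
    rows[[length(rows) + 1L]] <- sm
    info[[length(info) + 1L]] <- data.frame(
      group = g,
      trial = as.numeric(attr(tab, "trial")),
      individual = as.integer(sub("^id", "", rownames(sp))),
      condition = as.character(attr(tab, "condition") %||% NA_character_),
      stringsAsFactors = FALSE
    )
  }
  vm <- list(
    speeds = do.call(rbind, rows),
    info = do.call(rbind, info)
  )
  rownames(vm$speeds) <- NULL
  structure(vm, class = "velocity_matrix",
            fps = attr(tables[[1]], "fps"), window = window)
}

#' @export
print.velocity_matrix <- function(x, ...) {
  cat(sprintf("<velocity_matrix> %d individual-trials x %d frames (%d groups)\n",
              nrow(x$speeds), ncol(x$speeds), length(unique(x$info$group))))
  invisible(x)
}
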