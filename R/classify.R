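#' Speed thresholds and duration rules for state classification
#'
#' Holds the two speed thresholds and the duration rules that map smoothed
#' speeds to behavioural states: frames below `v_freeze` are freezing-like,
#' frames at or above `v_high` are high-speed swimming, the rest normal
#' swimming. A 10-s interval is a freezing-like state (FS) when freezing
#' totals at least `fs_min_s` seconds, a normal state (NS) when it totals less
#' than `ns_max_s` seconds (and, by the exhaustiveness rule, for any
#' non-freezing, non-high interval), and a high-speed state (HS) when
#' high-speed swimming is sustained for at least `hs_min_s` seconds (one frame
#' at 5 fps).
#'
#' @param v_freeze Freezing speed threshold, cm/s (strict: speed < v_freeze).
#' @param v_high High-speed threshold, cm/s (inclusive: speed >= v_high).
#' @param fs_min_s Minimum total freezing seconds for FS.
#' @param ns_max_s Maximum total freezing seconds for a "clean" NS.
#' @param hs_min_s Minimum sustained high-speed seconds for HS.
#' @param fps Frame rate used to convert seconds to frames.
#' @return A list of class `threshold_spec`.
#' @export
threshold_spec <- function(v_freeze = 0.2, v_high = 6.0, fs_min_s = 8,
                           ns_max_s = 2, hs_min_s = 0.2, fps = 5) {
  if (!(v_freeze > 0 && v_high > v_freeze)) {
    stop("`v_freeze` must be positive and below `v_high`", call. = FALSE)
  }
  if (!(ns_max_s < fs_min_s)) stop("`ns_max_s` must be below `fs_min_s`", call. = FALSE)
  if (!(hs_min_s >= 1 / fps)) {
    stop("`hs_min_s` must be at least one frame (1/fps seconds)", call. = FALSE)
  }
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  structure(list(v_freeze = v_freeze, v_high = v_high, fs_min_s = fs_min_s,
                 ns_max_s = ns_max_s, hs_min_s = hs_min_s, fps = fps),
            class = "threshold_spec")
}

#' Label each frame by its speed-based behavioural type
#'
#' @param speeds Finite, non-negative smoothed speeds (cm/s).
#' @param th A [threshold_spec()].
#' @return Character vector in `{"freeze","normal","high"}`.
#' @examples
#' th <- threshold_spec()
#' label_frames(c(0.1, 0.2, 6.0), th) # freeze, normal, high
#' @export
label_frames <- function(speeds, th = threshold_spec()) {
  if (any(!is.finite(speeds))) stop("speeds must be finite", call. = FALSE)
  if (any(speeds < 0)) stop("negative speed: upstream computation is broken", call. = FALSE)
  ifelse(speeds < th$v_freeze, "freeze",
         ifelse(speeds >= th$v_high, "high", "normal"))
}

#' Classify one 10-s interval into FS / NS / HS
#'
#' Applies the duration rules with precedence HS > FS > NS: any interval with
#' at least `hs_min_s` seconds of high-speed frames is HS (a single frame at
#' 5 fps - escape bursts are that fast); otherwise FS when total freezing
#' reaches `fs_min_s` seconds; otherwise NS. Total (not longest-run) freezing
#' duration is used, and intervals with freezing between `ns_max_s` and
#' `fs_min_s` fall to NS so the three states are exhaustive.
#'
#' @param frames Frame labels for one interval (from [label_frames()]),
#'   exactly `fps * 10` entries.
#' @param th A [threshold_spec()].
#' @param precedence Which state wins when HS and FS criteria co-occur:
#'   `"HS"` (default) or `"FS"`.
#' @return A list: `state` ("FS"/"NS"/"HS"), `freeze_s` (total freezing
#'   seconds) and `high_frames` (count of high-speed frames).
#' @export
classify_interval <- function(frames, th = threshold_spec(), precedence = c("HS", "FS")) {
  precedence <- match.arg(precedence)
  expected <- as.integer(round(th$fps * 10))
  if (length(frames) != expected) {
    stop(sprintf("interval must have exactly %d frames, got %d", expected,
                 length(frames)), call. = FALSE)
  }
  if (!all(frames %in% c("freeze", "normal", "high"))) {
    stop("frame labels must be freeze/normal/high", call. = FALSE)
  }
  high_frames <- sum(frames == "high")
  freeze_s <- sum(frames == "freeze") / th$fps
  is_hs <- high_frames >= round(th$hs_min_s * th$fps)
  is_fs <- freeze_s >= th$fs_min_s
  state <- if (precedence == "HS") {
    if (is_hs) "HS" else if (is_fs) "FS" else "NS"
  } else {
    if (is_fs) "FS" else if (is_hs) "HS" else "NS"
  }
  list(state = state, freeze_s = freeze_s, high_frames = high_frames)
}

#' Classify one individual-trial into its state triple
#'
#' Splits a 150-frame smoothed speed series into the three 10-s intervals
#' (before, during, after LS) and classifies each with [classify_interval()].
#'
#' @param speeds Smoothed speed series, `3 * fps * 10` frames.
#' @param th A [threshold_spec()].
#' @param precedence Passed to [classify_interval()].
#' @return Named character vector `c(before=, during=, after=)` with a
#'   `provenance` attribute (data.frame of freeze seconds and high-frame
#'   counts per interval).
#' @examples
#' th <- threshold_spec()
#' classify_trial(rep(0.05, 150), th) # c(before="FS", during="FS", after="FS")
#' @export
classify_trial <- function(speeds, th = threshold_spec(), precedence = c("HS", "FS")) {
  precedence <- match.arg(precedence)
  fpi <- as.integer(round(th$fps * 10))
  if (length(speeds) != 3L * fpi) {
    stop(sprintf("trial must have exactly %d frames, got %d", 3L * fpi,
                 length(speeds)), call. = FALSE)
  }
  labels <- label_frames(speeds, th)
  parts <- split(labels, rep(1:3, each = fpi))
  res <- lapply(parts, classify_interval, th = th, precedence = precedence)
  states <- vapply(res, `[[`, "", "state")
  names(states) <- c("before", "during", "after")
  attr(states, "provenance") <- data.frame(
    interval = c("before", "during", "after"),
    freeze_s = vapply(res, `[[`, 0, "freeze_s"),
    high_frames = vapply(res, `[[`, 0L, "high_frames"),
    row.names = NULL
  )
  states
}

#' Classify every row of a velocity matrix
#'
#' Bulk application of [classify_trial()]: one state triple per
#' individual-trial, with per-interval provenance columns.
#'
#' @param vm A `velocity_matrix` from [build_velocity_matrix()].
#' @param th A [threshold_spec()].
#' @param precedence Passed to [classify_interval()].
#' @return data.frame: group, trial, individual, condition, before, during,
#'   after, plus `freeze_s_*` and `high_frames_*` provenance columns.
#' @export
classify_states <- function(vm, th = threshold_spec(), precedence = c("HS", "FS")) {
  stopifnot(inherits(vm, "velocity_matrix"))
  precedence <- match.arg(precedence)
  n <- nrow(vm$speeds)
  out <- vm$info
  st <- matrix("", nrow = n, ncol = 3L)
  prov <- matrix(0, nrow = n, ncol = 6L)
  for (i in seq_len(n)) {
    s <- classify_trial(vm$speeds[i, ], th, precedence)
    st[i, ] <- s
    p <- attr(s, "provenance")
    prov[i, ] <- c(p$freeze_s, p$high_frames)
  }
  out$before <- st[, 1]; out$during <- st[, 2]; out$after <- st[, 3]
  out$freeze_s_before <- prov[, 1]; out$freeze_s_during <- prov[, 2]
  out$freeze_s_after <- prov[, 3]
  out$high_frames_before <- prov[, 4]; out$high_frames_during <- prov[, 5]
  out$high_frames_after <- prov[, 6]
  out
}

#' Derive the two speed thresholds from a velocity matrix
#'
#' Recovers the freezing and high-speed thresholds from the data the way they
#' were originally motivated: the post-LS speed distribution is bimodal
#' (freezing vs swimming) and `v_freeze` is placed at the kernel-density
#' trough between its two largest modes; the pre-LS distribution contains
#' essentially no escape-like speeds, and `v_high` is the smallest speed above
#' which the pre-LS density stays below `peak_frac` of its peak. When the
#' post-LS density is not separably bimodal, or the search degenerates, the
#' conventional defaults (0.2, 6.0 cm/s) are returned with a warning.
#'
#' @param vm A `velocity_matrix` (at least 2 rows).
#' @param peak_frac Fraction of the pre-LS density peak defining "negligible".
#' @param bw_freeze Kernel bandwidth (cm/s) for the post-LS trough search.
#'   The default 0.03 resolves the narrow freezing mode (width ~0.1 cm/s)
#'   that rule-of-thumb bandwidths over-smooth on strongly bimodal mixtures.
#' @param bw_high Bandwidth for the pre-LS tail search ([stats::density()]
#'   rule or a number); the tail criterion needs a smooth global density, so
#'   the rule-of-thumb default is appropriate here.
#' @param min_prominence Minimum height of a mode, as a fraction of the
#'   tallest, for it to count towards bimodality.
#' @param n_grid Grid size for the density evaluations.
#' @return A [threshold_spec()] with derived `v_freeze` / `v_high`; the
#'   attribute `"derivation"` records troughs, peaks and fallback flags.
#' @export
derive_thresholds <- function(vm, peak_frac = 0.01, bw_freeze = 0.03,
                              bw_high = "nrd0", min_prominence = 0.05,
                              n_grid = 2048) {
  stopifnot(inherits(vm, "velocity_matrix"))
  if (nrow(vm$speeds) < 2L) stop("need at least 2 individual-trials", call. = FALSE)
  fpi <- ncol(vm$speeds) / 3L
  post <- as.vector(vm$speeds[, (2L * fpi + 1L):(3L * fpi)])
  pre <- as.vector(vm$speeds[, 1:fpi])
  if (stats::sd(post) == 0) {
    warning("post-LS speeds are constant; falling back to default thresholds")
    return(structure(threshold_spec(),
                     derivation = list(fallback_freeze = TRUE, fallback_high = TRUE)))
  }

  fallback_freeze <- FALSE
  d_post <- stats::density(post, bw = bw_freeze, n = n_grid, from = 0)
  y <- d_post$y; x <- d_post$x
  loc_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) loc_max <- c(1L, loc_max) # mode pinned at zero speed
  loc_max <- loc_max[y[loc_max] >= min_prominence * max(y)]
  separable <- length(loc_max) >= 2L
  if (separable) {
    top2 <- loc_max[order(y[loc_max], decreasing = TRUE)[1:2]]
    lo <- min(top2); hi <- max(top2)
    imin <- lo + which.min(y[(lo + 1L):(hi - 1L)])
    # a genuine trough must dip well below the lower of the two modes
    separable <- y[imin] < 0.8 * min(y[top2])
  }
  if (!separable) {
    warning("post-LS speed density not separably bimodal; falling back to default thresholds")
    return(structure(threshold_spec(),
                     derivation = list(trough = NA_real_, fallback_freeze = TRUE,
                                       fallback_high = TRUE)))
  }
  v_freeze <- x[imin]
  trough <- v_freeze

  fallback_high <- FALSE
  d_pre <- stats::density(pre, bw = bw_high, n = n_grid, from = 0)
  peak <- max(d_pre$y)
  above <- which(d_pre$y >= peak_frac * peak)
  if (length(above) == 0L || max(above) >= length(d_pre$x)) {
    warning("pre-LS density never falls below the peak fraction; using default v_high = 6")
    v_high <- 6.0
    fallback_high <- TRUE
  } else {
    v_high <- d_pre$x[max(above) + 1L]
  }
  if (!fallback_freeze && !(v_freeze < v_high)) {
    warning("derived thresholds are inconsistent (v_freeze >= v_high); using defaults")
    v_freeze <- 0.2; v_high <- 6.0
    fallback_freeze <- fallback_high <- TRUE
  }
  structure(
    threshold_spec(v_freeze = v_freeze, v_high = v_high),
    derivation = list(
      trough = trough, pre_peak = peak,
      fallback_freeze = fallback_freeze, fallback_high = fallback_high
    )
  )
}
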