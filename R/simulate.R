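#' Draw ground-truth behavioural states for a simulated experiment
#'
#' Runs only the state-level (decision) layer of the generator: per group an
#' archetype, per trial pre-LS freezing, escape bursts during LS, and post-LS
#' freezing decided by a two-stage consensus draw. Stage one samples each
#' individual's independent freezing intention from its archetype baseline
#' (plus an escape boost); stage two forms the group majority direction and
#' redraws each individual with the majority signal scaled by `coupling` added
#' on the log-odds scale. `coupling = 0` reduces exactly to independent
#' Bernoulli draws; `coupling = Inf` forces unanimous groups.
#'
#' @param cfg A [sim_config()].
#' @return A list with `states` (data.frame: group, trial, individual,
#'   archetype, escaped, before, during, after) and `archetypes` (data.frame:
#'   group, archetype). States are in `{"FS","NS","HS"}`.
#' @export
simulate_states <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, simulate_states_impl(cfg))
}

# state-layer draws using the current RNG stream
simulate_states_impl <- function(cfg) {
  mix <- cfg$group_trait_mix
  n_g <- cfg$n_groups; n_t <- cfg$n_trials; n_i <- cfg$n_individuals
  arch_idx <- if (identical(cfg$archetype_assignment, "balanced")) {
    base <- floor(mix$weight * n_g)
    rem <- n_g - sum(base)
    if (rem > 0) {
      extra <- order(mix$weight * n_g - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    rep(seq_len(nrow(mix)), base)
  } else {
    sample.int(nrow(mix), n_g, replace = TRUE, prob = mix$weight)
  }
  archetypes <- data.frame(
    group = sprintf("g%02d", seq_len(n_g)),
    archetype = mix$archetype[arch_idx],
    stringsAsFactors = FALSE
  )
  esc_logit_base <- stats::qlogis(min(max(cfg$p_escape_base, 1e-12), 1 - 1e-12))
  frz_boost <- stats::qlogis(min(max(cfg$p_freeze_after_escape, 1e-12), 1 - 1e-12))

  rows <- vector("list", n_g * n_t)
  k <- 0L
  for (g in seq_len(n_g)) {
    a <- arch_idx[g]
    b_freeze <- mix$freeze_logit[a]
    p_escape <- if (cfg$p_escape_base %in% c(0, 1)) cfg$p_escape_base else
      stats::plogis(esc_logit_base + mix$escape_logit[a])
    for (t in seq_len(n_t)) {
      before_fs <- stats::runif(n_i) < cfg$p_before_freeze
      escaped <- stats::runif(n_i) < p_escape
      stay <- stats::runif(n_i) < cfg$p_stay_freeze
      during <- ifelse(escaped, "HS", ifelse(before_fs & stay, "FS", "NS"))
      l <- b_freeze + ifelse(escaped, frz_boost, 0)
      # stage 1: independent intentions; stage 2: conformity to the majority
      z <- stats::runif(n_i) < stats::plogis(l)
      m <- mean(z)
      d <- if (m > 0.5) 1 else if (m < 0.5) 0 else
        as.integer(stats::runif(1) < stats::plogis(b_freeze))
      shift <- cfg$coupling * (2 * d - 1)
      p_final <- stats::plogis(l + shift)
      if (is.infinite(cfg$coupling)) p_final <- rep(as.numeric(d), n_i)
      after_fs <- stats::runif(n_i) < p_final
      k <- k + 1L
      rows[[k]] <- data.frame(
        group = archetypes$group[g],
        trial = t,
        individual = seq_len(n_i) - 1L,
        archetype = mix$archetype[a],
        escaped = escaped,
        before = ifelse(before_fs, "FS", "NS"),
        during = during,
        after = ifelse(after_fs, "FS", "NS"),
        stringsAsFactors = FALSE
      )
    }
  }
  list(states = do.call(rbind, rows), archetypes = archetypes)
}

#' Simulate one individual-trial trajectory realising a state triple
#'
#' Renders a commanded state triple (before, during, after) into a per-frame
#' x/y path inside the arena. Freezing is small-amplitude jitter (speed below
#' `v_freeze_max`), normal swimming a correlated random walk whose log speed
#' follows an AR(1) process capped at `v_normal_cap`, and a high-speed during
#' interval contains a 3-frame escape burst at `v_burst` aimed at the farthest
#' corner (so the burst never hits a wall). Boundaries reflect; displacements
#' of any magnitude are folded back into the arena. Uses the current RNG
#' stream; seed externally for reproducibility.
#'
#' @param states Character vector of length 3 (before, during, after) with
#'   values in `{"FS","NS","HS"}`.
#' @param cfg A [sim_config()].
#' @param noise_sd Tracking-noise sd in cm; defaults to `cfg$position_noise_sd`.
#'   Set to 0 to obtain the pure commanded regime.
#' @return data.frame with columns `x`, `y` (cm), one row per frame
#'   (3 x fps x interval_s rows).
#' @export
simulate_trajectory <- function(states, cfg, noise_sd = cfg$position_noise_sd) {
  validate_sim_config(cfg)
  if (length(states) != 3L || !all(states %in% .STATES)) {
    stop("`states` must be a length-3 vector over {FS, NS, HS}", call. = FALSE)
  }
  fpi <- as.integer(round(cfg$fps * cfg$interval_s))
  n <- 3L * fpi

  # per-frame regime: "freeze", "normal" or "burst"
  regime <- character(n)
  iv <- rep(1:3, each = fpi)
  regime[iv == 1] <- if (states[1] == "FS") "freeze" else "normal"
  regime[iv == 3] <- if (states[3] == "FS") "freeze" else "normal"
  if (states[2] == "HS") {
    # escape occurs rapidly after LS onset: burst starts within the first 2 s
    b0 <- fpi + 1L + sample.int(max(1L, 2L * cfg$fps), 1L) - 1L
    pre <- if (states[1] == "FS") "freeze" else "normal"
    post <- if (states[3] == "FS") "freeze" else "normal"
    regime[iv == 2] <- post
    if (b0 > fpi + 1L) regime[(fpi + 1L):(b0 - 1L)] <- pre
    regime[b0:min(b0 + 2L, 2L * fpi)] <- "burst"
  } else if (states[2] == "FS") {
    regime[iv == 2] <- "freeze"
  } else {
    regime[iv == 2] <- "normal"
  }

  # commanded speeds (cm/s)
  sdlog <- sqrt(log(1 + (cfg$v_normal_sd / cfg$v_normal_mean)^2))
  mulog <- log(cfg$v_normal_mean) - sdlog^2 / 2
  rho <- cfg$speed_autocorr
  v <- numeric(n)
  lv_prev <- NA_real_
  for (i in seq_len(n)) {
    if (regime[i] == "freeze") {
      v[i] <- stats::runif(1, 0, cfg$v_freeze_max)
      lv_prev <- NA_real_
    } else if (regime[i] == "burst") {
      v[i] <- cfg$v_burst
      lv_prev <- NA_real_
    } else {
      lv <- if (is.na(lv_prev)) stats::rnorm(1, mulog, sdlog) else
        mulog + rho * (lv_prev - mulog) + stats::rnorm(1, 0, sdlog * sqrt(1 - rho^2))
      lv_prev <- lv
      v[i] <- min(exp(lv), cfg$v_normal_cap)
    }
  }

  # headings: correlated turning while swimming, uniform while jittering
  step <- v / cfg$fps
  x <- numeric(n); y <- numeric(n)
  margin <- min(0.5, cfg$arena_w / 4, cfg$arena_h / 4)
  px <- stats::runif(1, margin, cfg$arena_w - margin)
  py <- stats::runif(1, margin, cfg$arena_h - margin)
  h <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n)) {
    if (regime[i] == "burst") {
      if (i == 1L || regime[i - 1L] != "burst") {
        # aim at the farthest corner: guarantees >= half-diagonal of free run
        cx <- if (px < cfg$arena_w / 2) cfg$arena_w else 0
        cy <- if (py < cfg$arena_h / 2) cfg$arena_h else 0
        h <- atan2(cy - py, cx - px)
      }
      # folding is a no-op at default burst speeds (the farthest corner is at
      # least half a diagonal away) but keeps absurd speeds in-bounds
      nx <- reflect_into(px + step[i] * cos(h), cfg$arena_w)
      ny <- reflect_into(py + step[i] * sin(h), cfg$arena_h)
    } else {
      h <- if (regime[i] == "freeze") stats::runif(1, 0, 2 * pi) else
        h + stats::rnorm(1, 0, 0.6)
      nx <- reflect_into(px + step[i] * cos(h), cfg$arena_w)
      ny <- reflect_into(py + step[i] * sin(h), cfg$arena_h)
    }
    px <- nx; py <- ny
    x[i] <- px; y[i] <- py
  }
  if (noise_sd > 0) {
    x <- pmin(pmax(x + stats::rnorm(n, 0, noise_sd), 0), cfg$arena_w)
    y <- pmin(pmax(y + stats::rnorm(n, 0, noise_sd), 0), cfg$arena_h)
  }
  data.frame(x = x, y = y)
}

#' Simulate a full looming-stimulus experiment
#'
#' Draws ground-truth states with [simulate_states()] and renders one tracking
#' table per group-trial with [simulate_trajectory()]. Identical configs
#' (including the seed) give identical output.
#'
#' @param cfg A [sim_config()].
#' @param condition Condition label stored in each table (e.g. "familiar").
#' @return A list with `tables` (named list of `tracking_table` data frames,
#'   one per group-trial, coordinates in cm) and `truth` (the
#'   [simulate_states()] result).
#' @examples
#' sim <- simulate_experiment(sim_config(n_groups = 2, n_trials = 2, seed = 1))
#' length(sim$tables) # 4 group-trials
#' @export
simulate_experiment <- function(cfg, condition = "familiar") {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    truth <- simulate_states_impl(cfg)
    st <- truth$states
    fpi <- as.integer(round(cfg$fps * cfg$interval_s))
    tables <- list()
    for (g in unique(st$group)) {
      for (t in sort(unique(st$trial[st$group == g]))) {
        sub <- st[st$group == g & st$trial == t, ]
        sub <- sub[order(sub$individual), ]
        coords <- matrix(NA_real_, nrow = 3L * fpi, ncol = 2L * nrow(sub))
        cols <- character(2L * nrow(sub))
        for (j in seq_len(nrow(sub))) {
          path <- simulate_trajectory(
            c(sub$before[j], sub$during[j], sub$after[j]), cfg
          )
          coords[, 2L * j - 1L] <- path$x
          coords[, 2L * j] <- path$y
          cols[2L * j - 1L] <- sprintf("id%d_x", sub$individual[j])
          cols[2L * j] <- sprintf("id%d_y", sub$individual[j])
        }
        tab <- data.frame(frame = seq_len(3L * fpi) - 1L, coords)
        names(tab) <- c("frame", cols)
        tables[[sprintf("%s_t%02d", g, t)]] <- new_tracking_table(
          tab, group = g, trial = t, condition = condition,
          units = "cm", fps = cfg$fps
        )
      }
    }
    list(tables = tables, truth = truth)
  })
}

#' Write simulated tracking tables as a CSV fixture set
#'
#' Writes one CSV per group-trial in the tracking dialect
#' (`frame,id0_x,id0_y,...`) plus a `manifest.json` sidecar holding per-file
#' metadata (group, trial, condition, units, fps, pixels-per-cm and, when
#' ground truth is supplied, the group archetypes and seed). Coordinates are
#' converted to pixels with `pixels_per_cm` so the fixture exercises the
#' calibration step; pass `pixels_per_cm = NULL` to keep cm.
#'
#' @param tables Named list of `tracking_table` objects (e.g. from
#'   [simulate_experiment()]).
#' @param dir Output directory (created if missing).
#' @param pixels_per_cm Pixel scale used to write pixel units, or NULL.
#' @param truth Optional [simulate_states()] result recorded in the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture <- function(tables, dir, pixels_per_cm = 20, truth = NULL, seed = NULL) {
  if (length(tables) == 0L) stop("`tables` must be a non-empty list", call. = FALSE)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  }
  files <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    stopifnot(inherits(tab, "tracking_table"))
    out <- as.data.frame(tab)
    units <- attr(tab, "units")
    if (!is.null(pixels_per_cm)) {
      if (pixels_per_cm <= 0) stop("`pixels_per_cm` must be positive", call. = FALSE)
      if (units == "cm") {
        coord_cols <- setdiff(names(out), "frame")
        out[coord_cols] <- out[coord_cols] * pixels_per_cm
        units <- "px"
      }
    }
    file <- paste0(nm, ".csv")
    utils::write.csv(out, file.path(dir, file), row.names = FALSE)
    files[[length(files) + 1L]] <- list(
      file = file,
      group = attr(tab, "group"),
      trial = attr(tab, "trial"),
      condition = attr(tab, "condition"),
      units = units,
      fps = attr(tab, "fps"),
      pixels_per_cm = if (units == "px") pixels_per_cm else NULL
    )
  }
  manifest <- list(files = files)
  if (!is.null(seed)) manifest$seed <- seed
  if (!is.null(truth)) {
    manifest$archetypes <- truth$archetypes
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
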