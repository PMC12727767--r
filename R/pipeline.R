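# Configuration-driven end-to-end runner with logging and a reproducibility
# manifest.

default_run_config <- function() {
  list(
    simulate = TRUE,
    sim = list(), # overrides for sim_config()
    condition = "familiar",
    input_dir = NULL,
    calibration = NULL, # list(pixels_per_cm=) or list(pixels_span=, source_length_cm=)
    thresholds = list(), # overrides for threshold_spec()
    derive_thresholds = FALSE,
    shuffle = list(n_replicates = 1000),
    k_grid = 2:6,
    seed_analysis = 1,
    seed_embedding = 1,
    glmm_fixed = NULL, # default: condition if >=2 conditions, else cluster
    write_velocity = FALSE
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- utils::modifyList(default_run_config(), config)
  if (isTRUE(cfg$simulate) && !is.null(cfg$input_dir)) {
    stop("config must name exactly one input source: simulate or input_dir", call. = FALSE)
  }
  if (!isTRUE(cfg$simulate) && is.null(cfg$input_dir)) {
    stop("config must name an input source: set simulate=TRUE or input_dir", call. = FALSE)
  }
  cfg$k_grid <- as.integer(cfg$k_grid)
  cfg
}

stage_msg <- function(stage, t0, fmt, ...) {
  message(sprintf("[%s] %.1fs %s", stage, as.numeric(Sys.time()) - t0,
                  sprintf(fmt, ...)))
}

#' Run the full looming-stimulus analysis pipeline
#'
#' Executes read/simulate, calibration, velocity-matrix assembly, state
#' classification, transition statistics (pattern enrichment + DOT diagram),
#' the shuffle-null synchrony test, group-profile clustering and - when at
#' least two conditions or clusters are present - the binomial GLMM. All
#' tabular outputs are CSV, test results JSON, diagrams DOT; a manifest
#' records the config, seeds, per-stage row counts and output checksums, so a
#' rerun with an identical config is byte-identical.
#'
#' @param config Named list, or path to a YAML/JSON file, overriding the
#'   defaults: `simulate` (logical) + `sim` (overrides for [sim_config()]) or
#'   `input_dir`; `calibration`; `thresholds` / `derive_thresholds`;
#'   `shuffle` (overrides for [shuffle_config()]); `k_grid`; `seed_analysis`;
#'   `seed_embedding`; `glmm_fixed`; `write_velocity`.
#' @param out_dir Output directory (created if missing).
#' @return The run manifest (invisibly), also written to
#'   `out_dir/manifest.json`.
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "lsrun")
#' man <- run_pipeline(list(sim = list(n_groups = 8, seed = 3),
#'                          shuffle = list(n_replicates = 100)), out)
#' man$row_counts
#' }
#' @export
run_pipeline <- function(config = list(), out_dir) {
  t0 <- as.numeric(Sys.time())
  cfg <- read_run_config(config)
  if (!isTRUE(cfg$simulate) && !dir.exists(cfg$input_dir)) {
    stop(sprintf("input_dir does not exist: %s", cfg$input_dir), call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  # --- input stage -------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    sim_cfg <- do.call(sim_config, cfg$sim)
    stage_msg("input", t0, "simulating %d groups x %d trials (seed %s)",
              sim_cfg$n_groups, sim_cfg$n_trials, format(sim_cfg$seed))
    sim <- simulate_experiment(sim_cfg, condition = cfg$condition)
    tables <- sim$tables
    truth <- sim$truth
  } else {
    files <- list.files(cfg$input_dir, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0L) stop("input_dir contains no CSV files", call. = FALSE)
    stage_msg("input", t0, "reading %d tracking tables from %s", length(files),
              cfg$input_dir)
    tables <- lapply(files, read_tracking)
    names(tables) <- vapply(tables, function(tb) {
      sprintf("%s_t%02d", attr(tb, "group"), as.integer(attr(tb, "trial")))
    }, "")
    truth <- NULL
  }

  # --- velocity matrix ---------------------------------------------------
  cal <- if (!is.null(cfg$calibration)) do.call(calibration_spec, cfg$calibration)
  vm <- build_velocity_matrix(tables, cal = cal)
  stage_msg("velocity", t0, "%d rows x %d frames", nrow(vm$speeds), ncol(vm$speeds))
  if (isTRUE(cfg$write_velocity)) {
    utils::write.csv(cbind(vm$info, vm$speeds), file.path(out_dir, "velocity_matrix.csv"),
                     row.names = FALSE)
  }

  # --- states ------------------------------------------------------------
  th <- if (isTRUE(cfg$derive_thresholds)) derive_thresholds(vm) else
    do.call(threshold_spec, cfg$thresholds)
  states <- classify_states(vm, th)
  out_states <- states
  for (cc in c("before", "during", "after")) {
    out_states[[cc]] <- substr(out_states[[cc]], 1, 1)
  }
  utils::write.csv(out_states, file.path(out_dir, "states.csv"), row.names = FALSE)
  stage_msg("states", t0, "classified %d individual-trials", nrow(states))

  # --- transition statistics --------------------------------------------
  m_bd <- count_transitions(states, "before_during")
  m_da <- count_transitions(states, "during_after")
  enrich <- binomial_enrichment(pattern_frequencies(states))
  utils::write.csv(
    enrich[, c("index", "pattern", "count", "freq", "p", "q", "stars")],
    file.path(out_dir, "pattern_frequencies.csv"), row.names = FALSE
  )
  export_dot(m_bd, m_da, file = file.path(out_dir, "transitions.dot"))
  stage_msg("transitions", t0, "%d patterns enriched at q<0.001",
            sum(enrich$q < 0.001))

  # --- synchrony ---------------------------------------------------------
  obs <- count_fs_per_trial(states)
  sh_cfg <- do.call(shuffle_config, cfg$shuffle)
  null <- shuffle_null(states, sh_cfg)
  chi <- chi_square_compare(obs, null)
  utils::write.csv(
    data.frame(fs = 0:obs$n_individuals, observed = as.integer(obs$freq),
               null_prop = null$props),
    file.path(out_dir, "fs_histogram.csv"), row.names = FALSE
  )
  jsonlite::write_json(
    list(statistic = chi$statistic, df = chi$df, p = chi$p.value,
         n_replicates = sh_cfg$n_replicates,
         seeds_hash = unname(substr(digest_vector(sh_cfg$seeds), 1, 16))),
    file.path(out_dir, "chi_square.json"), auto_unbox = TRUE, digits = NA
  )
  stage_msg("synchrony", t0, "chi2(%d) = %.1f, p = %.3g", chi$df, chi$statistic,
            chi$p.value)

  # --- profiles ----------------------------------------------------------
  n_groups <- length(unique(states$group))
  prof <- NULL
  if (n_groups >= max(cfg$k_grid) + 1L) {
    prof <- cluster_profiles(states, k_grid = cfg$k_grid, seed = cfg$seed_analysis)
    utils::write.csv(prof$assignments, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(k = prof$k, d95 = prof$d95, silhouette = prof$silhouette,
           seed = cfg$seed_analysis),
      file.path(out_dir, "model_selection.json"), auto_unbox = TRUE, digits = NA
    )
    stage_msg("profiles", t0, "d95 = %d, chosen k = %d", prof$d95, prof$k)
  } else {
    stage_msg("profiles", t0, "skipped (only %d groups for k_grid up to %d)",
              n_groups, max(cfg$k_grid))
  }

  # --- GLMM --------------------------------------------------------------
  glmm <- NULL
  n_cond <- length(unique(stats::na.omit(states$condition)))
  fixed <- cfg$glmm_fixed
  if (is.null(fixed)) {
    fixed <- if (n_cond >= 2L) "condition" else if (!is.null(prof) && prof$k >= 2L)
      "cluster" else NULL
  }
  if (!is.null(fixed)) {
    d <- obs$counts
    d <- merge(d, unique(states[, c("group", "condition")]), by = "group")
    if (!is.null(prof)) {
      d <- merge(d, prof$assignments[, c("group", "cluster")], by = "group")
    }
    if (all(fixed %in% names(d))) {
      glmm <- fit_group_glmm(d, fixed = fixed, random = c("group", "trial"))
      gl <- list(fixed = fixed, converged = glmm$converged,
                 separation = glmm$separation,
                 coefficients = glmm$coefficients, contrasts = glmm$contrasts)
      jsonlite::write_json(gl, file.path(out_dir, "glmm.json"),
                           auto_unbox = TRUE, digits = NA)
      stage_msg("glmm", t0, "fixed = %s, converged = %s",
                paste(fixed, collapse = "+"), glmm$converged)
    }
  }

  # --- manifest ----------------------------------------------------------
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("loomsync")),
    config = cfg[setdiff(names(cfg), "k_grid")],
    k_grid = cfg$k_grid,
    row_counts = list(
      tables = length(tables),
      velocity_rows = nrow(vm$speeds),
      velocity_frames = ncol(vm$speeds),
      individual_trials = nrow(states),
      trials = obs$total,
      groups = n_groups
    ),
    thresholds = unclass(th)[c("v_freeze", "v_high", "fs_min_s", "ns_max_s",
                               "hs_min_s", "fps")],
    seeds = list(
      sim = if (isTRUE(cfg$simulate)) sim_cfg$seed else NULL,
      shuffle = range(sh_cfg$seeds),
      analysis = cfg$seed_analysis,
      embedding = cfg$seed_embedding
    ),
    checksums = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_msg("done", t0, "outputs in %s", out_dir)
  invisible(manifest)
}

# order-sensitive hash of an integer vector (no external digest dependency)
digest_vector <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(x, collapse = ","), f)
  unname(tools::md5sum(f))
}

#' Summarise a pipeline run as readable markdown
#'
#' Reads the files produced by [run_pipeline()] and assembles a one-page
#' summary: top enriched transition patterns with q-values and stars, the
#' observed vs null FS-count histogram with the chi-square result, the chosen
#' cluster count and per-cluster FS-count modes, and GLMM contrasts when
#' fitted.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param file Optional path for the markdown (defaults to
#'   `out_dir/report.md`; NULL to skip writing).
#' @return The report lines, invisibly, as a character vector.
#' @export
pipeline_report <- function(out_dir, file = file.path(out_dir, "report.md")) {
  need <- file.path(out_dir, c("pattern_frequencies.csv", "fs_histogram.csv",
                               "chi_square.json", "states.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) {
    stop(sprintf("missing pipeline outputs: %s",
                 paste(basename(missing), collapse = ", ")), call. = FALSE)
  }
  pat <- utils::read.csv(file.path(out_dir, "pattern_frequencies.csv"))
  hist <- utils::read.csv(file.path(out_dir, "fs_histogram.csv"))
  chi <- jsonlite::read_json(file.path(out_dir, "chi_square.json"))

  sig <- pat[pat$q < 0.05, ]
  sig <- sig[order(sig$count, decreasing = TRUE), ]
  lines <- c(
    "# Looming-stimulus collective response report", "",
    "## Enriched transition patterns (q < 0.05)", ""
  )
  if (nrow(sig) == 0L) {
    lines <- c(lines, "none")
  } else {
    lines <- c(lines, "| pattern | count | freq | q | |",
               "|---|---|---|---|---|",
               sprintf("| %s | %d | %.3f | %.2g | %s |", sig$pattern, sig$count,
                       sig$freq, sig$q, ifelse(is.na(sig$stars), "", sig$stars)))
  }
  lines <- c(lines, "", "## Group synchrony of post-LS freezing", "",
             "| FS count | observed | expected (null) |", "|---|---|---|",
             sprintf("| %d | %d | %.1f |", hist$fs, hist$observed,
                     hist$null_prop * sum(hist$observed)),
             "",
             sprintf("chi-square(%d) = %.1f, p = %.3g (shuffle null, %s replicates)",
                     chi$df, chi$statistic, chi$p, chi$n_replicates))

  cl_path <- file.path(out_dir, "clusters.csv")
  if (file.exists(cl_path)) {
    cl <- utils::read.csv(cl_path)
    ms <- jsonlite::read_json(file.path(out_dir, "model_selection.json"))
    # single-letter states: stop read.csv turning "F" into FALSE
    states <- utils::read.csv(
      file.path(out_dir, "states.csv"),
      colClasses = c(before = "character", during = "character",
                     after = "character")
    )
    lines <- c(lines, "", "## Group response profiles", "",
               sprintf("PCA retained %s components (>95%% variance); silhouette-chosen k = %s.",
                       ms$d95, ms$k))
    for (k in sort(unique(cl$cluster))) {
      gs <- cl$group[cl$cluster == k]
      sub <- states[states$group %in% gs, ]
      fs <- tapply(sub$after == "F", paste(sub$group, sub$trial), sum)
      tab <- tabulate(as.integer(fs) + 1L, nbins = 7L)
      mode_fs <- which.max(tab) - 1L
      lines <- c(lines, sprintf(
        "- cluster %d: %d groups, FS-count mode %d (histogram %s)",
        k, length(gs), mode_fs, paste(tab, collapse = "/")
      ))
    }
  }
  gl_path <- file.path(out_dir, "glmm.json")
  if (file.exists(gl_path)) {
    gl <- jsonlite::read_json(gl_path, simplifyVector = TRUE)
    lines <- c(lines, "", "## GLMM (binomial-logit) contrasts", "")
    if (!is.null(gl$contrasts) && length(gl$contrasts) > 0) {
      ct <- as.data.frame(gl$contrasts)
      lines <- c(lines, sprintf("- %s: estimate %.2f (log-odds), Tukey p = %.3g",
                                ct$contrast, ct$estimate, ct$p_tukey))
    }
    lines <- c(lines, sprintf("(converged: %s, separation flag: %s)",
                              gl$converged, gl$separation))
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
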