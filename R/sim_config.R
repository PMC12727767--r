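#' Group archetype mixture for the trajectory generator
#'
#' Defines the group-level behavioural archetypes that the generator mixes
#' over: freeze-dominant groups (react to the looming stimulus and then freeze
#' together), non-freeze groups (largely ignore it and keep swimming) and
#' mixed groups (heterogeneous responses). Each archetype carries a mixture
#' weight, a baseline log-odds of post-LS freezing (`freeze_logit`) and an
#' offset on the log-odds of showing an escape burst during LS
#' (`escape_logit`).
#'
#' @param archetype Character vector of archetype names.
#' @param weight Mixture weights (normalised internally to sum to 1).
#' @param freeze_logit Baseline log-odds that an individual in such a group
#'   freezes after LS (before any escape effect or social coupling).
#' @param escape_logit Offset added to `qlogis(p_escape_base)` for the
#'   probability of a high-speed escape burst during LS.
#' @return A `data.frame` with one row per archetype.
#' @seealso [sim_config()]
#' @export
archetype_mix <- function(archetype = c("freeze_dominant", "non_freeze", "mixed"),
                          weight = c(0.40, 0.35, 0.25),
                          freeze_logit = c(2.2, -3.0, -1.5),
                          escape_logit = c(1.4, -2.2, 0.8)) {
  if (length(archetype) < 1L) stop_config("archetype", "must list at least one archetype")
  if (length(weight) != length(archetype) ||
      length(freeze_logit) != length(archetype) ||
      length(escape_logit) != length(archetype)) {
    stop_config("group_trait_mix", "weight/logit vectors must match the number of archetypes")
  }
  if (any(!is.finite(weight)) || any(weight < 0) || sum(weight) <= 0) {
    stop_config("group_trait_mix$weight", "must be non-negative and sum to a positive value")
  }
  data.frame(
    archetype = as.character(archetype),
    weight = weight / sum(weight),
    freeze_logit = as.numeric(freeze_logit),
    escape_logit = as.numeric(escape_logit),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the agent-based experiment simulator
#'
#' Bundles every tunable of the synthetic looming-stimulus experiment: the
#' design (groups, individuals, trials, frame rate, interval length), the
#' arena, the three speed regimes (freezing jitter, normal swimming,
#' escape bursts), the response probabilities and the group-level consensus
#' mechanism.
#'
#' Defaults emulate the familiar-condition design: 17 groups of 6 fish, 10
#' trials per group, 5 fps over three 10-s intervals, a 20.25 x 14.5 cm tank.
#' Speed regimes are chosen so that smoothed speeds show a freezing mode below
#' 0.2 cm/s, a normal-swimming mode around 1.5 cm/s with an autocorrelated
#' (burst-and-coast-like) tail capped just below 6 cm/s, and escape bursts
#' well above 6 cm/s during LS only.
#'
#' @param n_groups,n_individuals,n_trials Experimental design counts.
#' @param fps Analysis frame rate (frames per second).
#' @param interval_s Duration of each of the three intervals, in seconds.
#' @param arena_w,arena_h Arena width/height in cm.
#' @param v_normal_mean,v_normal_sd Mean and sd (cm/s) of the lognormal
#'   marginal speed during normal swimming.
#' @param v_normal_cap Hard cap (cm/s) on normal-swimming speed; must stay
#'   below the 6 cm/s escape threshold so normal swimming never reads as an
#'   escape burst.
#' @param v_freeze_max Maximum commanded jitter speed (cm/s) while freezing.
#' @param v_burst Commanded speed (cm/s) of escape bursts (3 consecutive
#'   frames), chosen so the burst survives the window-5 moving average.
#' @param speed_autocorr Lag-1 autocorrelation of log speed during normal
#'   swimming (burst-and-coast structure).
#' @param p_escape_base Baseline probability of an escape burst during LS.
#' @param p_freeze_after_escape Probability of post-LS freezing given escape
#'   (acts as a log-odds boost on the freezing intention).
#' @param p_before_freeze Probability an individual is already freezing in the
#'   pre-LS interval.
#' @param p_stay_freeze Probability a pre-LS freezer that does not escape
#'   stays frozen during LS.
#' @param coupling Strength (log-odds units, >= 0) of conformity to the group
#'   majority intention; 0 = fully independent individuals, large values force
#'   all-or-none group responses.
#' @param group_trait_mix Archetype mixture, see [archetype_mix()].
#' @param archetype_assignment `"random"` draws each group's archetype from
#'   the mixture weights; `"balanced"` plants archetypes with deterministic
#'   counts proportional to the weights (largest-remainder rounding), the
#'   stratified design used for recovery experiments.
#' @param position_noise_sd Tracking (centroid) noise sd in cm added to every
#'   simulated position.
#' @param seed Integer seed; identical configs give identical output.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_groups = 2, n_trials = 3, seed = 7)
#' sim <- simulate_states(cfg)
#' head(sim$states)
#' @export
sim_config <- function(n_groups = 17,
                       n_individuals = 6,
                       n_trials = 10,
                       fps = 5,
                       interval_s = 10,
                       arena_w = 20.25,
                       arena_h = 14.5,
                       v_normal_mean = 1.5,
                       v_normal_sd = 1.3,
                       v_normal_cap = 5.7,
                       v_freeze_max = 0.05,
                       v_burst = 12,
                       speed_autocorr = 0.92,
                       p_escape_base = 0.5,
                       p_freeze_after_escape = 0.7,
                       p_before_freeze = 0.15,
                       p_stay_freeze = 0.8,
                       coupling = 4,
                       group_trait_mix = archetype_mix(),
                       archetype_assignment = c("random", "balanced"),
                       position_noise_sd = 0.01,
                       seed = 1) {
  archetype_assignment <- match.arg(archetype_assignment)
  cfg <- list(
    n_groups = n_groups, n_individuals = n_individuals, n_trials = n_trials,
    fps = fps, interval_s = interval_s,
    arena_w = arena_w, arena_h = arena_h,
    v_normal_mean = v_normal_mean, v_normal_sd = v_normal_sd,
    v_normal_cap = v_normal_cap, v_freeze_max = v_freeze_max, v_burst = v_burst,
    speed_autocorr = speed_autocorr,
    p_escape_base = p_escape_base, p_freeze_after_escape = p_freeze_after_escape,
    p_before_freeze = p_before_freeze, p_stay_freeze = p_stay_freeze,
    coupling = coupling, group_trait_mix = group_trait_mix,
    archetype_assignment = archetype_assignment,
    position_noise_sd = position_noise_sd, seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("n_groups", "n_individuals", "n_trials")) {
    if (!is_count(cfg[[f]])) stop_config(f, "must be a positive integer")
  }
  if (!is.numeric(cfg$fps) || cfg$fps <= 0) stop_config("fps", "must be positive")
  if (!is.numeric(cfg$interval_s) || cfg$interval_s <= 0) {
    stop_config("interval_s", "must be positive")
  }
  fpi <- cfg$fps * cfg$interval_s
  if (abs(fpi - round(fpi)) > 1e-9) {
    stop_config("fps", "times `interval_s` must be an integer number of frames")
  }
  if (cfg$arena_w <= 0 || cfg$arena_h <= 0) stop_config("arena_w", "and `arena_h` must be positive")
  for (f in c("p_escape_base", "p_freeze_after_escape", "p_before_freeze", "p_stay_freeze")) {
    if (!is_prob(cfg[[f]])) stop_config(f, "must be a probability in [0, 1]")
  }
  if (!is.numeric(cfg$coupling) || length(cfg$coupling) != 1L || is.na(cfg$coupling) ||
      cfg$coupling < 0) {
    stop_config("coupling", "must be a non-negative number")
  }
  if (!(cfg$v_freeze_max < 0.2)) stop_config("v_freeze_max", "must be below 0.2 cm/s")
  if (!(cfg$v_normal_mean > 0.2)) stop_config("v_normal_mean", "must exceed 0.2 cm/s")
  if (!(cfg$v_normal_mean < 6)) stop_config("v_normal_mean", "must be below 6 cm/s")
  if (!(cfg$v_burst >= 6)) stop_config("v_burst", "must be at least 6 cm/s")
  if (!(cfg$v_normal_cap > cfg$v_normal_mean && cfg$v_normal_cap < 6)) {
    stop_config("v_normal_cap", "must lie between `v_normal_mean` and 6 cm/s")
  }
  if (!is.numeric(cfg$v_normal_sd) || cfg$v_normal_sd <= 0) {
    stop_config("v_normal_sd", "must be positive")
  }
  if (!is.numeric(cfg$speed_autocorr) || cfg$speed_autocorr < 0 || cfg$speed_autocorr >= 1) {
    stop_config("speed_autocorr", "must be in [0, 1)")
  }
  if (!is.numeric(cfg$position_noise_sd) || cfg$position_noise_sd < 0) {
    stop_config("position_noise_sd", "must be non-negative")
  }
  if (!is.data.frame(cfg$group_trait_mix) ||
      !all(c("archetype", "weight", "freeze_logit", "escape_logit") %in%
             names(cfg$group_trait_mix))) {
    stop_config("group_trait_mix", "must be an archetype_mix() data frame")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed)) {
    stop_config("seed", "must be a finite number")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d groups x %d individuals x %d trials, %g fps, %g s intervals\n",
    x$n_groups, x$n_individuals, x$n_trials, x$fps, x$interval_s
  ))
  cat(sprintf("  arena %g x %g cm; coupling %g; seed %g\n", x$arena_w, x$arena_h,
              x$coupling, x$seed))
  cat(sprintf("  archetypes: %s\n",
              paste(sprintf("%s (w=%.2f)", x$group_trait_mix$archetype,
                            x$group_trait_mix$weight), collapse = ", ")))
  invisible(x)
}
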