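# Group-level synchrony of post-LS freezing: FS counts per trial, the seeded
# shuffle null of independent responding, and the chi-square comparison.

#' Count freezing individuals per trial and build the FS-count histogram
#'
#' For each group-trial, counts the individuals whose after-LS state is FS and
#' tabulates the counts over bins 0-6 (for groups of six). Bimodality with
#' mass at 0 and 6 is the signature of all-or-none collective responses.
#'
#' @param states data.frame with `group`, `trial`, `individual` and `after`
#'   columns (from [classify_states()] or [simulate_states()]).
#' @param n_individuals Group size; every group-trial must have exactly this
#'   many rows.
#' @return An `fs_count_histogram`: list with `freq` (named integer vector
#'   over bins 0..n), `counts` (data.frame group, trial, fs), `total` (number
#'   of trials) and `condition`.
#' @export
count_fs_per_trial <- function(states, n_individuals = 6) {
  if (!all(c("group", "trial", "after") %in% names(states))) {
    stop("`states` needs group, trial and after columns", call. = FALSE)
  }
  key <- interaction(states$group, states$trial, drop = TRUE)
  sizes <- tapply(rep(1L, nrow(states)), key, sum)
  if (any(sizes != n_individuals)) {
    bad <- names(sizes)[which(sizes != n_individuals)[1]]
    stop(sprintf("group-trial %s has %d individuals, expected %d",
                 bad, sizes[[bad]], n_individuals), call. = FALSE)
  }
  fs <- tapply(states$after == "FS", key, sum)
  parts <- do.call(rbind, strsplit(names(fs), ".", fixed = TRUE))
  counts <- data.frame(group = parts[, 1], trial = parts[, 2],
                       fs = as.integer(fs), row.names = NULL,
                       stringsAsFactors = FALSE)
  freq <- tabulate(counts$fs + 1L, nbins = n_individuals + 1L)
  names(freq) <- 0:n_individuals
  cond <- if ("condition" %in% names(states)) {
    paste(unique(states$condition), collapse = "+")
  } else NA_character_
  structure(list(freq = freq, counts = counts, total = nrow(counts),
                 n_individuals = n_individuals, condition = cond),
            class = "fs_count_histogram")
}

#' @export
print.fs_count_histogram <- function(x, ...) {
  cat(sprintf("<fs_count_histogram> %d trials, groups of %d\n", x$total,
              x$n_individuals))
  print(x$freq)
  invisible(x)
}

#' Configuration of the shuffle null
#'
#' @param n_replicates Number of shuffled virtual datasets.
#' @param seeds Integer seed per replicate (defaults to 1..n_replicates,
#'   the convention used for the published virtual datasets).
#' @param pool_scope `"within_trial"` permutes individuals across groups
#'   separately for each trial index (shuffling the states of each trial
#'   among groups); `"global"` pools all individual-trials.
#' @return A list of class `shuffle_config`.
#' @export
shuffle_config <- function(n_replicates = 1000,
                           seeds = seq_len(n_replicates),
                           pool_scope = c("within_trial", "global")) {
  pool_scope <- match.arg(pool_scope)
  if (!is_count(n_replicates)) stop("`n_replicates` must be a positive integer", call. = FALSE)
  if (length(seeds) != n_replicates) {
    stop("`seeds` must have length `n_replicates`", call. = FALSE)
  }
  structure(list(n_replicates = n_replicates, seeds = as.integer(seeds),
                 pool_scope = pool_scope),
            class = "shuffle_config")
}

#' Shuffle null distribution of FS counts under independent responding
#'
#' Builds virtual datasets under the null that each individual's post-LS
#' freezing is independent of its group: for every replicate (with its own
#' seed), the binary FS indicators are pooled across groups (within each
#' trial index by default), permuted uniformly, reassigned to groups of six,
#' and the FS-count histogram recomputed. Per-bin proportions are averaged
#' across replicates. The permutation preserves the marginal FS prevalence
#' exactly in every replicate.
#'
#' @param states data.frame with `group`, `trial`, `individual`, `after`
#'   columns.
#' @param cfg A [shuffle_config()].
#' @param n_individuals Group size.
#' @return A `shuffle_null_dist`: list with `props` (expected per-bin
#'   proportions, summing to 1), `replicate_freq` (replicates x bins matrix),
#'   `total` (trials per replicate) and the config.
#' @export
shuffle_null <- function(states, cfg = shuffle_config(), n_individuals = 6) {
  if (!all(c("group", "trial", "after") %in% names(states))) {
    stop("`states` needs group, trial and after columns", call. = FALSE)
  }
  groups <- sort(unique(states$group))
  trials <- sort(unique(states$trial))
  if (cfg$pool_scope == "within_trial" && length(groups) < 2L) {
    stop("need at least 2 groups to shuffle within trial indices", call. = FALSE)
  }
  # flags[individual-slot, group, trial]
  ord <- order(match(states$group, groups), states$trial)
  st <- states[ord, ]
  key <- paste(st$group, st$trial)
  sizes <- table(key)
  if (any(sizes != n_individuals)) {
    stop(sprintf("every group-trial must have exactly %d individuals", n_individuals),
         call. = FALSE)
  }
  flag_arr <- array(NA, dim = c(n_individuals, length(groups), length(trials)))
  for (gi in seq_along(groups)) for (ti in seq_along(trials)) {
    rows <- st$group == groups[gi] & st$trial == trials[ti]
    flag_arr[, gi, ti] <- st$after[rows] == "FS"
  }
  if (anyNA(flag_arr)) stop("incomplete design: missing group-trial cells", call. = FALSE)

  n_bins <- n_individuals + 1L
  total <- length(groups) * length(trials)
  rep_freq <- matrix(0L, nrow = cfg$n_replicates, ncol = n_bins,
                     dimnames = list(NULL, 0:n_individuals))
  for (r in seq_len(cfg$n_replicates)) {
    rep_freq[r, ] <- with_seed(cfg$seeds[r], {
      counts <- integer(0)
      if (cfg$pool_scope == "within_trial") {
        for (ti in seq_along(trials)) {
          pool <- as.vector(flag_arr[, , ti])
          pool <- pool[sample.int(length(pool))]
          counts <- c(counts, colSums(matrix(pool, nrow = n_individuals)))
        }
      } else {
        pool <- as.vector(flag_arr)
        pool <- pool[sample.int(length(pool))]
        counts <- colSums(matrix(pool, nrow = n_individuals))
      }
      tabulate(counts + 1L, nbins = n_bins)
    })
  }
  props <- colMeans(rep_freq) / total
  structure(list(props = props, replicate_freq = rep_freq, total = total,
                 n_individuals = n_individuals, config = cfg),
            class = "shuffle_null_dist")
}

#' Chi-square comparison of observed vs null FS-count distributions
#'
#' Plug-in goodness-of-fit test: expected counts are the null per-bin
#' proportions times the observed trial total, giving `df = bins - 1 = 6` for
#' groups of six. Bins with zero expected count are merged into their nearest
#' non-zero neighbour (reducing df) and the result is flagged.
#'
#' @param obs An [count_fs_per_trial()] histogram.
#' @param null A [shuffle_null()] distribution (or a bare vector of per-bin
#'   proportions).
#' @return List with `statistic`, `df`, `p.value`, `expected`, `merged`.
#' @examples
#' # two-bin toy: O = (90, 10) against proportions (0.5, 0.5) gives chi2 = 64
#' @export
chi_square_compare <- function(obs, null) {
  stopifnot(inherits(obs, "fs_count_histogram"))
  props <- if (inherits(null, "shuffle_null_dist")) null$props else as.numeric(null)
  if (length(props) != length(obs$freq)) {
    stop("null proportions and observed bins differ in length", call. = FALSE)
  }
  if (obs$total <= 0) stop("observed histogram is empty", call. = FALSE)
  if (abs(sum(props) - 1) > 1e-8) stop("null proportions must sum to 1", call. = FALSE)
  O <- as.numeric(obs$freq)
  E <- props * obs$total
  merged <- FALSE
  while (any(E == 0) && length(E) > 1L) {
    merged <- TRUE
    i <- which(E == 0)[1]
    j <- if (i < length(E)) i + 1L else i - 1L
    E[j] <- E[j] + E[i]; O[j] <- O[j] + O[i]
    E <- E[-i]; O <- O[-i]
  }
  if (any(E == 0)) stop("all expected counts are zero", call. = FALSE)
  stat <- sum((O - E)^2 / E)
  df <- length(E) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = E, merged = merged)
}
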