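# Independent brute-force oracles, written without reference to the package
# implementations they check.

# naive frame-counting interval classifier
oracle_classify_interval <- function(labels, fps = 5, v_fs_min_s = 8,
                                     hs_min_frames = 1) {
  n_high <- 0
  n_freeze <- 0
  for (l in labels) {
    if (l == "high") n_high <- n_high + 1
    if (l == "freeze") n_freeze <- n_freeze + 1
  }
  if (n_high >= hs_min_frames) return("HS")
  if (n_freeze / fps >= v_fs_min_s) return("FS")
  "NS"
}

# naive pair-counting of transitions
oracle_transition_counts <- function(triples, step) {
  states <- c("FS", "NS", "HS")
  m <- matrix(0, 3, 3, dimnames = list(states, states))
  for (i in seq_len(nrow(triples))) {
    from <- if (step == "before_during") triples$before[i] else triples$during[i]
    to <- if (step == "before_during") triples$during[i] else triples$after[i]
    m[from, to] <- m[from, to] + 1
  }
  m
}

# explicit binomial upper-tail sum
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), 0))
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# state triples data.frame from a matrix of pattern draws
make_triples <- function(before, during, after, group = "g01", trial = NULL) {
  n <- length(before)
  data.frame(
    group = rep_len(group, n),
    trial = if (is.null(trial)) seq_len(n) else trial,
    individual = seq_len(n) - 1L,
    before = before, during = during, after = after,
    stringsAsFactors = FALSE
  )
}

# full-design states table with i.i.d. Bernoulli(p) post-LS freezing
make_bernoulli_states <- function(n_groups, n_trials, p, n_ind = 6) {
  df <- expand.grid(individual = seq_len(n_ind) - 1L,
                    group = sprintf("g%02d", seq_len(n_groups)),
                    trial = seq_len(n_trials),
                    stringsAsFactors = FALSE)
  df$before <- "NS"
  df$during <- "NS"
  df$after <- ifelse(stats::runif(nrow(df)) < p, "FS", "NS")
  df
}

# wrap a bare speeds matrix as a velocity_matrix
make_vm <- function(speeds, group = "g01", condition = "familiar") {
  n <- nrow(speeds)
  structure(
    list(speeds = speeds,
         info = data.frame(group = rep(group, n), trial = seq_len(n),
                           individual = 0L, condition = condition,
                           stringsAsFactors = FALSE)),
    class = "velocity_matrix", fps = 5, window = 5
  )
}
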