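# Markov transition matrices, the 27-pattern space, enrichment tests and DOT
# export of transition diagrams. State order is fixed as (FS, NS, HS).

#' Enumerate the 27 before/during/after transition patterns
#'
#' Each individual-trial's state sequence over the three intervals is one of
#' `3^3 = 27` patterns. The integer index is `9*before + 3*during + after`
#' with FS = 0, NS = 1, HS = 2.
#'
#' @return data.frame with columns `index` (0-26), `before`, `during`,
#'   `after` and `pattern` (e.g. `"N->H->F"`).
#' @examples
#' nrow(enumerate_patterns()) # 27
#' @export
enumerate_patterns <- function() {
  grid <- expand.grid(after = 0:2, during = 0:2, before = 0:2)
  grid <- grid[, c("before", "during", "after")]
  grid <- grid[order(9 * grid$before + 3 * grid$during + grid$after), ]
  df <- data.frame(
    index = as.integer(9 * grid$before + 3 * grid$during + grid$after),
    before = .STATES[grid$before + 1L],
    during = .STATES[grid$during + 1L],
    after = .STATES[grid$after + 1L],
    stringsAsFactors = FALSE
  )
  df$pattern <- pattern_label(df$before, df$during, df$after)
  rownames(df) <- NULL
  df
}

pattern_label <- function(before, during, after) {
  paste(substr(before, 1, 1), substr(during, 1, 1), substr(after, 1, 1),
        sep = "->")
}

#' Integer pattern code of state triples
#'
#' @param before,during,after Character vectors over `{"FS","NS","HS"}`.
#' @return Integer vector in 0-26 (`9*before + 3*during + after`, FS=0, NS=1,
#'   HS=2).
#' @examples
#' pattern_index("NS", "NS", "NS") # 13
#' @export
pattern_index <- function(before, during, after) {
  enc <- function(s) {
    i <- match(s, .STATES) - 1L
    if (anyNA(i)) stop("states must be FS, NS or HS", call. = FALSE)
    i
  }
  9L * enc(before) + 3L * enc(during) + enc(after)
}

check_triples <- function(triples) {
  if (!is.data.frame(triples) ||
      !all(c("before", "during", "after") %in% names(triples))) {
    stop("`triples` must be a data.frame with before/during/after columns",
         call. = FALSE)
  }
  if (nrow(triples) == 0L) stop("`triples` is empty", call. = FALSE)
  invisible(triples)
}

#' Count and normalise state transitions across one step
#'
#' Builds the 3x3 transition count matrix for one step of the trial (before to
#' during, or during to after) and row-normalises it into transition
#' probabilities. Rows with zero counts are left all-zero and flagged rather
#' than divided.
#'
#' @param triples data.frame with `before`, `during`, `after` columns.
#' @param step `"before_during"` or `"during_after"`.
#' @return A `transition_matrix`: list with `counts`, `probs` (both 3x3 in
#'   (FS, NS, HS) order), `step` and `zero_rows` (logical).
#' @export
count_transitions <- function(triples, step = c("before_during", "during_after")) {
  check_triples(triples)
  step <- match.arg(step)
  from <- factor(if (step == "before_during") triples$before else triples$during,
                 levels = .STATES)
  to <- factor(if (step == "before_during") triples$during else triples$after,
               levels = .STATES)
  if (anyNA(from) || anyNA(to)) stop("states must be FS, NS or HS", call. = FALSE)
  counts <- unclass(table(from, to))
  dimnames(counts) <- list(.STATES, .STATES)
  rs <- rowSums(counts)
  probs <- counts
  nz <- rs > 0
  probs[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  probs[!nz, ] <- 0
  structure(list(counts = counts, probs = probs, step = step, zero_rows = !nz),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> step %s (n = %d)\n", x$step, sum(x$counts)))
  print(round(x$probs, 3))
  invisible(x)
}

#' Tabulate the frequencies of the 27 transition patterns
#'
#' @param triples data.frame with `before`, `during`, `after` columns.
#' @return A `pattern_table` data.frame: index, pattern, before, during,
#'   after, count, freq (relative frequency); counts sum to `nrow(triples)`.
#' @export
pattern_frequencies <- function(triples) {
  check_triples(triples)
  idx <- pattern_index(triples$before, triples$during, triples$after)
  tab <- enumerate_patterns()
  tab$count <- tabulate(idx + 1L, nbins = 27L)
  tab$freq <- tab$count / nrow(triples)
  class(tab) <- c("pattern_table", "data.frame")
  tab
}

#' One-sided binomial enrichment test over the 27 patterns
#'
#' Tests each pattern against the null that all 27 patterns occur with equal
#' probability `p0 = 1/27`: the one-sided (upper tail) p-value is the exact
#' binomial tail `P(X >= k)` for `X ~ Binomial(n, p0)`, and q-values come from
#' Benjamini-Hochberg correction over the full 27-pattern family (zero-count
#' patterns have p = 1 and stay in the family). Stars follow the usual
#' convention: `***` q < 0.001, `**` q < 0.01, `*` q < 0.05.
#'
#' @param table A `pattern_table` from [pattern_frequencies()].
#' @param n Total number of individual-trials (defaults to the count sum).
#' @param p0 Null probability per pattern.
#' @param method Multiple-testing method passed to [stats::p.adjust()].
#' @return The table with `p`, `q` and `stars` columns filled.
#' @export
binomial_enrichment <- function(table, n = sum(table$count), p0 = 1 / 27,
                                method = "BH") {
  if (!all(c("count") %in% names(table))) {
    stop("`table` must come from pattern_frequencies()", call. = FALSE)
  }
  if (!(p0 > 0 && p0 < 1)) stop("`p0` must lie in (0, 1)", call. = FALSE)
  if (any(table$count > n)) stop("a pattern count exceeds `n`", call. = FALSE)
  table$p <- stats::pbinom(table$count - 1L, size = n, prob = p0,
                           lower.tail = FALSE)
  table$q <- stats::p.adjust(table$p, method = method)
  table$stars <- ifelse(table$q < 0.001, "***",
                        ifelse(table$q < 0.01, "**",
                               ifelse(table$q < 0.05, "*", "")))
  table
}

#' Export the two-step transition diagram as DOT text
#'
#' Emits a Graphviz DOT digraph with 9 nodes (3 states x 3 intervals). Node
#' size is proportional to the share of individuals in that state during that
#' interval, edge labels carry transition probabilities (2 decimals) and edge
#' thickness is proportional to transition counts; zero-count edges are
#' omitted.
#'
#' @param m_bd `transition_matrix` for the before-to-during step.
#' @param m_da `transition_matrix` for the during-to-after step.
#' @param state_counts 3x3 numeric matrix of state counts, rows = intervals
#'   (before, during, after), columns = states (FS, NS, HS). Defaults to the
#'   margins of the two transition matrices.
#' @param file Optional path to write the DOT text to.
#' @return The DOT source as a single character string (invisibly when
#'   `file` is given).
#' @export
export_dot <- function(m_bd, m_da, state_counts = NULL, file = NULL) {
  stopifnot(inherits(m_bd, "transition_matrix"), inherits(m_da, "transition_matrix"))
  if (is.null(state_counts)) {
    state_counts <- rbind(
      before = rowSums(m_bd$counts),
      during = colSums(m_bd$counts),
      after = colSums(m_da$counts)
    )
  }
  total <- sum(m_bd$counts)
  intervals <- c("before", "during", "after")
  colour <- c(FS = "grey70", NS = "lightblue", HS = "red")
  lines <- c(
    "digraph state_transitions {",
    "  rankdir=LR;",
    "  node [shape=circle, style=filled, fixedsize=true];"
  )
  for (i in seq_along(intervals)) {
    for (s in .STATES) {
      n <- state_counts[i, s]
      prop <- if (total > 0) n / total else 0
      lines <- c(lines, sprintf(
        '  %s_%s [label="%s\\n%d", width=%.3f, fillcolor="%s"];',
        intervals[i], s, s, as.integer(n), 0.5 + 1.5 * prop, colour[[s]]
      ))
    }
  }
  emit_edges <- function(m, from_iv, to_iv) {
    out <- character(0)
    maxc <- max(m$counts, 1)
    for (a in .STATES) for (b in .STATES) {
      k <- m$counts[a, b]
      if (k > 0) {
        out <- c(out, sprintf(
          '  %s_%s -> %s_%s [label="%.2f", penwidth=%.2f, weight=%d];',
          from_iv, a, to_iv, b, m$probs[a, b], 0.5 + 4 * k / maxc, as.integer(k)
        ))
      }
    }
    out
  }
  lines <- c(lines,
             emit_edges(m_bd, "before", "during"),
             emit_edges(m_da, "during", "after"),
             "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}
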