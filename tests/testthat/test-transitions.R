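# Pattern space, transition matrices, enrichment testing and DOT export.

test_that("the pattern space enumerates all 27 sequences bijectively", {
  pat <- enumerate_patterns()
  expect_identical(nrow(pat), 27L)
  expect_identical(pat$index, 0:26)
  expect_identical(pattern_index("NS", "NS", "NS"), 13L)
  expect_identical(pattern_index("FS", "FS", "FS"), 0L)
  expect_identical(pattern_index("HS", "HS", "HS"), 26L)
  rebuilt <- pattern_index(pat$before, pat$during, pat$after)
  expect_identical(rebuilt, pat$index)
  expect_identical(anyDuplicated(pat$pattern), 0L)
  expect_error(pattern_index("XX", "NS", "NS"), "FS, NS or HS")
})

test_that("transition counting and normalisation follow the observed pairs", {
  one <- make_triples("NS", "HS", "FS")
  m <- count_transitions(one, "before_during")
  expect_equal(m$counts["NS", "HS"], 1)
  expect_equal(sum(m$counts), 1)
  expect_equal(m$probs["NS", "HS"], 1)
  expect_true(m$zero_rows[["FS"]] && m$zero_rows[["HS"]])
  expect_true(all(m$probs[m$zero_rows, ] == 0))

  pat <- enumerate_patterns()
  all27 <- make_triples(pat$before, pat$during, pat$after)
  for (step in c("before_during", "during_after")) {
    m27 <- count_transitions(all27, step)
    expect_true(all(rowSums(m27$counts) == 9))
    expect_true(all(abs(m27$probs - 1 / 3) < 1e-12))
  }
  expect_error(count_transitions(all27[0, ]), "empty")
})

test_that("transition matrices equal a brute-force pair-counting oracle", {
  set.seed(21)
  states <- c("FS", "NS", "HS")
  for (rep in 1:10) {
    tr <- make_triples(sample(states, 100, TRUE), sample(states, 100, TRUE),
                       sample(states, 100, TRUE))
    for (step in c("before_during", "during_after")) {
      m <- count_transitions(tr, step)
      expect_equal(unclass(m$counts), oracle_transition_counts(tr, step),
                   ignore_attr = TRUE)
      expect_true(all(abs(rowSums(m$probs)[!m$zero_rows] - 1) < 1e-12))
    }
  }
})

test_that("pattern frequencies tally every individual-trial exactly once", {
  uni <- make_triples(rep("NS", 1020), rep("NS", 1020), rep("NS", 1020))
  tab <- pattern_frequencies(uni)
  expect_identical(tab$count[tab$index == 13], 1020L)
  expect_identical(sum(tab$count), 1020L)
  single <- pattern_frequencies(make_triples("HS", "NS", "FS"))
  expect_identical(sum(single$count), 1L)
  expect_identical(single$count[single$index == pattern_index("HS", "NS", "FS")], 1L)
})

test_that("enrichment p-values are exact binomial upper tails with BH control", {
  pat <- enumerate_patterns()
  counts <- integer(27); counts[14] <- 27 # index 13 gets everything
  tab <- pattern_frequencies(
    make_triples(rep("NS", 27), rep("NS", 27), rep("NS", 27))
  )
  enr <- binomial_enrichment(tab)
  # k = 0 has p = 1; k = n has p = p0^n
  expect_equal(enr$p[enr$count == 0], rep(1, 26))
  expect_equal(enr$p[enr$index == 13], (1 / 27)^27)
  # oracle tail sum at k = 3, n = 27: pattern 13 thrice, 24 others once each
  others <- pat[pat$index != 13, ][1:24, ]
  k3 <- pattern_frequencies(make_triples(
    c(rep("NS", 3), others$before),
    c(rep("NS", 3), others$during),
    c(rep("NS", 3), others$after)
  ))
  stopifnot(max(k3$count) == 3)
  enr3 <- binomial_enrichment(k3)
  i3 <- which(k3$count == 3)[1]
  expect_equal(enr3$p[i3], oracle_binom_tail(3, 27, 1 / 27), tolerance = 1e-12)
  # BH agrees with the textbook step-up computed independently
  expect_equal(enr3$q, oracle_bh(enr3$p), tolerance = 1e-12)
  expect_true(all(enr3$q >= enr3$p - 1e-15))
  expect_true(all(enr3$q >= 0 & enr3$q <= 1))
  expect_error(binomial_enrichment(tab, n = 5), "exceeds")
})

test_that("q-values are monotone in the sorted p-values", {
  set.seed(5)
  tr <- make_triples(sample(c("FS", "NS", "HS"), 500, TRUE, c(.2, .6, .2)),
                     sample(c("FS", "NS", "HS"), 500, TRUE, c(.1, .5, .4)),
                     sample(c("FS", "NS", "HS"), 500, TRUE, c(.4, .5, .1)))
  enr <- binomial_enrichment(pattern_frequencies(tr))
  o <- order(enr$p)
  expect_true(all(diff(enr$q[o]) >= -1e-15))
})

test_that("the DOT diagram carries 9 nodes and probability-labelled edges", {
  uni <- make_triples(rep("NS", 60), rep("NS", 60), rep("NS", 60))
  dot <- export_dot(count_transitions(uni, "before_during"),
                    count_transitions(uni, "during_after"))
  lines <- strsplit(dot, "\n")[[1]]
  expect_length(grep("fillcolor", lines), 9) # node statements
  edges <- grep("->", lines, value = TRUE)
  expect_length(edges, 2)
  expect_true(all(grepl('label="1.00"', edges, fixed = TRUE)))

  set.seed(77)
  tr <- make_triples(sample(c("FS", "NS", "HS"), 200, TRUE),
                     sample(c("FS", "NS", "HS"), 200, TRUE),
                     sample(c("FS", "NS", "HS"), 200, TRUE))
  m_bd <- count_transitions(tr, "before_during")
  m_da <- count_transitions(tr, "during_after")
  dot2 <- export_dot(m_bd, m_da)
  # re-parse edge labels and compare against the probability matrices
  el <- regmatches(dot2, gregexpr(
    "(before|during)_(FS|NS|HS) -> (during|after)_(FS|NS|HS) \\[label=\"[0-9.]+\"",
    dot2
  ))[[1]]
  expect_gt(length(el), 0)
  for (e in el) {
    parts <- regmatches(e, regexec(
      "(before|during)_(FS|NS|HS) -> (during|after)_(FS|NS|HS) \\[label=\"([0-9.]+)\"", e
    ))[[1]]
    m <- if (parts[2] == "before") m_bd else m_da
    expect_equal(as.numeric(parts[6]), round(m$probs[parts[3], parts[5]], 2),
                 tolerance = 1e-9)
  }
  # the text parses as a DOT digraph: balanced braces, digraph header
  expect_match(dot2, "^digraph")
  expect_equal(lengths(regmatches(dot2, gregexpr("\\{", dot2))),
               lengths(regmatches(dot2, gregexpr("\\}", dot2))))
})

test_that("uniform pattern draws almost never reach q < 0.001 (type-I control)", {
  set.seed(61)
  pat <- enumerate_patterns()
  hits <- vapply(1:50, function(r) {
    draw <- sample.int(27, 1020, replace = TRUE)
    enr <- binomial_enrichment(pattern_frequencies(
      make_triples(pat$before[draw], pat$during[draw], pat$after[draw])
    ))
    sum(enr$q < 0.001)
  }, 0)
  expect_lt(mean(hits), 0.05)
})
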