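# Frame labelling, interval state rules, trial classification and data-driven
# threshold derivation.

th <- threshold_spec()

test_that("frame labels respect the stated boundary conventions", {
  expect_identical(label_frames(c(0.1, 0.2, 5.99, 6.0, 12), th),
                   c("freeze", "normal", "normal", "high", "high"))
  expect_identical(label_frames(0.19999, th), "freeze")
  expect_error(label_frames(c(1, -0.1), th), "negative")
  expect_error(label_frames(c(1, NA), th), "finite")
})

test_that("interval rules: total freezing >= 8 s is FS, any high frame is HS", {
  fs <- classify_interval(rep("freeze", 50), th)
  expect_identical(fs$state, "FS")
  expect_equal(fs$freeze_s, 10)
  ns <- classify_interval(rep("normal", 50), th)
  expect_identical(ns$state, "NS")
  expect_equal(ns$freeze_s, 0)
  hs <- classify_interval(c(rep("normal", 49), "high"), th)
  expect_identical(hs$state, "HS")
  expect_identical(hs$high_frames, 1L)
  # intermediate total freezing (2 s <= f < 8 s) falls to NS: exhaustiveness
  mid <- classify_interval(c(rep("freeze", 25), rep("normal", 25)), th)
  expect_identical(mid$state, "NS")
  expect_equal(mid$freeze_s, 5)
  expect_error(classify_interval(rep("normal", 49), th), "exactly 50")
})

test_that("HS takes precedence over FS by default, configurably", {
  frames <- c("high", rep("freeze", 45), rep("normal", 4))
  expect_identical(classify_interval(frames, th)$state, "HS")
  expect_identical(classify_interval(frames, th, precedence = "FS")$state, "FS")
})

test_that("interval classification matches the brute-force oracle", {
  set.seed(123)
  for (i in 1:1000) {
    probs <- as.vector(stats::rmultinom(1, 10, rep(1, 3))) / 10
    labels <- sample(c("freeze", "normal", "high"), 50, replace = TRUE,
                     prob = probs + 0.01)
    expect_identical(classify_interval(labels, th)$state,
                     oracle_classify_interval(labels))
  }
})

test_that("adding high or freeze frames never demotes the respective state", {
  set.seed(9)
  for (i in 1:200) {
    labels <- sample(c("freeze", "normal", "high"), 50, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1))
    s0 <- classify_interval(labels, th)$state
    # promote one non-high frame to high
    if (any(labels != "high")) {
      lab1 <- labels
      lab1[which(lab1 != "high")[1]] <- "high"
      expect_identical(classify_interval(lab1, th)$state, "HS")
    }
    # promoting normal frames to freeze can only move NS towards FS
    if (s0 == "FS") {
      lab2 <- labels
      lab2[lab2 == "normal"] <- "freeze"
      expect_identical(classify_interval(lab2, th)$state, "FS")
    }
  }
})

test_that("trials split into three intervals classified independently", {
  expect_identical(as.character(classify_trial(rep(0.05, 150), th)),
                   c("FS", "FS", "FS"))
  expect_identical(as.character(classify_trial(rep(1.0, 150), th)),
                   c("NS", "NS", "NS"))
  reactive <- c(rep(1.0, 50), rep(1.0, 20), 8, 8, rep(1.0, 28), rep(0.05, 50))
  expect_identical(as.character(classify_trial(reactive, th)), c("NS", "HS", "FS"))
  prov <- attr(classify_trial(reactive, th), "provenance")
  expect_equal(prov$high_frames, c(0, 2, 0))
  expect_equal(prov$freeze_s[3], 10)
})

test_that("derived thresholds find the trough between well-separated modes", {
  set.seed(31)
  speeds <- matrix(c(abs(rnorm(50 * 150, 0.01, 0.003)),
                     abs(rnorm(50 * 150, 1.0, 0.05))),
                   nrow = 100, byrow = TRUE)
  vm <- make_vm(speeds)
  d <- derive_thresholds(vm)
  expect_gt(d$v_freeze, 0.02)
  expect_lt(d$v_freeze, 1.0)
})

test_that("degenerate speed distributions fall back to the defaults loudly", {
  set.seed(32)
  vm_uni <- make_vm(matrix(stats::rlnorm(100 * 150, log(1.5), 0.3), nrow = 100))
  expect_warning(d <- derive_thresholds(vm_uni), "bimodal")
  expect_equal(d$v_freeze, 0.2)
  expect_equal(d$v_high, 6.0)
  vm_const <- make_vm(matrix(1, nrow = 10, ncol = 150))
  expect_warning(dc <- derive_thresholds(vm_const), "constant")
  expect_equal(dc$v_freeze, 0.2)
  expect_error(derive_thresholds(make_vm(matrix(1, 1, 150))), "at least 2")
})

test_that("thresholds derived from default synthetic data recover the
          construction, agreeing with a brute-force KDE scan", {
  sim <- simulate_experiment(sim_config(seed = 77))
  vm <- build_velocity_matrix(sim$tables)
  d <- derive_thresholds(vm)
  expect_gte(d$v_freeze, 0.1)
  expect_lte(d$v_freeze, 0.3)
  expect_gte(d$v_high, 5)
  expect_lte(d$v_high, 7)

  # oracle: independent scan of the same kernel densities
  post <- as.vector(vm$speeds[, 101:150])
  dp <- stats::density(post, bw = 0.03, n = 2048, from = 0)
  modes <- integer(0)
  for (i in seq_along(dp$y)) {
    left <- if (i == 1) -Inf else dp$y[i - 1]
    right <- if (i == length(dp$y)) -Inf else dp$y[i + 1]
    if (dp$y[i] > left && dp$y[i] > right) modes <- c(modes, i)
  }
  top2 <- modes[order(dp$y[modes], decreasing = TRUE)[1:2]]
  grid <- (min(top2) + 1):(max(top2) - 1)
  trough_oracle <- dp$x[grid][which.min(dp$y[grid])]
  expect_equal(d$v_freeze, trough_oracle, tolerance = 1e-8)

  pre <- as.vector(vm$speeds[, 1:50])
  dq <- stats::density(pre, bw = "nrd0", n = 2048, from = 0)
  keep <- dq$y >= 0.01 * max(dq$y)
  v_high_oracle <- dq$x[max(which(keep)) + 1]
  expect_equal(d$v_high, v_high_oracle, tolerance = 1e-8)
})
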