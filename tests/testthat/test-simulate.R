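# Agent-based generator: configuration validation, seeded determinism,
# commanded speed regimes and the consensus mechanism.

small_cfg <- function(...) sim_config(n_groups = 2, n_trials = 2, seed = 99, ...)

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_groups = 0), "n_groups")
  expect_error(sim_config(p_escape_base = 1.2), "p_escape_base")
  expect_error(sim_config(v_freeze_max = 0.3), "v_freeze_max")
  expect_error(sim_config(v_burst = 4), "v_burst")
  expect_error(sim_config(arena_w = -1), "arena_w")
  expect_error(sim_config(fps = 3, interval_s = 10.1), "fps")
  expect_error(sim_config(coupling = -2), "coupling")
})

test_that("identical config and seed give byte-identical experiments", {
  a <- simulate_experiment(small_cfg())
  b <- simulate_experiment(small_cfg())
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth, b$truth)
  # and the RNG state of the session is not what made them equal
  c <- simulate_experiment(sim_config(n_groups = 2, n_trials = 2, seed = 100))
  expect_false(identical(a$tables[[1]], c$tables[[1]]))
})

test_that("forced consensus (infinite coupling) yields only unanimous trials", {
  cfg <- sim_config(n_groups = 10, n_trials = 50, coupling = Inf, seed = 4)
  h <- count_fs_per_trial(simulate_states(cfg)$states)
  expect_identical(sum(h$freq[c("1", "2", "3", "4", "5")]), 0L)
  expect_identical(sum(h$freq), 500L)
})

test_that("independent individuals (coupling 0) follow the exact binomial law", {
  q <- 0.35
  cfg <- sim_config(
    n_groups = 10, n_trials = 100, coupling = 0, p_escape_base = 0,
    group_trait_mix = archetype_mix("uniform", 1, stats::qlogis(q), 0),
    seed = 3
  )
  h <- count_fs_per_trial(simulate_states(cfg)$states)
  emp <- h$freq / h$total
  exact <- vapply(0:6, function(k) choose(6, k) * q^k * (1 - q)^(6 - k), 0)
  expect_lt(0.5 * sum(abs(emp - exact)), 0.06) # total variation at 1000 trials
})

test_that("mass at unanimous outcomes is monotone in the coupling strength", {
  mass <- vapply(c(0, 2, 6), function(cp) {
    cfg <- sim_config(n_groups = 10, n_trials = 100, coupling = cp,
                      group_trait_mix = archetype_mix("u", 1, stats::qlogis(0.4), 0),
                      seed = 5)
    h <- count_fs_per_trial(simulate_states(cfg)$states)
    (h$freq[["0"]] + h$freq[["6"]]) / h$total
  }, 0)
  expect_true(all(diff(mass) >= 0))
})

test_that("trajectories realise the commanded speed regimes", {
  cfg <- small_cfg()
  set.seed(11)
  # commanded regime, no tracking noise: all-freeze means every speed < 0.2
  path <- simulate_trajectory(c("FS", "FS", "FS"), cfg, noise_sd = 0)
  sp <- sqrt(diff(path$x)^2 + diff(path$y)^2) * cfg$fps
  expect_true(all(sp < 0.2))
  expect_true(all(path$x >= 0 & path$x <= cfg$arena_w))
  expect_true(all(path$y >= 0 & path$y <= cfg$arena_h))
  # a high-speed during interval carries a burst >= 6 cm/s in frames 51..100
  path2 <- simulate_trajectory(c("NS", "HS", "FS"), cfg)
  sp2 <- sqrt(diff(path2$x)^2 + diff(path2$y)^2) * cfg$fps
  expect_true(any(sp2[50:99] >= 6))
})

test_that("reflection keeps even absurdly fast paths inside the arena", {
  cfg <- sim_config(n_groups = 1, n_trials = 1, v_burst = 200, seed = 2)
  set.seed(3)
  for (i in 1:5) {
    path <- simulate_trajectory(c("NS", "HS", "NS"), cfg)
    expect_true(all(path$x >= 0 & path$x <= cfg$arena_w))
    expect_true(all(path$y >= 0 & path$y <= cfg$arena_h))
  }
})

test_that("ground-truth states are realised by the rendered trajectories", {
  cfg <- sim_config(n_groups = 3, seed = 8)
  sim <- simulate_experiment(cfg)
  vm <- build_velocity_matrix(sim$tables)
  st <- classify_states(vm)
  m <- merge(st, sim$truth$states, by = c("group", "trial", "individual"),
             suffixes = c("", ".true"))
  agree <- m$before == m$before.true & m$during == m$during.true &
    m$after == m$after.true
  expect_gte(mean(agree), 0.99)
})

test_that("fixtures round-trip through the tracking reader", {
  sim <- simulate_experiment(small_cfg())
  dir <- withr::local_tempdir()
  man <- write_fixture(sim$tables, dir, pixels_per_cm = 20,
                       truth = sim$truth, seed = 99)
  expect_length(man$files, 4) # n_groups x n_trials
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  expect_length(files, 4)
  tab <- read_tracking(files[1])
  expect_s3_class(tab, "tracking_table")
  expect_identical(attr(tab, "units"), "px")
  cal <- calibration_spec(pixels_per_cm = 20)
  back <- calibrate(tab, cal)
  orig <- sim$tables[[basename(tools::file_path_sans_ext(files[1]))]]
  expect_equal(as.data.frame(back)$id0_x, orig$id0_x, tolerance = 1e-8)
  expect_equal(as.data.frame(back)$id5_y, orig$id5_y, tolerance = 1e-8)
})

test_that("writing an empty fixture set is an error", {
  expect_error(write_fixture(list(), tempdir()), "non-empty")
})
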