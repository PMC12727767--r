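# Reading, validation, calibration, speed computation and the velocity matrix.

make_table <- function(coords, units = "cm", fps = 5, group = "g01", trial = 1) {
  df <- data.frame(frame = seq_len(nrow(coords)) - 1L, coords)
  loomsync:::new_tracking_table(df, group = group, trial = trial,
                                condition = "familiar", units = units, fps = fps)
}

test_that("malformed tracking files are rejected with informative errors", {
  dir <- withr::local_tempdir()
  meta <- list(group = "g01", trial = 1, condition = "x", units = "cm", fps = 5)
  good <- data.frame(frame = 0:149, id0_x = runif(150), id0_y = runif(150))

  f1 <- file.path(dir, "gap.csv")
  bad1 <- good; bad1$frame[80:150] <- bad1$frame[80:150] + 1L
  write.csv(bad1, f1, row.names = FALSE)
  expect_error(read_tracking(f1, meta), "frame gap")

  f2 <- file.path(dir, "short.csv")
  write.csv(good[1:149, ], f2, row.names = FALSE)
  expect_error(read_tracking(f2, meta), "insufficient frames")

  f3 <- file.path(dir, "nan.csv")
  bad3 <- good; bad3$id0_y[7] <- NaN
  write.csv(bad3, f3, row.names = FALSE)
  expect_error(read_tracking(f3, meta), "id0_y.*row 7")

  f4 <- file.path(dir, "ok.csv")
  write.csv(good, f4, row.names = FALSE)
  expect_error(read_tracking(f4), "no metadata")
  expect_s3_class(read_tracking(f4, meta), "tracking_table")
})

test_that("calibration scales pixels linearly and is idempotent on cm", {
  cal <- calibration_spec(pixels_span = 400, source_length_cm = 20.0)
  expect_equal(cal$pixels_per_cm, 20)
  tab <- make_table(data.frame(id0_x = rep(40, 150), id0_y = rep(20, 150)),
                    units = "px")
  out <- calibrate(tab, cal)
  expect_equal(out$id0_x[1], 2.0)
  expect_equal(out$id0_y[1], 1.0)
  expect_identical(attr(out, "units"), "cm")
  expect_warning(again <- calibrate(out, cal), "no-op")
  expect_equal(as.data.frame(again), as.data.frame(out))
  expect_error(calibration_spec(pixels_per_cm = 0), "positive")
  expect_warning(calibration_spec(pixels_span = 400, source_length_cm = 25),
                 "20.0-20.5")
})

test_that("speed is displacement times frame rate, first frame duplicated", {
  x <- c(0, 0.2, rep(0.2, 148))
  tab <- make_table(data.frame(id0_x = x, id0_y = rep(0, 150)))
  sp <- compute_speed(tab)
  expect_equal(as.numeric(sp[1, 1]), 1.0) # duplicated from frame 2
  expect_equal(as.numeric(sp[1, 2]), 1.0) # 0.2 cm in 0.2 s
  expect_equal(as.numeric(sp[1, 3]), 0.0)

  still <- make_table(data.frame(id0_x = rep(3, 150), id0_y = rep(4, 150)))
  expect_true(all(compute_speed(still) == 0))

  diag <- make_table(data.frame(id0_x = c(0, rep(0.9, 149)),
                                id0_y = c(0, rep(1.2, 149))))
  expect_equal(as.numeric(compute_speed(diag)[1, 2]), 7.5) # hypotenuse 1.5 cm at 5 fps

  px <- make_table(data.frame(id0_x = rep(1, 150), id0_y = rep(1, 150)),
                   units = "px")
  expect_error(compute_speed(px), "calibrate first")
})

test_that("speed is invariant under rigid motions of the coordinate frame", {
  set.seed(42)
  for (rep in 1:5) {
    xy <- apply(matrix(rnorm(300, sd = 0.3), ncol = 2), 2, cumsum)
    tab <- make_table(data.frame(id0_x = xy[, 1], id0_y = xy[, 2]))
    th <- runif(1, 0, 2 * pi); dx <- runif(1, -5, 5); dy <- runif(1, -5, 5)
    rot <- data.frame(
      id0_x = cos(th) * xy[, 1] - sin(th) * xy[, 2] + dx,
      id0_y = sin(th) * xy[, 1] + cos(th) * xy[, 2] + dy
    )
    expect_equal(compute_speed(make_table(rot)), compute_speed(tab),
                 tolerance = 1e-10)
  }
})

test_that("trailing moving average uses partial leading windows", {
  expect_equal(smooth_speed(rep(3.3, 20), 5), rep(3.3, 20))
  expect_equal(smooth_speed(c(0, 0, 0, 0, 5), 5), c(0, 0, 0, 0, 1))
  expect_equal(smooth_speed(c(2, 4, 6), 2), c(2, 3, 5))
  x <- runif(50)
  expect_identical(smooth_speed(x, 1), x)
  expect_error(smooth_speed(x, 0), "positive integer")
})

test_that("smoothing never leaves the range of the raw series", {
  set.seed(7)
  for (rep in 1:20) {
    x <- runif(150, 0, 10)
    for (w in c(2, 5, 11)) {
      s <- smooth_speed(x, w)
      expect_true(all(s >= min(x) - 1e-12 & s <= max(x) + 1e-12))
    }
  }
})

test_that("velocity matrix dimensions follow the design exactly", {
  sim <- simulate_experiment(sim_config(n_groups = 1, n_trials = 1, seed = 6))
  vm <- build_velocity_matrix(sim$tables)
  expect_identical(dim(vm$speeds), c(6L, 150L))
  expect_identical(vm$info$individual, 0:5)
  expect_true(all(is.finite(vm$speeds)) && all(vm$speeds >= 0))
})

test_that("heterogeneous individual counts within a group are rejected", {
  sim <- simulate_experiment(sim_config(n_groups = 1, n_trials = 2, seed = 6))
  crippled <- sim$tables
  crippled[[2]] <- crippled[[2]][, 1:11] # drop one individual's columns
  class(crippled[[2]]) <- class(sim$tables[[2]])
  for (a in c("group", "trial", "condition", "units", "fps")) {
    attr(crippled[[2]], a) <- attr(sim$tables[[2]], a)
  }
  expect_error(build_velocity_matrix(crippled), "heterogeneous")
})
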