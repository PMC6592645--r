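make_records <- function(raw, od_loaded, lc = 100, protein = "Cln2",
                         mix_id = "mixA") {
  tibble::tibble(
    condition = "TEST", replicate = 1L, blot_id = "b1", mix_id = mix_id,
    protein = protein, time_min = seq(0, by = 10, length.out = length(raw)),
    raw_intensity = raw, loading_control = lc
  )
}

test_that("mixing correction rescales to the reference load", {
  d <- function(od) mix_design(tibble::tibble(
    mix_id = "mixA", strain = "s", protein = "Cln2", od_loaded = od
  ))
  expect_equal(correct_mixing(make_records(100, 0.1), d(0.1))$corrected, 100)
  expect_equal(correct_mixing(make_records(200, 0.2), d(0.2))$corrected, 100)
  expect_equal(correct_mixing(make_records(50, 0.05), d(0.05))$corrected, 100)

  expect_error(correct_mixing(make_records(10, 0.1, protein = "Pcl7"), d(0.1)),
               class = "g1waves_xref_error")
})

test_that("mixing correction is invariant to joint scaling of load and signal", {
  withr::local_seed(21)
  for (i in 1:20) {
    c_scale <- runif(1, 0.1, 10)
    raw <- runif(1, 1, 500); od <- runif(1, 0.02, 0.4)
    d1 <- mix_design(tibble::tibble(mix_id = "mixA", strain = "s",
                                    protein = "Cln2", od_loaded = od))
    d2 <- mix_design(tibble::tibble(mix_id = "mixA", strain = "s",
                                    protein = "Cln2",
                                    od_loaded = od * c_scale))
    expect_equal(
      correct_mixing(make_records(raw, od), d1)$corrected,
      correct_mixing(make_records(raw * c_scale, od), d2)$corrected,
      tolerance = 1e-12
    )
  }
})

test_that("loading-control normalization equalizes lanes", {
  expect_equal(normalize_loading(c(10, 20), c(100, 200), 150), c(15, 15))
  expect_equal(normalize_loading(7, 150, 150), 7)
  expect_error(normalize_loading(10, 0, 150),
               class = "g1waves_validation_error")

  # per-record scalar multiplications commute
  corrected <- c(3, 8, 12)
  lc <- c(90, 110, 130)
  a <- normalize_loading(corrected * 2, lc, 100)
  b <- normalize_loading(corrected, lc, 100) * 2
  expect_equal(a, b)
})

test_that("the full chain is invariant to per-lane gains", {
  cfg0 <- scenario_config(noise = noise_model(0, 0, 5),
                          sample_times = seq(0, 120, 15))
  clean <- quantify_records(simulate_blot_experiment(cfg0)$records,
                            cfg0$design)
  # lane gains only (band noise 0): output must match the zero-noise chain
  for (seed in c(5, 17)) {
    cfgg <- scenario_config(noise = noise_model(lane_gain_sd = 0.4,
                                                band_noise_sd = 0,
                                                seed = seed),
                            sample_times = seq(0, 120, 15))
    noisy <- quantify_records(simulate_blot_experiment(cfgg)$records,
                              cfgg$design)
    expect_equal(noisy$value, clean$value, tolerance = 1e-9)
  }

  # explicit random gains applied to every band and loading control of a lane
  withr::local_seed(31)
  rec <- simulate_blot_experiment(cfg0)$records
  lane_key <- paste(rec$mix_id, rec$time_min, rec$replicate)
  gains <- setNames(exp(rnorm(length(unique(lane_key)), 0, 0.5)),
                    unique(lane_key))
  rec2 <- rec
  rec2$raw_intensity <- rec$raw_intensity * unname(gains[lane_key])
  rec2$loading_control <- rec$loading_control * unname(gains[lane_key])
  expect_equal(quantify_records(rec2, cfg0$design)$value, clean$value,
               tolerance = 1e-9)
})

test_that("relativization divides by the single global maximum", {
  courses <- tibble::tibble(
    condition = "TEST", replicate = 1L,
    protein = "Cln2", time_min = c(0, 10, 20), value = c(2, 4, 8)
  )
  out <- relativize(courses)
  expect_equal(out$value, c(0.25, 0.5, 1))

  two <- dplyr::bind_rows(
    tibble::tibble(condition = "TEST", replicate = 1L, protein = "Cln2",
                   time_min = c(0, 10), value = c(0.2, 0.5)),
    tibble::tibble(condition = "TEST", replicate = 1L, protein = "Sic1",
                   time_min = c(0, 10), value = c(1.0, 0.1))
  )
  out2 <- relativize(two)
  expect_equal(out2$value, c(0.2, 0.5, 1.0, 0.1))  # max already 1

  zero <- dplyr::mutate(courses, value = 0)
  expect_error(relativize(zero), class = "g1waves_data_error")
})

test_that("relativization preserves curve crossings", {
  withr::local_seed(41)
  times <- seq(0, 60, 15)
  for (i in 1:10) {
    clb5 <- sort(runif(length(times)))
    sic1 <- rev(sort(runif(length(times))))
    scale <- runif(1, 0.2, 5)
    courses <- dplyr::bind_rows(
      tibble::tibble(condition = "T", replicate = 1L, protein = "Clb5",
                     time_min = times, value = clb5 * scale),
      tibble::tibble(condition = "T", replicate = 1L, protein = "Sic1",
                     time_min = times, value = sic1 * scale)
    )
    rel <- relativize(courses)
    t_rel <- find_start(times, rel$value[rel$protein == "Clb5"],
                        rel$value[rel$protein == "Sic1"])$t_start
    t_raw <- find_start(times, clb5, sic1)$t_start
    expect_equal(t_rel, t_raw, tolerance = 1e-12)
  }
})

test_that("replicate aggregation reports mean and SEM correctly", {
  courses <- tibble::tibble(
    condition = "TEST", replicate = 1:3, protein = "Cln2",
    time_min = 0, value = c(1, 2, 3)
  )
  bp <- aggregate_replicates(courses, rescale = FALSE)
  expect_equal(bp$mean, 2)
  expect_equal(bp$sem, 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(bp$n, 3L)

  same <- dplyr::mutate(courses, value = 5)
  expect_equal(aggregate_replicates(same, rescale = FALSE)$sem, 0)

  single <- courses[1, ]
  one <- aggregate_replicates(single, rescale = FALSE)
  expect_equal(one$mean, 1)
  expect_true(is.na(one$sem))

  staggered <- courses
  staggered$time_min <- c(0, 0, 5)
  expect_error(aggregate_replicates(staggered),
               class = "g1waves_validation_error")
})

test_that("blueprint means peak at exactly 1 after rescaling", {
  cfg <- scenario_config(noise = noise_model(0.1, 0.05, 2),
                         sample_times = seq(0, 120, 10))
  sim <- simulate_blot_experiment(cfg)
  bp <- aggregate_replicates(quantify_records(sim$records, cfg$design))
  expect_equal(max(bp$mean), 1)
})

test_that("the zero-noise chain reproduces ground truth", {
  cfg <- scenario_config(noise = noise_model(0, 0, 1),
                         sample_times = seq(0, 120, 5))
  sim <- simulate_blot_experiment(cfg)
  out <- quantify_records(sim$records, cfg$design) |>
    dplyr::arrange(replicate, protein, time_min)
  truth <- dplyr::arrange(sim$truth, protein, time_min)
  for (r in unique(out$replicate)) {
    sub <- out[out$replicate == r, ]
    expect_lt(max(abs(sub$value - truth$relative)), 1e-9)
  }
})
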