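test_that("START is the interpolated first negative-to-positive crossing", {
  est <- find_start(c(0, 15, 30, 45), clb5 = c(0, 0, 1, 1),
                    sic1 = c(1, 1, 0, 0))
  expect_true(est$crossing_found)
  expect_equal(est$t_start, 22.5)
  expect_equal(est$bracket, c(15, 30))
  expect_false(est$at_boundary)

  # Clb5 already above Sic1 at release
  boundary <- find_start(c(0, 10, 20), clb5 = c(1, 1, 1), sic1 = c(0.5, 1, 2))
  expect_equal(boundary$t_start, 0)
  expect_true(boundary$at_boundary)

  none <- find_start(c(0, 10, 20), clb5 = c(0, 0, 0), sic1 = c(1, 1, 1))
  expect_false(none$crossing_found)
  expect_true(is.na(none$t_start))

  # only the FIRST crossing counts
  re_cross <- find_start(c(0, 10, 20, 30, 40),
                         clb5 = c(0, 1, 0, 1, 1), sic1 = c(0.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(re_cross$t_start, 5)
})

test_that("START is invariant to a common rescaling of both landmark curves", {
  withr::local_seed(13)
  times <- seq(0, 90, 15)
  for (i in 1:15) {
    sic1 <- rev(sort(runif(length(times), 0, 1))) + 0.01
    clb5 <- sort(runif(length(times), 0, 1))
    base <- find_start(times, clb5, sic1)
    c_scale <- runif(1, 1e-3, 1e3)
    scaled <- find_start(times, clb5 * c_scale, sic1 * c_scale)
    expect_equal(scaled$t_start, base$t_start, tolerance = 1e-9)
    expect_equal(scaled$crossing_found, base$crossing_found)
  }
})

test_that("mismatched landmark grids raise an alignment error", {
  courses <- dplyr::bind_rows(
    tibble::tibble(condition = "T", replicate = 1L, protein = "Clb5",
                   time_min = c(0, 10, 20), value = c(0, 0.5, 1)),
    tibble::tibble(condition = "T", replicate = 1L, protein = "Sic1",
                   time_min = c(0, 10, 25), value = c(1, 0.5, 0))
  )
  expect_error(estimate_start(courses, mode = "per-replicate"),
               class = "g1waves_validation_error")
})

test_that("AUC to START integrates trapezoidally with endpoint interpolation", {
  expect_equal(auc_to_start(c(0, 15, 30, 45), rep(1, 4), 30), 30)
  expect_equal(auc_to_start(c(0, 60), c(0, 1), 60), 30)
  expect_equal(auc_to_start(c(0, 60), c(0, 1), 30), 7.5)
  expect_error(auc_to_start(c(0, 60), c(0, 1), 90),
               class = "g1waves_validation_error")
  expect_error(auc_to_start(c(0, 60), c(0, 1), NA_real_),
               class = "g1waves_data_error")

  # additive over subintervals
  times <- seq(0, 100, 10)
  vals <- c(0, 1, 3, 2, 5, 4, 4, 2, 1, 0.5, 0)
  full <- auc_to_start(times, vals, 95)
  expect_equal(auc_to_start(times, vals, 45) +
                 (full - auc_to_start(times, vals, 45)), full)

  # non-decreasing in t_start for non-negative curves
  withr::local_seed(17)
  for (i in 1:10) {
    v <- runif(11, 0, 2)
    cuts <- sort(runif(5, 0, 100))
    aucs <- vapply(cuts, function(ct) auc_to_start(times, v, ct), numeric(1))
    expect_true(all(diff(aucs) >= -1e-12))
  }
})

test_that("grid refinement leaves piecewise-linear results unchanged and converges for pulses", {
  # piecewise-linear landmark curves: halving the step is exact
  t1 <- seq(0, 60, 10)
  t2 <- seq(0, 60, 5)
  clb5_f <- function(t) pmin(t / 40, 1.5)
  sic1_f <- function(t) pmax(1 - t / 30, 0)
  s1 <- find_start(t1, clb5_f(t1), sic1_f(t1))
  s2 <- find_start(t2, clb5_f(t2), sic1_f(t2))
  expect_equal(s1$t_start, s2$t_start, tolerance = 1e-12)
  expect_equal(auc_to_start(t1, clb5_f(t1), s1$t_start),
               auc_to_start(t2, clb5_f(t2), s2$t_start), tolerance = 1e-12)

  # smooth pulse cut at t = 0: the truncation leaves an O(h^2) boundary
  # term, so the error shrinks monotonically with the step and at h = 1 is
  # within the a-priori (h^2/12)|f'(0)| bound
  p <- wave_params("Cln2", 0, 1, 30, 8, 10)
  oracle <- quadrature_oracle(p, 0, 120, step = 0.01)
  err <- vapply(c(4, 2, 1), function(h) {
    tt <- seq(0, 120, h)
    abs(auc_to_start(tt, simulate_cyclin_wave(p, tt), 120) - oracle)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-4)

  # over the pulse's full support the boundary terms vanish and the 1-min
  # trapezoid matches dense quadrature to 1e-6
  tt <- seq(30 - 10 * 8, 30 + 10 * 10, by = 1)
  expect_equal(auc_to_start(tt, simulate_cyclin_wave(p, tt), max(tt)),
               quadrature_oracle(p, min(tt), max(tt), step = 0.01),
               tolerance = 1e-6)
})

test_that("peak metrics report the grid argmax with earliest-time ties", {
  expect_equal(peak_metrics(c(0, 10, 20), c(0, 2, 1)),
               list(peak_time = 10, peak_value = 2))
  expect_equal(peak_metrics(c(0, 10, 20), c(3, 3, 3))$peak_time, 0)

  p <- wave_params("Pcl1", baseline = 0.1, amplitude = 0.7, peak_time = 40,
                   sigma_rise = 9, sigma_fall = 13)
  tt <- seq(0, 120, 1)
  pm <- peak_metrics(tt, simulate_cyclin_wave(p, tt))
  expect_equal(pm$peak_time, 40)
  expect_equal(pm$peak_value, 0.8)
})

test_that("family fractions follow their definitions and sum to one", {
  ws <- family_fractions(c(Pcl1 = 2, Pcl2 = 1.5, Pcl7 = 0.5,
                           Cln1 = 0.4, Cln2 = 0.5, Cln3 = 0.1))
  expect_equal(ws$pcl_total, 4)
  expect_equal(ws$cln_total, 1)
  expect_equal(ws$pcl_fraction, 0.8)

  even <- family_fractions(setNames(rep(2, 6), c(cln_family(), pcl_family())))
  expect_equal(even$pcl_fraction, 0.5)
  expect_equal(unname(even$per_cyclin_fraction), rep(1 / 6, 6))

  expect_error(family_fractions(setNames(rep(0, 6),
                                         c(cln_family(), pcl_family()))),
               class = "g1waves_data_error")

  withr::local_seed(23)
  for (i in 1:20) {
    aucs <- setNames(runif(8, 0, 10), cyclin_proteins())
    f <- family_fractions(aucs)
    expect_equal(sum(f$per_cyclin_fraction), 1, tolerance = 1e-12)
    expect_equal(f$pcl_fraction,
                 f$pcl_total / (f$pcl_total + f$cln_total))
  }
})

test_that("zero-noise scenarios recover the analytic family AUC ratio", {
  # verification scenario: START falls after the G1-cyclin pulses have
  # decayed, so trapezoid boundary terms vanish and the analytic ratio is
  # recovered at 1e-6 on a 1-min grid
  cfg <- scenario_with_family_auc(4, 1, base_waves = verification_waves(),
                                  sample_times = seq(0, 160, 1))
  sim <- simulate_blot_experiment(cfg)
  ws <- summarise_waves(quantify_records(sim$records, cfg$design),
                        mode = "mean-curve")[[1]]
  expect_equal(ws$pcl_fraction, attr(cfg, "pcl_fraction_true"),
               tolerance = 1e-6)
  expect_equal(ws$t_start, attr(cfg, "t_start_true"), tolerance = 0.05)

  # realistic waves: START cuts mid-pulse, leaving an O(h^2) trapezoid
  # boundary term; agreement is bounded by the a-priori 1e-3 estimate
  cfg2 <- scenario_with_family_auc(4, 1)
  sim2 <- simulate_blot_experiment(cfg2)
  ws2 <- summarise_waves(quantify_records(sim2$records, cfg2$design),
                         mode = "mean-curve")[[1]]
  expect_equal(ws2$pcl_fraction, 0.8, tolerance = 1e-3)
})

test_that("mean-curve and per-replicate summaries agree at zero noise", {
  cfg <- scenario_with_family_auc(3, 2, sample_times = seq(0, 120, 2))
  sim <- simulate_blot_experiment(cfg)
  courses <- quantify_records(sim$records, cfg$design)
  a <- summarise_waves(courses, mode = "mean-curve")[[1]]
  b <- summarise_waves(courses, mode = "per-replicate")[[1]]
  expect_equal(a$pcl_fraction, b$pcl_fraction, tolerance = 1e-9)
  expect_equal(a$t_start, b$t_start, tolerance = 1e-9)
  expect_equal(a$pcl_fraction, 0.6, tolerance = 1e-3)
})

test_that("missing crossings propagate as unavailable summaries", {
  courses <- dplyr::bind_rows(lapply(c("Clb5", "Sic1", "Cln2"), function(p) {
    tibble::tibble(condition = "T", replicate = 1L, protein = p,
                   time_min = c(0, 10, 20),
                   value = if (p == "Sic1") c(1, 1, 1) else c(0, 0.1, 0.2))
  }))
  st <- estimate_start(courses, mode = "mean-curve")
  expect_false(st$crossing_found)
  expect_error(summarise_waves(courses, mode = "mean-curve"),
               class = "g1waves_data_error")
})
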