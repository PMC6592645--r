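# Shared fixtures and independent oracles for the test suite.

# Wave table for numerical-verification scenarios: every G1-cyclin pulse
# sits >= 7 rise-sigmas after release and >= 4 fall-sigmas before the
# Sic1/Clb5 crossing (near 85 min), so the integrand has decayed below 1e-9
# of its peak at both integration ends, trapezoid boundary terms vanish,
# and area recovery can be checked at tight tolerance.
verification_waves <- function() {
  dplyr::bind_rows(
    wave_params("Cln3", 0, 0.15, 36, 5.0, 6),
    wave_params("Cln1", 0, 0.85, 40, 5.5, 8),
    wave_params("Cln2", 0, 1.00, 42, 6.0, 8),
    wave_params("Pcl1", 0, 0.50, 40, 5.5, 8),
    wave_params("Pcl2", 0, 0.45, 38, 5.3, 8),
    wave_params("Pcl7", 0, 0.25, 45, 6.0, 9),
    wave_params("Clb5", 0, 0.70, 140, 20, 20),
    wave_params("Sic1", 0, 0.80, 0, 10, 30)
  )
}

# Independent quadrature oracle: dense trapezoid sum at a fixed fine step,
# sharing no code with wave_auc_analytic or auc_to_start.
quadrature_oracle <- function(params, from, to, step = 0.01) {
  grid <- seq(from, to, by = step)
  if (grid[length(grid)] < to) grid <- c(grid, to)
  v <- simulate_cyclin_wave(params, grid)
  sum(diff(grid) * (v[-length(v)] + v[-1]) / 2)
}

# A small two-mix design used by I/O and normalization tests.
small_design <- function(reference_od = 0.1) {
  mix_design(tibble::tibble(
    mix_id = c("mixA", "mixA", "mixB", "mixB"),
    strain = c("sCLN2", "sSIC1", "sCLB5", "sPCL1"),
    protein = c("Cln2", "Sic1", "Clb5", "Pcl1"),
    od_loaded = c(0.1, 0.2, 0.1, 0.05)
  ), reference_od = reference_od)
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Random band-intensity table consistent with a design (for round-trip
# property tests).
random_records <- function(design, n_times = 4, replicates = 2) {
  times <- sort(sample(0:120, n_times))
  grid <- tidyr::expand_grid(
    replicate = seq_len(replicates),
    tibble::as_tibble(design)[c("mix_id", "protein")],
    time_min = as.numeric(times)
  )
  lanes <- dplyr::distinct(grid, replicate, mix_id, time_min)
  lanes$loading_control <- stats::runif(nrow(lanes), 50, 150)
  out <- dplyr::left_join(grid, lanes,
                          by = c("replicate", "mix_id", "time_min"))
  tibble::tibble(
    condition = "TEST",
    replicate = as.integer(out$replicate),
    blot_id = paste0("TEST_rep", out$replicate),
    mix_id = out$mix_id,
    protein = out$protein,
    time_min = out$time_min,
    raw_intensity = stats::runif(nrow(out), 0, 1000),
    loading_control = out$loading_control
  )
}
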