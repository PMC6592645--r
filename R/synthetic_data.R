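# Synthetic-data generator: pulse-shaped cyclin abundance waves, the
# pooled-blot observation model, and OD660 growth curves, all with known
# ground truth so the downstream pipeline can be validated end to end.

#' Parameters of one cyclin abundance pulse
#'
#' Each protein's wave is modelled as a two-sided Gaussian pulse: a baseline
#' plus a peak of height `amplitude` at `peak_time`, rising with width
#' `sigma_rise` and decaying with width `sigma_fall` (minutes). The
#' asymmetric widths reproduce the skewed appearance/disappearance dynamics
#' of cyclin waves with five interpretable parameters.
#'
#' @param protein Protein label (see \code{\link{cyclin_proteins}}).
#' @param baseline Constant floor, relative units >= 0.
#' @param amplitude Pulse height above baseline, relative units >= 0.
#' @param peak_time Time of the maximum, minutes since release.
#' @param sigma_rise,sigma_fall Gaussian widths (minutes, > 0) before and
#'   after the peak.
#' @return One-row tibble of wave parameters.
#' @export
#' @examples
#' wave_params("Cln2", amplitude = 1, peak_time = 30,
#'             sigma_rise = 10, sigma_fall = 14)
wave_params <- function(protein, baseline = 0, amplitude = 1,
                        peak_time = 30, sigma_rise = 10, sigma_fall = 10) {
  if (!is.finite(sigma_rise) || sigma_rise <= 0 ||
      !is.finite(sigma_fall) || sigma_fall <= 0) {
    abort_validation("sigma_rise and sigma_fall must be positive")
  }
  if (baseline < 0 || amplitude < 0) {
    abort_validation("baseline and amplitude must be >= 0")
  }
  tibble::tibble(protein = as.character(protein), baseline = baseline,
                 amplitude = amplitude, peak_time = peak_time,
                 sigma_rise = sigma_rise, sigma_fall = sigma_fall)
}

#' Evaluate a cyclin pulse on a time grid
#'
#' `a(t) = baseline + amplitude * exp(-(t - peak_time)^2 / (2 sigma^2))` with
#' `sigma = sigma_rise` before the peak and `sigma_fall` after it.
#'
#' @param params One-row wave-parameter tibble (or a list with the same
#'   fields), as from \code{\link{wave_params}}.
#' @param times Numeric vector of times (minutes); must be finite.
#' @return Numeric vector of relative abundances, `>= baseline` everywhere.
#' @export
simulate_cyclin_wave <- function(params, times) {
  if (!is.finite(params$sigma_rise) || params$sigma_rise <= 0 ||
      !is.finite(params$sigma_fall) || params$sigma_fall <= 0) {
    abort_validation("sigma_rise and sigma_fall must be positive")
  }
  if (any(!is.finite(times))) abort_validation("times must be finite")
  sigma <- ifelse(times < params$peak_time, params$sigma_rise,
                  params$sigma_fall)
  params$baseline +
    params$amplitude * exp(-(times - params$peak_time)^2 / (2 * sigma^2))
}

#' Analytic integral of a cyclin pulse over a time window
#'
#' Closed form for the area under \code{\link{simulate_cyclin_wave}} over
#' `[from, to]`, using the Gaussian CDF piecewise on either side of the
#' peak. Over the whole real line a baseline-0 pulse integrates to
#' `amplitude * sqrt(pi/2) * (sigma_rise + sigma_fall)`.
#'
#' @inheritParams simulate_cyclin_wave
#' @param from,to Window bounds in minutes, `from <= to`.
#' @return Area in relative units x minutes.
#' @export
wave_auc_analytic <- function(params, from, to) {
  if (to < from) abort_validation("requires from <= to")
  p <- params$peak_time
  gauss <- function(s, a, b) {
    s * sqrt(2 * pi) * (pnorm((b - p) / s) - pnorm((a - p) / s))
  }
  area <- params$baseline * (to - from)
  if (from < p) {
    area <- area + params$amplitude * gauss(params$sigma_rise, from, min(to, p))
  }
  if (to > p) {
    area <- area + params$amplitude * gauss(params$sigma_fall, max(from, p), to)
  }
  area
}

#' Default wave-parameter tables per condition
#'
#' Ships a qualitative wave table for each preset condition: the YPD30 base
#' table places the global maximum on Cln2 and the Sic1/Clb5 crossing near
#' 37 min after release; stress and medium presets apply qualitative
#' modifications (e.g. strongly elevated Pcl cyclins in malt-based medium at
#' 37 degrees C, delayed Cln waves under osmotic stress). The numbers encode
#' qualitative patterns only and are package fixtures, not measured data.
#'
#' @param condition One of \code{\link{condition_presets}}.
#' @return Tibble with one row per protein (all eight).
#' @export
default_waves <- function(condition = "YPD30") {
  base <- dplyr::bind_rows(
    wave_params("Cln3", baseline = 0.05, amplitude = 0.15, peak_time = 10,
                sigma_rise = 8, sigma_fall = 12),
    wave_params("Cln1", amplitude = 0.85, peak_time = 30,
                sigma_rise = 10, sigma_fall = 12),
    wave_params("Cln2", amplitude = 1.00, peak_time = 30,
                sigma_rise = 10, sigma_fall = 14),
    wave_params("Pcl1", amplitude = 0.50, peak_time = 35,
                sigma_rise = 10, sigma_fall = 12),
    wave_params("Pcl2", amplitude = 0.45, peak_time = 30,
                sigma_rise = 10, sigma_fall = 14),
    wave_params("Pcl7", amplitude = 0.25, peak_time = 45,
                sigma_rise = 15, sigma_fall = 20),
    wave_params("Clb5", amplitude = 0.70, peak_time = 60,
                sigma_rise = 15, sigma_fall = 18),
    wave_params("Sic1", amplitude = 0.80, peak_time = 0,
                sigma_rise = 10, sigma_fall = 22)
  )
  if (!condition %in% condition_presets()) {
    abort_validation(paste0("unknown condition preset: ", condition))
  }
  scale_amp <- function(df, proteins, f) {
    df$amplitude[df$protein %in% proteins] <-
      df$amplitude[df$protein %in% proteins] * f
    df
  }
  shift_peak <- function(df, proteins, d) {
    df$peak_time[df$protein %in% proteins] <-
      df$peak_time[df$protein %in% proteins] + d
    df
  }
  w <- base
  if (condition == "YPD37") {
    w <- scale_amp(w, "Pcl2", 2.2)
    w <- scale_amp(w, c("Cln1", "Cln2"), 0.8)
  } else if (condition == "MALT30") {
    w <- scale_amp(w, c("Pcl1", "Pcl2"), 1.3)
  } else if (condition == "MALT37") {
    w <- scale_amp(w, "Pcl1", 2.0)
    w <- scale_amp(w, "Pcl2", 4.0)
    w <- scale_amp(w, "Pcl7", 1.5)
    w <- scale_amp(w, c("Cln1", "Cln2"), 0.45)
  } else if (condition == "NACL0.4M") {
    w <- scale_amp(w, c("Cln1", "Cln2"), 0.7)
    w <- shift_peak(w, c("Cln1", "Cln2", "Clb5"), 10)
    w$sigma_fall[w$protein == "Sic1"] <- 28
  } else if (condition == "NAC100MM") {
    w <- scale_amp(w, setdiff(cyclin_proteins(), "Sic1"), 0.9)
  } else if (condition == "MEN10UM") {
    w <- scale_amp(w, setdiff(cyclin_proteins(), "Sic1"), 0.8)
    w <- shift_peak(w, setdiff(cyclin_proteins(), "Sic1"), 15)
  }
  w
}

#' The canonical three-mix pooling design
#'
#' Mirrors the pooling scheme used to detect all eight tagged proteins on one
#' blot: mix 1 pools Cln2, Pcl2 and Clb5 at 0.1 OD each (0.3 OD total);
#' mix 2 pools Pcl1 at 0.1 OD and Cln3 at 0.2 OD; mix 3 pools Cln1 at
#' 0.05 OD, Pcl7 at 0.1 OD and Sic1 at 0.15 OD. Strain names follow the
#' tagged-gene convention (`CLN2-3HA` etc.).
#'
#' @inheritParams mix_design
#' @return A `mix_design`.
#' @export
default_mix_design <- function(reference_od = 0.1) {
  mix_design(tibble::tibble(
    mix_id = c("mix1", "mix1", "mix1", "mix2", "mix2",
               "mix3", "mix3", "mix3"),
    strain = c("CLN2-3HA", "PCL2-3HA", "CLB5-3HA", "PCL1-3HA", "CLN3-3HA",
               "CLN1-3HA", "PCL7-3HA", "SIC1-3HA"),
    protein = c("Cln2", "Pcl2", "Clb5", "Pcl1", "Cln3",
                "Cln1", "Pcl7", "Sic1"),
    od_loaded = c(0.1, 0.1, 0.1, 0.1, 0.2, 0.05, 0.1, 0.15)
  ), reference_od = reference_od)
}

#' Measurement-noise model for the pooled-blot simulator
#'
#' Noise is multiplicative log-normal at two levels: a per-lane gain
#' (transfer/exposure variability shared by every band in a lane, including
#' the loading control) and an independent per-band factor. Setting both
#' sigmas to 0 yields a deterministic observation model.
#'
#' @param lane_gain_sd,band_noise_sd Log-scale standard deviations (>= 0).
#' @param seed Integer RNG seed.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(lane_gain_sd = 0.1, band_noise_sd = 0.05, seed = 1L) {
  if (lane_gain_sd < 0 || band_noise_sd < 0) {
    abort_validation("noise standard deviations must be >= 0")
  }
  structure(list(lane_gain_sd = lane_gain_sd, band_noise_sd = band_noise_sd,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Assemble and validate a simulation scenario
#'
#' Bundles everything one synchronized-release experiment needs: the
#' condition label, a wave table for all eight proteins, the pooling design,
#' the sampling grid, the number of independent replicates (each replicate is
#' one blot), the noise model, and the growth-curve parameters.
#'
#' @param condition Condition label.
#' @param waves Wave-parameter tibble covering every protein in `design`;
#'   must include Clb5 and Sic1 (required to locate START downstream).
#' @param design A `mix_design`.
#' @param sample_times Strictly increasing minutes, starting at 0.
#' @param replicates Number of independent experiments (>= 1).
#' @param noise A \code{\link{noise_model}}.
#' @param growth List with `od0`, `doubling_time` (minutes), optional
#'   `capacity` (OD660 carrying capacity; NULL for pure exponential) and
#'   `noise_sd`.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(condition = "YPD30",
                            waves = default_waves(condition),
                            design = default_mix_design(),
                            sample_times = seq(0, 120, by = 5),
                            replicates = 3L,
                            noise = noise_model(),
                            growth = list(od0 = 0.05, doubling_time = 89,
                                          capacity = NULL, noise_sd = 0)) {
  if (!inherits(design, "mix_design")) design <- mix_design(design)
  waves <- tibble::as_tibble(waves)
  if (!all(c("Clb5", "Sic1") %in% waves$protein) ||
      !all(c("Clb5", "Sic1") %in% design$protein)) {
    abort_validation(
      "scenario must include Clb5 and Sic1 (START cannot be located without them)")
  }
  missing <- setdiff(design$protein, waves$protein)
  if (length(missing) > 0) {
    abort_validation(paste0("no wave parameters for protein(s): ",
                            paste(missing, collapse = ", ")))
  }
  if (any(waves$sigma_rise <= 0) || any(waves$sigma_fall <= 0)) {
    abort_validation("all sigma_rise/sigma_fall must be positive")
  }
  if (length(sample_times) < 2 || sample_times[1] != 0 ||
      any(diff(sample_times) <= 0)) {
    abort_validation("sample_times must be strictly increasing and start at 0")
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) abort_validation("replicates must be >= 1")
  if (!inherits(noise, "noise_model")) {
    noise <- do.call(noise_model, as.list(noise))
  }
  growth <- utils::modifyList(
    list(od0 = 0.05, doubling_time = 89, capacity = NULL, noise_sd = 0),
    growth[!vapply(growth, is.null, logical(1))]
  )
  structure(list(condition = condition, waves = waves, design = design,
                 sample_times = as.numeric(sample_times),
                 replicates = replicates, noise = noise, growth = growth),
            class = "scenario_config")
}

#' Preset scenarios for the shipped conditions
#'
#' @param name One of \code{\link{condition_presets}}.
#' @param seed RNG seed stored in the scenario's noise model.
#' @param ... Overrides passed on to \code{\link{scenario_config}}.
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(name = "YPD30", seed = 1L, ...) {
  if (!name %in% condition_presets()) {
    abort_validation(paste0("unknown preset '", name, "'; available: ",
                            paste(condition_presets(), collapse = ", ")))
  }
  scenario_config(condition = name, waves = default_waves(name),
                  noise = noise_model(seed = seed), ...)
}

#' Simulate a pooled-strain western-blot experiment
#'
#' For every lane (one mix at one sampling time on one replicate's blot) the
#' observed band intensity is
#' `abundance(t) * od_loaded * lane_gain * band_noise`, and the lane's
#' loading-control intensity is `total_od(mix) * lane_gain * lc_noise` —
#' band signal proportional to loaded cell amount times abundance, the
#' loading control proportional to total loaded cells, with multiplicative
#' log-normal lane gains and band noise. Each replicate is one blot.
#'
#' @param config A \code{\link{scenario_config}}.
#' @return List with `records` (a band-intensity tibble as accepted by
#'   \code{\link{validate_intensity_records}}) and `truth` (per-protein
#'   ground-truth curves on the sampling grid, with `abundance` and
#'   `relative` = abundance / global grid maximum).
#' @export
simulate_blot_experiment <- function(config) {
  if (!inherits(config, "scenario_config")) {
    abort_validation("config must be a scenario_config")
  }
  design <- config$design
  times <- config$sample_times
  waves <- config$waves
  totals <- total_od(design)

  truth <- waves |>
    dplyr::filter(.data$protein %in% design$protein) |>
    dplyr::rowwise() |>
    dplyr::reframe(protein = .data$protein, time_min = times,
                   abundance = simulate_cyclin_wave(
                     list(baseline = .data$baseline,
                          amplitude = .data$amplitude,
                          peak_time = .data$peak_time,
                          sigma_rise = .data$sigma_rise,
                          sigma_fall = .data$sigma_fall), times))
  truth$relative <- truth$abundance / max(truth$abundance)

  lanes <- tidyr::expand_grid(
    replicate = seq_len(config$replicates),
    mix_id = unique(design$mix_id),
    time_min = times
  )
  bands <- dplyr::inner_join(
    lanes, tibble::as_tibble(design)[c("mix_id", "protein", "od_loaded")],
    by = "mix_id", relationship = "many-to-many"
  )

  noise <- config$noise
  rec <- with_seed(noise$seed, {
    lanes$gain <- exp(rnorm(nrow(lanes), 0, noise$lane_gain_sd))
    lanes$eps_lc <- exp(rnorm(nrow(lanes), 0, noise$band_noise_sd))
    bands$eps_band <- exp(rnorm(nrow(bands), 0, noise$band_noise_sd))
    lanes <- dplyr::left_join(lanes, totals, by = "mix_id")
    lanes$loading_control <- lanes$total_od * lanes$gain * lanes$eps_lc
    b <- dplyr::left_join(
      bands,
      lanes[c("replicate", "mix_id", "time_min", "gain", "loading_control")],
      by = c("replicate", "mix_id", "time_min")
    )
    b <- dplyr::left_join(b, truth[c("protein", "time_min", "abundance")],
                          by = c("protein", "time_min"))
    b$raw_intensity <- b$abundance * b$od_loaded * b$gain * b$eps_band
    b
  })

  records <- tibble::tibble(
    condition = config$condition,
    replicate = as.integer(rec$replicate),
    blot_id = paste0(config$condition, "_rep", rec$replicate),
    mix_id = rec$mix_id,
    protein = rec$protein,
    time_min = rec$time_min,
    raw_intensity = rec$raw_intensity,
    loading_control = rec$loading_control
  )
  records <- dplyr::arrange(records, .data$condition, .data$replicate,
                            .data$protein, .data$time_min)
  list(records = records, truth = truth)
}

#' Simulate an OD660 growth curve
#'
#' Exponential growth `OD(t) = od0 * 2^(t / doubling_time)` when `capacity`
#' is NULL, otherwise logistic growth with that carrying capacity and the
#' same low-density doubling time; optional multiplicative log-normal noise.
#'
#' @param od0 Inoculation density (OD660, > 0).
#' @param doubling_time Doubling time in minutes (> 0).
#' @param capacity Carrying capacity in OD660 units, or NULL.
#' @param times Sampling times in minutes.
#' @param noise_sd Log-scale noise standard deviation (>= 0).
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @param strain Strain label for the output series.
#' @return Growth tibble with columns `strain`, `time_min`, `od660`.
#' @export
simulate_growth_curve <- function(od0, doubling_time, capacity = NULL,
                                  times = seq(0, 420, by = 10),
                                  noise_sd = 0, seed = NULL,
                                  strain = "strain1") {
  if (!is.finite(od0) || od0 <= 0 || !is.finite(doubling_time) ||
      doubling_time <= 0) {
    abort_validation("od0 and doubling_time must be positive")
  }
  if (is.null(capacity)) {
    od <- od0 * 2^(times / doubling_time)
  } else {
    if (capacity <= od0) abort_validation("capacity must exceed od0")
    r <- log(2) / doubling_time
    od <- capacity / (1 + ((capacity - od0) / od0) * exp(-r * times))
  }
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) {
      exp(rnorm(length(times), 0, noise_sd))
    } else {
      with_seed(seed, exp(rnorm(length(times), 0, noise_sd)))
    }
    od <- od * eps
  }
  tibble::tibble(strain = strain, time_min = as.numeric(times), od660 = od)
}

#' Construct a zero-noise scenario with prescribed family areas
#'
#' Builds a scenario whose Cln-family (Cln1+Cln2+Cln3) and Pcl-family
#' (Pcl1+Pcl2+Pcl7) pulses integrate, analytically, to the requested areas
#' over `[0, t*]`, where `t*` is the exact Sic1/Clb5 crossing of the
#' scenario's landmark waves. Baselines of the six G1 cyclins are set to 0
#' so the family areas scale linearly with the amplitudes. Used for
#' validating the area-under-curve and family-fraction stages against a
#' known answer.
#'
#' @param pcl_auc,cln_auc Target analytic family areas (relative units x
#'   minutes) over `[0, t*]`.
#' @param base_waves Wave table supplying the shapes (default YPD30).
#' @param sample_times Sampling grid (default 1-min from 0 to 120).
#' @param replicates Number of replicates.
#' @param condition Condition label for the generated records.
#' @return A `scenario_config` with attributes `t_start_true` (the analytic
#'   crossing time) and `pcl_fraction_true` (`pcl_auc / (pcl_auc + cln_auc)`).
#' @export
scenario_with_family_auc <- function(pcl_auc = 4, cln_auc = 1,
                                     base_waves = default_waves("YPD30"),
                                     sample_times = seq(0, 120, by = 1),
                                     replicates = 3L,
                                     condition = "SYNTH_FAMILY") {
  waves <- tibble::as_tibble(base_waves)
  fam <- c(cln_family(), pcl_family())
  waves$baseline[waves$protein %in% fam] <- 0

  wave_row <- function(p) waves[waves$protein == p, ]
  d <- function(t) {
    simulate_cyclin_wave(wave_row("Clb5"), t) -
      simulate_cyclin_wave(wave_row("Sic1"), t)
  }
  upper <- max(sample_times)
  if (d(0) >= 0 || d(upper) <= 0) {
    abort_validation("landmark waves do not cross within the sampling window")
  }
  t_star <- uniroot(d, interval = c(0, upper), tol = 1e-12)$root

  fam_auc <- function(proteins) {
    sum(vapply(proteins, function(p) wave_auc_analytic(wave_row(p), 0, t_star),
               numeric(1)))
  }
  waves$amplitude[waves$protein %in% cln_family()] <-
    waves$amplitude[waves$protein %in% cln_family()] *
    (cln_auc / fam_auc(cln_family()))
  waves$amplitude[waves$protein %in% pcl_family()] <-
    waves$amplitude[waves$protein %in% pcl_family()] *
    (pcl_auc / fam_auc(pcl_family()))

  cfg <- scenario_config(
    condition = condition, waves = waves,
    sample_times = sample_times, replicates = replicates,
    noise = noise_model(lane_gain_sd = 0, band_noise_sd = 0, seed = 1L)
  )
  attr(cfg, "t_start_true") <- t_star
  attr(cfg, "pcl_fraction_true") <- pcl_auc / (pcl_auc + cln_auc)
  cfg
}

#' Read or write a scenario configuration as YAML
#'
#' @param config A `scenario_config`.
#' @param path File path.
#' @return `read_scenario_config` returns a `scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  if (!inherits(config, "scenario_config")) {
    abort_validation("config must be a scenario_config")
  }
  out <- list(
    condition = config$condition,
    reference_od = reference_od(config$design),
    waves = lapply(seq_len(nrow(config$waves)),
                   function(i) as.list(config$waves[i, ])),
    design = lapply(seq_len(nrow(config$design)), function(i) {
      as.list(tibble::as_tibble(config$design)[i, ])
    }),
    sample_times = config$sample_times,
    replicates = config$replicates,
    noise = unclass(config$noise),
    growth = config$growth
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  raw <- yaml::read_yaml(path)
  needed <- c("condition", "waves", "design", "sample_times", "replicates")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort_format(paste0("scenario config is missing field(s): ",
                        paste(missing, collapse = ", ")))
  }
  waves <- dplyr::bind_rows(lapply(raw$waves, tibble::as_tibble))
  design <- mix_design(
    dplyr::bind_rows(lapply(raw$design, tibble::as_tibble)),
    reference_od = raw$reference_od %||% 0.1
  )
  scenario_config(
    condition = raw$condition, waves = waves, design = design,
    sample_times = unlist(raw$sample_times),
    replicates = raw$replicates,
    noise = do.call(noise_model, raw$noise %||% list()),
    growth = raw$growth %||% list()
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
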