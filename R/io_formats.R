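# Tabular I/O for all pipeline artifacts. Dialect: comma-separated UTF-8 with
# a header row; optional leading metadata lines starting with '#'. Times are
# minutes since release (alpha-factor removal or elutriation retrieval).

#' Construct and validate a mix design
#'
#' A mix design records which tagged strain (and hence which protein) is
#' pooled into which lane mix and at what OD660 contribution. The reference
#' OD is the load every protein is rescaled to by the mixing correction
#' (default 0.1 OD, the modal contribution in the pooling scheme).
#'
#' @param design Data frame with columns `mix_id`, `strain`, `protein`,
#'   `od_loaded` (one row per pooled strain).
#' @param reference_od Reference OD660 load, a single positive number.
#' @return A tibble of class `mix_design` with attribute `reference_od`.
#' @export
#' @examples
#' mix_design(data.frame(
#'   mix_id = "mix1", strain = c("sCLN2", "sPCL2", "sCLB5"),
#'   protein = c("Cln2", "Pcl2", "Clb5"), od_loaded = 0.1
#' ))
mix_design <- function(design, reference_od = 0.1) {
  design <- tibble::as_tibble(design)
  needed <- c("mix_id", "strain", "protein", "od_loaded")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    abort_format(paste0("sample sheet is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  design <- design[needed]
  design$mix_id <- as.character(design$mix_id)
  design$strain <- as.character(design$strain)
  design$protein <- as.character(design$protein)
  design$od_loaded <- as.numeric(design$od_loaded)
  if (!is.numeric(reference_od) || length(reference_od) != 1 ||
      !is.finite(reference_od) || reference_od <= 0) {
    abort_validation("reference_od must be a single positive number")
  }
  bad <- design$protein[!design$protein %in% cyclin_proteins()]
  if (length(bad) > 0) {
    abort_validation(paste0("unknown protein label(s): ",
                            paste(unique(bad), collapse = ", ")))
  }
  if (any(!is.finite(design$od_loaded)) || any(design$od_loaded <= 0)) {
    abort_validation("every od_loaded must be a finite positive OD660 value")
  }
  dup <- design |>
    dplyr::count(.data$mix_id, .data$protein) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_validation(paste0(
      "protein listed more than once within a mix: ",
      paste(paste0(dup$mix_id, "/", dup$protein), collapse = ", ")
    ))
  }
  attr(design, "reference_od") <- reference_od
  class(design) <- c("mix_design", class(design))
  design
}

#' Reference OD of a mix design
#' @param design A `mix_design`.
#' @return The reference OD660 load (scalar).
#' @export
reference_od <- function(design) {
  out <- attr(design, "reference_od")
  if (is.null(out)) 0.1 else out
}

#' Total pooled OD per mix
#'
#' Sums the OD660 contributions of the strains pooled into each mix; in the
#' canonical three-mix design every mix totals 0.3 OD.
#'
#' @param design A `mix_design`.
#' @return Tibble with columns `mix_id`, `total_od`.
#' @export
total_od <- function(design) {
  design |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$mix_id) |>
    dplyr::summarise(total_od = sum(.data$od_loaded), .groups = "drop")
}

#' Read a sample sheet describing the pooled mixes
#'
#' @param path Path to a CSV file with header columns
#'   `mix_id,strain,protein,od_loaded`.
#' @inheritParams mix_design
#' @return A validated `mix_design`.
#' @export
read_sample_sheet <- function(path, reference_od = 0.1) {
  df <- read_g1_csv(path)
  mix_design(df, reference_od = reference_od)
}

#' @rdname read_sample_sheet
#' @param design A `mix_design` to write.
#' @param meta Optional named character vector written as `# key: value`
#'   metadata header lines.
#' @export
write_sample_sheet <- function(design, path, meta = NULL) {
  write_g1_csv(tibble::as_tibble(design), path, meta = meta)
}

#' Read a band-intensity table and cross-check it against the mix design
#'
#' Each row is one densitometry measurement: a protein band in one lane
#' (condition, replicate, mix, time) plus that lane's loading-control
#' intensity. Every (mix_id, protein) pair must exist in the design.
#'
#' @param path CSV with header columns
#'   `condition,replicate,blot_id,mix_id,protein,time_min,raw_intensity,loading_control`.
#' @param design A `mix_design` the records must be consistent with.
#' @return Tibble of band-intensity records sorted by
#'   (condition, replicate, protein, time_min).
#' @export
read_intensity_table <- function(path, design) {
  df <- read_g1_csv(path)
  validate_intensity_records(df, design)
}

#' @rdname read_intensity_table
#' @param records A record tibble to write.
#' @inheritParams write_sample_sheet
#' @export
write_intensity_table <- function(records, path, meta = NULL) {
  write_g1_csv(tibble::as_tibble(records), path, meta = meta)
}

#' Validate band-intensity records against a design
#'
#' @param records Data frame of raw band-intensity rows.
#' @inheritParams read_intensity_table
#' @return Typed, sorted record tibble.
#' @export
validate_intensity_records <- function(records, design) {
  needed <- c("condition", "replicate", "blot_id", "mix_id", "protein",
              "time_min", "raw_intensity", "loading_control")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort_format(paste0("intensity table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  rec <- tibble::as_tibble(records)[needed]
  if (nrow(rec) == 0) {
    warn("intensity table contains a header but no records")
    return(rec)
  }
  rec$condition <- as.character(rec$condition)
  rec$replicate <- as.integer(rec$replicate)
  rec$blot_id <- as.character(rec$blot_id)
  rec$mix_id <- as.character(rec$mix_id)
  rec$protein <- as.character(rec$protein)
  rec$time_min <- as.numeric(rec$time_min)
  rec$raw_intensity <- as.numeric(rec$raw_intensity)
  rec$loading_control <- as.numeric(rec$loading_control)

  if (any(rec$replicate < 1L)) abort_validation("replicate indices must be >= 1")
  if (any(!is.finite(rec$time_min)) || any(rec$time_min < 0)) {
    abort_validation("time_min must be finite and >= 0 (minutes since release)")
  }
  if (any(!is.finite(rec$raw_intensity)) || any(rec$raw_intensity < 0)) {
    abort_validation("raw_intensity must be finite and >= 0")
  }
  if (any(!is.finite(rec$loading_control)) || any(rec$loading_control <= 0)) {
    abort_validation("loading_control must be strictly positive")
  }
  key <- paste(rec$condition, rec$replicate, rec$mix_id, rec$protein,
               rec$time_min, sep = "\r")
  if (anyDuplicated(key)) {
    abort_validation(
      "duplicate (condition, replicate, mix_id, protein, time_min) records")
  }
  pairs <- paste(design$mix_id, design$protein, sep = "\r")
  seen <- paste(rec$mix_id, rec$protein, sep = "\r")
  bad <- !seen %in% pairs
  if (any(bad)) {
    off <- unique(paste0(rec$mix_id[bad], "/", rec$protein[bad]))
    abort_xref(paste0("records reference (mix, protein) pairs absent from the ",
                      "design: ", paste(off, collapse = ", ")))
  }
  dplyr::arrange(rec, .data$condition, .data$replicate, .data$protein,
                 .data$time_min)
}

#' Read or write a cyclin blueprint table
#'
#' Long-format export of aggregated wave blueprints: one row per
#' (condition, protein, time_min) with replicate mean, SEM and n. SEM is NA
#' for n = 1 (undefined, not zero). `write_csv` emits a shortest round-trip
#' decimal representation, so read-back reproduces the doubles bit-exactly.
#'
#' @param blueprint Blueprint tibble from \code{\link{aggregate_replicates}}.
#' @param path File path.
#' @inheritParams write_sample_sheet
#' @return `read_blueprint` returns the blueprint tibble.
#' @export
write_blueprint <- function(blueprint, path, meta = NULL) {
  cols <- c("condition", "protein", "time_min", "mean", "sem", "n")
  missing <- setdiff(cols, names(blueprint))
  if (length(missing) > 0) {
    abort_format(paste0("blueprint is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  write_g1_csv(tibble::as_tibble(blueprint)[cols], path, meta = meta)
}

#' @rdname write_blueprint
#' @export
read_blueprint <- function(path) {
  df <- read_g1_csv(path)
  needed <- c("condition", "protein", "time_min", "mean", "sem", "n")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort_format(paste0("blueprint file is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  df$condition <- as.character(df$condition)
  df$protein <- as.character(df$protein)
  df$n <- as.integer(df$n)
  df
}

#' Read or write OD660 growth series
#'
#' @param path CSV with header columns `strain,time_min,od660`; one series
#'   per strain label (use suffixed labels for replicate cultures).
#' @return Tibble with columns `strain`, `time_min`, `od660`, each strain's
#'   times strictly increasing.
#' @export
read_growth_series <- function(path) {
  df <- read_g1_csv(path)
  needed <- c("strain", "time_min", "od660")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort_format(paste0("growth series file is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  df$strain <- as.character(df$strain)
  df$time_min <- as.numeric(df$time_min)
  df$od660 <- as.numeric(df$od660)
  validate_growth_series(df)
}

#' @rdname read_growth_series
#' @param series Growth tibble to write.
#' @inheritParams write_sample_sheet
#' @export
write_growth_series <- function(series, path, meta = NULL) {
  write_g1_csv(tibble::as_tibble(series), path, meta = meta)
}

validate_growth_series <- function(series) {
  if (any(!is.finite(series$od660)) || any(series$od660 <= 0)) {
    abort_validation("od660 values must be finite and > 0")
  }
  by_strain <- split(series$time_min, series$strain)
  for (s in names(by_strain)) {
    t <- by_strain[[s]]
    if (any(diff(t) <= 0)) {
      abort_validation(paste0("times for strain '", s,
                              "' must be strictly increasing"))
    }
  }
  tibble::as_tibble(series)
}

# -- low-level CSV helpers --------------------------------------------------

read_g1_csv <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

write_g1_csv <- function(df, path, meta = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io(paste0("directory does not exist: ", dir))
  header <- c(paste0("# g1waves: ", as.character(packageVersion("g1waves"))))
  if (!is.null(meta)) {
    header <- c(header, paste0("# ", names(meta), ": ", unname(meta)))
  }
  ok <- tryCatch({
    writeLines(header, path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort_io(paste0("failed to write ", path, ": ",
                                   conditionMessage(ok)))
  invisible(path)
}
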