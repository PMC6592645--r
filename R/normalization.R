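# The quantification chain: mixing correction -> loading-control
# normalization -> relativization to the maximum blot signal -> replicate
# aggregation into a mean +/- SEM blueprint.

#' Revert the mixing proportions of a pooled blot
#'
#' Pooled strains contribute different OD660 amounts to their mix; assuming
#' band intensity proportional to loaded cell amount, dividing by the loaded
#' OD and rescaling to a common reference OD reverts the differences
#' introduced in mixing: `corrected = raw * reference_od / od_loaded`.
#' Proteins loaded at the reference OD are unchanged.
#'
#' @param records Band-intensity tibble (see
#'   \code{\link{validate_intensity_records}}).
#' @param design The `mix_design` the records were pooled under.
#' @return `records` with a `corrected` column (densitometry units per
#'   reference OD).
#' @export
correct_mixing <- function(records, design) {
  if (!inherits(design, "mix_design")) design <- mix_design(design)
  pairs <- paste(records$mix_id, records$protein, sep = "\r")
  known <- paste(design$mix_id, design$protein, sep = "\r")
  if (any(!pairs %in% known)) {
    off <- unique(paste0(records$mix_id, "/", records$protein)[!pairs %in% known])
    abort_xref(paste0("(mix, protein) pair(s) absent from the design: ",
                      paste(off, collapse = ", ")))
  }
  out <- dplyr::left_join(
    tibble::as_tibble(records),
    tibble::as_tibble(design)[c("mix_id", "protein", "od_loaded")],
    by = c("mix_id", "protein")
  )
  out$corrected <- out$raw_intensity * reference_od(design) / out$od_loaded
  out$od_loaded <- NULL
  out
}

#' Normalize a corrected intensity by its lane's loading control
#'
#' `normalized = corrected / (lane_lc / blot_lc_reference)`, where the blot
#' reference is the mean loading-control intensity over the blot's lanes.
#' Multiplying an entire lane (every band and its loading control) by any
#' gain g > 0 leaves the normalized value unchanged.
#'
#' @param corrected Mixing-corrected intensity (vectorized).
#' @param lane_lc Loading-control intensity of the band's lane (> 0).
#' @param blot_lc_reference Reference loading-control intensity (> 0),
#'   typically the mean over the blot's lanes.
#' @return Normalized intensity.
#' @export
#' @examples
#' normalize_loading(c(10, 20), c(100, 200), 150)  # both lanes -> 15
normalize_loading <- function(corrected, lane_lc, blot_lc_reference) {
  if (any(!is.finite(lane_lc)) || any(lane_lc <= 0)) {
    abort_validation("lane loading-control intensities must be > 0")
  }
  if (any(!is.finite(blot_lc_reference)) || any(blot_lc_reference <= 0)) {
    abort_validation("blot_lc_reference must be > 0")
  }
  corrected / (lane_lc / blot_lc_reference)
}

#' Apply loading-control normalization across a record table
#'
#' Divides each corrected band by its lane's relative loading,
#' `lane_lc / blot_lc_reference`, where the reference is the mean
#' loading-control intensity over the blot's lanes (one lane per mix x
#' time). When a design is supplied, each lane's loading control is first
#' divided by its mix's designed total OD, so that mixes pooled to
#' different totals remain on a common scale; for designs where every mix
#' totals the same OD (the canonical scheme) this reduces exactly to the
#' plain blot-mean rule. Requires the `corrected` column from
#' \code{\link{correct_mixing}}.
#'
#' @param records Record tibble with a `corrected` column.
#' @param design Optional `mix_design` used to account for per-mix total
#'   loads; omit for equal-total designs.
#' @return `records` with a `normalized` column.
#' @export
normalize_records <- function(records, design = NULL) {
  if (!"corrected" %in% names(records)) {
    abort_validation("records lack a 'corrected' column; run correct_mixing first")
  }
  out <- tibble::as_tibble(records)
  if (!is.null(design)) {
    if (!inherits(design, "mix_design")) design <- mix_design(design)
    out <- dplyr::left_join(out, total_od(design), by = "mix_id")
  } else {
    out$total_od <- 1
  }
  out$.rel_load <- out$loading_control / out$total_od
  lanes <- out |>
    dplyr::distinct(.data$blot_id, .data$replicate, .data$mix_id,
                    .data$time_min, .data$.rel_load)
  refs <- lanes |>
    dplyr::group_by(.data$blot_id) |>
    dplyr::summarise(blot_lc_reference = mean(.data$.rel_load),
                     .groups = "drop")
  out <- dplyr::left_join(out, refs, by = "blot_id")
  out$normalized <- normalize_loading(out$corrected, out$.rel_load,
                                      out$blot_lc_reference)
  out$total_od <- NULL
  out$.rel_load <- NULL
  out$blot_lc_reference <- NULL
  out
}

#' Reshape normalized records into per-protein time courses
#'
#' @param records Record tibble with a `normalized` column.
#' @return Tibble with columns `condition`, `replicate`, `protein`,
#'   `time_min`, `value`, sorted by time within each course.
#' @export
as_time_courses <- function(records) {
  if (!"normalized" %in% names(records)) {
    abort_validation("records lack a 'normalized' column; run normalize_records first")
  }
  records |>
    dplyr::select("condition", "replicate", "protein", "time_min",
                  value = "normalized") |>
    dplyr::arrange(.data$condition, .data$replicate, .data$protein,
                   .data$time_min)
}

#' Relativize time courses to the maximum signal
#'
#' Divides every value by the single maximum across all proteins and times
#' within the chosen scope, so the global maximum of the output is 1 and all
#' curves share one scale (crossing points, in particular the Sic1/Clb5
#' crossing, are preserved). The default scope `"blot"` rescales each
#' (condition, replicate) — i.e. each blot, since one blot carries every mix
#' of one release — by its own maximum; `"condition"` uses one maximum
#' across all replicates of a condition.
#'
#' @param courses Time-course tibble from \code{\link{as_time_courses}}.
#' @param scope `"blot"` or `"condition"`.
#' @return Relativized time-course tibble.
#' @export
relativize <- function(courses, scope = c("blot", "condition")) {
  scope <- match.arg(scope)
  keys <- if (scope == "blot") c("condition", "replicate") else "condition"
  out <- courses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(.max = max(.data$value)) |>
    dplyr::ungroup()
  if (any(out$.max <= 0)) {
    abort_data("all intensities are zero within a relativization scope")
  }
  out$value <- out$value / out$.max
  out$.max <- NULL
  out
}

#' Aggregate replicate time courses into a blueprint
#'
#' Per (condition, protein, time) computes the replicate mean and
#' SEM = sd(n-1 denominator) / sqrt(n). SEM is NA when n = 1 (undefined, not
#' zero). All replicates of a (condition, protein) must share the same time
#' grid. By default the aggregated means are rescaled by their global
#' maximum per condition so the blueprint's maximum mean is exactly 1 (with
#' noisy replicates the mean of per-replicate-relativized curves peaks
#' slightly below 1); SEM is scaled by the same factor.
#'
#' @param courses Relativized time-course tibble.
#' @param rescale Rescale means (and SEMs) so the per-condition maximum mean
#'   is 1.
#' @return Blueprint tibble with columns `condition`, `protein`, `time_min`,
#'   `mean`, `sem`, `n`.
#' @export
aggregate_replicates <- function(courses, rescale = TRUE) {
  grids <- courses |>
    dplyr::group_by(.data$condition, .data$protein, .data$replicate) |>
    dplyr::summarise(grid = paste(.data$time_min, collapse = ","),
                     .groups = "drop_last") |>
    dplyr::summarise(n_grids = dplyr::n_distinct(.data$grid), .groups = "drop")
  if (any(grids$n_grids > 1)) {
    abort_validation(
      "replicates of one (condition, protein) are on different time grids")
  }
  bp <- courses |>
    dplyr::group_by(.data$condition, .data$protein, .data$time_min) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() >= 2) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  if (rescale) {
    bp <- bp |>
      dplyr::group_by(.data$condition) |>
      dplyr::mutate(.max = max(.data$mean)) |>
      dplyr::ungroup()
    if (any(bp$.max <= 0)) abort_data("blueprint means are all zero")
    bp$mean <- bp$mean / bp$.max
    bp$sem <- bp$sem / bp$.max
    bp$.max <- NULL
  }
  dplyr::arrange(bp, .data$condition, .data$protein, .data$time_min)
}

#' Run the full quantification chain on raw records
#'
#' Convenience wrapper: \code{\link{correct_mixing}} then
#' \code{\link{normalize_records}}, \code{\link{as_time_courses}} and
#' \code{\link{relativize}}.
#'
#' @inheritParams correct_mixing
#' @inheritParams relativize
#' @return Relativized time-course tibble.
#' @export
quantify_records <- function(records, design, scope = c("blot", "condition")) {
  records |>
    correct_mixing(design) |>
    normalize_records(design) |>
    as_time_courses() |>
    relativize(scope = match.arg(scope))
}
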