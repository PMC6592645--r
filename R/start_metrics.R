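# START detection (the Sic1/Clb5 crossing), trapezoidal area under the
# curve from release to START, and Cln/Pcl family contribution summaries.

#' Locate START as the Sic1/Clb5 crossing
#'
#' START is the moment at which the relative amounts of Clb5 and Sic1 are
#' identical. On the sampled grid, the difference `d(t) = clb5(t) - sic1(t)`
#' is scanned for the first interval where it changes sign from negative to
#' non-negative; the crossing time is linearly interpolated within that
#' interval. If Clb5 already equals or exceeds Sic1 at the first sample the
#' estimate is the first time with an at-boundary flag. Later re-crossings
#' are ignored: START is a single moment per release.
#'
#' @param times Shared, strictly increasing time grid (minutes).
#' @param clb5,sic1 Relative amounts on `times`, on a common scale.
#' @return List of class `start_estimate`: `t_start`, `crossing_found`,
#'   `at_boundary`, `bracket` (the grid interval containing the crossing).
#' @export
#' @examples
#' find_start(c(0, 15, 30, 45), clb5 = c(0, 0, 1, 1),
#'            sic1 = c(1, 1, 0, 0))$t_start  # 22.5
find_start <- function(times, clb5, sic1) {
  n <- length(times)
  if (length(clb5) != n || length(sic1) != n) {
    abort_validation("clb5, sic1 and times must share one grid")
  }
  if (n < 2 || any(diff(times) <= 0)) {
    abort_validation("times must be strictly increasing with >= 2 points")
  }
  d <- clb5 - sic1
  if (d[1] >= 0) {
    return(structure(list(t_start = times[1], crossing_found = TRUE,
                          at_boundary = TRUE,
                          bracket = c(times[1], times[1])),
                     class = "start_estimate"))
  }
  for (i in seq_len(n - 1)) {
    if (d[i] < 0 && d[i + 1] >= 0) {
      t_star <- times[i] +
        (times[i + 1] - times[i]) * (-d[i]) / (d[i + 1] - d[i])
      return(structure(list(t_start = t_star, crossing_found = TRUE,
                            at_boundary = FALSE,
                            bracket = c(times[i], times[i + 1])),
                       class = "start_estimate"))
    }
  }
  structure(list(t_start = NA_real_, crossing_found = FALSE,
                 at_boundary = FALSE, bracket = c(NA_real_, NA_real_)),
            class = "start_estimate")
}

#' @export
print.start_estimate <- function(x, ...) {
  if (x$crossing_found) {
    cat(sprintf("START at %.3f min%s (bracket [%g, %g])\n", x$t_start,
                if (x$at_boundary) " [at boundary]" else "",
                x$bracket[1], x$bracket[2]))
  } else {
    cat("No Sic1/Clb5 crossing found\n")
  }
  invisible(x)
}

#' Estimate START for every condition of a course set or blueprint
#'
#' With `mode = "mean-curve"` (default, matching the single dashed START
#' line drawn through a blueprint) the crossing is located on the
#' replicate-mean curves; a blueprint input implies this mode. With
#' `mode = "per-replicate"` a crossing is located for every replicate,
#' giving an SEM for `t_start` across replicates.
#'
#' @param x A relativized time-course tibble (columns `condition`,
#'   `replicate`, `protein`, `time_min`, `value`) or a blueprint tibble
#'   (columns `condition`, `protein`, `time_min`, `mean`).
#' @param mode `"mean-curve"` or `"per-replicate"`.
#' @return Tibble with columns `condition`, `replicate` (`"mean"` or the
#'   replicate index as character), `t_start`, `crossing_found`,
#'   `at_boundary`, `bracket_lo`, `bracket_hi`.
#' @export
estimate_start <- function(x, mode = c("mean-curve", "per-replicate")) {
  mode <- match.arg(mode)
  is_blueprint <- "mean" %in% names(x)
  if (is_blueprint && mode == "per-replicate") {
    abort_validation("per-replicate START needs replicate courses, not a blueprint")
  }
  one <- function(sub, label) {
    wide <- landmark_curves(sub, value_col = if ("mean" %in% names(sub)) "mean"
                                             else "value")
    est <- find_start(wide$time_min, wide$Clb5, wide$Sic1)
    tibble::tibble(condition = sub$condition[1], replicate = label,
                   t_start = est$t_start, crossing_found = est$crossing_found,
                   at_boundary = est$at_boundary,
                   bracket_lo = est$bracket[1], bracket_hi = est$bracket[2])
  }
  if (mode == "mean-curve") {
    if (!is_blueprint) x <- aggregate_replicates(x, rescale = FALSE)
    groups <- split(x, x$condition)
    dplyr::bind_rows(lapply(groups, one, label = "mean"))
  } else {
    groups <- split(x, paste(x$condition, x$replicate, sep = "\r"))
    dplyr::bind_rows(lapply(groups, function(sub) {
      one(sub, label = as.character(sub$replicate[1]))
    }))
  }
}

# Pivot Clb5/Sic1 curves of one condition (or one replicate) to a wide grid.
landmark_curves <- function(sub, value_col) {
  for (p in c("Clb5", "Sic1")) {
    if (!p %in% sub$protein) {
      abort_data(paste0("cannot locate START: ", p, " curve is missing"))
    }
  }
  clb5 <- sub[sub$protein == "Clb5", ]
  sic1 <- sub[sub$protein == "Sic1", ]
  clb5 <- clb5[order(clb5$time_min), ]
  sic1 <- sic1[order(sic1$time_min), ]
  if (!isTRUE(all.equal(clb5$time_min, sic1$time_min))) {
    abort_validation("Clb5 and Sic1 are sampled on different time grids")
  }
  tibble::tibble(time_min = clb5$time_min, Clb5 = clb5[[value_col]],
                 Sic1 = sic1[[value_col]])
}

#' Trapezoidal area under a curve from release to START
#'
#' Integrates the sampled curve over `[t_0, t_start]` with the trapezoidal
#' rule; the final partial interval uses the linearly interpolated value at
#' `t_start`. Exact for piecewise-linear curves, additive over subintervals
#' and non-decreasing in `t_start` for non-negative curves.
#'
#' @param times Strictly increasing grid (minutes).
#' @param values Curve values on `times`.
#' @param t_start Upper integration bound; must lie within the grid range.
#' @return Area in relative units x minutes.
#' @export
#' @examples
#' auc_to_start(c(0, 60), c(0, 1), 60)  # 30
#' auc_to_start(c(0, 60), c(0, 1), 30)  # 7.5
auc_to_start <- function(times, values, t_start) {
  if (length(times) != length(values) || any(diff(times) <= 0)) {
    abort_validation("times must be strictly increasing and match values")
  }
  if (is.na(t_start)) {
    abort_data("t_start is undefined (no Sic1/Clb5 crossing found upstream)")
  }
  if (t_start < times[1] || t_start > times[length(times)]) {
    abort_validation("t_start lies outside the sampled time range")
  }
  k <- max(which(times <= t_start))
  area <- 0
  if (k > 1) {
    dt <- diff(times[1:k])
    area <- sum(dt * (values[1:(k - 1)] + values[2:k]) / 2)
  }
  if (t_start > times[k]) {
    v_star <- values[k] + (values[k + 1] - values[k]) *
      (t_start - times[k]) / (times[k + 1] - times[k])
    area <- area + (t_start - times[k]) * (values[k] + v_star) / 2
  }
  area
}

#' Peak time and height of a sampled wave
#'
#' @inheritParams auc_to_start
#' @return List with `peak_time` (minutes) and `peak_value`; the earliest
#'   time wins ties.
#' @export
peak_metrics <- function(times, values) {
  if (length(times) == 0 || length(times) != length(values)) {
    abort_validation("times and values must be non-empty and equal length")
  }
  i <- which.max(values)
  list(peak_time = times[i], peak_value = values[i])
}

#' Family totals and fractional contributions from per-cyclin areas
#'
#' Sums the release-to-START areas of the Cdc28 G1 cyclins
#' (`cln_total` = Cln1 + Cln2 + Cln3) and the Pho85 G1 cyclins
#' (`pcl_total` = Pcl1 + Pcl2 + Pcl7), and reports
#' `pcl_fraction = pcl_total / (pcl_total + cln_total)` together with each
#' cyclin's share of the six-cyclin total. Clb5 and Sic1 are START
#' landmarks, not G1 cyclins, and are excluded from the families (their
#' areas, if supplied, are carried through in the `auc` table).
#'
#' @param aucs Named numeric vector of per-protein areas, or a tibble with
#'   columns `protein` and `auc`.
#' @param condition Condition label attached to the summary.
#' @param t_start START time attached to the summary (optional).
#' @return List of class `wave_summary`: `condition`, `t_start`, `auc`
#'   (tibble `protein`, `auc`, `family`, `fraction`), `cln_total`,
#'   `pcl_total`, `pcl_fraction`, `per_cyclin_fraction`.
#' @export
#' @examples
#' family_fractions(c(Pcl1 = 2, Pcl2 = 1.5, Pcl7 = 0.5,
#'                    Cln1 = 0.4, Cln2 = 0.5, Cln3 = 0.1))$pcl_fraction
family_fractions <- function(aucs, condition = NA_character_,
                             t_start = NA_real_) {
  if (is.data.frame(aucs)) {
    aucs <- setNames(aucs$auc, aucs$protein)
  }
  if (any(!is.finite(aucs)) || any(aucs < 0)) {
    abort_validation("areas must be finite and >= 0")
  }
  fam <- c(cln_family(), pcl_family())
  fam_auc <- setNames(rep(0, length(fam)), fam)
  present <- intersect(names(aucs), fam)
  fam_auc[present] <- aucs[present]
  cln_total <- sum(fam_auc[cln_family()])
  pcl_total <- sum(fam_auc[pcl_family()])
  if (cln_total + pcl_total <= 0) {
    abort_data("all G1-cyclin areas are zero; fractions are undefined")
  }
  per_cyclin <- fam_auc / (cln_total + pcl_total)
  auc_tbl <- tibble::tibble(
    protein = names(aucs),
    auc = unname(aucs),
    family = dplyr::case_when(
      names(aucs) %in% cln_family() ~ "Cln",
      names(aucs) %in% pcl_family() ~ "Pcl",
      TRUE ~ "landmark"
    ),
    fraction = ifelse(names(aucs) %in% fam,
                      unname(per_cyclin[names(aucs)]), NA_real_)
  )
  structure(list(condition = condition, t_start = t_start, auc = auc_tbl,
                 cln_total = cln_total, pcl_total = pcl_total,
                 pcl_fraction = pcl_total / (pcl_total + cln_total),
                 per_cyclin_fraction = per_cyclin),
            class = "wave_summary")
}

#' @export
print.wave_summary <- function(x, ...) {
  cat(sprintf("Wave summary%s%s\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              if (is.na(x$t_start)) "" else
                sprintf(", START at %.2f min", x$t_start)))
  cat(sprintf("  Cln total %.4g, Pcl total %.4g, Pcl fraction %.1f%%\n",
              x$cln_total, x$pcl_total, 100 * x$pcl_fraction))
  invisible(x)
}

#' Per-cyclin areas and family fractions for each condition
#'
#' Runs \code{\link{estimate_start}} and \code{\link{auc_to_start}} for every
#' condition. With `mode = "mean-curve"` the areas are integrals of the
#' replicate-mean curves up to the mean-curve START; with
#' `mode = "per-replicate"` each replicate's curves are integrated to its
#' own START and the per-replicate areas are averaged.
#'
#' @param x A relativized course tibble or a blueprint tibble.
#' @param starts Optional precomputed START table from
#'   \code{\link{estimate_start}} (mean-curve rows are used).
#' @param mode `"mean-curve"` or `"per-replicate"`.
#' @return Named list of \code{\link{family_fractions}} summaries, one per
#'   condition.
#' @export
summarise_waves <- function(x, starts = NULL,
                            mode = c("mean-curve", "per-replicate")) {
  mode <- match.arg(mode)
  is_blueprint <- "mean" %in% names(x)
  if (is_blueprint && mode == "per-replicate") {
    abort_validation("per-replicate areas need replicate courses, not a blueprint")
  }
  value_col <- if (is_blueprint) "mean" else "value"

  integrate_set <- function(sub, t_start) {
    prots <- unique(sub$protein)
    vapply(prots, function(p) {
      cur <- sub[sub$protein == p, ]
      cur <- cur[order(cur$time_min), ]
      auc_to_start(cur$time_min, cur[[value_col]], t_start)
    }, numeric(1))
  }

  conditions <- unique(x$condition)
  out <- lapply(conditions, function(cond) {
    sub <- x[x$condition == cond, ]
    if (mode == "mean-curve") {
      if (!is_blueprint) {
        sub <- aggregate_replicates(sub, rescale = FALSE)
        value_col <- "mean"
      }
      st <- if (is.null(starts)) {
        estimate_start(sub, mode = "mean-curve")
      } else {
        starts[starts$condition == cond & starts$replicate == "mean", ]
      }
      if (nrow(st) == 0 || !isTRUE(st$crossing_found[1])) {
        abort_data(paste0("no Sic1/Clb5 crossing for condition ", cond,
                          "; areas to START are unavailable"))
      }
      prots <- unique(sub$protein)
      aucs <- vapply(prots, function(p) {
        cur <- sub[sub$protein == p, ]
        cur <- cur[order(cur$time_min), ]
        auc_to_start(cur$time_min, cur[[value_col]], st$t_start[1])
      }, numeric(1))
      family_fractions(aucs, condition = cond, t_start = st$t_start[1])
    } else {
      st <- estimate_start(sub, mode = "per-replicate")
      if (!all(st$crossing_found)) {
        abort_data(paste0("no Sic1/Clb5 crossing in some replicate of ",
                          cond))
      }
      reps <- unique(sub$replicate)
      mats <- lapply(reps, function(r) {
        integrate_set(sub[sub$replicate == r, ],
                      st$t_start[st$replicate == as.character(r)])
      })
      aucs <- Reduce(`+`, mats) / length(mats)
      family_fractions(aucs, condition = cond, t_start = mean(st$t_start))
    }
  })
  setNames(out, conditions)
}

#' Tidy family-fraction table across conditions
#'
#' @param summaries List of `wave_summary` objects from
#'   \code{\link{summarise_waves}}.
#' @return Tibble (`condition`, `t_start`, `cln_total`, `pcl_total`,
#'   `pcl_fraction`) sorted by ascending Pcl fraction, the ordering used for
#'   family bar charts.
#' @export
family_table <- function(summaries) {
  tbl <- dplyr::bind_rows(lapply(summaries, function(s) {
    tibble::tibble(condition = s$condition, t_start = s$t_start,
                   cln_total = s$cln_total, pcl_total = s$pcl_total,
                   pcl_fraction = s$pcl_fraction)
  }))
  dplyr::arrange(tbl, .data$pcl_fraction)
}

#' Tidy per-cyclin area table across conditions
#'
#' @inheritParams family_table
#' @return Tibble (`condition`, `protein`, `auc`, `family`, `fraction`).
#' @export
auc_table <- function(summaries) {
  dplyr::bind_rows(lapply(summaries, function(s) {
    dplyr::mutate(s$auc, condition = s$condition, .before = 1)
  }))
}
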