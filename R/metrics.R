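# Tissue measurement procedures: COM thickness, segment tracking, turnover,
# stability and recovery detection. All metrics are pure functions of the
# sampled cell census (or a state), so they can be recomputed from dumps.

cells_of <- function(x) {
  if (inherits(x, "cornea_state")) x$cells else x
}

#' Epithelial thickness by the centre-of-mass difference method
#'
#' Distance between the superficial layer and the deepest layer: mean y-COM
#' of superficial cells minus mean y-COM of basal and stem cells, converted
#' to micrometres. When either layer is absent (e.g. immediately after an
#' ablation) the metric is undefined and `NA` is returned rather than an
#' error, so injury transients remain representable.
#'
#' @param x A `cornea_state`, or a cell table with `type`, `comy` columns.
#' @param pixel_um Voxel edge length in micrometres (default 2).
#' @return Thickness in micrometres, or `NA_real_`.
#' @export
thickness_com <- function(x, pixel_um = 2) {
  cells <- cells_of(x)
  sup <- cells$comy[cells$type == TYPES[["SUPER"]]]
  deep <- cells$comy[cells$type %in% TYPES[c("BASAL", "STEM")]]
  if (!length(sup) || !length(deep)) return(NA_real_)
  (mean(sup) - mean(deep)) * pixel_um
}

#' Per-segment superficial surface positions
#'
#' Divides the lattice into `n_segments` equal segments along x (for the
#' default ten segments of a 200-voxel lattice: x in 0-19, 20-39, ...,
#' 180-199) and reports the mean y-COM of superficial cells whose COM falls
#' in each segment, in micrometres. Empty segments yield `NA`.
#'
#' @param x A `cornea_state` or cell table (with `comx`).
#' @param n_segments Number of segments (default 10).
#' @param width Lattice width in voxels (default 200).
#' @param pixel_um Voxel edge in micrometres.
#' @return Numeric vector of length `n_segments`.
#' @export
segment_surface_positions <- function(x, n_segments = 10, width = 200,
                                      pixel_um = 2) {
  cells <- cells_of(x)
  sup <- cells[cells$type == TYPES[["SUPER"]], ]
  seg_w <- width / n_segments
  seg <- pmin(floor(sup$comx / seg_w), n_segments - 1)
  out <- rep(NA_real_, n_segments)
  if (nrow(sup)) {
    agg <- tapply(sup$comy, factor(seg, levels = 0:(n_segments - 1)), mean)
    out <- as.numeric(agg) * pixel_um
  }
  out
}

#' Per-segment epithelial thickness
#'
#' Segment-wise analogue of [thickness_com()]: within each x segment, the
#' mean y-COM of superficial cells minus the mean y-COM of basal and stem
#' cells, in micrometres. Used to quantify thickness uniformity across the
#' tissue (the cross-segment standard deviation of temporal means).
#'
#' @inheritParams segment_surface_positions
#' @return Numeric vector of length `n_segments`.
#' @export
segment_thickness <- function(x, n_segments = 10, width = 200, pixel_um = 2) {
  cells <- cells_of(x)
  seg_w <- width / n_segments
  lev <- 0:(n_segments - 1)
  seg_mean <- function(df) {
    s <- pmin(floor(df$comx / seg_w), n_segments - 1)
    as.numeric(tapply(df$comy, factor(s, levels = lev), mean))
  }
  sup <- seg_mean(cells[cells$type == TYPES[["SUPER"]], ])
  deep <- seg_mean(cells[cells$type %in% TYPES[c("BASAL", "STEM")], ])
  (sup - deep) * pixel_um
}

#' Per-sample tissue metrics from a run census
#'
#' Collapses the long per-cell census of a simulation into one row per
#' sampled MCS: epithelial counts by type, total epithelial count, and
#' COM-difference thickness.
#'
#' @param x A `cornea_sim` or a census data frame.
#' @param pixel_um Voxel edge in micrometres.
#' @return Data frame with columns `mcs`, `day`, `n_stem`, `n_basal`,
#'   `n_wing`, `n_super`, `n_epithelial`, `thickness_um`.
#' @export
metrics_series <- function(x, pixel_um = 2) {
  census <- if (inherits(x, "cornea_sim")) x$census else x
  day_to_mcs <- if (inherits(x, "cornea_sim")) x$config$rules$day_to_mcs else 240L
  mcs_vals <- sort(unique(census$mcs))
  idx <- split(seq_len(nrow(census)), factor(census$mcs, levels = mcs_vals))
  rows <- lapply(seq_along(mcs_vals), function(i) {
    cc <- census[idx[[i]], ]
    n <- function(tt) sum(cc$type == TYPES[[tt]])
    sup <- cc$comy[cc$type == TYPES[["SUPER"]]]
    deep <- cc$comy[cc$type %in% TYPES[c("BASAL", "STEM")]]
    th <- if (length(sup) && length(deep)) (mean(sup) - mean(deep)) * pixel_um
          else NA_real_
    data.frame(mcs = mcs_vals[i], n_stem = n("STEM"), n_basal = n("BASAL"),
               n_wing = n("WING"), n_super = n("SUPER"),
               n_epithelial = nrow(cc), thickness_um = th)
  })
  out <- do.call(rbind, rows)
  out$day <- out$mcs / day_to_mcs
  out[, c("mcs", "day", "n_stem", "n_basal", "n_wing", "n_super",
          "n_epithelial", "thickness_um")]
}

#' Regional turnover: survival of a baseline cell cohort
#'
#' Takes the set of epithelial cells alive at `baseline_mcs` whose COM lies
#' in the chosen region (limbal zone `x < limbal_width` voxels, peripheral
#' zone otherwise) and follows the surviving fraction of those cell ids
#' over time. Division retires the parent id (daughters are new cells), so
#' ids disappear through division, sloughing or injury death and the curve
#' is monotone non-increasing. The turnover time is the first time the
#' surviving fraction drops to `threshold` (default 5%, the operational
#' reading of "nearly complete substitution").
#'
#' @param x A `cornea_sim` or census data frame.
#' @param region `"peripheral"` or `"limbal"`.
#' @param baseline_mcs MCS of the baseline snapshot (typically after the
#'   stability time).
#' @param threshold Surviving fraction defining turnover (default 0.05).
#' @param limbal_width Limbal/peripheral boundary in voxels (default 40).
#' @param day_to_mcs MCS per simulated day (default 240).
#' @return List: `days` (turnover time in days since baseline, `NA` if
#'   censored), `censored`, `last_fraction`, and `curve` (data frame of
#'   `mcs`, `fraction`).
#' @export
turnover_time <- function(x, region = c("peripheral", "limbal"),
                          baseline_mcs, threshold = 0.05, limbal_width = 40,
                          day_to_mcs = 240) {
  region <- match.arg(region)
  census <- if (inherits(x, "cornea_sim")) x$census else x
  samples <- sort(unique(census$mcs))
  b <- samples[samples >= baseline_mcs][1]
  if (is.na(b)) stop("baseline MCS is beyond the sampled range")
  base <- census[census$mcs == b, ]
  in_region <- if (region == "limbal") base$comx < limbal_width
               else base$comx >= limbal_width
  ids <- base$id[in_region]
  if (!length(ids)) stop("no baseline cells in the ", region, " region")
  later <- samples[samples >= b]
  frac <- vapply(later, function(m) {
    mean(ids %in% census$id[census$mcs == m])
  }, numeric(1))
  hit <- which(frac <= threshold)
  list(
    days = if (length(hit)) (later[hit[1]] - b) / day_to_mcs else NA_real_,
    censored = !length(hit),
    last_fraction = frac[length(frac)],
    curve = data.frame(mcs = later, fraction = frac)
  )
}

#' Stratification time
#'
#' First simulated day at which the developing tissue contains all four
#' epithelial cell types with the correct vertical ordering: mean y-COM of
#' basal and stem cells below wing cells, wing cells below superficial
#' cells.
#'
#' @param census A run census data frame (or `cornea_sim`).
#' @param day_to_mcs MCS per day.
#' @return First day in days (`NA` if never during the run).
#' @export
stratification_time <- function(census, day_to_mcs = 240) {
  if (inherits(census, "cornea_sim")) census <- census$census
  for (m in sort(unique(census$mcs))) {
    cc <- census[census$mcs == m, ]
    deep <- cc$comy[cc$type %in% TYPES[c("BASAL", "STEM")]]
    wing <- cc$comy[cc$type == TYPES[["WING"]]]
    sup <- cc$comy[cc$type == TYPES[["SUPER"]]]
    if (!any(cc$type == TYPES[["STEM"]]) || !any(cc$type == TYPES[["BASAL"]]) ||
        !length(wing) || !length(sup)) next
    if (mean(deep) < mean(wing) && mean(wing) < mean(sup))
      return(m / day_to_mcs)
  }
  NA_real_
}

#' Homeostatic stability time
#'
#' The tissue is declared stable on the first day opening a
#' `window_days`-day run in which, every day, all four epithelial cell-type
#' counts stay within a relative `band` of their trailing
#' `window_days`-day mean, with all four types present throughout. Counts
#' are averaged per day before testing, and the band has an absolute floor
#' of `floor_cells` (relative tolerances cannot resolve below the integer
#' granularity of populations of a handful of stem cells).
#'
#' @param metrics A metrics data frame from [metrics_series()].
#' @param band Relative tolerance (default 0.10).
#' @param window_days Trailing-mean window and required persistence
#'   (default 5 days).
#' @param floor_cells Absolute band floor in cells (default 2).
#' @param day_to_mcs MCS per day.
#' @return Stability time in days (`NA` if never reached).
#' @export
stability_time <- function(metrics, band = 0.10, window_days = 5,
                           floor_cells = 2, day_to_mcs = 240) {
  cols <- c("n_stem", "n_basal", "n_wing", "n_super")
  m <- metrics[order(metrics$mcs), ]
  # daily means of the sampled counts
  dday <- ceiling(m$mcs / day_to_mcs)
  dday[m$mcs == 0] <- 0
  daily <- data.frame(day = sort(unique(dday)))
  for (cl in cols)
    daily[[cl]] <- as.numeric(tapply(m[[cl]], dday, mean))
  nd <- nrow(daily)
  ok <- logical(nd)
  for (i in seq_len(nd)) {
    win <- daily$day > daily$day[i] - window_days & daily$day <= daily$day[i]
    good <- TRUE
    for (cl in cols) {
      v <- daily[[cl]][win]
      tm <- mean(v)
      tol <- max(band * tm, floor_cells)
      if (tm <= 0 || any(v == 0) || abs(daily[[cl]][i] - tm) > tol) {
        good <- FALSE
        break
      }
    }
    ok[i] <- good
  }
  # report the day the qualifying window opens
  for (i in seq_len(nd)) {
    ahead <- daily$day >= daily$day[i] & daily$day < daily$day[i] + window_days
    if (sum(ahead) >= window_days && all(ok[ahead])) return(daily$day[i])
  }
  NA_real_
}

#' Post-injury recovery time and recurrence count
#'
#' Recovery is the first post-injury time at which both the total
#' epithelial cell count and the COM thickness are within `tol` of their
#' pre-injury baselines and remain so for `sustain_days`. Later exits below
#' the band (after first recovery) are counted as recurrences, the
#' signature of recurrent-erosion-like breakdown.
#'
#' @param metrics A [metrics_series()] data frame covering the injury.
#' @param injury_mcs MCS at which the injury was applied.
#' @param baseline_count,baseline_thickness Pre-injury stable means.
#' @param tol Relative tolerance (default 0.10).
#' @param sustain_days Time the band must hold (default 1 day).
#' @param day_to_mcs MCS per day.
#' @return List: `days` (first recovery, in days post-injury; 0 if the
#'   series never left the band; `NA` if never recovered), `censored`,
#'   `recurrences`.
#' @export
recovery_time <- function(metrics, injury_mcs, baseline_count,
                          baseline_thickness, tol = 0.10, sustain_days = 1,
                          day_to_mcs = 240) {
  m <- metrics[metrics$mcs >= injury_mcs, ]
  m <- m[order(m$mcs), ]
  if (!nrow(m)) stop("metrics series does not cover the injury")
  in_band <- abs(m$n_epithelial - baseline_count) <= tol * baseline_count &
    !is.na(m$thickness_um) &
    abs(m$thickness_um - baseline_thickness) <= tol * baseline_thickness
  smcs <- sustain_days * day_to_mcs
  first <- NA_real_
  for (i in seq_along(in_band)) {
    upto <- m$mcs >= m$mcs[i] & m$mcs <= m$mcs[i] + smcs
    if (all(in_band[upto]) && any(upto)) {
      first <- m$mcs[i]
      break
    }
  }
  if (is.na(first))
    return(list(days = NA_real_, censored = TRUE, recurrences = 0L))
  days <- if (all(in_band)) 0 else (first - injury_mcs) / day_to_mcs
  after <- in_band[m$mcs > first]
  r <- rle(after)
  recurrences <- sum(!r$values)
  list(days = days, censored = FALSE, recurrences = as.integer(recurrences))
}
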