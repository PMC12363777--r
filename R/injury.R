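# Injury mechanisms: instantaneous circular ablation and chemical exposure
# via a diffusing toxicant field with threshold-triggered death, plus depth
# classification (slight / mild / moderate).

#' Define an injury scenario
#'
#' @param mode `"ablation"` (instantaneous geometric removal),
#'   `"chemical_droplet"` (localized deposit, Gaussian of width `sigma`;
#'   `sigma = 0` deposits the full amplitude into the single `center`
#'   pixel), or `"chemical_uniform"` (amplitude added to all tear pixels in
#'   contact with the epithelial surface).
#' @param center `c(x, y)` in 0-based voxel coordinates.
#' @param radius Ablation disc radius in voxels.
#' @param amplitude Chemical amplitude in arbitrary concentration units
#'   (the depth-graded reference exposures are 750, 1500 and 2500 a.u.).
#' @param sigma Gaussian droplet width (voxels); 0 = single-pixel deposit.
#' @param apply_at MCS at which the injury fires during [simulate_cornea()].
#' @return A list of class `injury_spec`.
#' @export
injury_spec <- function(mode = c("ablation", "chemical_droplet",
                                 "chemical_uniform"),
                        center = c(100, 75), radius = 0, amplitude = 0,
                        sigma = 0, apply_at = 0L) {
  mode <- match.arg(mode)
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (radius < 0) stop("radius must be non-negative")
  spec <- list(mode = mode, center = as.numeric(center), radius = radius,
               amplitude = amplitude, sigma = sigma,
               apply_at = as.integer(apply_at))
  class(spec) <- "injury_spec"
  spec
}

#' Ablate a circular region
#'
#' Physical trauma: every epithelial cell whose centre of mass lies within
#' the disc is removed instantly and its pixels are converted to tear film
#' (reflecting increased tear production after injury). Frozen
#' compartments (membranes, stroma, walls) are untouched.
#'
#' @param state A `cornea_state`.
#' @param spec An [injury_spec()] with `mode = "ablation"`.
#' @return List: updated `state` and an injury `report` (killed counts by
#'   type, deepest layer hit, classification).
#' @export
ablate <- function(state, spec) {
  stopifnot(inherits(spec, "injury_spec"), spec$mode == "ablation")
  g <- dim(state$owner)
  if (spec$center[1] < 0 || spec$center[1] > g[1] - 1 ||
      spec$center[2] < 0 || spec$center[2] > g[2] - 1)
    stop("ablation disc lies outside the lattice")
  cells <- state$cells
  d2 <- (cells$comx - spec$center[1])^2 + (cells$comy - spec$center[2])^2
  victim <- cells$type %in% TYPES[EPITHELIAL] & d2 <= spec$radius^2
  killed <- cells[victim, ]
  tear_id <- cells$id[cells$type == TYPES[["TEAR"]]][1]
  if (nrow(killed)) {
    state$owner[state$owner %in% killed$id] <- tear_id
    state$cells <- cells[!victim, , drop = FALSE]
    state <- refresh_state(state)
  }
  kbt <- table(factor(type_name(killed$type), levels = TYPE_NAMES))
  list(state = state,
       report = injury_report(as.integer(kbt[EPITHELIAL]), memb_destroyed = 0L))
}

#' Deposit a chemical exposure into the toxicant field
#'
#' Droplet mode adds `amplitude * exp(-|p - center|^2 / (2 sigma^2))` to
#' the toxicant field (with `sigma = 0`, the whole amplitude lands in the
#' single centre pixel, the point-deposit limit); uniform mode adds the
#' amplitude to every tear pixel contacting the epithelial surface.
#' Thereafter the field diffuses and decays with its own coefficients each
#' MCS, and cells die when their mean concentration exceeds the kill
#' threshold (see [kill_by_concentration()]).
#'
#' @param state A `cornea_state`.
#' @param spec An [injury_spec()] with a chemical mode.
#' @return The updated `cornea_state` (toxicant field now active).
#' @export
apply_chemical <- function(state, spec) {
  stopifnot(inherits(spec, "injury_spec"),
            spec$mode %in% c("chemical_droplet", "chemical_uniform"))
  W <- nrow(state$owner); H <- ncol(state$owner)
  if (is.null(state$tox)) state$tox <- matrix(0, nrow = W, ncol = H)
  if (spec$amplitude == 0) return(state)
  if (spec$mode == "chemical_droplet") {
    cx <- spec$center[1]; cy <- spec$center[2]
    if (spec$sigma <= 0) {
      state$tox[cx + 1L, cy + 1L] <- state$tox[cx + 1L, cy + 1L] + spec$amplitude
    } else {
      xx <- matrix(0:(W - 1L), nrow = W, ncol = H)
      yy <- matrix(0:(H - 1L), nrow = W, ncol = H, byrow = TRUE)
      r2 <- (xx - cx)^2 + (yy - cy)^2
      state$tox <- state$tox + spec$amplitude * exp(-r2 / (2 * spec$sigma^2))
    }
  } else {
    surf <- surface_tear_pixels(state)
    state$tox[surf] <- state$tox[surf] + spec$amplitude
  }
  state
}

# Tear-owned pixels with at least one epithelial 8-neighbour.
surface_tear_pixels <- function(state) {
  W <- nrow(state$owner); H <- ncol(state$owner)
  type_of_id <- integer(state$next_id + 1L)
  type_of_id[state$cells$id + 1L] <- state$cells$type
  tmap <- matrix(type_of_id[state$owner + 1L], nrow = W, ncol = H)
  is_tear <- tmap == TYPES[["TEAR"]]
  is_epi <- tmap %in% TYPES[EPITHELIAL]
  dim(is_epi) <- dim(is_tear)
  nb <- matrix(FALSE, W, H)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 + dx):min(W, W + dx)
    xt <- xs - dx
    ys <- max(1, 1 + dy):min(H, H + dy)
    yt <- ys - dy
    nb[xt, yt] <- nb[xt, yt] | is_epi[xs, ys]
  }
  which(is_tear & nb)
}

#' Concentration-triggered cell death
#'
#' Every epithelial cell whose mean toxicant concentration exceeds the
#' kill threshold is marked dying: its target volume is set to zero, so it
#' shrinks away under the volume constraint and is removed when its last
#' pixel is lost (programmed death by volume reduction). Basement-membrane
#' pixels whose local concentration exceeds the threshold are permanently
#' converted to a passive damaged state that never regenerates; this is
#' the pathway to moderate, erosion-prone injury. During
#' [simulate_cornea()] this check runs automatically every MCS while the
#' toxicant field is active.
#'
#' @param state A `cornea_state` with an active toxicant field.
#' @param config A `cornea_config`.
#' @param kill_threshold Threshold in field units (defaults to
#'   `config$tox$kill_threshold`).
#' @return List: updated `state` and injury `report`.
#' @export
kill_by_concentration <- function(state, config,
                                  kill_threshold = config$tox$kill_threshold) {
  if (is.null(state$tox)) stop("no toxicant field is active")
  cells <- state$cells
  epi <- cells$type %in% TYPES[EPITHELIAL] & cells$dying == 0L
  mean_tox <- vapply(cells$id, function(id) mean(state$tox[state$owner == id]),
                     numeric(1))
  mark <- epi & mean_tox > kill_threshold
  cells$dying[mark] <- 1L
  cells$target_volume[mark] <- 0
  kbt <- table(factor(type_name(cells$type[mark]), levels = TYPE_NAMES))

  # membrane destruction: per-pixel, permanent
  memb_ids <- cells$id[cells$type %in% TYPES[c("LIMB", "MEMB")]]
  hit <- state$owner %in% memb_ids & state$tox > kill_threshold
  n_memb <- sum(hit)
  if (n_memb > 0) {
    dmg_id <- cells$id[cells$type == TYPES[["DMG"]]]
    if (!length(dmg_id)) {
      dmg_id <- state$next_id
      state$next_id <- state$next_id + 1L
      cells <- rbind(cells, new_cells_df(dmg_id, TYPES[["DMG"]], 0))
    }
    state$owner[hit] <- dmg_id[1]
  }
  state$cells <- cells
  state <- refresh_state(state)
  list(state = state,
       report = injury_report(as.integer(kbt[EPITHELIAL]), n_memb))
}

#' Assemble an injury report
#'
#' @param killed_epithelial Integer vector of killed-cell counts in the
#'   order stem, basal, wing, superficial.
#' @param memb_destroyed Number of basement-membrane pixels destroyed.
#' @return List of class `injury_report`: `killed_by_type`,
#'   `deepest_layer_hit`, `classification` (slight = superficial and wing
#'   cells only; mild = reaches basal or stem cells; moderate = breaches
#'   the basement membrane towards the stroma).
#' @export
injury_report <- function(killed_epithelial, memb_destroyed = 0L) {
  kbt <- setNames(as.integer(killed_epithelial), EPITHELIAL)
  deepest <- NA_character_
  if (memb_destroyed > 0) deepest <- "EpBM/STROMA"
  else if (kbt[["BASAL"]] > 0 || kbt[["STEM"]] > 0) deepest <- "BASAL"
  else if (kbt[["WING"]] > 0) deepest <- "WING"
  else if (kbt[["SUPER"]] > 0) deepest <- "SUPER"
  cls <- if (memb_destroyed > 0) "moderate"
         else if (kbt[["BASAL"]] > 0 || kbt[["STEM"]] > 0) "mild"
         else if (kbt[["WING"]] > 0 || kbt[["SUPER"]] > 0) "slight"
         else "none"
  out <- list(killed_by_type = kbt, memb_destroyed = as.integer(memb_destroyed),
              deepest_layer_hit = deepest, classification = cls)
  class(out) <- "injury_report"
  out
}

#' @export
print.injury_report <- function(x, ...) {
  cat("Injury classification:", x$classification, "\n")
  cat("  killed:", paste(sprintf("%s=%d", names(x$killed_by_type),
                                 x$killed_by_type), collapse = ", "), "\n")
  cat("  membrane pixels destroyed:", x$memb_destroyed, "\n")
  invisible(x)
}

# Report accumulated during a simulation's post-injury segments, from the
# event log (chemical death marks and membrane destruction events).
report_from_events <- function(events, from_mcs = 0) {
  ev <- events[events$mcs >= from_mcs, , drop = FALSE]
  marks <- ev[ev$code == 3, , drop = FALSE]
  kbt <- vapply(TYPES[EPITHELIAL], function(tc) sum(marks$type == tc),
                numeric(1))
  injury_report(as.integer(kbt), memb_destroyed = sum(ev$code == 5))
}
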