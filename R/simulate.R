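# Simulation orchestration: the per-MCS pipeline, injury scheduling, and
# seeded replicate campaigns.

seg_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 104729) %% 2147483629)
}

#' Run the corneal epithelium simulation
#'
#' Executes the fixed per-MCS pipeline (field update, chemical-death check,
#' growth, differentiation, mitosis, sloughing, Metropolis dynamics, tear
#' re-wetting) for the requested duration, applying any scheduled injuries
#' at their `apply_at` MCS. One MCS represents 6 minutes; one day is 240
#' MCS. Runs are deterministic for a given seed: the same seed and
#' configuration reproduce the owner grid and all outputs exactly.
#'
#' @param config A [cornea_config()].
#' @param state Optional starting `cornea_state` (e.g. a stored
#'   homeostatic tissue); defaults to [build_initial_state()].
#' @param days,mcs Run length (specify one; `days` is converted with
#'   `day_to_mcs`).
#' @param seed Integer seed; all stochastic components (Metropolis
#'   acceptance, cleavage planes, sloughing draws) flow from this single
#'   stream per run segment.
#' @param injuries List of [injury_spec()] objects (or a single spec).
#' @param sample_every Census sampling cadence in MCS.
#' @return An object of class `cornea_sim`: final `state`, long per-cell
#'   `census` data frame (one row per live epithelial cell per sampled
#'   MCS), `events` log (divisions, differentiations, sloughing, deaths,
#'   membrane destruction), `injury_reports`, acceptance diagnostics, the
#'   configuration and seed.
#' @export
#' @examples
#' cfg <- cornea_config(geometry = list(width = 60, height = 50,
#'                                      limbal_width = 20, stroma_rows = 20))
#' sim <- simulate_cornea(cfg, days = 0.25, seed = 1)
#' tail(metrics_series(sim))
simulate_cornea <- function(config = cornea_config(), state = NULL,
                            days = NULL, mcs = NULL,
                            seed = config$run$seed, injuries = list(),
                            sample_every = config$run$sample_every) {
  if (inherits(injuries, "injury_spec")) injuries <- list(injuries)
  if (is.null(mcs)) {
    if (is.null(days)) stop("specify a run length via days or mcs")
    mcs <- as.integer(round(days * config$rules$day_to_mcs))
  }
  if (is.null(state)) state <- build_initial_state(config)
  start_mcs <- state$mcs
  end_mcs <- start_mcs + mcs

  sched <- injuries[order(vapply(injuries, `[[`, 0L, "apply_at"))]
  for (sp in sched)
    if (sp$apply_at < start_mcs || sp$apply_at > end_mcs)
      stop("injury scheduled at MCS ", sp$apply_at,
           " outside the run window [", start_mcs, ", ", end_mcs, "]")

  census <- list(); events <- list()
  attempts <- 0; accepts <- 0
  injury_reports <- list()
  k <- 0L
  cursor <- start_mcs
  boundaries <- c(vapply(sched, `[[`, 0L, "apply_at"), end_mcs)
  i_sp <- 1L
  if (end_mcs == start_mcs) {
    res <- engine_call(state, config, n_mcs = 0L, seed = seg_seed(seed, 0L),
                       sample_every = sample_every)
    census[[1L]] <- res$census
    events[[1L]] <- res$events
  }
  for (b in boundaries) {
    if (b > cursor) {
      res <- engine_call(state, config, n_mcs = b - cursor,
                         seed = seg_seed(seed, k), sample_every = sample_every)
      k <- k + 1L
      state <- res$state
      cen <- res$census
      # a segment re-samples its starting MCS; keep only the first segment's
      if (length(census) > 0 && nrow(cen))
        cen <- cen[cen[, "mcs"] > cursor, , drop = FALSE]
      census[[length(census) + 1L]] <- cen
      events[[length(events) + 1L]] <- res$events
      attempts <- attempts + res$attempts
      accepts <- accepts + res$accepts
      cursor <- b
    }
    if (i_sp <= length(sched) && b == sched[[i_sp]]$apply_at) {
      sp <- sched[[i_sp]]
      if (sp$mode == "ablation") {
        ab <- ablate(state, sp)
        state <- ab$state
        injury_reports[[i_sp]] <- ab$report
      } else {
        state <- apply_chemical(state, sp)
        injury_reports[[i_sp]] <- sp$apply_at  # placeholder, filled below
      }
      i_sp <- i_sp + 1L
    }
  }

  census <- as.data.frame(do.call(rbind, census))
  events <- as.data.frame(do.call(rbind, events))
  # chemical injuries: report assembled from the post-injury event log
  for (j in seq_along(sched)) {
    if (sched[[j]]$mode != "ablation")
      injury_reports[[j]] <- report_from_events(events, sched[[j]]$apply_at)
  }

  out <- list(state = state, census = census, events = events,
              config = config, seed = as.integer(seed),
              start_mcs = start_mcs, end_mcs = end_mcs,
              injuries = sched, injury_reports = injury_reports,
              attempts = attempts, accepts = accepts,
              config_hash = config_hash(config))
  class(out) <- "cornea_sim"
  out
}

#' @export
print.cornea_sim <- function(x, ...) {
  cat(sprintf("cornea_sim: MCS %d to %d (%.1f days), seed %d, config %s\n",
              x$start_mcs, x$end_mcs,
              (x$end_mcs - x$start_mcs) / x$config$rules$day_to_mcs,
              x$seed, x$config_hash))
  if (length(x$injury_reports))
    for (r in x$injury_reports)
      if (inherits(r, "injury_report"))
        cat("  injury:", r$classification, "\n")
  print(x$state)
  invisible(x)
}

#' @export
summary.cornea_sim <- function(object, ...) {
  m <- metrics_series(object)
  st <- stability_time(m, day_to_mcs = object$config$rules$day_to_mcs)
  structure(list(metrics = m, stability_day = st,
                 accept_rate = object$accepts / max(1, object$attempts)),
            class = "summary.cornea_sim")
}

#' @export
print.summary.cornea_sim <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("final day %.1f: %d epithelial cells, thickness %.1f um\n",
              last$day, last$n_epithelial, last$thickness_um))
  cat(sprintf("stability day: %s; Metropolis acceptance rate %.3f\n",
              format(x$stability_day), x$accept_rate))
  invisible(x)
}

#' Plot cell-population dynamics of a run
#'
#' Counts of the four epithelial types against simulated days, with the
#' stability time marked, in the conventional palette.
#'
#' @param x A `cornea_sim`.
#' @param ... Passed to [graphics::matplot()].
#' @return The metrics data frame, invisibly.
#' @export
plot.cornea_sim <- function(x, ...) {
  m <- metrics_series(x)
  pal <- cornea_palette()
  graphics::matplot(m$day, m[, c("n_stem", "n_basal", "n_wing", "n_super")],
                    type = "l", lty = 1, lwd = 2,
                    col = pal[c("STEM", "BASAL", "WING", "SUPER")],
                    xlab = "simulated days", ylab = "cell count", ...)
  st <- stability_time(m, day_to_mcs = x$config$rules$day_to_mcs)
  if (!is.na(st)) graphics::abline(v = st, lty = 2)
  graphics::legend("topleft", legend = c("stem", "basal", "wing", "superficial"),
                   col = pal[c("STEM", "BASAL", "WING", "SUPER")],
                   lty = 1, lwd = 2, bty = "n")
  invisible(m)
}

#' Run seeded replicate campaigns
#'
#' Runs `n` independent replicates (one RNG stream each) of the same
#' configuration and aggregates per-sample mean and standard deviation of
#' the cell counts and thickness, the per-replicate stability times, and a
#' normality check (Shapiro-Wilk p-values of the stable-window counts,
#' reported, not asserted).
#'
#' @param config A [cornea_config()].
#' @param days Run length in days.
#' @param n Number of replicates.
#' @param seeds Optional integer vector of seeds (default `1:n`).
#' @param state Optional common starting state.
#' @param keep_sims Keep the individual `cornea_sim` objects (default
#'   FALSE to save memory).
#' @return An object of class `cornea_replicates`: `summary` data frame
#'   (mean/sd per sampled MCS), `stability_days`, `normality_p`, `seeds`.
#' @export
run_replicates <- function(config = cornea_config(), days, n = 3,
                           seeds = NULL, state = NULL, keep_sims = FALSE) {
  stopifnot(n >= 1)
  if (is.null(seeds)) seeds <- seq_len(n)
  stopifnot(length(seeds) == n)
  sims <- vector("list", n)
  metrics <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_cornea(config, state = state, days = days,
                           seed = seeds[i])
    metrics[[i]] <- metrics_series(sim)
    if (keep_sims) sims[[i]] <- sim
  }
  mcs_common <- Reduce(intersect, lapply(metrics, `[[`, "mcs"))
  cols <- c("n_stem", "n_basal", "n_wing", "n_super", "n_epithelial",
            "thickness_um")
  agg <- data.frame(mcs = mcs_common,
                    day = mcs_common / config$rules$day_to_mcs)
  for (cl in cols) {
    vals <- vapply(metrics, function(m) {
      m[[cl]][match(mcs_common, m$mcs)]
    }, numeric(length(mcs_common)))
    vals <- matrix(vals, nrow = length(mcs_common))
    agg[[paste0(cl, "_mean")]] <- rowMeans(vals)
    agg[[paste0(cl, "_sd")]] <- if (n > 1) apply(vals, 1, sd) else 0
  }
  stability_days <- vapply(metrics, stability_time, numeric(1),
                           day_to_mcs = config$rules$day_to_mcs)
  normality_p <- rep(NA_real_, 4)
  names(normality_p) <- c("n_stem", "n_basal", "n_wing", "n_super")
  stable <- suppressWarnings(min(stability_days, na.rm = TRUE))
  if (is.finite(stable)) {
    pooled <- do.call(rbind, metrics)
    pooled <- pooled[pooled$day >= stable, ]
    for (cl in names(normality_p)) {
      v <- pooled[[cl]]
      if (length(unique(v)) > 3 && length(v) >= 10) {
        v <- if (length(v) > 4000) sample(v, 4000) else v
        normality_p[cl] <- stats::shapiro.test(v)$p.value
      }
    }
  }
  out <- list(summary = agg, stability_days = stability_days,
              normality_p = normality_p, seeds = as.integer(seeds),
              metrics = metrics, sims = if (keep_sims) sims else NULL,
              config = config)
  class(out) <- "cornea_replicates"
  out
}

#' @export
print.cornea_replicates <- function(x, ...) {
  n <- length(x$seeds)
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("cornea_replicates: %d replicates, %.1f days\n", n, last$day))
  cat(sprintf("  final epithelial count %.1f +/- %.1f, thickness %.1f um\n",
              last$n_epithelial_mean, last$n_epithelial_sd,
              last$thickness_um_mean))
  cat("  stability days:", paste(format(x$stability_days), collapse = ", "),
      "\n")
  invisible(x)
}
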