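# Structured outputs: metrics/event CSV (RFC 4180, UTF-8, '.' decimal),
# run summary JSON, and lattice snapshot containers.

#' Write a metrics or event table as CSV
#'
#' @param df A data frame (e.g. from [metrics_series()] or `sim$events`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the run summary JSON
#'
#' Records the configuration hash, seed, run window, final cell counts,
#' stability time and any injury reports, so a run directory is
#' self-describing and reproducible.
#'
#' @param sim A `cornea_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(sim, path) {
  m <- metrics_series(sim)
  last <- m[nrow(m), ]
  reports <- lapply(sim$injury_reports, function(r) {
    if (!inherits(r, "injury_report")) return(NULL)
    list(classification = r$classification,
         deepest_layer_hit = r$deepest_layer_hit,
         killed_by_type = as.list(r$killed_by_type),
         memb_destroyed = r$memb_destroyed)
  })
  out <- list(
    config_hash = sim$config_hash,
    seed = sim$seed,
    mcs = c(sim$start_mcs, sim$end_mcs),
    day_to_mcs = sim$config$rules$day_to_mcs,
    stability_day = stability_time(m, day_to_mcs = sim$config$rules$day_to_mcs),
    final_counts = list(stem = last$n_stem, basal = last$n_basal,
                        wing = last$n_wing, super = last$n_super),
    final_thickness_um = last$thickness_um,
    accept_rate = sim$accepts / max(1, sim$attempts),
    injuries = reports
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Save and load lattice snapshots
#'
#' `save_snapshot()` stores the full state (owner grid, cell registry,
#' fields, counters) in an RDS container; `save_owner_csv()` writes the
#' owner grid alone as a plain-text CSV for external tools.
#'
#' @param state A `cornea_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_snapshot <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "cornea_state"))
  state
}

#' @rdname save_snapshot
#' @export
save_owner_csv <- function(state, path) {
  utils::write.table(state$owner, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
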