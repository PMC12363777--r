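# Lattice state construction and accessors.

new_cells_df <- function(id, type, target_volume, age = 0L, dying = 0L,
                         anchored = 0L, anchor_x = 0, anchor_y = 0,
                         parent = 0L) {
  data.frame(id = as.integer(id), type = as.integer(type),
             volume = 0L, target_volume = as.numeric(target_volume),
             surface = 0L, comx = NA_real_, comy = NA_real_,
             age = as.integer(rep_len(age, length(id))),
             dying = as.integer(rep_len(dying, length(id))),
             anchored = as.integer(rep_len(anchored, length(id))),
             anchor_x = as.numeric(rep_len(anchor_x, length(id))),
             anchor_y = as.numeric(rep_len(anchor_y, length(id))),
             parent = as.integer(rep_len(parent, length(id))))
}

# Refresh volume/surface/COM bookkeeping of a state from its owner grid.
refresh_state <- function(state) {
  rs <- cpp_rescan(state$owner)
  cells <- state$cells
  m <- match(cells$id, rs$id)
  cells$volume <- ifelse(is.na(m), 0L, rs$volume[m])
  cells$surface <- ifelse(is.na(m), 0L, rs$surface[m])
  cells$comx <- rs$comx[m]
  cells$comy <- rs$comy[m]
  state$cells <- cells[cells$volume > 0L, , drop = FALSE]
  state
}

#' Build the day-0 initial lattice state
#'
#' Constructs the starting configuration of the developing tissue: frozen
#' stroma at the bottom, a one-pixel basement membrane row (limbal segment
#' on the left, central segment elsewhere), a row of 25-pixel limbal
#' epithelial stem cells seeded on the limbal segment only, tear film over
#' every exposed surface, lateral wall columns, and air above. The EGF
#' field is relaxed to its tear-clamped steady configuration. No basal,
#' wing or superficial cells exist yet; the stratified tissue must emerge
#' from the simulation.
#'
#' @param config A [cornea_config()].
#' @return A list of class `cornea_state`: `owner` (width x height integer
#'   matrix of cell ids, 0 = air), `cells` (registry data frame), `egf`
#'   and `tox` concentration matrices, `mcs` counter and `next_id`.
#' @export
#' @examples
#' st <- build_initial_state(cornea_config())
#' table(type_name(st$cells$type))
build_initial_state <- function(config) {
  stopifnot(inherits(config, "cornea_config"))
  g <- config$geometry
  W <- g$width; H <- g$height
  owner <- matrix(0L, nrow = W, ncol = H)

  TEAR_ID <- 1L; LIMB_ID <- 2L; MEMB_ID <- 3L; STROMA_ID <- 4L
  WALL_L <- 5L; WALL_R <- 6L
  owner[1L, ] <- WALL_L
  owner[W, ] <- WALL_R
  inner <- 2:(W - 1L)
  owner[inner, seq_len(g$stroma_rows)] <- STROMA_ID
  memb_row <- g$stroma_rows + 1L
  limb_cols <- inner[inner <= g$limbal_width]      # x < limbal_width (0-based)
  memb_cols <- inner[inner > g$limbal_width]
  owner[limb_cols, memb_row] <- LIMB_ID
  owner[memb_cols, memb_row] <- MEMB_ID

  # stem cells tile the limbal membrane segment
  stem_rows <- (memb_row + 1L):(memb_row + g$stem_height)
  next_id <- 7L
  stem_ids <- integer(0)
  x0 <- min(limb_cols)
  while (x0 <= max(limb_cols)) {
    x1 <- min(x0 + g$stem_width - 1L, max(limb_cols))
    owner[x0:x1, stem_rows] <- next_id
    stem_ids <- c(stem_ids, next_id)
    next_id <- next_id + 1L
    x0 <- x1 + 1L
  }

  # tear film: fixed thickness over every exposed solid surface
  solid_codes <- TYPES[c("STEM", "BASAL", "WING", "SUPER", "LIMB", "MEMB",
                         "STROMA", "DMG")]
  type_of <- function(ids, cells) {
    tt <- integer(max(ids, 1L) + 1L)
    tt[cells$id + 1L] <- cells$type
    tt[ids + 1L]
  }
  cells <- new_cells_df(
    id = c(TEAR_ID, LIMB_ID, MEMB_ID, STROMA_ID, WALL_L, WALL_R, stem_ids),
    type = c(TYPES[["TEAR"]], TYPES[["LIMB"]], TYPES[["MEMB"]],
             TYPES[["STROMA"]], TYPES[["WALL"]], TYPES[["WALL"]],
             rep(TYPES[["STEM"]], length(stem_ids))),
    target_volume = c(0, 0, 0, 0, 0, 0,
                      rep(config$rules$init_volume, length(stem_ids))))
  for (x in inner) {
    col_types <- type_of(owner[x, ], cells)
    top <- max(which(col_types %in% solid_codes))
    ytear <- (top + 1L):min(top + g$tear_thickness, H)
    owner[x, ytear] <- TEAR_ID
  }

  state <- list(owner = owner, cells = cells,
                egf = matrix(0, nrow = W, ncol = H),
                tox = NULL, mcs = 0L, next_id = next_id,
                config = config)
  class(state) <- "cornea_state"
  state <- refresh_state(state)

  # relax the EGF field to the tear-clamped steady profile
  res <- engine_call(state, config, n_mcs = 60L, seed = 0L, sample_every = 0L,
                     enable = enable_flags(fields = TRUE))
  state$egf <- res$state$egf
  state
}

# Canonical enable-flag list for the C++ pipeline.
enable_flags <- function(fields = FALSE, kill = FALSE, growth = FALSE,
                         differentiation = FALSE, mitosis = FALSE,
                         slough = FALSE, metropolis = FALSE, rewet = FALSE,
                         all = FALSE) {
  if (all)
    return(list(fields = TRUE, kill = TRUE, growth = TRUE,
                differentiation = TRUE, mitosis = TRUE, slough = TRUE,
                metropolis = TRUE, rewet = TRUE))
  list(fields = fields, kill = kill, growth = growth,
       differentiation = differentiation, mitosis = mitosis, slough = slough,
       metropolis = metropolis, rewet = rewet)
}

# Strip names/classes for the C++ boundary.
flatten_params <- function(config) {
  potts <- config$potts
  potts$J <- unname(config$potts$J)
  potts$lambda_volume <- unname(config$potts$lambda_volume)
  potts$lambda_surface <- unname(config$potts$lambda_surface)
  potts$chemotaxis_mu <- unname(config$potts$chemotaxis_mu)
  potts$surface_factor <- unname(config$potts$surface_factor)
  rules <- config$rules
  rules$tear_thickness <- config$geometry$tear_thickness
  list(potts = potts, rules = rules)
}

state_for_cpp <- function(state) {
  st <- unclass(state)[c("owner", "cells", "egf", "tox", "mcs", "next_id")]
  st$cells <- as.list(st$cells)
  st
}

# Shared bridge into the compiled pipeline.
engine_call <- function(state, config, n_mcs, seed, sample_every,
                        enable = enable_flags(all = TRUE)) {
  st <- state_for_cpp(state)
  tox_par <- NULL
  if (!is.null(state$tox)) tox_par <- config$tox
  fp <- flatten_params(config)
  res <- cpp_run(st, fp$potts, fp$rules, config$egf, tox_par,
                 as.integer(n_mcs), as.integer(seed),
                 as.integer(sample_every), enable)
  res$state$cells <- as.data.frame(res$state$cells)
  res$state$config <- config
  if (is.null(state$tox)) res$state$tox <- NULL
  class(res$state) <- "cornea_state"
  res
}

#' @export
print.cornea_state <- function(x, ...) {
  tc <- table(factor(type_name(x$cells$type), levels = TYPE_NAMES))
  cat(sprintf("cornea_state: %d x %d lattice, MCS %d (day %.2f)\n",
              nrow(x$owner), ncol(x$owner), x$mcs,
              x$mcs / x$config$rules$day_to_mcs))
  ep <- tc[EPITHELIAL]
  cat("  epithelial cells:",
      paste(sprintf("%s=%d", names(ep), ep), collapse = ", "), "\n")
  th <- thickness_com(x)
  if (!is.na(th)) cat(sprintf("  thickness (COM difference): %.1f um\n", th))
  invisible(x)
}

#' @export
summary.cornea_state <- function(object, ...) {
  cells <- object$cells
  ep <- cells[cells$type %in% TYPES[EPITHELIAL], ]
  out <- list(
    mcs = object$mcs,
    counts = table(factor(type_name(ep$type), levels = EPITHELIAL)),
    thickness_um = thickness_com(object),
    mean_volume = if (nrow(ep)) mean(ep$volume) else NA_real_,
    fragmented = cpp_count_fragmented(object$owner)
  )
  class(out) <- "summary.cornea_state"
  out
}

#' @export
print.summary.cornea_state <- function(x, ...) {
  cat("MCS:", x$mcs, "\n")
  print(x$counts)
  cat(sprintf("thickness %.1f um, mean cell volume %.1f px, %d fragmented cells\n",
              x$thickness_um, x$mean_volume, x$fragmented))
  invisible(x)
}
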