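# Shared fixtures: small configurations, hand-built lattice states, and the
# independent brute-force Hamiltonian oracle (kept free of the engine's
# incremental code path).

TY <- cornea_types()

small_config <- function(...) {
  cornea_config(geometry = list(width = 60, height = 50, limbal_width = 20,
                                stroma_rows = 20),
                ...)
}

# Build a cornea_state from an explicit owner grid and an id -> type map.
make_state <- function(owner, types, config, target_volume = NULL) {
  storage.mode(owner) <- "integer"
  ids <- sort(unique(owner[owner > 0]))
  tcode <- unname(types[as.character(ids)])
  stopifnot(!anyNA(tcode))
  if (is.null(target_volume))
    target_volume <- as.numeric(tabulate(match(owner, ids), length(ids)))
  cells <- corneacpm:::new_cells_df(ids, tcode, target_volume)
  state <- list(owner = owner, cells = cells,
                egf = matrix(0, nrow(owner), ncol(owner)),
                tox = NULL, mcs = 0L, next_id = max(ids) + 1L,
                config = config)
  class(state) <- "cornea_state"
  corneacpm:::refresh_state(state)
}

# A layered mini-tissue: stroma, membrane row (LIMB left / MEMB right),
# a basal row of cells `bw` voxels wide, optional wing and superficial rows,
# tear on top, wall columns. Cell heights are `ch` voxels.
layered_state <- function(config, bw = 8, ch = 4, wing_rows = 1,
                          super_row = TRUE) {
  g <- config$geometry
  W <- g$width; H <- g$height
  owner <- matrix(0L, W, H)
  owner[1, ] <- 5L; owner[W, ] <- 6L          # walls
  inner <- 2:(W - 1)
  owner[inner, 1:g$stroma_rows] <- 4L          # stroma
  memb <- g$stroma_rows + 1L
  owner[inner[inner <= g$limbal_width], memb] <- 2L
  owner[inner[inner > g$limbal_width], memb] <- 3L
  types <- c(`1` = TY[["TEAR"]], `2` = TY[["LIMB"]], `3` = TY[["MEMB"]],
             `4` = TY[["STROMA"]], `5` = TY[["WALL"]], `6` = TY[["WALL"]])
  nid <- 7L
  add_row <- function(owner, types, y0, typec, nid) {
    x0 <- 2L
    while (x0 <= W - 1L) {
      x1 <- min(x0 + bw - 1L, W - 1L)
      owner[x0:x1, y0:(y0 + ch - 1L)] <- nid
      types[as.character(nid)] <- typec
      nid <- nid + 1L
      x0 <- x1 + 1L
    }
    list(owner = owner, types = types, nid = nid)
  }
  y <- memb + 1L
  r <- add_row(owner, types, y, TY[["BASAL"]], nid)
  y <- y + ch
  for (k in seq_len(wing_rows)) {
    r <- add_row(r$owner, r$types, y, TY[["WING"]], r$nid)
    y <- y + ch
  }
  if (super_row) {
    r <- add_row(r$owner, r$types, y, TY[["SUPER"]], r$nid)
    y <- y + ch
  }
  owner <- r$owner
  owner[inner, y:(y + g$tear_thickness - 1L)] <- 1L   # tear
  make_state(owner, r$types, config)
}

# ---- brute-force Hamiltonian oracle ---------------------------------------
# Independent total-energy computation: contact over unordered 8-neighbour
# pairs, volume and surface constraints, and adhesion-spring energies.
# Chemotaxis is not a state function and is checked separately.
brute_force_H <- function(state, config) {
  owner <- state$owner
  W <- nrow(owner); H <- ncol(owner)
  cells <- state$cells
  type_of <- integer(max(cells$id) + 1L)
  type_of[cells$id + 1L] <- cells$type
  tmap <- matrix(type_of[owner + 1L], W, H)
  J <- config$potts$J
  Hc <- 0
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    xs <- 1:(W - d[1]); ys <- max(1, 1 - d[2]):min(H, H - d[2])
    o1 <- owner[xs, ys]
    o2 <- owner[xs + d[1], ys + d[2]]
    diffpair <- o1 != o2
    Hc <- Hc + sum(J[cbind(tmap[xs, ys][diffpair] + 1L,
                           tmap[xs + d[1], ys + d[2]][diffpair] + 1L)])
  }
  lamv <- config$potts$lambda_volume
  lams <- config$potts$lambda_surface
  sfac <- config$potts$surface_factor
  rs <- corneacpm:::cpp_rescan(owner)
  m <- match(cells$id, rs$id)
  vol <- ifelse(is.na(m), 0, rs$volume[m])
  surf <- ifelse(is.na(m), 0, rs$surface[m])
  tn <- cells$type + 1L
  Hv <- sum(lamv[tn] * (vol - cells$target_volume)^2)
  st <- sfac[tn] * sqrt(pmax(cells$target_volume, 0))
  Hs <- sum(lams[tn] * (surf - st)^2)
  Hl <- 0
  if (config$potts$lambda_link > 0) {
    anch <- cells$anchored == 1L
    if (any(anch)) {
      cx <- rs$comx[m][anch]; cy <- rs$comy[m][anch]
      d <- sqrt((cx - cells$anchor_x[anch])^2 + (cy - cells$anchor_y[anch])^2)
      Hl <- sum(config$potts$lambda_link * (d - config$potts$link_rest)^2)
    }
  }
  Hc + Hv + Hs + Hl
}

# Random two-to-four cell states on a small lattice for property tests.
random_small_state <- function(config, seed, n_cells = 3) {
  set.seed(seed)
  W <- config$geometry$width; H <- config$geometry$height
  owner <- matrix(0L, W, H)
  # random blobs of mobile types plus a tear background region
  owner[, 1:floor(H / 3)] <- 1L  # tear
  types <- c(`1` = TY[["TEAR"]])
  for (i in seq_len(n_cells)) {
    id <- i + 1L
    cx <- sample(3:(W - 2), 1); cy <- sample(floor(H / 3):(H - 2), 1)
    rx <- sample(2:4, 1); ry <- sample(2:4, 1)
    xs <- max(1, cx - rx):min(W, cx + rx)
    ys <- max(1, cy - ry):min(H, cy + ry)
    owner[xs, ys] <- id
    types[as.character(id)] <- sample(c(TY[["BASAL"]], TY[["WING"]],
                                        TY[["SUPER"]]), 1)
  }
  n_alive <- length(unique(owner[owner > 0]))
  tv <- 1 + round(runif(n_alive) * 30)
  st <- make_state(owner, types, config, target_volume = tv)
  st$egf <- matrix(runif(W * H), W, H)
  st
}

# random neighbouring pixel pair with differing mobile owners, or NULL
random_copy_pair <- function(state) {
  W <- nrow(state$owner); H <- ncol(state$owner)
  for (try in 1:300) {
    x <- sample(2:(W - 1), 1); y <- sample(2:(H - 1), 1)
    dx <- sample(c(-1, 0, 1), 1); dy <- sample(c(-1, 0, 1), 1)
    if (dx == 0 && dy == 0) next
    t <- state$owner[x, y]; s <- state$owner[x + dx, y + dy]
    if (s == t || s == 0 || t == 0) next
    return(list(src = c(x + dx, y + dy) - 1L, tgt = c(x, y) - 1L))
  }
  NULL
}

# apply one pixel copy by hand (returns refreshed state)
apply_copy <- function(state, src, tgt) {
  state$owner[tgt[1] + 1L, tgt[2] + 1L] <- state$owner[src[1] + 1L, src[2] + 1L]
  corneacpm:::refresh_state(state)
}
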