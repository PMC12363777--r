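# PNG rendering of lattice snapshots.

#' Render a lattice snapshot
#'
#' Draws the owner grid with the conventional palette (see
#' [cornea_palette()]), one pixel per voxel (scalable), with the air at the
#' top of the image. Optionally overlays cell boundaries in black.
#'
#' @param state A `cornea_state`.
#' @param file Optional PNG output path; when `NULL` the image is returned
#'   as a raster object.
#' @param palette Named color vector by type (default [cornea_palette()]).
#' @param scale Integer magnification factor.
#' @param boundaries Draw cell-cell boundaries (default TRUE).
#' @return A `raster` object (invisibly if written to file).
#' @export
render_snapshot <- function(state, file = NULL, palette = cornea_palette(),
                            scale = 1L, boundaries = TRUE) {
  W <- nrow(state$owner); H <- ncol(state$owner)
  type_of_id <- integer(state$next_id + 1L)
  type_of_id[state$cells$id + 1L] <- state$cells$type
  tmap <- matrix(type_of_id[state$owner + 1L], nrow = W, ncol = H)
  cols <- palette[TYPE_NAMES[tmap + 1L]]
  dim(cols) <- c(W, H)
  if (boundaries) {
    own <- state$owner
    edge <- matrix(FALSE, W, H)
    edge[-W, ] <- edge[-W, ] | (own[-W, ] != own[-1, ])
    edge[, -H] <- edge[, -H] | (own[, -H] != own[, -1])
    epi <- matrix(tmap %in% TYPES[EPITHELIAL], W, H)
    cols[edge & epi] <- "#202020"
  }
  # image rows run top-down: flip y so air is at the top
  img <- t(cols)[H:1, , drop = FALSE]
  if (scale > 1) {
    img <- img[rep(seq_len(nrow(img)), each = scale),
               rep(seq_len(ncol(img)), each = scale)]
  }
  rast <- grDevices::as.raster(img)
  if (is.null(file)) return(rast)
  rgb <- grDevices::col2rgb(img) / 255
  arr <- array(0, dim = c(nrow(img), ncol(img), 3))
  arr[, , 1] <- matrix(rgb[1, ], nrow(img), ncol(img))
  arr[, , 2] <- matrix(rgb[2, ], nrow(img), ncol(img))
  arr[, , 3] <- matrix(rgb[3, ], nrow(img), ncol(img))
  png::writePNG(arr, target = file)
  invisible(rast)
}

#' Plot a lattice state
#'
#' @param x A `cornea_state`.
#' @param ... Ignored.
#' @return The raster, invisibly.
#' @export
plot.cornea_state <- function(x, ...) {
  rast <- render_snapshot(x)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = ncol(x$owner) /
                          nrow(x$owner))
  graphics::rasterImage(rast, 0, 0, 1, 1, interpolate = FALSE)
  graphics::title(sprintf("MCS %d", x$mcs))
  invisible(rast)
}
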