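# Sliding-window decomposition of multitissue regions.
#
# Large images are tiled with partially overlapping 224 px windows (stride
# 112 = 50% overlap by default, plus a flush-to-edge window so borders are
# covered), each tile is classified, and the per-tile softmax activations are
# averaged into a region-level activation vector. Per-patient vectors pool
# region vectors by the componentwise maximum.

#' Sliding-window offsets along one axis
#'
#' Offsets `0, stride, 2*stride, ...` plus a final flush-to-edge offset when
#' the last regular window does not reach the border.
#'
#' @param n Axis length in pixels.
#' @param tile Window size.
#' @param stride Step between windows.
#' @return Integer vector of 0-based offsets.
#' @export
tile_offsets <- function(n, tile = 224L, stride = 112L) {
  if (n < tile) stop("region smaller than the tile size", call. = FALSE)
  off <- seq.int(0L, n - tile, by = stride)
  if (off[length(off)] < n - tile) off <- c(off, n - tile)
  as.integer(off)
}

#' Extract overlapping tiles from a region image
#'
#' @param region RGB array (`H x W x 3`), both dimensions at least `tile`.
#' @param tile Tile side length (default 224).
#' @param stride Sliding-window step (default 112, i.e. 50% overlap).
#' @return List with `tiles` (list of tile arrays) and `offsets` (data frame
#'   of 0-based `x`/`y` tile origins, x = column, y = row).
#' @export
tile_region <- function(region, tile = 224L, stride = 112L) {
  d <- dim(region)
  if (is.null(d) || length(d) != 3L) stop("region must be an H x W x 3 array")
  ys <- tile_offsets(d[1], tile, stride)
  xs <- tile_offsets(d[2], tile, stride)
  grid <- expand.grid(y = ys, x = xs)
  tiles <- lapply(seq_len(nrow(grid)), function(i) {
    region[grid$y[i] + seq_len(tile), grid$x[i] + seq_len(tile), , drop = FALSE]
  })
  list(tiles = tiles, offsets = grid[, c("x", "y")], tile = as.integer(tile))
}

#' Per-tile activation map of a region
#'
#' @param model A trained tissue classifier.
#' @param region RGB region array.
#' @inheritParams tile_region
#' @return Object of class `activation_map`: list with `activations` (one row
#'   per tile, nine columns), `offsets`, `tile`, and `dim` (region size).
#' @export
activation_map <- function(model, region, tile = 224L, stride = 112L) {
  tl <- tile_region(region, tile, stride)
  A <- predict(model, tl$tiles)
  structure(list(activations = A, offsets = tl$offsets, tile = tl$tile,
                 dim = dim(region)[1:2]),
            class = "activation_map")
}

#' Mean activation vector of a region
#'
#' The elementwise mean of all tile activation vectors; still a probability
#' vector (summing to 1).
#'
#' @inheritParams activation_map
#' @return Named numeric activation vector over the nine classes.
#' @export
region_activation <- function(model, region, tile = 224L, stride = 112L) {
  colMeans(activation_map(model, region, tile, stride)$activations)
}

#' Render an activation map as an RGB overlay
#'
#' Each pixel's colour is the palette colour sum weighted by the class
#' activations, averaged over all tiles covering that pixel (uniform tile
#' weights), clipped to `[0, 255]`.
#'
#' @param map An [activation_map()].
#' @param palette Named list/matrix of one RGB triplet (0-255) per class.
#' @return RGB array of the region's size.
#' @export
render_map <- function(map, palette = class_palette()) {
  stopifnot(inherits(map, "activation_map"))
  classes <- colnames(map$activations)
  if (!all(classes %in% names(palette))) {
    stop("palette missing classes: ",
         paste(setdiff(classes, names(palette)), collapse = ", "),
         call. = FALSE)
  }
  pal <- do.call(rbind, palette[classes])          # 9 x 3
  cols <- map$activations %*% pal                  # tile colours, n x 3
  H <- map$dim[1]; W <- map$dim[2]; tile <- map$tile
  acc <- array(0, dim = c(H, W, 3L))
  cnt <- matrix(0, H, W)
  for (i in seq_len(nrow(cols))) {
    ry <- map$offsets$y[i] + seq_len(tile)
    rx <- map$offsets$x[i] + seq_len(tile)
    for (ch in 1:3) acc[ry, rx, ch] <- acc[ry, rx, ch] + cols[i, ch]
    cnt[ry, rx] <- cnt[ry, rx] + 1
  }
  for (ch in 1:3) acc[, , ch] <- acc[, , ch] / cnt
  acc[acc < 0] <- 0; acc[acc > 255] <- 255
  acc
}

#' Default class colour palette for activation overlays
#'
#' @return Named list of RGB triplets (0-255), one per tissue class.
#' @export
class_palette <- function() {
  list(ADI  = c(255, 255, 160),
       BACK = c(190, 190, 190),
       DEB  = c(120,  70,  20),
       LYM  = c( 30,  30, 200),
       MUC  = c(120, 220, 220),
       MUS  = c(230, 130, 200),
       NORM = c( 40, 160,  40),
       STR  = c(240, 120,  40),
       TUM  = c(200,  30,  30))
}

#' Pool region activation vectors to the patient level
#'
#' Componentwise maximum over a patient's region vectors ("max pooling");
#' the result need not sum to 1.
#'
#' @param vectors A matrix with one activation vector per row, or a list of
#'   activation vectors.
#' @return Named numeric vector, the componentwise maximum.
#' @export
pool_patient <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (nrow(vectors) == 0L) stop("no region vectors to pool", call. = FALSE)
  apply(vectors, 2L, max)
}
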