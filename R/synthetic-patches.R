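# Procedural H&E texture generator.
#
# Each tissue class is an archetypal two-stain texture: per-pixel hematoxylin
# and eosin concentration fields are built from simple primitives (disks,
# rings, fibres, speckle, smooth noise) and converted to RGB through the
# Beer-Lambert law I = I_bg * 10^(-M %*% c), with M the canonical H&E optical
# density vectors. This makes the patches genuinely two-stain in OD space, so
# the Macenko estimator can be exercised on them, and gives each class one
# documented scalar texture statistic that separates it from every other class:
#   ADI  - near-white with thin membrane rings: high white fraction, nonzero edge density
#   BACK - uniformly near-white: white fraction ~1, negligible edge density
#   DEB  - eosinophilic speckle clumps: high high-frequency energy, no orientation
#   LYM  - dense small dark basophilic disks: highest dark-pixel fraction
#   MUC  - smooth pale chroma: low gradient energy, intermediate intensity
#   MUS  - broad eosinophilic fibres: strong long-lag autocorrelation (period ~26 px)
#   NORM - regularly spaced glandular rings: ring-scale autocorrelation, high H content
#   STR  - narrow wavy fibres: strong short-lag anticorrelation (period ~9 px)
#   TUM  - large irregular basophilic blobs: intermediate dark fraction, coarse blobs

#' Texture generator settings
#'
#' Parameters of the procedural nine-class H&E texture generator. Geometry is
#' in pixels at the nominal 0.5 um/px scale of the emitted patches; densities
#' are per pixel squared so that patches and large regions share one texture
#' model.
#'
#' @param seed Integer seed; together with the class code it fully determines
#'   every emitted image.
#' @param stain_hematoxylin,stain_eosin RGB optical-density direction of each
#'   stain (normalised internally to unit length).
#' @param background_intensity Transmitted-light background level in
#'   `[0, 255]`.
#' @param noise_sd Standard deviation (intensity units) of the additive sensor
#'   noise.
#' @param lym_blob_radius,lym_blob_density Radius (px) and density (per px^2)
#'   of the small dark lymphocyte disks.
#' @param tum_blob_radius,tum_blob_density Radius and density of the larger
#'   tumour-epithelium blobs.
#' @param adi_vacuole_radius Radius (px) of adipose vacuoles (rendered as thin
#'   membrane rings on a white field).
#' @param norm_gland_spacing,norm_gland_radius Centre spacing and ring radius
#'   (px) of the regular glands of normal mucosa.
#' @param mus_fiber_period,str_fiber_period Fibre period (px) of smooth muscle
#'   (broad) and desmoplastic stroma (narrow).
#' @param deb_speckle_density Bernoulli density of debris speckle seeds.
#' @param muc_chroma Base eosin concentration of the mucus field.
#' @return An object of class `texture_params`.
#' @export
#' @examples
#' p <- texture_params(seed = 7)
#' img <- generate_patch("LYM", p)
#' dim(img)
texture_params <- function(seed = 1L,
                           stain_hematoxylin = c(0.65, 0.70, 0.29),
                           stain_eosin = c(0.07, 0.99, 0.11),
                           background_intensity = 247,
                           noise_sd = 2,
                           lym_blob_radius = 4,
                           lym_blob_density = 0.012,
                           tum_blob_radius = 10,
                           tum_blob_density = 0.0035,
                           adi_vacuole_radius = 26,
                           norm_gland_spacing = 38,
                           norm_gland_radius = 13,
                           mus_fiber_period = 26,
                           str_fiber_period = 9,
                           deb_speckle_density = 0.03,
                           muc_chroma = 0.28) {
  p <- list(seed = as.integer(seed),
            stain_hematoxylin = stain_hematoxylin / sqrt(sum(stain_hematoxylin^2)),
            stain_eosin = stain_eosin / sqrt(sum(stain_eosin^2)),
            background_intensity = background_intensity,
            noise_sd = noise_sd,
            lym_blob_radius = lym_blob_radius,
            lym_blob_density = lym_blob_density,
            tum_blob_radius = tum_blob_radius,
            tum_blob_density = tum_blob_density,
            adi_vacuole_radius = adi_vacuole_radius,
            norm_gland_spacing = norm_gland_spacing,
            norm_gland_radius = norm_gland_radius,
            mus_fiber_period = mus_fiber_period,
            str_fiber_period = str_fiber_period,
            deb_speckle_density = deb_speckle_density,
            muc_chroma = muc_chroma)
  stopifnot(p$background_intensity >= 0, p$background_intensity <= 255,
            p$noise_sd >= 0,
            p$lym_blob_radius > 0, p$lym_blob_density > 0,
            p$tum_blob_radius > 0, p$tum_blob_density > 0,
            p$adi_vacuole_radius > 0,
            p$norm_gland_spacing > 0, p$norm_gland_radius > 0,
            p$mus_fiber_period > 0, p$str_fiber_period > 0,
            p$deb_speckle_density > 0, p$muc_chroma > 0)
  structure(p, class = "texture_params")
}

# ---- texture primitives -----------------------------------------------------

.disk_template <- function(r, inner = -1) {
  cr <- ceiling(r)
  x <- seq(-cr, cr)
  d2 <- outer(x^2, x^2, `+`)
  (d2 <= r^2 & d2 > inner^2) * 1
}

# Additively stamp `template * value` at integer centres (cy = row, cx = col),
# clipped to the matrix bounds.
.stamp <- function(mat, cy, cx, template, value) {
  tr <- (nrow(template) - 1L) %/% 2L
  H <- nrow(mat); W <- ncol(mat)
  for (i in seq_along(cy)) {
    y0 <- cy[i] - tr; y1 <- cy[i] + tr
    x0 <- cx[i] - tr; x1 <- cx[i] + tr
    ty0 <- 1L + max(0L, 1L - y0); ty1 <- nrow(template) - max(0L, y1 - H)
    tx0 <- 1L + max(0L, 1L - x0); tx1 <- ncol(template) - max(0L, x1 - W)
    if (ty0 > ty1 || tx0 > tx1) next
    ry <- max(1L, y0):min(H, y1)
    rx <- max(1L, x0):min(W, x1)
    mat[ry, rx] <- mat[ry, rx] + template[ty0:ty1, tx0:tx1] * value
  }
  mat
}

.grid_centers <- function(H, W, spacing, jitter) {
  gy <- seq(spacing / 2, H, by = spacing)
  gx <- seq(spacing / 2, W, by = spacing)
  pts <- expand.grid(y = gy, x = gx)
  n <- nrow(pts)
  cy <- as.integer(round(clamp(pts$y + stats::runif(n, -jitter, jitter), 1, H)))
  cx <- as.integer(round(clamp(pts$x + stats::runif(n, -jitter, jitter), 1, W)))
  list(cy = cy, cx = cx)
}

.random_centers <- function(H, W, n) {
  list(cy = as.integer(ceiling(stats::runif(n) * H)),
       cx = as.integer(ceiling(stats::runif(n) * W)))
}

# Smooth unit-variance noise field.
.smooth_noise <- function(H, W, k) {
  z <- box_blur(matrix(stats::rnorm(H * W), H, W), k)
  z / max(stats::sd(z), 1e-9)
}

# Sinusoidal fibre field in [0, 1] with random orientation and phase wiggle.
.fiber_field <- function(H, W, period, wiggle) {
  theta <- stats::runif(1, 0, pi)
  phase <- stats::runif(1, 0, 2 * pi)
  u <- outer(seq_len(H) * sin(theta), rep(1, W)) +
       outer(rep(1, H), seq_len(W) * cos(theta))
  if (wiggle > 0) u <- u + wiggle * .smooth_noise(H, W, 31)
  (1 + sin(2 * pi * u / period + phase)) / 2
}

# Hematoxylin/eosin concentration fields for one class. Consumes the current
# RNG stream; callers wrap it in with_seed().
.texture_fields <- function(cls, H, W, p) {
  hmat <- matrix(0, H, W)
  emat <- matrix(0, H, W)
  area <- H * W
  switch(cls,
    BACK = {
      emat <- 0.012 * abs(.smooth_noise(H, W, 7))
    },
    ADI = {
      ring <- .disk_template(p$adi_vacuole_radius, p$adi_vacuole_radius - 3)
      ctr <- .grid_centers(H, W, 1.8 * p$adi_vacuole_radius, 6)
      emat <- .stamp(emat, ctr$cy, ctr$cx, ring, 0.40)
      hmat <- .stamp(hmat, ctr$cy, ctr$cx, ring, 0.18)
    },
    DEB = {
      seedmask <- matrix(stats::rbinom(area, 1L, p$deb_speckle_density), H, W)
      clumps <- box_blur(seedmask, 5) > p$deb_speckle_density * 1.2
      emat <- clumps * 0.55 + 0.10
      hmat <- clumps * 0.35 + 0.05 * abs(.smooth_noise(H, W, 9))
    },
    LYM = {
      disk <- .disk_template(p$lym_blob_radius)
      ctr <- .random_centers(H, W, round(p$lym_blob_density * area))
      hmat <- .stamp(hmat, ctr$cy, ctr$cx, disk, 1.25)
      hmat <- pmin(hmat, 1.6)
      emat <- emat + 0.06
    },
    MUC = {
      emat <- p$muc_chroma * (1 + 0.25 * .smooth_noise(H, W, 25))
      hmat <- 0.09 * (1 + 0.6 * .smooth_noise(H, W, 25))
    },
    MUS = {
      s <- .fiber_field(H, W, p$mus_fiber_period, 2)
      emat <- 0.18 + 0.45 * s
      hmat <- 0.10 + 0.06 * s
    },
    NORM = {
      ring <- .disk_template(p$norm_gland_radius, p$norm_gland_radius - 4)
      ctr <- .grid_centers(H, W, p$norm_gland_spacing, 3)
      hmat <- .stamp(hmat, ctr$cy, ctr$cx, ring, 0.85)
      emat <- matrix(0.25, H, W)
    },
    STR = {
      s <- .fiber_field(H, W, p$str_fiber_period, 3)
      emat <- 0.16 + 0.50 * s
      hmat <- 0.14 + 0.08 * s
    },
    TUM = {
      disk <- .disk_template(p$tum_blob_radius)
      ctr <- .random_centers(H, W, round(p$tum_blob_density * area))
      hmat <- .stamp(hmat, ctr$cy, ctr$cx, disk, 0.85)
      hmat <- pmin(hmat, 1.3)
      emat <- emat + 0.22
    },
    stop("unhandled class ", cls))
  list(h = pmax(hmat, 0), e = pmax(emat, 0))
}

# Render concentration fields to an 8-bit RGB array (Beer-Lambert + noise).
.render_stains <- function(fields, p) {
  H <- nrow(fields$h); W <- ncol(fields$h)
  M <- cbind(p$stain_hematoxylin, p$stain_eosin)      # 3 x 2 OD matrix
  od <- cbind(as.vector(fields$h), as.vector(fields$e)) %*% t(M)
  img <- p$background_intensity * exp(-log(10) * as.vector(od))
  if (p$noise_sd > 0) img <- img + stats::rnorm(length(img), sd = p$noise_sd)
  img <- trunc(pmin(pmax(img, 0), 255) + 0.5)   # clamp, then round half-up
  storage.mode(img) <- "integer"                # 8-bit content, half the RAM
  dim(img) <- c(H, W, 3L)
  img
}

.patch_seed <- function(seed, cls_index, salt = 0L) {
  as.integer((as.numeric(seed) * 1009 + cls_index * 97 + salt * 7919) %%
             .Machine$integer.max)
}

#' Generate one synthetic tissue patch
#'
#' Emits a 224 x 224 (by default) 8-bit RGB patch whose texture follows the
#' archetype of the requested tissue class. Output is bit-identical for a
#' fixed `(cls, params$seed)` pair.
#'
#' @param cls One of the nine codes in [tissue_classes()].
#' @param params A [texture_params()] object.
#' @param size Patch side length in pixels.
#' @return A `size x size x 3` numeric array with integer values in
#'   `[0, 255]`, carrying the class code in attribute `"tissue_class"`.
#' @export
generate_patch <- function(cls, params = texture_params(), size = 224L) {
  .check_class(cls)
  stopifnot(inherits(params, "texture_params"), size >= 16L)
  idx <- match(cls, tissue_classes())
  img <- with_seed(.patch_seed(params$seed, idx), {
    .render_stains(.texture_fields(cls, size, size, params), params)
  })
  attr(img, "tissue_class") <- cls
  img
}

#' Generate a composite multitissue region with its ground-truth mask
#'
#' Builds a large RGB image tiled from per-class textures on a randomised
#' rectangular block partition (a coarse Voronoi-like mosaic), honouring the
#' requested area fractions to within the block quantisation (+/- 1 block,
#' i.e. about 1 percentage point at the defaults), together with a pixelwise
#' ground-truth label mask.
#'
#' @param composition Named numeric vector of per-class area fractions
#'   (names from [tissue_classes()]); must be nonnegative and sum to 1.
#' @param params A [texture_params()] object.
#' @param size Region side length in pixels (default 1500).
#' @param block Side length of the square partition blocks (default 150 px).
#' @return A list with elements `image` (`size x size x 3` RGB array) and
#'   `mask` (`size x size` integer matrix of class indices into
#'   [tissue_classes()]).
#' @export
generate_region <- function(composition, params = texture_params(),
                            size = 1500L, block = 150L) {
  codes <- tissue_classes()
  if (is.null(names(composition)) || !all(names(composition) %in% codes)) {
    stop("composition must be named with valid tissue class codes: ",
         paste(codes, collapse = ", "), call. = FALSE)
  }
  if (any(composition < 0)) stop("composition fractions must be nonnegative")
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("composition fractions must sum to 1 (got ",
         format(sum(composition)), ")", call. = FALSE)
  }
  if (size %% block != 0L) stop("size must be a multiple of block")
  nb <- size %/% block
  ncell <- nb * nb
  frac <- composition[composition > 0]
  cls_present <- names(frac)

  with_seed(.patch_seed(params$seed, 0L, salt = 1L), {
    # largest-remainder apportionment of blocks to classes
    raw <- frac * ncell
    cnt <- floor(raw)
    rem <- ncell - sum(cnt)
    if (rem > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    # classes whose fraction rounds to zero blocks contribute no pixels
    cls_present <- cls_present[cnt > 0]
    assignment <- sample(rep(names(cnt)[cnt > 0], times = cnt[cnt > 0]))

    # each block gets an independently synthesised texture of its class
    mask <- matrix(0L, size, size)
    hmat <- matrix(0, size, size)
    emat <- matrix(0, size, size)
    cellmap <- matrix(assignment, nb, nb)
    for (by in seq_len(nb)) {
      for (bx in seq_len(nb)) {
        ry <- ((by - 1L) * block + 1L):(by * block)
        rx <- ((bx - 1L) * block + 1L):(bx * block)
        cl <- cellmap[by, bx]
        mask[ry, rx] <- match(cl, codes)
        f <- .texture_fields(cl, block, block, params)
        hmat[ry, rx] <- f$h
        emat[ry, rx] <- f$e
      }
    }
    img <- .render_stains(list(h = hmat, e = emat), params)
    list(image = img, mask = mask)
  })
}
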