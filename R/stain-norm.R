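# Macenko stain normalization.
#
# H&E colour variation is modelled in optical-density (OD) space, where stain
# mixing is linear: OD = M %*% c with M the 3x2 matrix of unit stain vectors
# (hematoxylin, eosin) and c >= 0 the per-pixel concentrations. The stain
# matrix of an image is estimated from the SVD of its tissue-pixel OD cloud
# (robust percentile angles in the top-2 singular plane), and an image is
# normalized by re-expressing its concentrations through a reference profile.

#' Convert an RGB image to optical density
#'
#' `OD = -log10(max(I, 1) / I0)` per channel; zero intensities are clamped to
#' 1 before the log so the OD stays finite.
#'
#' @param image Numeric array (any shape) of intensities in `[0, I0]`.
#' @param I0 Transmitted-light reference intensity (default 255).
#' @return Array of the same shape with nonnegative OD values.
#' @export
rgb_to_od <- function(image, I0 = 255) {
  if (I0 <= 0) stop("I0 must be positive", call. = FALSE)
  od <- -log10(pmax(image, 1) / I0)
  dim(od) <- dim(image)
  od
}

# Inverse map back to intensities, clipped to [0, I0].
od_to_rgb <- function(od, I0 = 255) {
  pmin(pmax(I0 * 10^(-od), 0), I0)
}

#' Construct a stain profile
#'
#' @param M 3 x 2 matrix of optical-density stain vectors (columns =
#'   hematoxylin, eosin); columns are normalised to unit length.
#' @param max_concentration Length-2 vector of reference (99th percentile)
#'   concentrations per stain.
#' @param alpha,beta,I0 Macenko percentile angle parameter, OD transparency
#'   threshold, and light reference.
#' @return An object of class `stain_profile`.
#' @export
stain_profile <- function(M, max_concentration, alpha = 1, beta = 0.15,
                          I0 = 255) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == 3L, ncol(M) == 2L, all(M >= -1e-9),
            length(max_concentration) == 2L, all(max_concentration > 0))
  M[M < 0] <- 0
  M <- sweep(M, 2L, sqrt(colSums(M^2)), "/")
  structure(list(M = unname(M),
                 max_concentration = unname(as.numeric(max_concentration)),
                 alpha = alpha, beta = beta, I0 = I0),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("Stain profile (Macenko)\n")
  m <- x$M
  dimnames(m) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  print(round(m, 4))
  cat("max concentrations:", paste(signif(x$max_concentration, 5),
                                   collapse = ", "),
      "\nalpha =", x$alpha, " beta =", x$beta, " I0 =", x$I0, "\n")
  invisible(x)
}

# Flatten an RGB array into an n x 3 OD matrix.
.od_matrix <- function(image, I0) {
  od <- rgb_to_od(image, I0)
  cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
}

# Achromatic exposure offset of an image: a global exposure change adds an
# equal-channel OD shift, visible on unstained glass. Estimated as the
# minimum channel of the median OD over transparent pixels (max-channel OD
# <= beta); zero when the image shows no glass, so fully stained fields are
# never "corrected" with tissue OD.
.gray_offset <- function(X, beta) {
  trans <- pmax(X[, 1], X[, 2], X[, 3]) <= beta
  if (sum(trans) < 100L) return(0)
  max(0, min(apply(X[trans, , drop = FALSE], 2L, stats::median)))
}

# Nonnegative concentration solve: least-squares through the stain matrix,
# then projection onto the nonnegative orthant.
.stain_concentrations <- function(M, od_pixels) {
  C <- solve(crossprod(M), crossprod(M, t(od_pixels)))   # 2 x n
  C[C < 0] <- 0
  C
}

#' Estimate the Macenko stain profile of an image
#'
#' Tissue pixels (max-channel OD above `beta`) are projected onto the plane of
#' the two leading singular directions of their OD cloud; the `alpha`-th and
#' `(100 - alpha)`-th percentile angles in that plane define the two stain
#' vectors. The hematoxylin column is the vector with the larger blue-channel
#' OD component. Reference concentrations are the per-stain 99th percentiles
#' of the nonnegative concentration solve.
#'
#' @inheritParams rgb_to_od
#' @param alpha Robust percentile (degrees of trimming) for the extreme
#'   angles; default 1.
#' @param beta OD threshold below which a pixel counts as transparent
#'   (default 0.15).
#' @return A [stain_profile()].
#' @export
estimate_stain_profile <- function(image, alpha = 1, beta = 0.15, I0 = 255) {
  X <- .od_matrix(image, I0)
  # luminosity standardization: remove the achromatic exposure offset so the
  # estimated stain directions are invariant to global intensity scaling
  off <- .gray_offset(X, beta)
  if (off > 0) {
    X <- X - off
    X[X < 0] <- 0
  }
  keep <- pmax(X[, 1], X[, 2], X[, 3]) > beta
  if (sum(keep) < 100L) {
    stop("insufficient stained pixels (", sum(keep),
         " with OD > beta = ", beta, ")", call. = FALSE)
  }
  X <- X[keep, , drop = FALSE]
  sv <- svd(X, nu = 0, nv = 2)
  if (sv$d[2] < 1e-3 * sv$d[1]) {
    stop("degenerate stain geometry: OD cloud has a single stain direction",
         call. = FALSE)
  }
  V <- sv$v                       # 3 x 2 basis of the stain plane
  # orient the basis so projections fall in a consistent half-plane
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  P <- X %*% V                    # n x 2 plane coordinates
  phi <- atan2(P[, 2], P[, 1])
  lo <- stats::quantile(phi, alpha / 100, names = FALSE)
  hi <- stats::quantile(phi, 1 - alpha / 100, names = FALSE)
  if ((hi - lo) < 2 * pi / 180) {
    stop("degenerate stain geometry: stain angle spread below 2 degrees",
         call. = FALSE)
  }
  v1 <- V %*% c(cos(lo), sin(lo))
  v2 <- V %*% c(cos(hi), sin(hi))
  fix <- function(v) { if (sum(v) < 0) v <- -v; v[v < 0] <- 0; v / sqrt(sum(v^2)) }
  v1 <- fix(v1); v2 <- fix(v2)
  # hematoxylin = larger blue-channel OD component
  M <- if (v1[3] >= v2[3]) cbind(v1, v2) else cbind(v2, v1)
  C <- .stain_concentrations(M, X)
  maxc <- apply(C, 1L, stats::quantile, probs = 0.99, names = FALSE)
  maxc[maxc <= 0] <- 1e-6
  stain_profile(M, maxc, alpha = alpha, beta = beta, I0 = I0)
}

#' Macenko-normalize an RGB image to a target stain profile
#'
#' Concentrations under the source profile are rescaled per stain by
#' `target$max_concentration / source$max_concentration` and reconstructed
#' through the target stain matrix. Pure-white (zero-OD) pixels have zero
#' concentration and stay white.
#'
#' @param image RGB array (`H x W x 3`), intensities in `[0, I0]`.
#' @param target Reference [stain_profile()]; defaults to the bundled profile
#'   from [default_stain_profile()].
#' @param source Optional source profile; estimated from `image` when `NULL`.
#' @return Normalized RGB array of the same shape, integer values in
#'   `[0, I0]`.
#' @export
normalize_stains <- function(image, target = default_stain_profile(),
                             source = NULL) {
  stopifnot(inherits(target, "stain_profile"))
  if (is.null(source)) {
    source <- estimate_stain_profile(image, alpha = target$alpha,
                                     beta = target$beta, I0 = target$I0)
  }
  stopifnot(inherits(source, "stain_profile"))
  H <- dim(image)[1]; W <- dim(image)[2]
  X <- .od_matrix(image, target$I0)
  # same exposure correction as the estimator, so the concentration solve and
  # the profile refer to the same frame (and normalization is idempotent)
  off <- .gray_offset(X, target$beta)
  if (off > 0) {
    X <- X - off
    X[X < 0] <- 0
  }
  C <- .stain_concentrations(source$M, X)
  C <- C * (target$max_concentration / source$max_concentration)
  od2 <- t(target$M %*% C)
  out <- od_to_rgb(as.vector(od2), target$I0)
  out <- trunc(out + 0.5)
  storage.mode(out) <- "integer"
  dim(out) <- c(H, W, 3L)
  out
}

#' The bundled reference stain profile
#'
#' A fixed Macenko profile, estimated once from a bundled synthetic reference
#' patch and frozen as JSON, so normalization is reproducible without any
#' external data.
#'
#' @return A [stain_profile()].
#' @export
default_stain_profile <- function() {
  path <- system.file("extdata", "default_stain_profile.json",
                      package = "deepstroma")
  if (path == "") {  # during development, before installation
    path <- file.path("inst", "extdata", "default_stain_profile.json")
  }
  read_stain_profile(path)
}

#' Read / write a stain profile as JSON
#'
#' @param path File path.
#' @return `read_stain_profile()` returns a [stain_profile()];
#'   `write_stain_profile()` returns `path` invisibly.
#' @export
read_stain_profile <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- if (is.list(j$M)) do.call(rbind, j$M) else as.matrix(j$M)
  stain_profile(M, j$maxC, alpha = j$alpha, beta = j$beta, I0 = j$I0)
}

#' @rdname read_stain_profile
#' @param profile A [stain_profile()].
#' @export
write_stain_profile <- function(profile, path) {
  stopifnot(inherits(profile, "stain_profile"))
  j <- list(M = apply(profile$M, 1L, as.list),
            maxC = profile$max_concentration,
            alpha = profile$alpha, beta = profile$beta, I0 = profile$I0)
  j$M <- lapply(seq_len(3), function(i) as.numeric(profile$M[i, ]))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
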