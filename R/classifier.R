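# Nine-class tissue-texture classifier.
#
# The desk-scale classifier is a texture-feature extractor followed by a small
# single-hidden-layer softmax network trained with mini-batch stochastic
# gradient descent with momentum. Features are hand-designed per-patch texture
# statistics (intensity moments, thresholded fractions, gradient energy,
# multi-scale contrast, chroma, and lagged autocorrelations) that mirror the
# scalar statistics separating the nine procedural archetypes; the network
# output is a softmax activation vector, one probability per tissue class.

#' Training configuration for the tissue classifier
#'
#' @param split Train/validation/test fractions; positive, summing to 1.
#' @param batch_size Mini-batch size for stochastic gradient descent.
#' @param learn_rate Learning rate.
#' @param epochs Number of passes over the training set.
#' @param flip_horizontal,flip_vertical Augment the training set with
#'   mirrored copies (rotational invariance through flips).
#' @param mixtures Mixture-augmentation ratio: this many two-class composite
#'   patches with soft area-fraction targets are added per original training
#'   patch, so softmax activations respond compositionally on mixed tiles
#'   (0 disables).
#' @param hidden Hidden-layer width of the softmax network.
#' @param momentum SGD momentum coefficient.
#' @param seed Integer seed controlling the split, initialisation, and batch
#'   order.
#' @return An object of class `training_config`.
#' @export
training_config <- function(split = c(0.70, 0.15, 0.15), batch_size = 32L,
                            learn_rate = 0.05, epochs = 40L,
                            flip_horizontal = TRUE, flip_vertical = TRUE,
                            mixtures = 1, hidden = 32L, momentum = 0.9,
                            seed = 1L) {
  stopifnot(length(split) == 3L, all(split > 0), abs(sum(split) - 1) < 1e-6,
            batch_size >= 1L, learn_rate > 0, epochs >= 1L, hidden >= 2L,
            momentum >= 0, momentum < 1, mixtures >= 0)
  structure(list(split = split, batch_size = as.integer(batch_size),
                 learn_rate = learn_rate, epochs = as.integer(epochs),
                 flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical),
                 mixtures = mixtures,
                 hidden = as.integer(hidden), momentum = momentum,
                 seed = as.integer(seed)),
            class = "training_config")
}

# ---- feature extraction -----------------------------------------------------

# Nearest-neighbour resize to size x size (contract: any patch is resizable
# to the network's input geometry).
resize_patch <- function(img, size = 224L) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("corrupt image: expected an H x W x 3 array", call. = FALSE)
  }
  if (d[1] == size && d[2] == size) return(img)
  ri <- ceiling(seq_len(size) * d[1] / size)
  ci <- ceiling(seq_len(size) * d[2] / size)
  img[ri, ci, , drop = FALSE]
}

#' Texture feature vector of a patch
#'
#' The fixed 19-dimensional per-patch texture summary feeding the classifier:
#' per-channel means and standard deviations, dark/mid/white pixel fractions,
#' horizontal and vertical gradient energy and edge density, high- and
#' low-frequency contrast, blue-chroma mean, near-white block fraction, and
#' gray-level autocorrelations at lags 3, 8, and 16 px.
#'
#' @param img RGB array (`H x W x 3`), intensities in `[0, 255]`.
#' @return Named numeric vector of length 19.
#' @export
patch_features <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || any(!is.finite(img))) {
    stop("corrupt image: expected a finite H x W x 3 array", call. = FALSE)
  }
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  g <- (R + G + B) / 3
  H <- nrow(g); W <- ncol(g)
  dx <- abs(g[, -1, drop = FALSE] - g[, -W, drop = FALSE])
  dy <- abs(g[-1, , drop = FALSE] - g[-H, , drop = FALSE])
  b5 <- box_blur(g, 5L)
  b15 <- box_blur(g, 15L)
  rows <- seq(1L, H, by = 2L)   # a row-subsample is ample for autocorrelation
  lag_cor <- function(k) {
    if (W <= k + 1L) return(0)
    a <- as.vector(g[rows, seq_len(W - k)])
    b <- as.vector(g[rows, (k + 1L):W])
    if (stats::sd(a) < 1e-9 || stats::sd(b) < 1e-9) return(0)
    stats::cor(a, b)
  }
  mdx <- mean(dx); mdy <- mean(dy)
  c(mean_r = mean(R), mean_g = mean(G), mean_b = mean(B),
    sd_r = stats::sd(R), sd_g = stats::sd(G), sd_b = stats::sd(B),
    frac_dark = mean(g < 100), frac_mid = mean(g < 180),
    frac_white = mean(g > 230),
    grad_x = mdx, grad_y = mdy,
    edge_density = (mean(dx > 25) + mean(dy > 25)) / 2,
    hf_energy = mean((g - b5)^2), lf_contrast = stats::sd(b15),
    anisotropy = abs(mdx - mdy) / (mdx + mdy + 1e-9),
    blue_chroma = mean(B / (R + G + B + 1)),
    white_blocks = mean(b15 > 235),
    acor3 = lag_cor(3L), acor8 = lag_cor(8L), acor16 = lag_cor(16L))[1:19]
}

.flip_h <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
.flip_v <- function(img) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]

.feature_matrix <- function(patches) {
  t(vapply(patches, patch_features, numeric(19)))
}

# ---- dataset splitting ------------------------------------------------------

#' Stratified train/validation/test split
#'
#' Splits patch indices by class into train/validation/test sets with the
#' given fractions (70/15/15 by default), deterministically under `seed`.
#'
#' @param labels Character vector of class labels, one per patch.
#' @param split Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `validation`, `test`;
#'   disjoint, with union `seq_along(labels)`.
#' @export
split_dataset <- function(labels, split = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(split) == 3L)
  if (any(split <= 0) || abs(sum(split) - 1) > 1e-6) {
    stop("split fractions must be positive and sum to 1", call. = FALSE)
  }
  tab <- table(labels)
  if (any(tab < 3L)) {
    stop("every class needs at least 3 patches; deficient: ",
         paste(names(tab)[tab < 3L], collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    out <- list(train = integer(0), validation = integer(0), test = integer(0))
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      n_tr <- round(n * split[1])
      n_va <- round(n * split[2])
      n_tr <- min(n_tr, n - 2L)         # keep every set nonempty per class
      n_va <- max(1L, min(n_va, n - n_tr - 1L))
      out$train <- c(out$train, idx[seq_len(n_tr)])
      out$validation <- c(out$validation, idx[n_tr + seq_len(n_va)])
      out$test <- c(out$test, idx[(n_tr + n_va + 1L):n])
    }
    lapply(out, sort)
  })
}

# ---- the softmax network ----------------------------------------------------

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.forward <- function(w, X) {
  Hh <- tanh(sweep(X %*% w$W1, 2L, w$b1, "+"))
  list(H = Hh, P = .softmax(sweep(Hh %*% w$W2, 2L, w$b2, "+")))
}

.xent <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))

#' Train the nine-class tissue classifier
#'
#' Extracts texture features, optionally augments the training set with
#' horizontal/vertical mirror copies, and trains a single-hidden-layer softmax
#' network by mini-batch stochastic gradient descent with momentum. The
#' per-epoch training loss and validation accuracy (including epoch 0, the
#' untrained network) are kept in the returned object's `log`.
#'
#' @param patches List of RGB patch arrays (training set).
#' @param labels Character class labels, one per patch.
#' @param val_patches,val_labels Optional validation set monitored during
#'   training (defaults to the training set when absent).
#' @param config A [training_config()].
#' @return An object of class `tissue_classifier`.
#' @export
train_tissue_classifier <- function(patches, labels,
                                    val_patches = NULL, val_labels = NULL,
                                    config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  if (length(patches) == 0L) stop("empty training set", call. = FALSE)
  if (length(patches) != length(labels)) stop("patches/labels length mismatch")
  classes <- tissue_classes()
  if (!all(labels %in% classes)) {
    stop("unknown labels: ", paste(setdiff(labels, classes), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("degenerate label space: training needs at least 2 classes",
         call. = FALSE)
  }

  # features of each patch and (when flips are on) of its mirror images,
  # computed patch by patch so the augmented set is never materialised
  n_aug <- 1L + config$flip_horizontal + config$flip_vertical
  X <- matrix(0, length(patches) * n_aug, 19L)
  aug_labels <- character(nrow(X))
  row <- 0L
  for (i in seq_along(patches)) {
    x <- resize_patch(patches[[i]])
    vars <- list(x)
    if (config$flip_horizontal) vars <- c(vars, list(.flip_h(x)))
    if (config$flip_vertical) vars <- c(vars, list(.flip_v(x)))
    for (v in vars) {
      row <- row + 1L
      X[row, ] <- patch_features(v)
      aug_labels[row] <- labels[i]
    }
  }
  k <- length(classes)
  Y <- matrix(0, nrow(X), k)
  Y[cbind(seq_len(nrow(X)), match(aug_labels, classes))] <- 1

  # mixture augmentation: composite two-class patches with soft (area
  # fraction) targets teach the softmax to respond compositionally on the
  # mixed tiles a sliding window inevitably produces at block borders
  n_mix <- round(config$mixtures * length(patches))
  if (n_mix > 0L && length(unique(labels)) >= 2L) {
    mix <- with_seed(config$seed + 1L, {
      Xm <- matrix(0, n_mix, ncol(X))
      Ym <- matrix(0, n_mix, k)
      for (j in seq_len(n_mix)) {
        ia <- sample.int(length(patches), 1L)
        ib <- sample(which(labels != labels[ia]), 1L)
        a <- resize_patch(patches[[ia]])
        b <- resize_patch(patches[[ib]])
        cut <- sample(68:156, 1L)          # split fraction ~ U(0.3, 0.7)
        comp <- a
        if (stats::runif(1) < 0.5) {
          comp[, (cut + 1L):224L, ] <- b[, (cut + 1L):224L, ]
        } else {
          comp[(cut + 1L):224L, , ] <- b[(cut + 1L):224L, , ]
        }
        f <- cut / 224
        Xm[j, ] <- patch_features(comp)
        Ym[j, match(labels[ia], classes)] <- f
        Ym[j, match(labels[ib], classes)] <- 1 - f
      }
      list(X = Xm, Y = Ym)
    })
    X <- rbind(X, mix$X)
    Y <- rbind(Y, mix$Y)
  }

  mu <- colMeans(X)
  sg <- apply(X, 2L, stats::sd)
  sg[sg < 1e-9] <- 1
  X <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
  n <- nrow(X); d <- ncol(X)

  if (is.null(val_patches)) {
    Xv <- X; yv <- max.col(Y, ties.method = "first")
  } else {
    Xv <- .feature_matrix(lapply(val_patches, resize_patch))
    Xv <- sweep(sweep(Xv, 2L, mu), 2L, sg, "/")
    yv <- match(val_labels, classes)
  }

  with_seed(config$seed, {
    h <- config$hidden
    w <- list(W1 = matrix(stats::rnorm(d * h, sd = 0.3), d, h),
              b1 = numeric(h),
              W2 = matrix(stats::rnorm(h * k, sd = 0.3), h, k),
              b2 = numeric(k))
    v <- lapply(w, function(z) z * 0)
    val_acc <- function() mean(max.col(.forward(w, Xv)$P) == yv)
    log <- data.frame(epoch = 0L, loss = .xent(.forward(w, X)$P, Y),
                      val_accuracy = val_acc())
    lr <- config$learn_rate; mom <- config$momentum
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[bi, , drop = FALSE]; Yb <- Y[bi, , drop = FALSE]
        fw <- .forward(w, Xb)
        dZ2 <- (fw$P - Yb) / length(bi)
        gW2 <- crossprod(fw$H, dZ2); gb2 <- colSums(dZ2)
        dH <- tcrossprod(dZ2, w$W2) * (1 - fw$H^2)
        gW1 <- crossprod(Xb, dH); gb1 <- colSums(dH)
        g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        for (nm in names(w)) {
          v[[nm]] <- mom * v[[nm]] - lr * g[[nm]]
          w[[nm]] <- w[[nm]] + v[[nm]]
        }
      }
      log <- rbind(log, data.frame(epoch = ep,
                                   loss = .xent(.forward(w, X)$P, Y),
                                   val_accuracy = val_acc()))
    }
    structure(list(weights = w, feature_center = mu, feature_scale = sg,
                   classes = classes, config = config, log = log),
              class = "tissue_classifier")
  })
}

#' @export
print.tissue_classifier <- function(x, ...) {
  fin <- x$log[nrow(x$log), ]
  cat("Nine-class tissue texture classifier\n",
      "hidden units: ", x$config$hidden,
      ", epochs: ", fin$epoch,
      ", final training loss: ", signif(fin$loss, 4),
      ", validation accuracy: ", signif(fin$val_accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' Softmax activation vector(s) for patches
#'
#' @param object A trained [train_tissue_classifier()] model.
#' @param newdata One RGB patch array, or a list of them.
#' @param ... Unused.
#' @return For one patch, a named numeric activation vector over the nine
#'   classes (sums to 1); for a list, a matrix with one row per patch.
#' @export
predict.tissue_classifier <- function(object, newdata, ...) {
  single <- !is.list(newdata)
  patches <- if (single) list(newdata) else newdata
  X <- .feature_matrix(lapply(patches, resize_patch))
  X <- sweep(sweep(X, 2L, object$feature_center), 2L, object$feature_scale, "/")
  P <- .forward(object$weights, X)$P
  colnames(P) <- object$classes
  if (single) P[1, ] else P
}

# ---- evaluation -------------------------------------------------------------

#' Confusion matrix over a fixed class order
#'
#' @param truth,prediction Character vectors of true and predicted labels.
#' @param classes Class order (defaults to the nine tissue classes).
#' @return Square integer count matrix, rows = true class, columns = predicted
#'   class, with `accuracy = trace / total` in attribute `"accuracy"`.
#' @export
confusion_matrix <- function(truth, prediction, classes = tissue_classes()) {
  stopifnot(length(truth) == length(prediction))
  if (anyNA(truth)) stop("unlabeled patch present in evaluation set",
                         call. = FALSE)
  cm <- table(factor(truth, levels = classes),
              factor(prediction, levels = classes))
  cm <- unclass(matrix(as.integer(cm), nrow(cm), ncol(cm),
                       dimnames = dimnames(cm)))
  attr(cm, "accuracy") <- sum(diag(cm)) / max(1L, sum(cm))
  cm
}

#' Evaluate a classifier on a labeled patch set
#'
#' @param model A trained classifier.
#' @param patches List of RGB patch arrays.
#' @param labels True class labels (no missing values).
#' @return List with `confusion` (9 x 9 count matrix) and `accuracy`.
#' @export
evaluate_classifier <- function(model, patches, labels) {
  if (length(patches) == 0L) stop("empty evaluation set", call. = FALSE)
  if (anyNA(labels)) stop("unlabeled patch present in evaluation set",
                          call. = FALSE)
  P <- predict(model, patches)
  pred <- model$classes[max.col(P, ties.method = "first")]
  cm <- confusion_matrix(labels, pred, model$classes)
  list(confusion = cm, accuracy = attr(cm, "accuracy"))
}

#' Per-class ROC statistics over k random subsets
#'
#' Splits the labeled set into `k` random class-stratified subsets, applies
#' the classifier to each, and summarises per-class one-vs-rest AUC (from the
#' class's softmax activation; trapezoidal area), sensitivity, specificity,
#' PPV, and NPV (from argmax predictions) as the median with the 5th and 95th
#' percentiles across subsets.
#'
#' @param model A trained classifier.
#' @param patches List of RGB patch arrays.
#' @param labels True class labels.
#' @param k Number of subsets (default 25).
#' @param seed Integer seed for the split.
#' @return List with `per_class` (data frame of median / q05 / q95 per metric
#'   and class) and `accuracy` (overall argmax accuracy on the full set).
#' @export
kfold_roc_stats <- function(model, patches, labels, k = 25L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("every class needs at least k = ", k, " examples; deficient: ",
         paste(names(tab)[tab < k], collapse = ", "), call. = FALSE)
  }
  P <- predict(model, patches)
  pred <- model$classes[max.col(P, ties.method = "first")]
  fold <- with_seed(seed, {
    f <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  metrics <- c("auc", "sensitivity", "specificity", "ppv", "npv")
  res <- array(NA_real_, dim = c(length(model$classes), k, length(metrics)),
               dimnames = list(model$classes, NULL, metrics))
  for (s in seq_len(k)) {
    sel <- fold == s
    tru <- labels[sel]; prd <- pred[sel]; act <- P[sel, , drop = FALSE]
    for (ci in seq_along(model$classes)) {
      cl <- model$classes[ci]
      pos <- tru == cl; ppos <- prd == cl
      tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
      fp <- sum(!pos & ppos); tn <- sum(!pos & !ppos)
      res[ci, s, "auc"] <- auc_rank(act[, ci], pos)
      res[ci, s, "sensitivity"] <- if (tp + fn > 0) tp / (tp + fn) else NA
      res[ci, s, "specificity"] <- if (tn + fp > 0) tn / (tn + fp) else NA
      res[ci, s, "ppv"] <- if (tp + fp > 0) tp / (tp + fp) else NA
      res[ci, s, "npv"] <- if (tn + fn > 0) tn / (tn + fn) else NA
    }
  }
  per_class <- do.call(rbind, lapply(seq_along(model$classes), function(ci) {
    row <- data.frame(class = model$classes[ci])
    for (m in metrics) {
      q <- stats::quantile(res[ci, , m], c(0.5, 0.05, 0.95), na.rm = TRUE,
                           names = FALSE)
      row[[paste0(m, "_median")]] <- q[1]
      row[[paste0(m, "_q05")]] <- q[2]
      row[[paste0(m, "_q95")]] <- q[3]
    }
    row
  }))
  list(per_class = per_class, accuracy = mean(pred == labels))
}

# ---- persistence ------------------------------------------------------------

#' Save / load a trained classifier
#'
#' The model weights go to a binary `.rds` file with a JSON sidecar recording
#' the class order and feature standardisation.
#'
#' @param model A trained classifier.
#' @param path Path to the `.rds` file (sidecar written alongside).
#' @return `save_classifier()` returns `path` invisibly; `load_classifier()`
#'   returns the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "tissue_classifier"))
  saveRDS(model, path)
  sidecar <- list(classes = model$classes,
                  feature_center = model$feature_center,
                  feature_scale = model$feature_scale,
                  input_size = 224L)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "tissue_classifier"))
  model
}
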