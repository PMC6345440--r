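# Shared fixtures, built lazily and memoized for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small labeled patch set: 24 patches per class.
fixture_patch_set <- function() {
  .memo("patch_set", function() {
    patches <- list()
    labels <- character(0)
    for (cl in tissue_classes()) {
      for (i in 1:24) {
        patches[[length(patches) + 1L]] <- generate_patch(
          cl, texture_params(seed = 500L + i))
        labels <- c(labels, cl)
      }
    }
    list(patches = patches, labels = labels)
  })
}

# A classifier trained on the small patch set (held-out indices kept).
fixture_model <- function() {
  .memo("model", function() {
    ds <- fixture_patch_set()
    sp <- split_dataset(ds$labels, seed = 7L)
    model <- train_tissue_classifier(
      ds$patches[sp$train], ds$labels[sp$train],
      ds$patches[sp$validation], ds$labels[sp$validation],
      training_config(epochs = 20L, seed = 7L))
    list(model = model, split = sp, data = ds)
  })
}

# Cohort with planted positive effects on DEB and MUS and protective effects
# on MUC and TUM.
fixture_planted_cohort <- function(n = 1000L, seed = 21L) {
  b <- stats::setNames(numeric(9), tissue_classes())
  b["DEB"] <- log(4); b["MUS"] <- log(3)
  b["MUC"] <- -1; b["TUM"] <- -0.7
  generate_cohort(cohort_config(n = n, beta = b, h0 = 0.05, seed = seed))
}

# Brute-force Youden maximiser used as the independent oracle: evaluates
# every midpoint candidate by direct counting, with the stated tie-breaks.
oracle_youden <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  u <- sort(unique(values))
  cand <- (u[-1] + u[-length(u)]) / 2
  best_j <- -Inf
  best <- c()
  for (tau in cand) {
    sens <- sum(values > tau & labels == 1) / sum(labels == 1)
    spec <- sum(values <= tau & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best <- tau
    } else if (j >= best_j - 1e-12) {
      best <- c(best, tau)
    }
  }
  if (length(best) > 1) {
    d <- abs(best - stats::median(values))
    best <- best[d <= min(d) + 1e-12]
    best <- min(best)
  }
  best
}
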