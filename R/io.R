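# Readers, writers, and the end-to-end pipeline runner.

#' Write a patch image as PNG
#'
#' @param img RGB array with intensities in `[0, 255]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patch_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a patch image from PNG
#'
#' @param path PNG file path.
#' @return RGB array with intensities in `[0, 255]` (grayscale images are
#'   expanded to three channels; any alpha channel is dropped).
#' @export
read_patch_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' Write a labeled patch set as class-named PNG folders
#'
#' Mirrors the deposited-archive layout: `<root>/<CLASS_CODE>/<name>.png`.
#'
#' @param patches List of RGB arrays.
#' @param labels Class codes, one per patch.
#' @param root Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_patch_dataset <- function(patches, labels, root) {
  stopifnot(length(patches) == length(labels), all(labels %in% tissue_classes()))
  paths <- character(length(patches))
  counter <- stats::setNames(integer(length(tissue_classes())), tissue_classes())
  for (i in seq_along(patches)) {
    cl <- labels[i]
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
    counter[cl] <- counter[cl] + 1L
    paths[i] <- file.path(root, cl, sprintf("%s_%05d.png", cl, counter[cl]))
    write_patch_png(patches[[i]], paths[i])
  }
  invisible(paths)
}

#' Read a class-foldered patch dataset
#'
#' Every image is labeled by its directory name; directories must be named
#' with the nine class codes. Non-image files are skipped with a warning, as
#' are empty class directories.
#'
#' @param root Dataset root containing class-named subdirectories.
#' @return List with `patches` (list of RGB arrays), `labels`, and `counts`
#'   (per-class table).
#' @export
read_patch_dataset <- function(root) {
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  codes <- tissue_classes()
  bad <- setdiff(dirs, codes)
  if (length(bad) > 0L) {
    stop("unknown class directory '", bad[1], "'; valid codes are: ",
         paste(codes, collapse = ", "), call. = FALSE)
  }
  patches <- list(); labels <- character(0)
  counts <- stats::setNames(integer(length(codes)), codes)
  for (cl in intersect(codes, dirs)) {
    files <- list.files(file.path(root, cl), full.names = TRUE)
    is_png <- grepl("\\.png$", files, ignore.case = TRUE)
    if (any(!is_png)) {
      warning(sum(!is_png), " non-image file(s) skipped in ", cl,
              call. = FALSE)
    }
    files <- files[is_png]
    if (length(files) == 0L) {
      warning("class directory ", cl, " contains no images", call. = FALSE)
      next
    }
    for (f in files) {
      patches[[length(patches) + 1L]] <- read_patch_png(f)
      labels <- c(labels, cl)
    }
    counts[cl] <- length(files)
  }
  list(patches = patches, labels = labels, counts = counts)
}

#' Read a clinical table
#'
#' Requires columns `patient_id`, `stage`, `sex`, `age`, `time_OS`,
#' `event_OS`; optional further endpoints (`DSS`, `RFS`), `caf_score`, and
#' `path_stroma_pct` are kept when present. Rows with missing required
#' endpoint data are dropped and counted (no imputation), the count being
#' attached as attribute `"dropped_missing"`.
#'
#' @param path CSV file path.
#' @return Data frame of typed patient records.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "stage", "sex", "age", "time_OS", "event_OS")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!df$stage %in% 1:4)) stop("stage out of range (must be 1-4)",
                                    call. = FALSE)
  if (any(!df$event_OS %in% c(0, 1, NA))) stop("event_OS must be 0/1",
                                               call. = FALSE)
  keep <- stats::complete.cases(df$time_OS, df$event_OS)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(dropped, " row(s) dropped for missing OS endpoint data")
  }
  df <- df[keep, , drop = FALSE]
  attr(df, "dropped_missing") <- dropped
  df
}

# ---- the pipeline runner ----------------------------------------------------

#' Configuration for the end-to-end demo pipeline
#'
#' Desk-scale defaults: 40 patches per class, a 120-patient planted-effect
#' cohort, and a handful of demonstration regions.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Global seed; every stochastic stage derives from it.
#' @param patches_per_class Patches synthesised per class for training.
#' @param cohort_n Patients in the demo cohort.
#' @param n_regions Demonstration regions to decompose.
#' @param normalize Macenko-normalize patches before training.
#' @param epochs Training epochs.
#' @param stages Stages to run, in order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("deepstroma_run_"),
                            seed = 1L,
                            patches_per_class = 40L,
                            cohort_n = 120L,
                            n_regions = 4L,
                            normalize = FALSE,
                            epochs = 25L,
                            stages = c("synthesize", "train", "evaluate",
                                       "decompose", "score", "report")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 patches_per_class = as.integer(patches_per_class),
                 cohort_n = as.integer(cohort_n),
                 n_regions = as.integer(n_regions),
                 normalize = isTRUE(normalize),
                 epochs = as.integer(epochs), stages = stages),
            class = "pipeline_config")
}

#' Run the end-to-end synthetic pipeline
#'
#' Synthesize patches and a planted-effect cohort, train and evaluate the
#' classifier, decompose demonstration regions, build and freeze a score
#' model, and write a survival report. Identical configuration and seed
#' reproduce bit-identical score JSON and group labels.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the artifact manifest: data frame of output files with
#'   their MD5 hashes.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, code) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    note("stage ", name, " started")
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  params <- texture_params(seed = cfg$seed)
  patches <- NULL; labels <- NULL; model <- NULL; cohort <- NULL

  stage("synthesize", {
    classes <- tissue_classes()
    patches <- list(); labels <- character(0)
    for (cl in classes) {
      for (i in seq_len(cfg$patches_per_class)) {
        patches[[length(patches) + 1L]] <-
          generate_patch(cl, texture_params(seed = cfg$seed * 1000L + i))
        labels <- c(labels, cl)
      }
    }
    b <- stats::setNames(numeric(9), classes)
    b["DEB"] <- log(3); b["MUS"] <- log(2)
    cohort <- generate_cohort(cohort_config(
      n = cfg$cohort_n, beta = b, h0 = 0.05, seed = cfg$seed + 7L))
    utils::write.csv(cohort, file.path(cfg$out_dir, "cohort.csv"),
                     row.names = FALSE)
    note("synthesized ", length(patches), " patches, cohort n = ",
         nrow(cohort))
  })

  if (cfg$normalize && "synthesize" %in% cfg$stages) {
    target <- default_stain_profile()
    skipped <- 0L
    patches <- lapply(patches, function(x) {
      tryCatch(normalize_stains(x, target), error = function(e) {
        skipped <<- skipped + 1L
        x   # background-only tiles carry no stain to estimate; pass through
      })
    })
    note("normalized patches (", skipped, " passed through unchanged)")
  }

  sp <- NULL
  stage("train", {
    sp <- split_dataset(labels, seed = cfg$seed)
    model <- train_tissue_classifier(
      patches[sp$train], labels[sp$train],
      patches[sp$validation], labels[sp$validation],
      training_config(epochs = cfg$epochs, seed = cfg$seed))
    save_classifier(model, file.path(cfg$out_dir, "classifier.rds"))
    utils::write.csv(model$log, file.path(cfg$out_dir, "training_log.csv"),
                     row.names = FALSE)
    note("trained classifier, final val accuracy ",
         signif(model$log$val_accuracy[nrow(model$log)], 4))
  })

  stage("evaluate", {
    ev <- evaluate_classifier(model, patches[sp$test], labels[sp$test])
    utils::write.csv(as.data.frame(ev$confusion),
                     file.path(cfg$out_dir, "confusion.csv"))
    jsonlite::write_json(list(accuracy = ev$accuracy),
                         file.path(cfg$out_dir, "test_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    note("test accuracy ", signif(ev$accuracy, 4))
  })

  stage("decompose", {
    rows <- list()
    for (i in seq_len(cfg$n_regions)) {
      comp <- with_seed(cfg$seed * 100L + i,
                        .rdirichlet(1, rep(0.5, 9))[1, ])
      names(comp) <- tissue_classes()
      reg <- generate_region(comp,
                             texture_params(seed = cfg$seed * 100L + i))
      act <- region_activation(model, reg$image)
      rows[[i]] <- data.frame(region_id = i, t(act),
                              t(stats::setNames(as.numeric(
                                table(factor(reg$mask, levels = 1:9)) /
                                  length(reg$mask)),
                                paste0("true_", tissue_classes()))))
    }
    acts <- do.call(rbind, rows)
    utils::write.csv(acts, file.path(cfg$out_dir, "region_activations.csv"),
                     row.names = FALSE)
    note("decomposed ", cfg$n_regions, " regions")
  })

  sm <- NULL
  stage("score", {
    sm <- build_score_model(cohort, endpoint = "OS")
    write_score_model(sm, file.path(cfg$out_dir, "score_model.json"))
    grp <- dichotomize(sm, compute_score(sm, cohort))
    utils::write.csv(data.frame(patient_id = cohort$patient_id,
                                score = compute_score(sm, cohort),
                                group = grp),
                     file.path(cfg$out_dir, "scores.csv"), row.names = FALSE)
    note("score model built; median split ", signif(sm$median, 5))
  })

  stage("report", {
    grp <- dichotomize(sm, compute_score(sm, cohort))
    mv <- multivariable_cox(cohort, grp, "OS")
    ps <- per_stage_models(cohort, grp, "OS")
    report <- list(
      multivariable = mv,
      per_stage = lapply(ps, function(x) if (is.character(x)) x else x),
      n = attr(mv, "n"), events = attr(mv, "events"))
    jsonlite::write_json(report, file.path(cfg$out_dir, "survival_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    note("survival report written")
  })

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  # the timestamped log is not a data artifact; keep the manifest
  # reproducible for identical config + seed
  files <- setdiff(list.files(cfg$out_dir, recursive = TRUE),
                   c("manifest.csv", "run_log.txt"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))))
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  note("pipeline finished in ",
       round(as.numeric(difftime(Sys.time(), t_start, units = "secs")), 1),
       " s")
  invisible(manifest)
}
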