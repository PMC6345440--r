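# The deep stroma score.
#
# Construction, on a training cohort with per-patient pooled activation
# vectors and survival endpoints:
#   1. one univariable Cox proportional-hazards fit per tissue class
#      (continuous, nonthresholded activation) -> hazard ratio HR_c;
#   2. one Youden-optimal ROC cutoff tau_c per class, against the endpoint's
#      event indicator;
#   3. the score of a patient is S = sum over classes with HR_c > 1 of
#      HR_c * 1[a_c > tau_c] (an HR-weighted count of above-threshold
#      nontumour components);
#   4. patients are stratified high/low at the training-cohort median score,
#      and that median is frozen for any validation cohort.

# ---- elementary fits --------------------------------------------------------

#' Univariable Cox hazard ratio for one continuous predictor
#'
#' @param x Numeric covariate (e.g. one class's pooled activation).
#' @param time,event Survival time and event indicator (1 = event).
#' @return Hazard ratio per unit of `x` (Efron ties).
#' @export
univariable_hr <- function(x, time, event) {
  keep <- stats::complete.cases(x, time, event)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  if (sum(event) == 0) stop("no events: hazard ratio not estimable",
                            call. = FALSE)
  if (stats::sd(x) < 1e-12) stop("non-identifiable: constant covariate",
                                 call. = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  unname(exp(stats::coef(fit)))
}

#' Youden-index optimal cutoff
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' values; "positive" means `value > tau`. The returned cutoff maximises the
#' Youden index J = sensitivity + specificity - 1; ties are broken by
#' proximity to the median of `values`, remaining ties by the smaller cutoff.
#'
#' @param values Numeric predictor values.
#' @param labels Binary labels (0/1 or logical), both present.
#' @return The optimal cutoff tau, with the achieved index in attribute
#'   `"youden"`.
#' @export
youden_cutoff <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  keep <- stats::complete.cases(values, labels)
  values <- values[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L) {
    stop("both label classes must be present", call. = FALSE)
  }
  u <- sort(unique(values))
  if (length(u) < 2L) stop("need at least 2 distinct values", call. = FALSE)
  cand <- (u[-1] + u[-length(u)]) / 2
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  j <- vapply(cand, function(tau) {
    sum(values > tau & labels == 1L) / npos +
      sum(values <= tau & labels == 0L) / nneg - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) {
    med <- stats::median(values)
    d <- abs(cand[best] - med)
    best <- best[d <= min(d) + 1e-12]
    best <- best[which.min(cand[best])]
  }
  structure(cand[best], youden = j[match(cand[best], cand)])
}

# ---- the fitted score model -------------------------------------------------

.endpoint_cols <- function(cohort, endpoint) {
  tc <- paste0("time_", endpoint); ec <- paste0("event_", endpoint)
  if (!all(c(tc, ec) %in% names(cohort))) {
    stop("cohort lacks columns ", tc, "/", ec, call. = FALSE)
  }
  keep <- stats::complete.cases(cohort[[tc]], cohort[[ec]])
  list(time = cohort[[tc]], event = cohort[[ec]], keep = keep,
       dropped = sum(!keep))
}

#' Build a deep stroma score model from a training cohort
#'
#' Fits per-class univariable hazard ratios and Youden cutoffs, selects the
#' classes with HR > 1, and freezes the training-cohort median score. Rows
#' with missing endpoint data are excluded (never imputed).
#'
#' @param cohort Data frame with pooled activation columns `a_ADI` ... `a_TUM`
#'   and endpoint columns `time_<endpoint>`, `event_<endpoint>`.
#' @param endpoint Endpoint code, e.g. `"OS"` (default).
#' @return An object of class `stroma_score_model` with components `hr`,
#'   `cutoff` (named per class), `selected` (codes with HR > 1), `median`
#'   (frozen split value), `scores` (training scores), and fit metadata.
#' @seealso [compute_score()], [dichotomize()], [published_score_model()]
#' @export
build_score_model <- function(cohort, endpoint = "OS") {
  acts <- .activation_cols()
  if (!all(acts %in% names(cohort))) {
    stop("cohort lacks activation columns ",
         paste(setdiff(acts, names(cohort)), collapse = ", "), call. = FALSE)
  }
  ep <- .endpoint_cols(cohort, endpoint)
  cohort <- cohort[ep$keep, , drop = FALSE]
  time <- ep$time[ep$keep]; event <- ep$event[ep$keep]
  classes <- tissue_classes()
  hr <- cutoff <- stats::setNames(numeric(length(classes)), classes)
  for (ci in seq_along(classes)) {
    a <- cohort[[acts[ci]]]
    hr[ci] <- univariable_hr(a, time, event)
    cutoff[ci] <- as.numeric(youden_cutoff(a, event))
  }
  selected <- classes[hr > 1]
  if (length(selected) == 0L) {
    stop("no class with HR > 1: score not constructible on this cohort",
         call. = FALSE)
  }
  model <- structure(list(classes = classes, hr = hr, cutoff = cutoff,
                          selected = selected, median = NA_real_,
                          endpoint = endpoint, n = nrow(cohort),
                          events = sum(event),
                          dropped_missing = ep$dropped),
                     class = "stroma_score_model")
  scores <- compute_score(model, cohort)
  model$median <- stats::median(scores)
  model$scores <- scores
  model
}

#' The frozen published reference score model
#'
#' The deep stroma score with the published per-class univariable hazard
#' ratios, Youden cutoffs, and median split (8.347) from the original
#' colorectal-cancer training cohort, usable without refitting. Five classes
#' carry HR > 1 (ADI, DEB, LYM, MUS, STR).
#'
#' @return A `stroma_score_model`.
#' @export
#' @examples
#' sm <- published_score_model()
#' coef(sm)
published_score_model <- function() {
  classes <- tissue_classes()
  hr <- stats::setNames(
    c(1.150, 0.015, 5.967, 1.226, 0.488, 3.761, 0.909, 1.154, 0.475),
    classes)
  cutoff <- stats::setNames(
    c(0.00056, 0.00227, 0.03151, 0.00121, 0.01123, 0.02359, 0.06405,
      0.00122, 0.99961),
    classes)
  structure(list(classes = classes, hr = hr, cutoff = cutoff,
                 selected = classes[hr > 1], median = 8.347,
                 endpoint = "OS", n = NA_integer_, events = NA_integer_,
                 dropped_missing = 0L),
            class = "stroma_score_model")
}

#' Compute deep stroma scores
#'
#' `S = sum over selected classes of HR_c * 1[a_c > tau_c]` — the number of
#' HR > 1 tissue classes above their Youden cutoff, weighted by their hazard
#' ratios.
#'
#' @param model A `stroma_score_model`.
#' @param activations A named activation vector, a matrix with named columns,
#'   or a data frame with `a_<CLASS>` columns.
#' @return Numeric score(s).
#' @export
compute_score <- function(model, activations) {
  stopifnot(inherits(model, "stroma_score_model"))
  A <- .as_activation_matrix(activations, model$classes)
  sel <- model$selected
  above <- sweep(A[, sel, drop = FALSE], 2L, model$cutoff[sel], ">")
  as.numeric(above %*% model$hr[sel])
}

.as_activation_matrix <- function(activations, classes) {
  if (is.data.frame(activations)) {
    cols <- paste0("a_", classes)
    if (all(cols %in% names(activations))) {
      A <- as.matrix(activations[cols])
      colnames(A) <- classes
      return(A)
    }
    activations <- as.matrix(activations)
  }
  if (is.null(dim(activations))) activations <- t(as.matrix(activations))
  if (is.null(colnames(activations))) {
    stopifnot(ncol(activations) == length(classes))
    colnames(activations) <- classes
  }
  activations[, classes, drop = FALSE]
}

#' Stratify scores into high/low at the frozen median
#'
#' `"high"` iff the score strictly exceeds the model's frozen training-cohort
#' median; the median is reused unchanged on validation cohorts.
#'
#' @param model A `stroma_score_model` with its median set.
#' @param scores Numeric scores from [compute_score()].
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(model, scores) {
  stopifnot(inherits(model, "stroma_score_model"), !is.na(model$median))
  factor(ifelse(scores > model$median, "high", "low"),
         levels = c("low", "high"))
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.stroma_score_model <- function(x, ...) {
  cat("Deep stroma score model (endpoint ", x$endpoint, ")\n", sep = "")
  if (!is.na(x$n)) {
    cat("fitted on n = ", x$n, " patients, ", x$events, " events\n", sep = "")
  }
  cat("selected classes (HR > 1): ",
      paste(sprintf("%s (%.3f)", x$selected, x$hr[x$selected]),
            collapse = ", "), "\n", sep = "")
  cat("median split value: ", format(x$median), "\n", sep = "")
  invisible(x)
}

#' @export
summary.stroma_score_model <- function(object, ...) {
  tab <- data.frame(class = object$classes,
                    hr = unname(object$hr),
                    cutoff = unname(object$cutoff),
                    selected = object$classes %in% object$selected)
  structure(list(table = tab, median = object$median,
                 endpoint = object$endpoint, n = object$n,
                 events = object$events,
                 dropped_missing = object$dropped_missing),
            class = "summary.stroma_score_model")
}

#' @export
print.summary.stroma_score_model <- function(x, ...) {
  cat("Deep stroma score model (endpoint ", x$endpoint, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  cat("median split value:", format(x$median), "\n")
  if (!is.na(x$n)) cat("n =", x$n, ", events =", x$events,
                       ", rows dropped for missing endpoint:",
                       x$dropped_missing, "\n")
  invisible(x)
}

#' @export
coef.stroma_score_model <- function(object, ...) object$hr

#' Predict scores or risk groups from a score model
#'
#' @param object A `stroma_score_model`.
#' @param newdata Activations (vector, matrix, or cohort data frame).
#' @param type `"score"` for the numeric score, `"group"` for the high/low
#'   stratification at the frozen median.
#' @param ... Unused.
#' @return Numeric scores or a `low`/`high` factor.
#' @export
predict.stroma_score_model <- function(object, newdata,
                                       type = c("score", "group"), ...) {
  type <- match.arg(type)
  s <- compute_score(object, newdata)
  if (type == "score") s else dichotomize(object, s)
}

#' @export
plot.stroma_score_model <- function(x, ...) {
  if (is.null(x$scores)) stop("model carries no training scores to plot")
  graphics::hist(x$scores, breaks = 20, col = "grey85", border = "white",
                 main = "Deep stroma score (training cohort)",
                 xlab = "score", ...)
  graphics::abline(v = x$median, col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("median split = %.3f", x$median), col = "firebrick")
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

#' Read / write a score model as JSON
#'
#' Serialization is exact (full double precision), so a reloaded model
#' reproduces identical scores and group labels.
#'
#' @param model A `stroma_score_model`.
#' @param path File path.
#' @return `write_score_model()` returns `path` invisibly;
#'   `read_score_model()` returns the model.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "stroma_score_model"))
  j <- list(class_order = model$classes,
            hr = unname(model$hr),
            cutoff = unname(model$cutoff),
            selected = model$selected,
            median = model$median,
            endpoint = model$endpoint)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  classes <- j$class_order
  structure(list(classes = classes,
                 hr = stats::setNames(j$hr, classes),
                 cutoff = stats::setNames(j$cutoff, classes),
                 selected = j$selected,
                 median = j$median,
                 endpoint = j$endpoint %||% "OS",
                 n = NA_integer_, events = NA_integer_,
                 dropped_missing = 0L),
            class = "stroma_score_model")
}

# ---- survival modelling around the score ------------------------------------

.cox_table <- function(fit, n, events) {
  s <- summary(fit)
  out <- data.frame(term = rownames(s$conf.int),
                    hr = s$conf.int[, "exp(coef)"],
                    ci_low = s$conf.int[, "lower .95"],
                    ci_high = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  attr(out, "n") <- n
  attr(out, "events") <- events
  out
}

#' Multivariable Cox model for a risk group
#'
#' Proportional-hazards fit of the endpoint on the group label adjusted for
#' UICC stage (continuous 1-4), sex (binary), and age in decades; Efron
#' handling of ties. Rows with missing endpoint data are excluded.
#'
#' @param cohort Data frame with `stage`, `sex`, `age`, and endpoint columns.
#' @param group Binary group label per patient (e.g. from [dichotomize()]).
#' @param endpoint Endpoint code (default `"OS"`).
#' @return Data frame of per-covariate HR, 95% CI, and p-value, with `n` and
#'   `events` attributes.
#' @export
multivariable_cox <- function(cohort, group, endpoint = "OS") {
  ep <- .endpoint_cols(cohort, endpoint)
  df <- data.frame(time = ep$time, event = ep$event,
                   group = as.integer(factor(group)) - 1L,
                   stage = as.numeric(cohort$stage),
                   sex = as.numeric(cohort$sex),
                   age_dec = as.numeric(cohort$age) / 10)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (sum(df$event) == 0) stop("no events: model not estimable", call. = FALSE)
  for (v in c("group", "stage", "sex", "age_dec")) {
    if (stats::sd(df[[v]]) < 1e-12) {
      stop("non-identifiable: constant covariate ", v, call. = FALSE)
    }
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ group + stage + sex +
                      age_dec, data = df, ties = "efron"),
    warning = function(w) {
      stop("proportional-hazards fit did not converge cleanly: ",
           conditionMessage(w), call. = FALSE)
    })
  .cox_table(fit, nrow(df), sum(df$event))
}

#' Per-stage multivariable Cox models
#'
#' One fit per UICC stage stratum (the stage covariate is dropped within a
#' stratum); strata with fewer than 10 events are reported as
#' `"insufficient events"` rather than errors.
#'
#' @inheritParams multivariable_cox
#' @return Named list, one element per stage: either a result data frame or
#'   the string `"insufficient events"`.
#' @export
per_stage_models <- function(cohort, group, endpoint = "OS") {
  ep <- .endpoint_cols(cohort, endpoint)
  out <- list()
  for (s in 1:4) {
    sel <- which(cohort$stage == s & ep$keep)
    nm <- paste0("stage_", s)
    ev <- sum(ep$event[sel])
    if (length(sel) == 0L || ev < 10) {
      out[[nm]] <- "insufficient events"
      next
    }
    df <- data.frame(time = ep$time[sel], event = ep$event[sel],
                     group = as.integer(factor(group[sel])) - 1L,
                     sex = as.numeric(cohort$sex[sel]),
                     age_dec = as.numeric(cohort$age[sel]) / 10)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    res <- tryCatch({
      fit <- survival::coxph(survival::Surv(time, event) ~ group + sex +
                               age_dec, data = df, ties = "efron")
      .cox_table(fit, nrow(df), sum(df$event))
    }, error = function(e) paste("fit failed:", conditionMessage(e)),
       warning = function(w) paste("fit unstable:", conditionMessage(w)))
    out[[nm]] <- res
  }
  out
}

#' Cancer-associated fibroblast (CAF) signature score
#'
#' Per-patient mean expression over the genes of a CAF signature present in
#' the expression matrix; listed genes missing from the matrix are reported
#' in a message.
#'
#' @param expression Numeric matrix, genes in rows (rownames = gene ids),
#'   patients in columns.
#' @param genes Character vector of signature gene ids.
#' @return Named numeric vector of per-patient scores.
#' @export
caf_score <- function(expression, genes) {
  if (length(genes) == 0L) stop("empty gene list", call. = FALSE)
  found <- intersect(genes, rownames(expression))
  if (length(found) == 0L) {
    stop("no signature gene found in the expression matrix", call. = FALSE)
  }
  missing <- setdiff(genes, found)
  if (length(missing) > 0L) {
    message(length(missing), " signature gene(s) absent from the matrix: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  }
  colMeans(expression[found, , drop = FALSE])
}

#' Compare the deep stroma score against reference stromal scores
#'
#' Binarizes each available score by its rule — deep stroma score at the
#' model's frozen median, CAF score and pathologist stromal percentage at
#' their own Youden-optimal cutoffs against the endpoint's event indicator —
#' fits the multivariable Cox model for each, and reports Pearson
#' correlations between the scores (and the TUM activation vs tumour purity
#' when present). Missing score columns are skipped with a log record.
#'
#' @param model A `stroma_score_model`.
#' @param cohort Cohort data frame (activations, clinical covariates,
#'   endpoints, optional `caf_score`, `path_stroma_pct`, `tumor_purity`).
#' @param endpoint Endpoint code.
#' @return List with `models` (per-score Cox tables), `correlations`
#'   (data frame), and `skipped` (character log of unavailable comparisons).
#' @export
compare_scores <- function(model, cohort, endpoint = "OS") {
  ep <- .endpoint_cols(cohort, endpoint)
  event <- ep$event
  deep <- compute_score(model, cohort)
  models <- list(deep_stroma = multivariable_cox(
    cohort, dichotomize(model, deep), endpoint))
  skipped <- character(0)
  for (nm in c("caf_score", "path_stroma_pct")) {
    if (!nm %in% names(cohort)) {
      skipped <- c(skipped, paste0(nm, ": column absent"))
      next
    }
    v <- cohort[[nm]]
    tau <- youden_cutoff(v[ep$keep], event[ep$keep])
    models[[nm]] <- multivariable_cox(cohort, as.integer(v > tau), endpoint)
  }
  corr <- function(x, y) stats::cor(x, y, use = "complete.obs")
  rows <- list()
  add_cor <- function(label, x, yname) {
    if (yname %in% names(cohort)) {
      rows[[length(rows) + 1]] <<- data.frame(
        comparison = label, pearson_r = corr(x, cohort[[yname]]))
    } else {
      skipped <<- c(skipped, paste0(label, ": ", yname, " absent"))
    }
  }
  add_cor("deep_stroma_vs_caf", deep, "caf_score")
  add_cor("deep_stroma_vs_pathologist", deep, "path_stroma_pct")
  add_cor("str_activation_vs_caf", cohort$a_STR, "caf_score")
  if (all(c("path_stroma_pct", "caf_score") %in% names(cohort))) {
    rows[[length(rows) + 1]] <- data.frame(
      comparison = "pathologist_vs_caf",
      pearson_r = corr(cohort$path_stroma_pct, cohort$caf_score))
  }
  add_cor("tum_activation_vs_purity", cohort$a_TUM, "tumor_purity")
  list(models = models,
       correlations = do.call(rbind, rows),
       skipped = skipped)
}
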