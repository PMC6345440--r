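# Synthetic survival cohorts with proportional-hazards structure.
#
# Each patient carries one or more true activation vectors drawn from a
# Dirichlet prior (one per tumour region), pooled by componentwise maximum;
# clinical covariates (UICC stage, sex, age); and per-endpoint exponential
# event times with hazard
#   h(t) = h0 * exp(sum_c beta_c a_c + beta_stage*stage + beta_sex*sex
#                    + beta_age*age/10),
# censored by an independent Uniform(0, C) time. These cohorts are the
# planted ground truth for every hazard-ratio recovery test.

#' Cohort generator configuration
#'
#' Defaults describe a TCGA-like colorectal training cohort: 500 patients,
#' two sampled regions per patient, a sparse tumour-dominated Dirichlet
#' activation prior (total concentration ~1, so each region is dominated by
#' one or two tissues, as manually sampled tumour regions are), null class
#' effects, baseline hazard 0.03 per month, and a 120-month (10-year)
#' follow-up horizon.
#'
#' @param n Number of patients (at least 2).
#' @param regions_per_patient Regions sampled per patient (1-3); activations
#'   are max-pooled across regions.
#' @param activation_prior Length-9 positive Dirichlet concentration vector
#'   (class order of [tissue_classes()]).
#' @param beta Length-9 numeric of per-class log-hazard coefficients.
#' @param beta_stage,beta_sex,beta_age Log-hazard effects of stage (per
#'   stage), sex (male vs female), and age (per decade).
#' @param h0 Baseline hazard (events per month), positive.
#' @param censor_horizon Upper bound C (months) of the Uniform(0, C)
#'   censoring time.
#' @param endpoints Endpoints to emit, subset of `c("OS", "DSS", "RFS")`.
#' @param caf_rho Optional planted Pearson correlation between a `caf_score`
#'   column and the STR activation; `NULL` omits the column.
#' @param path_stroma If `TRUE`, emit a noisy pathologist stromal-percentage
#'   column derived from the STR activation.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 500L, regions_per_patient = 2L,
                          activation_prior = c(ADI = 0.08, BACK = 0.04,
                                               DEB = 0.08, LYM = 0.10,
                                               MUC = 0.07, MUS = 0.10,
                                               NORM = 0.10, STR = 0.15,
                                               TUM = 0.25),
                          beta = stats::setNames(numeric(9), tissue_classes()),
                          beta_stage = 0, beta_sex = 0, beta_age = 0,
                          h0 = 0.03, censor_horizon = 120,
                          endpoints = "OS",
                          caf_rho = NULL, path_stroma = FALSE,
                          seed = 1L) {
  if (n < 2L) stop("cohort needs at least 2 patients", call. = FALSE)
  stopifnot(regions_per_patient %in% 1:3,
            length(activation_prior) == 9L, all(activation_prior > 0),
            length(beta) == 9L,
            h0 > 0, censor_horizon > 0,
            all(endpoints %in% c("OS", "DSS", "RFS")), length(endpoints) >= 1L)
  structure(list(n = as.integer(n),
                 regions_per_patient = as.integer(regions_per_patient),
                 activation_prior = stats::setNames(as.numeric(activation_prior),
                                                    tissue_classes()),
                 beta = stats::setNames(as.numeric(beta), tissue_classes()),
                 beta_stage = beta_stage, beta_sex = beta_sex,
                 beta_age = beta_age, h0 = h0,
                 censor_horizon = censor_horizon,
                 endpoints = endpoints,
                 caf_rho = caf_rho, path_stroma = isTRUE(path_stroma),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

#' Generate a synthetic clinical cohort
#'
#' @param cfg A [cohort_config()].
#' @return Data frame with columns `patient_id`, `stage`, `sex`, `age`,
#'   pooled true activations `a_ADI` ... `a_TUM`, per-endpoint
#'   `time_<EP>` / `event_<EP>`, and optional `caf_score`,
#'   `path_stroma_pct`. Deterministic given `cfg$seed`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  classes <- tissue_classes()
  with_seed(cfg$seed, {
    n <- cfg$n
    # pooled activations: componentwise max over per-region simplex draws
    A <- .rdirichlet(n, cfg$activation_prior)
    if (cfg$regions_per_patient > 1L) {
      for (r in seq_len(cfg$regions_per_patient - 1L)) {
        A <- pmax(A, .rdirichlet(n, cfg$activation_prior))
      }
    }
    colnames(A) <- classes

    stage <- sample(1:4, n, replace = TRUE)
    sex <- stats::rbinom(n, 1L, 0.5)
    age <- pmin(pmax(stats::rnorm(n, 68, 10), 30), 95)

    lp <- as.vector(A %*% cfg$beta) + cfg$beta_stage * stage +
      cfg$beta_sex * sex + cfg$beta_age * age / 10
    rate <- cfg$h0 * exp(lp)

    out <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                      stage = stage, sex = sex, age = round(age, 1))
    for (ci in seq_along(classes)) out[[paste0("a_", classes[ci])]] <- A[, ci]
    for (ep in cfg$endpoints) {
      tt <- stats::rexp(n, rate)
      cc <- stats::runif(n, 0, cfg$censor_horizon)
      out[[paste0("time_", ep)]] <- pmin(tt, cc)
      out[[paste0("event_", ep)]] <- as.integer(tt <= cc)
    }
    if (!is.null(cfg$caf_rho)) {
      rho <- cfg$caf_rho
      z <- as.vector(scale(A[, "STR"]))
      out$caf_score <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    if (cfg$path_stroma) {
      z <- as.vector(scale(A[, "STR"]))
      out$path_stroma_pct <- pmin(pmax(30 + 15 * (0.6 * z +
        0.8 * stats::rnorm(n)), 0), 100)
    }
    out
  })
}
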