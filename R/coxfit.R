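# Compositional Cox proportional hazards regression.
#
# The three-part waking-day composition enters the model as its two ilr
# pivot coordinates under a chosen rotation, alongside conventional
# covariates. The three rotations are orthogonal reparameterisations: the
# partial likelihood, linear predictors and all reallocation hazard ratios
# are identical across them, only the coordinate coefficients rotate.

#' Named covariate adjustment sets
#'
#' `"model1"` adjusts for sociodemographic and lifestyle factors; `"model2"`
#' additionally for cardiometabolic risk factors and the multimorbidity
#' index; `"none"` fits the composition alone.
#'
#' @param set Adjustment-set label.
#' @return Character vector of covariate column names.
#' @export
adjustment_covariates <- function(set = c("model2", "model1", "none")) {
  set <- match.arg(set)
  socio <- c("age", "sex", "ethnicity", "marital", "education", "occupation",
             "alcohol", "smoking", "diet")
  cardio <- c("bmi_cat", "diabetes", "hypertension", "hyperlipidaemia",
              "multimorbidity")
  switch(set, none = character(0), model1 = socio, model2 = c(socio, cardio))
}

#' Fit a compositional Cox model
#'
#' Computes ilr pivot coordinates of each subject's (SB, LIPA, MVPA)
#' composition under `rotation`, closes them to `total` minutes, and fits a
#' Cox proportional hazards model of follow-up time and event status on
#' (z1, z2) plus the requested covariates, with Efron handling of ties.
#'
#' @param cohort Data frame with columns `sb_min`, `lipa_min`, `mvpa_min`
#'   (strictly positive; impute zeros first), `followup_years`, `event`
#'   (0/1), and any covariate columns named by the adjustment set.
#' @param rotation Pivot rotation (see [rotations()]).
#' @param adjustment Adjustment-set label passed to
#'   [adjustment_covariates()], ignored when `covariates` is given.
#' @param covariates Optional explicit character vector of covariate column
#'   names, overriding `adjustment`.
#' @param total Waking-day closure total in minutes; set `normalize = FALSE`
#'   to use the recorded minutes unclosed (the usual companion is then
#'   adding `waking_min` to `covariates`).
#' @param normalize Close compositions to `total` before transforming?
#' @return An object of class `"comp_cox"`: list with elements `fit` (the
#'   underlying [survival::coxph()] fit), `rotation`, `adjustment`, `beta`,
#'   `beta_z` (the two coordinate coefficients), `vcov`, `vcov_z`,
#'   `loglik` (log partial likelihood at the solution), `n`, `n_events`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 400, seed = 1))
#' fit <- fit_compositional_cox(cohort, rotation = "mvpa_first",
#'                              adjustment = "model1")
#' coord_hr_table(fit)
fit_compositional_cox <- function(cohort, rotation = "sb_first",
                                  adjustment = "model2", covariates = NULL,
                                  total = 960, normalize = TRUE) {
  rotation <- match_rotation(rotation)
  need <- c("sb_min", "lipa_min", "mvpa_min", "followup_years", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(cohort$followup_years <= 0))
    stop("follow-up times must be positive", call. = FALSE)
  if (!all(cohort$event %in% c(0, 1)))
    stop("`event` must be 0/1", call. = FALSE)
  if (sum(cohort$event) < 2) stop("at least 2 events are required", call. = FALSE)

  covs <- if (is.null(covariates)) adjustment_covariates(adjustment) else covariates
  miss <- setdiff(covs, names(cohort))
  if (length(miss)) stop("covariates absent from cohort: ",
                         paste(miss, collapse = ", "), call. = FALSE)

  comp <- as_comp_matrix(cohort[, c("sb_min", "lipa_min", "mvpa_min")])
  if (normalize) comp <- close_composition(comp, total)
  z <- ilr_pivot(comp, rotation)

  df <- cohort
  df$z1 <- z[, 1]
  df$z2 <- z[, 2]
  fml <- stats::reformulate(c("z1", "z2", covs),
                            response = "survival::Surv(followup_years, event)")
  fit <- survival::coxph(fml, data = df, ties = "efron", model = TRUE)
  if (any(is.na(stats::coef(fit))))
    stop("collinear or inestimable terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)

  structure(list(
    fit = fit,
    rotation = rotation,
    adjustment = if (is.null(covariates)) adjustment else "custom",
    beta = stats::coef(fit),
    beta_z = stats::coef(fit)[c("z1", "z2")],
    vcov = stats::vcov(fit),
    vcov_z = stats::vcov(fit)[c("z1", "z2"), c("z1", "z2")],
    loglik = fit$loglik[2],
    n = fit$n,
    n_events = fit$nevent
  ), class = "comp_cox")
}

#' Construct a compositional Cox effect from known coefficients
#'
#' Builds a minimal `"comp_cox"` object from coordinate coefficients and
#' their covariance, for reallocation calculations under hypothesised or
#' externally reported effects.
#'
#' @param beta_z Length-2 coefficient vector for (z1, z2).
#' @param vcov_z 2 x 2 covariance matrix of `beta_z` (default zero: point
#'   contrasts without sampling uncertainty).
#' @param rotation Rotation the coefficients refer to.
#' @return A `"comp_cox"` object usable by [reallocation_hr()] and
#'   [hr_surface()].
#' @export
#' @examples
#' null_model <- as_comp_cox(c(0, 0))
as_comp_cox <- function(beta_z, vcov_z = matrix(0, 2, 2), rotation = "sb_first") {
  rotation <- match_rotation(rotation)
  beta_z <- as.numeric(beta_z)
  if (length(beta_z) != 2) stop("`beta_z` must have length 2", call. = FALSE)
  vcov_z <- as.matrix(vcov_z)
  if (!all(dim(vcov_z) == 2) || max(abs(vcov_z - t(vcov_z))) > 1e-12)
    stop("`vcov_z` must be a symmetric 2 x 2 matrix", call. = FALSE)
  names(beta_z) <- c("z1", "z2")
  structure(list(fit = NULL, rotation = rotation, adjustment = "manual",
                 beta = beta_z, beta_z = beta_z, vcov = vcov_z,
                 vcov_z = vcov_z, loglik = NA_real_, n = NA_integer_,
                 n_events = NA_integer_),
            class = "comp_cox")
}

#' @export
print.comp_cox <- function(x, ...) {
  cat("Compositional Cox model (rotation:", x$rotation,
      "; adjustment:", x$adjustment, ")\n")
  if (!is.na(x$n))
    cat(sprintf("  n = %d, events = %d, log partial likelihood = %.3f\n",
                x$n, x$n_events, x$loglik))
  print(coord_hr_table(x))
  invisible(x)
}

#' Hazard ratios for the ilr coordinates of a fitted model
#'
#' @param model A `"comp_cox"` object.
#' @param level Confidence level (default 0.95).
#' @return Data frame with one row per coordinate: `term`, `meaning`,
#'   `hr`, `ci_low`, `ci_high`, `p`.
#' @export
coord_hr_table <- function(model, level = 0.95) {
  stopifnot(inherits(model, "comp_cox"))
  qz <- stats::qnorm(1 - (1 - level) / 2)
  b <- model$beta_z
  se <- sqrt(diag(model$vcov_z))
  ord <- rotations()[[model$rotation]]
  meanings <- c(
    sprintf("%s increase relative to %s and %s",
            toupper(ord[1]), toupper(ord[2]), toupper(ord[3])),
    sprintf("%s increase relative to %s", toupper(ord[2]), toupper(ord[3]))
  )
  data.frame(
    term = c("z1", "z2"),
    meaning = meanings,
    hr = exp(b),
    ci_low = exp(b - qz * se),
    ci_high = exp(b + qz * se),
    p = ifelse(se > 0, 2 * stats::pnorm(-abs(b / se)), NA_real_),
    row.names = NULL
  )
}

#' Relative-importance table across all three rotations
#'
#' Fits the compositional Cox model under each rotation (and one or more
#' adjustment sets) and stacks the coordinate hazard ratios, mirroring the
#' conventional presentation of pivot-coordinate results.
#'
#' @param cohort Cohort data frame (see [fit_compositional_cox()]).
#' @param adjustments Character vector of adjustment-set labels.
#' @param ... Passed to [fit_compositional_cox()].
#' @return Data frame with columns `rotation`, `adjustment`, `term`,
#'   `meaning`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
behaviour_importance_table <- function(cohort, adjustments = c("model1", "model2"),
                                       ...) {
  out <- list()
  for (rot in names(rotations())) {
    for (adj in adjustments) {
      m <- fit_compositional_cox(cohort, rotation = rot, adjustment = adj, ...)
      tab <- coord_hr_table(m)
      tab$rotation <- rot
      tab$adjustment <- adj
      out[[length(out) + 1L]] <- tab
    }
  }
  out <- do.call(rbind, out)
  out[, c("rotation", "adjustment", "term", "meaning", "hr", "ci_low",
          "ci_high", "p")]
}

#' Grambsch-Therneau proportional hazards check
#'
#' Tests the proportional hazards assumption by the correlation of scaled
#' Schoenfeld residuals with time (via [survival::cox.zph()]), per term and
#' globally.
#'
#' @param model A fitted `"comp_cox"` object (from data, not
#'   [as_comp_cox()]).
#' @param transform Time transform for the test (default `"km"`, the
#'   [survival::cox.zph()] default).
#' @return Data frame with columns `term`, `chisq`, `df`, `p`; the last row
#'   is the global test.
#' @export
ph_check <- function(model, transform = "km") {
  stopifnot(inherits(model, "comp_cox"))
  if (is.null(model$fit))
    stop("proportional hazards check needs a model fitted to data", call. = FALSE)
  zp <- survival::cox.zph(model$fit, transform = transform, global = TRUE)
  tab <- as.data.frame(zp$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df, p = tab$p,
             row.names = NULL)
}

#' Effect-modification test for a binary covariate
#'
#' Adds `modifier:z1` and `modifier:z2` interaction terms to the adjusted
#' compositional Cox model and tests them jointly by a 2-df Wald test;
#' per-term Wald p-values are reported alongside.
#'
#' @param cohort Cohort data frame.
#' @param modifier Name of a binary (two-level) column in `cohort`.
#' @param rotation,adjustment As in [fit_compositional_cox()].
#' @param ... Optionally `covariates`, an explicit covariate vector
#'   overriding the adjustment set.
#' @return A list: `p` (joint 2-df Wald p-value), `statistic`, `df`,
#'   `per_term` (data frame of the two interaction coefficients with
#'   individual Wald p-values), `fit` (the interaction model).
#' @export
interaction_test <- function(cohort, modifier, rotation = "sb_first",
                             adjustment = "model2", ...) {
  rotation <- match_rotation(rotation)
  if (!modifier %in% names(cohort))
    stop("modifier column not found: ", modifier, call. = FALSE)
  mv <- cohort[[modifier]]
  if (length(unique(mv[!is.na(mv)])) < 2)
    stop("modifier is constant; effect modification is undefined", call. = FALSE)
  if (length(unique(mv[!is.na(mv)])) > 2)
    stop("modifier must be binary", call. = FALSE)

  dots <- list(...)
  covs <- if (!is.null(dots$covariates)) dots$covariates else
    adjustment_covariates(adjustment)
  covs <- union(covs, modifier)
  fml <- stats::reformulate(
    c("z1", "z2", covs, paste0(modifier, ":z1"), paste0(modifier, ":z2")),
    response = ".surv")
  comp <- close_composition(cohort[, c("sb_min", "lipa_min", "mvpa_min")])
  z <- ilr_pivot(comp, rotation)
  dat <- cohort
  dat$z1 <- z[, 1]; dat$z2 <- z[, 2]
  dat$.surv <- survival::Surv(cohort$followup_years, cohort$event)
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("collinear or inestimable terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  ix <- grep(":", names(cf))
  if (length(ix) != 2) stop("expected exactly two interaction terms", call. = FALSE)
  b <- cf[ix]
  V <- stats::vcov(fit)[ix, ix]
  W <- drop(t(b) %*% solve(V, b))
  se <- sqrt(diag(V))
  list(
    p = stats::pchisq(W, df = 2, lower.tail = FALSE),
    statistic = W,
    df = 2L,
    per_term = data.frame(term = names(b), estimate = unname(b),
                          se = unname(se),
                          p = 2 * stats::pnorm(-abs(b / se)), row.names = NULL),
    fit = fit
  )
}
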