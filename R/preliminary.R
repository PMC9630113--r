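#' Linear mixed model for the serum 25(OH)D outcome
#'
#' Fits the preliminary repeated-measures model: outcome on dose (arm),
#' time (visit week as a factor), baseline 25(OH)D, age, sex and body
#' size as fixed effects, with a participant-specific random intercept,
#' by restricted maximum likelihood (lme4). With `include_time = FALSE`
#' the time factor is dropped, matching single-follow-up designs. When
#' each participant contributes a single row the random intercept is not
#' identifiable and the model reduces to ordinary least squares with the
#' random-intercept variance reported as zero.
#'
#' @param table analysis table from [to_analysis_table()].
#' @param include_time keep the visit-week factor among the fixed effects.
#' @return object of class `netgain_lmm`: list with `fixed_effects`
#'   (matrix of estimate/se), `covariance`, `random_intercept_variance`,
#'   `residual_variance`, `n_obs`, `n_participants`, `formula_descriptor`
#'   and the underlying `fit`.
#' @export
fit_lmm <- function(table, include_time = TRUE) {
  stopifnot(inherits(table, "data.frame"))
  tab <- droplevels(as.data.frame(table))
  if (nlevels(factor(tab$arm)) < 2) {
    stop("model requires both arms to be present", call. = FALSE)
  }
  per_arm <- table(tab$arm[!duplicated(tab$participant_id)])
  if (any(per_arm < 2)) stop("need >= 2 participants per arm", call. = FALSE)
  if (include_time && length(unique(tab$visit_week)) < 2) {
    include_time <- FALSE
  }
  rhs <- c("arm", if (include_time) "factor(visit_week)",
           "baseline", "age", "sex", "body_size")
  fixed <- stats::reformulate(rhs, response = "outcome")
  mm <- stats::model.matrix(fixed, data = tab)
  if (qr(mm)$rank < ncol(mm)) {
    stop("singular fixed-effect design (rank-deficient); check for ",
         "constant or collinear covariates", call. = FALSE)
  }
  one_row_per_id <- !any(duplicated(tab$participant_id))
  if (one_row_per_id) {
    fit <- stats::lm(fixed, data = tab)
    beta <- stats::coef(fit)
    vc <- stats::vcov(fit)
    fe <- cbind(estimate = beta,
                se = sqrt(diag(vc)))
    out <- list(fixed_effects = fe, covariance = as.matrix(vc),
                random_intercept_variance = 0,
                residual_variance = summary(fit)$sigma^2,
                n_obs = nrow(tab),
                n_participants = length(unique(tab$participant_id)),
                formula_descriptor = paste(deparse(fixed),
                                           "[OLS: one row per participant]"),
                fit = fit)
    class(out) <- "netgain_lmm"
    return(out)
  }
  form <- stats::update.formula(fixed, . ~ . + (1 | participant_id))
  fit <- tryCatch(
    lme4::lmer(form, data = tab, REML = TRUE),
    error = function(e) stop("mixed-model fitting failed: ",
                             conditionMessage(e), call. = FALSE))
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  vcomp <- as.data.frame(lme4::VarCorr(fit))
  out <- list(
    fixed_effects = cbind(estimate = beta, se = sqrt(diag(vc))),
    covariance = vc,
    random_intercept_variance =
      vcomp$vcov[vcomp$grp == "participant_id"][1],
    residual_variance = vcomp$vcov[vcomp$grp == "Residual"][1],
    n_obs = nrow(tab),
    n_participants = length(unique(tab$participant_id)),
    formula_descriptor = paste(deparse(form), collapse = ""),
    fit = fit)
  class(out) <- "netgain_lmm"
  out
}

#' @export
print.netgain_lmm <- function(x, ...) {
  cat("Linear mixed model:", x$formula_descriptor, "\n")
  cat(x$n_obs, "observations,", x$n_participants, "participants\n")
  cat("Random-intercept variance:",
      format(x$random_intercept_variance, digits = 4),
      " Residual variance:", format(x$residual_variance, digits = 4), "\n")
  print(round(x$fixed_effects, 4))
  invisible(x)
}

#' Experimental-minus-standard dose contrast
#'
#' Extracts the fixed-effect contrast between the experimental and the
#' standard dose from a fitted mixed model, with a Wald confidence
#' interval at the given level and a two-sided normal p-value.
#'
#' @param fit a [fit_lmm()] result.
#' @param level confidence level, e.g. 0.95.
#' @return named numeric: `estimate`, `ci_low`, `ci_high`, `p_value`.
#' @export
dose_contrast <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "netgain_lmm"), level > 0, level < 1)
  nm <- rownames(fit$fixed_effects)
  hit <- grep("^arm", nm, value = TRUE)
  if (length(hit) != 1) {
    stop("fit contains no dose (arm) term", call. = FALSE)
  }
  est <- fit$fixed_effects[hit, "estimate"]
  se <- fit$fixed_effects[hit, "se"]
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(estimate = unname(est),
    ci_low = unname(est - z * se),
    ci_high = unname(est + z * se),
    p_value = unname(2 * stats::pnorm(-abs(est / se))))
}

#' Cut-off-based subgroup analysis with Bonferroni adjustment
#'
#' Splits participants on baseline 25(OH)D below vs at-or-above `cutoff`
#' (the conventional 30 ng/ml sufficiency threshold by default), refits
#' the preliminary model within each stratum, and reports the dose
#' contrast per stratum at the Bonferroni-adjusted level
#' `alpha / number of strata`. Baselines exactly at the cutoff are
#' assigned to the sufficient stratum.
#'
#' @param table analysis table from [to_analysis_table()].
#' @param cutoff ng/ml.
#' @param alpha family-wise significance level before adjustment.
#' @param include_time passed to [fit_lmm()].
#' @return data frame of class `subgroup_result` with one row per stratum:
#'   `stratum_label`, `cutoff`, `n`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `adjusted_alpha`.
#' @export
subgroup_analysis <- function(table, cutoff = 30, alpha = 0.05,
                              include_time = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  tab <- as.data.frame(table)
  strata <- list(
    insufficient = tab[tab$baseline < cutoff, , drop = FALSE],
    sufficient = tab[tab$baseline >= cutoff, , drop = FALSE])
  empty <- names(strata)[vapply(strata, nrow, integer(1)) == 0]
  if (length(empty)) {
    stop("empty stratum at cutoff ", cutoff, " ng/ml: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  adj_alpha <- alpha / length(strata)
  res <- lapply(names(strata), function(lab) {
    s <- strata[[lab]]
    fit <- fit_lmm(s, include_time = include_time)
    dc <- dose_contrast(fit, level = 1 - adj_alpha)
    data.frame(stratum_label = paste0(lab, " (baseline ",
                                      if (lab == "insufficient") "<" else ">=",
                                      " ", cutoff, " ng/ml)"),
               cutoff = cutoff,
               n = length(unique(s$participant_id)),
               estimate = dc[["estimate"]],
               ci_low = dc[["ci_low"]], ci_high = dc[["ci_high"]],
               p_value = dc[["p_value"]],
               adjusted_alpha = adj_alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("subgroup_result", class(out))
  out
}
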