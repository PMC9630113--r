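#' Per-arm regression of the end-of-trial outcome
#'
#' Fits the arm-specific working model for the serum 25(OH)D
#' concentration: outcome at the final week on an intercept, the baseline
#' concentration and the adjustment covariates (age, sex, body size) by
#' ordinary least squares within one arm. When several post-baseline
#' weeks are supplied the weeks are modelled jointly with a visit-week
#' factor and a participant random intercept (REML), so the
#' final-week contrast remains available.
#'
#' @param table analysis table from [to_analysis_table()].
#' @param arm `"standard"` or `"experimental"`.
#' @param week post-baseline week(s) to model; default the last one.
#' @param covariates character vector of adjustment covariates to include
#'   alongside `baseline`.
#' @return object of class `arm_model`: list with `arm`, `coefficients`,
#'   `covariance`, `residual_variance`, `n`, `final_week`,
#'   `design_descriptor` and the underlying `fit`.
#' @export
fit_arm_model <- function(table, arm, week = NULL,
                          covariates = c("age", "sex", "body_size")) {
  tab <- as.data.frame(table)
  arm <- match.arg(arm, c("standard", "experimental"))
  if (is.null(week)) week <- max(tab$visit_week)
  sub <- tab[tab$arm == arm & tab$visit_week %in% week, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for arm '", arm, "' at the given week(s)",
                       call. = FALSE)
  sub <- droplevels(sub)
  multi_week <- length(unique(sub$visit_week)) > 1
  rhs <- c("baseline", if (multi_week) "factor(visit_week)", covariates)
  form <- stats::reformulate(rhs, response = "outcome")
  mm <- stats::model.matrix(form, data = sub)
  n_id <- length(unique(sub$participant_id))
  if (n_id < ncol(mm) + 2) {
    stop("arm '", arm, "': ", n_id, " participants cannot support ",
         ncol(mm), " regressors", call. = FALSE)
  }
  if (qr(mm)$rank < ncol(mm)) {
    stop("rank-deficient design in arm '", arm, "'", call. = FALSE)
  }
  if (multi_week) {
    mform <- stats::update.formula(form, . ~ . + (1 | participant_id))
    fit <- lme4::lmer(mform, data = sub, REML = TRUE)
    beta <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    vcomp <- as.data.frame(lme4::VarCorr(fit))
    sigma2 <- vcomp$vcov[vcomp$grp == "Residual"][1]
    desc <- paste0("mixed, weeks ", paste(sort(unique(sub$visit_week)),
                                          collapse = "/"))
  } else {
    fit <- stats::lm(form, data = sub)
    beta <- stats::coef(fit)
    vc <- as.matrix(stats::vcov(fit))
    sigma2 <- summary(fit)$sigma^2
    desc <- paste0("OLS, week ", unique(sub$visit_week))
  }
  structure(list(arm = arm, coefficients = beta, covariance = vc,
                 residual_variance = sigma2, n = n_id,
                 final_week = max(sub$visit_week),
                 design_descriptor = desc, fit = fit, data = sub),
            class = "arm_model")
}

#' @export
print.arm_model <- function(x, ...) {
  cat("Arm model (", x$arm, "; ", x$design_descriptor, "; n = ", x$n,
      ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

# Covariate profile at which curves are drawn: adjustment covariates fixed
# at pooled sample means, sex at the sample proportion of females.
default_profile <- function(table) {
  tab <- as.data.frame(table)
  first <- tab[!duplicated(tab$participant_id), , drop = FALSE]
  list(age = mean(first$age),
       sexfemale = mean(first$sex == "female"),
       body_size = mean(first$body_size))
}

# Linear contrast vector matching an arm_model's coefficients for
# prediction at baseline x under a covariate profile.
contrast_vector <- function(fit, x, profile) {
  nm <- names(fit$coefficients)
  cv <- numeric(length(nm))
  names(cv) <- nm
  cv["(Intercept)"] <- 1
  cv["baseline"] <- x
  for (j in nm) {
    if (j %in% c("(Intercept)", "baseline")) next
    if (startsWith(j, "factor(visit_week)")) {
      wk <- sub("factor\\(visit_week\\)", "", j)
      cv[j] <- as.numeric(as.numeric(wk) == fit$final_week)
    } else if (j == "sexfemale") {
      cv[j] <- profile$sexfemale
    } else if (j %in% names(profile)) {
      cv[j] <- profile[[j]]
    } else {
      stop("no profile value for regressor '", j, "'", call. = FALSE)
    }
  }
  cv
}

#' Delta-method confidence interval for a linear contrast
#'
#' For a linear combination of estimated coefficients the delta method is
#' exact: the point estimate is `contrast' estimates` and its variance
#' `contrast' covariance contrast`. The interval uses the standard normal
#' quantile. A numerically negative variance is clipped to zero with a
#' warning.
#'
#' @param contrast numeric vector.
#' @param estimates numeric vector of the same length.
#' @param covariance covariance matrix of `estimates`.
#' @param level confidence level.
#' @return numeric `c(low, high)` with attributes `point` and `se`.
#' @export
delta_method_ci <- function(contrast, estimates, covariance, level = 0.95) {
  stopifnot(length(contrast) == length(estimates),
            all(dim(covariance) == length(contrast)),
            level > 0, level < 1)
  point <- sum(contrast * estimates)
  v <- drop(t(contrast) %*% covariance %*% contrast)
  if (v < 0) {
    if (v < -1e-8) warning("negative contrast variance clipped to zero")
    v <- 0
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(v)
  structure(c(low = point - hw, high = point + hw),
            point = point, se = sqrt(v))
}

#' Parametric net-gain curve
#'
#' The estimated net gain at baseline x from preferring the experimental
#' over the standard dose is the difference of the two arm predictions,
#' \deqn{\Delta(x) = m_2(x, \hat\beta_2) - m_1(x, \hat\beta_1)
#'   = (\hat\beta_{20} - \hat\beta_{10}) + (\hat\beta_{21} - \hat\beta_{11}) x
#'   + \sum_j (\hat\beta_{2j} - \hat\beta_{1j})\, \mathrm{profile}_j,}
#' with pointwise delta-method variance
#' \eqn{c(x)' V_1 c(x) + c(x)' V_2 c(x)} (arms fitted independently, so the
#' two contributions add) and a normal-quantile band.
#'
#' @param fit1 `arm_model` for the standard arm.
#' @param fit2 `arm_model` for the experimental arm.
#' @param grid strictly increasing baseline values, ng/ml.
#' @param profile named list fixing the adjustment covariates; see
#'   [fit_arm_model()]. Required entries: `age`, `sexfemale`, `body_size`
#'   (as present among the fits' regressors).
#' @param level confidence level of the pointwise band.
#' @return object of class `netgain_curve`: data frame with columns
#'   `baseline`, `estimate`, `se`, `ci_low`, `ci_high` and attributes
#'   `level`, `profile`, `method_tag`.
#' @export
net_gain <- function(fit1, fit2, grid, profile, level = 0.95) {
  stopifnot(inherits(fit1, "arm_model"), inherits(fit2, "arm_model"),
            length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  if (!identical(names(fit1$coefficients), names(fit2$coefficients))) {
    stop("arm models have mismatched regressor sets", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- se <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cv <- contrast_vector(fit2, grid[i], profile)
    est[i] <- sum(cv * fit2$coefficients) - sum(cv * fit1$coefficients)
    v <- drop(t(cv) %*% fit1$covariance %*% cv) +
      drop(t(cv) %*% fit2$covariance %*% cv)
    se[i] <- sqrt(max(v, 0))
  }
  netgain_curve(grid, est, se, est - z * se, est + z * se,
                level = level, profile = profile, method_tag = "parametric")
}

netgain_curve <- function(baseline, estimate, se, ci_low, ci_high,
                          level, profile, method_tag) {
  out <- data.frame(baseline = baseline, estimate = estimate, se = se,
                    ci_low = ci_low, ci_high = ci_high)
  attr(out, "level") <- level
  attr(out, "profile") <- profile
  attr(out, "method_tag") <- method_tag
  class(out) <- c("netgain_curve", class(out))
  out
}

#' @export
print.netgain_curve <- function(x, ...) {
  cat("Net-gain curve (", attr(x, "method_tag"), "), ",
      nrow(x), " grid points over [",
      format(min(x$baseline), digits = 4), ", ",
      format(max(x$baseline), digits = 4), "] ng/ml",
      sep = "")
  if (all(is.finite(x$se))) {
    cat(", ", attr(x, "level") * 100, "% pointwise band", sep = "")
  }
  cat("\n")
  print(utils::head(round(as.data.frame(x), 3)))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
plot.netgain_curve <- function(x, add = FALSE, col = "steelblue4",
                               band = TRUE, ...) {
  if (!add) {
    graphics::plot(x$baseline, x$estimate, type = "n",
                   ylim = range(c(x$ci_low, x$ci_high, 0), finite = TRUE),
                   xlab = "baseline 25(OH)D (ng/ml)",
                   ylab = "net gain (ng/ml)", ...)
    graphics::abline(h = 0, col = "grey60", lty = 3)
  }
  if (band && all(is.finite(x$se))) {
    graphics::polygon(c(x$baseline, rev(x$baseline)),
                      c(x$ci_low, rev(x$ci_high)),
                      col = grDevices::adjustcolor(col, 0.2), border = NA)
  }
  graphics::lines(x$baseline, x$estimate, col = col, lwd = 2)
  invisible(x)
}

#' Baseline threshold above which the higher dose shows a clear benefit
#'
#' Finds the smallest baseline grid value x* such that the lower
#' confidence limit of the net gain stays above zero at every grid point
#' from x* to the right edge (the band no longer crosses zero), i.e. the
#' uniform-tail rule. The analogous lower-tail threshold reports the
#' largest x below which the upper limit stays below zero (the standard
#' dose is clearly preferable). `rule = "first_crossing"` instead returns
#' the first grid point where the band excludes zero.
#'
#' @param curve a [net_gain()] curve.
#' @param rule `"uniform_tail"` (default) or `"first_crossing"`.
#' @return named numeric `c(upper = , lower = )`, `NA` when no threshold
#'   exists in the grid.
#' @export
benefit_threshold <- function(curve, rule = c("uniform_tail",
                                              "first_crossing")) {
  stopifnot(inherits(curve, "netgain_curve"), nrow(curve) >= 2)
  rule <- match.arg(rule)
  x <- curve$baseline
  pos <- curve$ci_low > 0
  neg <- curve$ci_high < 0
  upper <- lower <- NA_real_
  if (rule == "uniform_tail") {
    # smallest index from which positivity persists to the right edge
    tail_pos <- rev(cumprod(rev(pos))) == 1
    if (any(tail_pos)) upper <- x[which(tail_pos)[1]]
    head_neg <- cumprod(neg) == 1
    if (any(head_neg)) lower <- x[max(which(head_neg))]
  } else {
    if (any(pos)) upper <- x[which(pos)[1]]
    if (any(neg)) lower <- x[max(which(neg))]
  }
  c(upper = upper, lower = lower)
}

#' Predicted change from baseline within one arm
#'
#' The arm-model prediction of the end-of-trial concentration minus the
#' baseline itself, \eqn{m_k(x) - x}, over a baseline grid with
#' delta-method bands (the subtraction of the known x leaves the variance
#' unchanged).
#'
#' @param fit an [fit_arm_model()] result.
#' @param grid baseline values, ng/ml.
#' @param profile covariate profile (see [net_gain()]).
#' @param level confidence level.
#' @return a `netgain_curve`-classed data frame whose `estimate` column is
#'   the predicted change (method tag `change`).
#' @export
predict_change <- function(fit, grid, profile, level = 0.95) {
  stopifnot(inherits(fit, "arm_model"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- se <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cv <- contrast_vector(fit, grid[i], profile)
    est[i] <- sum(cv * fit$coefficients) - grid[i]
    se[i] <- sqrt(max(drop(t(cv) %*% fit$covariance %*% cv), 0))
  }
  netgain_curve(grid, est, se, est - z * se, est + z * se,
                level = level, profile = profile,
                method_tag = paste0("change:", fit$arm))
}

#' Net-gain surface over baseline and age
#'
#' Extends the net-gain contrast to condition on both the baseline
#' concentration and age (one more slope term): \eqn{\Delta(x, a)} with
#' contrast (1, x, a, profile) and the same delta-method machinery. When
#' the two arms share the same age slope the surface is constant in age.
#'
#' @param fit1,fit2 arm models that both include an `age` regressor.
#' @param grid_x baseline values, ng/ml.
#' @param grid_a age values, years.
#' @param profile covariate profile for the remaining covariates.
#' @param level confidence level.
#' @return data frame with columns `baseline`, `age`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
net_gain_bivariate <- function(fit1, fit2, grid_x, grid_a, profile,
                               level = 0.95) {
  stopifnot(inherits(fit1, "arm_model"), inherits(fit2, "arm_model"))
  if (!("age" %in% names(fit1$coefficients)) ||
      !("age" %in% names(fit2$coefficients))) {
    stop("both arm models must include an age regressor", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- expand.grid(baseline = grid_x, age = grid_a)
  est <- se <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    prof <- profile
    prof$age <- out$age[i]
    cv <- contrast_vector(fit2, out$baseline[i], prof)
    est[i] <- sum(cv * fit2$coefficients) - sum(cv * fit1$coefficients)
    v <- drop(t(cv) %*% fit1$covariance %*% cv) +
      drop(t(cv) %*% fit2$covariance %*% cv)
    se[i] <- sqrt(max(v, 0))
  }
  out$estimate <- est
  out$ci_low <- est - z * se
  out$ci_high <- est + z * se
  out
}

#' Fit the individualized net-gain model to a two-arm trial
#'
#' The central fitting function. Fits the per-arm end-of-trial
#' regressions, forms the net-gain curve \eqn{\Delta(x) = m_2(x) - m_1(x)}
#' over a baseline grid with pointwise delta-method confidence bands, and
#' locates the benefit threshold: the baseline concentration above which
#' the band excludes zero, i.e. above which only the experimental
#' (higher) dose promises a clear additional increase in serum 25(OH)D.
#' Optionally adds the two-step semi-parametric (kernel-smoothed) curve.
#'
#' @param data a [trial_dataset()] or an analysis table from
#'   [to_analysis_table()].
#' @param week final post-baseline week to model; default the last
#'   observed.
#' @param grid baseline grid; default 200 evenly spaced points spanning
#'   the observed pooled baseline range (optionally overridden by
#'   `grid_step` for a fixed step, e.g. 0.1 ng/ml).
#' @param grid_step optional fixed grid step, ng/ml.
#' @param level confidence level of the pointwise bands.
#' @param profile covariate profile; default: pooled covariate means with
#'   sex at the sample female proportion.
#' @param kernel optional [kernel_spec()]; when given, semi-parametric
#'   net-gain curves are added for each value of `bandwidths`.
#' @param bandwidths bandwidths (standardized-baseline scale) for the
#'   semi-parametric step; default `c(0.6, 0.8)`.
#' @param covariates adjustment covariates for the arm models.
#' @return object of class `netgain`: list with the arm fits, the
#'   parametric `curve`, `threshold`, any `semiparametric` curves, the
#'   `profile`, `level` and the analysis `table`.
#' @examples
#' tr <- simulate_trial(steenhoff_like_config(), seed = 1)
#' tab <- to_analysis_table(complete_cases(tr, c(0, 12)))
#' fit <- netgain(tab)
#' fit
#' predict(fit, newdata = c(25, 35, 45))
#' @export
netgain <- function(data, week = NULL, grid = NULL, grid_step = NULL,
                    level = 0.95, profile = NULL, kernel = NULL,
                    bandwidths = c(0.6, 0.8),
                    covariates = c("age", "sex", "body_size")) {
  tab <- if (inherits(data, "trial_dataset")) to_analysis_table(data)
         else data
  stopifnot(is.data.frame(tab))
  if (is.null(week)) week <- max(tab$visit_week)
  if (is.null(profile)) profile <- default_profile(tab)
  if (is.null(grid)) {
    rng <- range(tab$baseline)
    grid <- if (is.null(grid_step)) {
      seq(rng[1], rng[2], length.out = 200)
    } else {
      seq(rng[1], rng[2], by = grid_step)
    }
  }
  fit1 <- fit_arm_model(tab, "standard", week = week,
                        covariates = covariates)
  fit2 <- fit_arm_model(tab, "experimental", week = week,
                        covariates = covariates)
  curve <- net_gain(fit1, fit2, grid, profile, level = level)
  thr <- benefit_threshold(curve)
  semi <- NULL
  if (!is.null(kernel)) {
    semi <- compare_bandwidths(tab, fit1, fit2, grid = grid,
                               bandwidths = bandwidths, profile = profile,
                               spec = kernel)
  }
  structure(list(fits = list(standard = fit1, experimental = fit2),
                 curve = curve, threshold = thr, semiparametric = semi,
                 profile = profile, level = level, week = week,
                 table = tab),
            class = "netgain")
}

#' @export
print.netgain <- function(x, ...) {
  cat("Individualized net-gain fit (experimental minus standard dose)\n")
  cat("  final week:", x$week,
      "; n =", x$fits$standard$n, "+", x$fits$experimental$n,
      "participants\n")
  cf <- coef(x)
  cat("  net-gain line: ",
      format(cf["(Intercept)", "difference"], digits = 4), " + ",
      format(cf["baseline", "difference"], digits = 4),
      " * baseline (ng/ml)\n", sep = "")
  cat("  benefit threshold (", x$level * 100, "% band excludes zero): ",
      sep = "")
  if (is.na(x$threshold["upper"])) cat("none within observed range\n")
  else cat(format(x$threshold["upper"], digits = 4), "ng/ml and above\n")
  if (!is.null(x$semiparametric)) {
    cat("  semi-parametric curves at h =",
        paste(names(x$semiparametric), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.netgain <- function(object, ...) {
  b1 <- object$fits$standard$coefficients
  b2 <- object$fits$experimental$coefficients
  cbind(standard = b1, experimental = b2, difference = b2 - b1)
}

#' @export
summary.netgain <- function(object, ...) {
  structure(list(coef = coef(object), threshold = object$threshold,
                 level = object$level, curve = object$curve,
                 fits = object$fits), class = "summary.netgain")
}

#' @export
print.summary.netgain <- function(x, ...) {
  cat("Per-arm coefficients (final-week outcome model):\n")
  print(round(x$coef, 4))
  cat("\nNet gain across the baseline grid (", x$level * 100,
      "% pointwise band):\n", sep = "")
  q <- x$curve[round(seq(1, nrow(x$curve), length.out = 5)), ]
  print(round(as.data.frame(q), 3), row.names = FALSE)
  cat("\nBenefit thresholds: upper =",
      format(x$threshold["upper"], digits = 4),
      ", lower =", format(x$threshold["lower"], digits = 4), "ng/ml\n")
  invisible(x)
}

#' Predict the net gain at new baseline values
#'
#' @param object a [netgain()] fit.
#' @param newdata numeric vector of baseline 25(OH)D values (or a data
#'   frame with a `baseline` column).
#' @param ... unused.
#' @return data frame with `baseline`, `estimate`, `se`, `ci_low`,
#'   `ci_high`.
#' @export
predict.netgain <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(as.data.frame(object$curve))
  x <- if (is.data.frame(newdata)) newdata$baseline else as.numeric(newdata)
  cv <- net_gain(object$fits$standard, object$fits$experimental,
                 sort(unique(x)), object$profile, level = object$level)
  out <- as.data.frame(cv)
  out[match(x, out$baseline), , drop = FALSE]
}

#' @export
residuals.netgain <- function(object, ...) {
  list(standard = stats::residuals(object$fits$standard$fit),
       experimental = stats::residuals(object$fits$experimental$fit))
}

#' Plot a fitted net-gain model
#'
#' `which = "netgain"` draws the net-gain curve with its pointwise band,
#' the zero line, the benefit threshold, and any semi-parametric curves;
#' `which = "change"` draws the two per-arm predicted change-from-baseline
#' curves with marginal bands.
#'
#' @param x a [netgain()] fit.
#' @param which `"netgain"` or `"change"`.
#' @param ... passed to the underlying plot.
#' @export
plot.netgain <- function(x, which = c("netgain", "change"), ...) {
  which <- match.arg(which)
  if (which == "netgain") {
    plot(x$curve, main = "Net gain: experimental minus standard dose", ...)
    if (!is.na(x$threshold["upper"])) {
      graphics::abline(v = x$threshold["upper"], col = "grey40", lty = 2)
    }
    if (!is.null(x$semiparametric)) {
      cols <- c("darkorange3", "forestgreen", "purple3")
      for (i in seq_along(x$semiparametric)) {
        plot(x$semiparametric[[i]], add = TRUE, band = FALSE,
             col = cols[(i - 1) %% length(cols) + 1])
      }
    }
  } else {
    ch1 <- predict_change(x$fits$standard, x$curve$baseline, x$profile,
                          level = x$level)
    ch2 <- predict_change(x$fits$experimental, x$curve$baseline, x$profile,
                          level = x$level)
    graphics::plot(range(x$curve$baseline),
                   range(c(ch1$ci_low, ch1$ci_high, ch2$ci_low,
                           ch2$ci_high)),
                   type = "n", xlab = "baseline 25(OH)D (ng/ml)",
                   ylab = "predicted change (ng/ml)",
                   main = "Predicted change from baseline per arm", ...)
    plot(ch1, add = TRUE, col = "grey35")
    plot(ch2, add = TRUE, col = "steelblue4")
    graphics::legend("topright", c("standard", "experimental"),
                     col = c("grey35", "steelblue4"), lwd = 2, bty = "n")
  }
  invisible(x)
}
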