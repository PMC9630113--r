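test_that("per-arm OLS interpolates the noise-free generating line", {
  cfg <- quiet_config(
    n_per_arm = 20, visit_weeks = c(0, 12),
    arm_intercepts = c(standard = 20, experimental = 12),
    arm_baseline_slopes = c(standard = 0.6, experimental = 0.95))
  tab <- make_table(cfg, seed = 14)
  f1 <- fit_arm_model(tab, "standard")
  expect_equal(unname(f1$coefficients["(Intercept)"]), 20, tolerance = 1e-6)
  expect_equal(unname(f1$coefficients["baseline"]), 0.6, tolerance = 1e-6)
  f2 <- fit_arm_model(tab, "experimental")
  expect_equal(unname(f2$coefficients["baseline"]), 0.95, tolerance = 1e-6)
  expect_equal(f1$covariance, t(f1$covariance))
})

test_that("underdetermined arm fits are refused", {
  tab <- make_table(steenhoff_like_config(n_per_arm = 4), seed = 15)
  expect_error(fit_arm_model(tab, "standard"), "cannot support")
})

test_that("baseline slopes are recovered at large n", {
  tab <- make_table(steenhoff_like_config(n_per_arm = 500), seed = 16)
  f1 <- fit_arm_model(tab, "standard", week = 12)
  f2 <- fit_arm_model(tab, "experimental", week = 12)
  expect_lt(abs(f1$coefficients[["baseline"]] - 0.6), 0.05)
  expect_lt(abs(f2$coefficients[["baseline"]] - 0.95), 0.05)
})

test_that("net gain of identical fits is exactly zero; swapping negates it", {
  tab <- make_table(steenhoff_like_config(), seed = 17)
  f1 <- fit_arm_model(tab, "standard")
  f2 <- fit_arm_model(tab, "experimental")
  prof <- list(age = 20, sexfemale = 0.5, body_size = 58)
  grid <- seq(15, 55, length.out = 41)
  self <- net_gain(f1, f1, grid, prof)
  expect_equal(self$estimate, rep(0, 41))
  ab <- net_gain(f1, f2, grid, prof)
  ba <- net_gain(f2, f1, grid, prof)
  expect_equal(ba$estimate, -ab$estimate, tolerance = 1e-12)
  expect_equal(ba$ci_low, -ab$ci_high, tolerance = 1e-12)
  expect_equal(ba$ci_high, -ab$ci_low, tolerance = 1e-12)
  expect_true(all(ab$ci_low <= ab$estimate & ab$estimate <= ab$ci_high))
})

test_that("the parametric net-gain curve is affine in the baseline", {
  tab <- make_table(steenhoff_like_config(), seed = 18)
  fit <- netgain(tab)
  d2 <- diff(fit$curve$estimate, differences = 2)
  expect_lt(max(abs(d2)), 1e-9)
  # and the line equals the coefficient differences applied to x
  cf <- coef(fit)
  prof <- fit$profile
  x <- fit$curve$baseline
  manual <- cf["(Intercept)", "difference"] +
    cf["baseline", "difference"] * x +
    cf["age", "difference"] * prof$age +
    cf["sexfemale", "difference"] * prof$sexfemale +
    cf["body_size", "difference"] * prof$body_size
  expect_equal(fit$curve$estimate, manual, tolerance = 1e-10)
})

test_that("delta-method interval matches the closed form for linear contrasts", {
  ci <- delta_method_ci(c(1, 0, 0), c(2, 5, 7), diag(3), level = 0.95)
  expect_equal(as.numeric(ci), c(2 - 1.959964, 2 + 1.959964),
               tolerance = 1e-6)
  # degenerate covariance collapses the interval onto the point
  ci0 <- delta_method_ci(c(1, 2), c(3, 4), matrix(0, 2, 2))
  expect_equal(as.numeric(ci0), c(11, 11))
  # arbitrary PSD covariance: manual quadratic form
  set.seed(19)
  A <- matrix(rnorm(16), 4)
  V <- crossprod(A)
  ct <- rnorm(4)
  b <- rnorm(4)
  ci2 <- delta_method_ci(ct, b, V, level = 0.9)
  hw <- qnorm(0.95) * sqrt(drop(t(ct) %*% V %*% ct))
  expect_equal(as.numeric(ci2), sum(ct * b) + c(-hw, hw), tolerance = 1e-12)
})

test_that("benefit threshold follows the uniform-tail rule", {
  grid <- seq(10, 50, by = 1)
  mk <- function(lo, hi) {
    netgain:::netgain_curve(grid, (lo + hi) / 2, (hi - lo) / 4, lo, hi,
                            level = 0.95, profile = list(),
                            method_tag = "parametric")
  }
  # significant everywhere -> first grid point
  all_pos <- mk(rep(1, 41), rep(3, 41))
  expect_equal(unname(benefit_threshold(all_pos)["upper"]), 10)
  # never significant -> none
  never <- mk(rep(-1, 41), rep(1, 41))
  expect_true(is.na(benefit_threshold(never)["upper"]))
  expect_true(is.na(benefit_threshold(never)["lower"]))
  # band excludes zero from x = 30 onwards
  lo <- ifelse(grid >= 30, 0.5, -0.5)
  tail_pos <- mk(lo, lo + 2)
  expect_equal(unname(benefit_threshold(tail_pos)["upper"]), 30)
  # a significant island that does not persist: uniform rule ignores it,
  # first-crossing picks it up
  island <- lo
  island[grid %in% 18:20] <- 0.4
  island[grid %in% 25:28] <- -0.3
  isl <- mk(island, island + 2)
  expect_equal(unname(benefit_threshold(isl)["upper"]), 30)
  expect_equal(unname(benefit_threshold(isl, "first_crossing")["upper"]), 18)
  # reverse preference: upper band below zero at low baselines
  lo2 <- ifelse(grid <= 20, -3, -0.5)
  hi2 <- ifelse(grid <= 20, -1, 0.5)
  rev_thr <- benefit_threshold(mk(lo2, hi2))
  expect_equal(unname(rev_thr["lower"]), 20)
})

test_that("predicted change is m(x) - x with the model's slope sign", {
  f <- fake_arm_model("standard",
                      c("(Intercept)" = 20, baseline = 0.6))
  prof <- list()
  grid <- seq(0, 50, by = 5)
  ch <- predict_change(f, grid, prof)
  expect_equal(ch$estimate, 20 - 0.4 * grid)
  expect_true(all(diff(ch$estimate) < 0))  # slope < 1: decreasing
  f2 <- fake_arm_model("experimental",
                       c("(Intercept)" = 5, baseline = 1.2))
  ch2 <- predict_change(f2, grid, prof)
  expect_true(all(diff(ch2$estimate) > 0))  # slope > 1: increasing
})

test_that("per-arm change curves show the crossing pattern of the default design", {
  cfg <- steenhoff_like_config()
  # generating slopes: standard 0.6 (< 1, change decreases with baseline),
  # experimental 0.95 with the intercept advantage reversing at high baseline
  tab <- make_table(cfg, seed = 20)
  fit <- netgain(tab)
  ch1 <- predict_change(fit$fits$standard, c(20, 50), fit$profile)
  expect_gt(ch1$estimate[1], ch1$estimate[2])
  expect_gt(true_net_gain(cfg, 50), true_net_gain(cfg, 20))
})

test_that("bivariate net gain collapses when age slopes agree and recovers a difference", {
  cf1 <- c("(Intercept)" = 20, baseline = 0.6, age = 0.3)
  cf2 <- c("(Intercept)" = 12, baseline = 0.95, age = 0.3)
  f1 <- fake_arm_model("standard", cf1)
  f2 <- fake_arm_model("experimental", cf2)
  prof <- list(age = 25, sexfemale = 0, body_size = 0)
  surf <- net_gain_bivariate(f1, f2, grid_x = c(30, 40), grid_a = c(10, 30, 50),
                             profile = prof)
  # equal age slopes: constant in age
  for (x in c(30, 40)) {
    v <- surf$estimate[surf$baseline == x]
    expect_equal(max(v) - min(v), 0, tolerance = 1e-12)
  }
  # single age at the profile value reduces to the univariate curve
  uni <- net_gain(f1, f2, c(30, 40), prof)
  red <- net_gain_bivariate(f1, f2, c(30, 40), grid_a = 25, profile = prof)
  expect_equal(red$estimate, uni$estimate)
  # differing age slopes reappear as the age gradient of the surface
  cf2b <- cf2
  cf2b["age"] <- 0.5
  surf2 <- net_gain_bivariate(f1, fake_arm_model("experimental", cf2b),
                              c(30, 40), c(10, 30), prof)
  d <- surf2$estimate[surf2$age == 30] - surf2$estimate[surf2$age == 10]
  expect_equal(d, rep(0.2 * 20, 2), tolerance = 1e-12)
  # fits without an age term are rejected
  f_noage <- fake_arm_model("standard", c("(Intercept)" = 1, baseline = 1))
  expect_error(net_gain_bivariate(f_noage, f_noage, 30, 20, prof),
               "age regressor")
})

test_that("delta-method band agrees with a participant bootstrap", {
  cfg <- synthetic_config(n_per_arm = 100, visit_weeks = c(0, 12))
  tab <- make_table(cfg, seed = 22)
  fit <- netgain(tab)
  prof <- fit$profile
  grid <- quantile(tab$baseline, c(0.2, 0.35, 0.5, 0.65, 0.8), names = FALSE)
  para <- net_gain(fit$fits$standard, fit$fits$experimental, grid, prof)
  set.seed(23)
  boot <- replicate(1000, {
    ids1 <- sample(unique(tab$participant_id[tab$arm == "standard"]),
                   replace = TRUE)
    ids2 <- sample(unique(tab$participant_id[tab$arm == "experimental"]),
                   replace = TRUE)
    rs <- function(ids) {
      d <- tab[match(ids, tab$participant_id), ]
      d$participant_id <- paste0(seq_along(ids))
      d
    }
    b <- rbind(rs(ids1), rs(ids2))
    g1 <- fit_arm_model(b, "standard")
    g2 <- fit_arm_model(b, "experimental")
    net_gain(g1, g2, grid, prof)$estimate
  })
  boot_hw <- qnorm(0.975) * apply(boot, 1, sd)
  delta_hw <- (para$ci_high - para$ci_low) / 2
  expect_true(all(abs(boot_hw - delta_hw) / delta_hw < 0.15))
})

test_that("net-gain error at the grid midpoint shrinks with sample size", {
  cfg0 <- function(n) synthetic_config(n_per_arm = n, visit_weeks = c(0, 12))
  x0 <- 35
  mae <- vapply(c(50, 200, 1000), function(n) {
    errs <- vapply(1:30, function(s) {
      tab <- make_table(cfg0(n), seed = 4000 + s)
      fit <- netgain(tab, grid = c(x0 - 1, x0, x0 + 1))
      abs(fit$curve$estimate[2] - true_net_gain(cfg0(n), x0))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("mismatched regressor sets are refused", {
  f1 <- fake_arm_model("standard", c("(Intercept)" = 1, baseline = 1))
  f2 <- fake_arm_model("experimental",
                       c("(Intercept)" = 1, baseline = 1, age = 0))
  expect_error(net_gain(f1, f2, c(10, 20), list()), "mismatched")
})

test_that("netgain object methods are coherent", {
  tr <- simulate_trial(steenhoff_like_config(), seed = 24)
  fit <- netgain(tr)
  expect_s3_class(fit, "netgain")
  expect_output(print(fit), "net-gain line")
  expect_output(print(summary(fit)), "Benefit thresholds")
  cf <- coef(fit)
  expect_equal(colnames(cf), c("standard", "experimental", "difference"))
  pr <- predict(fit, newdata = c(25, 35, 45))
  expect_equal(pr$baseline, c(25, 35, 45))
  expect_equal(pr$estimate,
               cf["(Intercept)", "difference"] +
                 cf["baseline", "difference"] * c(25, 35, 45) +
                 cf["age", "difference"] * fit$profile$age +
                 cf["sexfemale", "difference"] * fit$profile$sexfemale +
                 cf["body_size", "difference"] * fit$profile$body_size,
               tolerance = 1e-10)
  r <- residuals(fit)
  expect_named(r, c("standard", "experimental"))
  expect_equal(length(r$standard), 30)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  plot(fit)
  plot(fit, which = "change")
  grDevices::dev.off()
  expect_true(file.exists(path))
})
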