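#' Descriptive summary of a trial
#'
#' Per arm and visit week: n, mean and standard deviation (n-1
#' denominator) of the serum 25(OH)D concentration; the max-minus-min
#' range at the final week per arm (a simple heterogeneity indicator);
#' and a cohort summary of age, sex and body size.
#'
#' @param dataset a [trial_dataset()].
#' @return list with elements `by_arm_week` (data frame), `final_range`
#'   (named numeric per arm) and `cohort` (list), of class
#'   `trial_summary`.
#' @export
describe_trial <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  r <- dataset$records[!is.na(dataset$records$serum_25ohd), , drop = FALSE]
  if (!nrow(r)) stop("dataset has no observed outcomes", call. = FALSE)
  grp <- split(r, list(r$arm, r$visit_week), drop = TRUE, sep = "|")
  baw <- do.call(rbind, lapply(names(grp), function(g) {
    d <- grp[[g]]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    data.frame(arm = parts[1], visit_week = as.numeric(parts[2]),
               n = nrow(d), mean = mean(d$serum_25ohd),
               sd = if (nrow(d) > 1) stats::sd(d$serum_25ohd) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  baw <- baw[order(baw$arm, baw$visit_week), , drop = FALSE]
  rownames(baw) <- NULL
  fw <- max(r$visit_week)
  fin <- r[r$visit_week == fw, , drop = FALSE]
  final_range <- tapply(fin$serum_25ohd, droplevels(fin$arm),
                        function(y) diff(range(y)))
  first <- r[!duplicated(r$participant_id), , drop = FALSE]
  cohort <- list(
    n = nrow(first),
    age_mean = mean(first$age), age_sd = stats::sd(first$age),
    female_fraction = mean(first$sex == "female"),
    body_size_tag = dataset$body_size_tag,
    body_size_mean = mean(first$body_size),
    body_size_sd = stats::sd(first$body_size))
  structure(list(by_arm_week = baw,
                 final_range = unclass(final_range),
                 final_week = fw, cohort = cohort,
                 unit = dataset$concentration_unit),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("Serum 25(OH)D by arm and week (", x$unit, "):\n", sep = "")
  print(transform(x$by_arm_week, mean = round(mean, 2), sd = round(sd, 2)),
        row.names = FALSE)
  cat("Final-week max-min range:",
      paste(names(x$final_range), round(x$final_range, 1),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf(
    "Cohort: n=%d, age %.1f +/- %.1f y, %.0f%% female, %s %.1f +/- %.1f\n",
    x$cohort$n, x$cohort$age_mean, x$cohort$age_sd,
    100 * x$cohort$female_fraction, x$cohort$body_size_tag,
    x$cohort$body_size_mean, x$cohort$body_size_sd))
  invisible(x)
}

#' Run the full outcome-based analysis pipeline
#'
#' Executes, in order: completer filtering, descriptive summary, the
#' preliminary linear mixed model with its dose contrast, the
#' Bonferroni-adjusted subgroup analysis (skipped with a recorded reason
#' when a stratum is empty, e.g. when an inclusion criterion keeps all
#' baselines below the cut-off), the parametric net-gain curve with
#' benefit threshold, and the semi-parametric curves at each bandwidth.
#' Optionally writes the tables as CSV and the summary as JSON-like text
#' under `out_dir`.
#'
#' @param data a [trial_dataset()], or a path to a CSV readable by
#'   [read_trial_csv()] (then `mapping`/`unit` apply).
#' @param required_weeks weeks a completer must have; default baseline
#'   plus the final observed week.
#' @param cutoff subgroup cut-off, ng/ml.
#' @param alpha family-wise level for the subgroup analysis.
#' @param level confidence level for contrasts and bands.
#' @param include_time keep the visit-week factor in the mixed model.
#' @param bandwidths semi-parametric bandwidths.
#' @param kernel template [kernel_spec()].
#' @param mapping,unit passed to [read_trial_csv()] when `data` is a path.
#' @param out_dir optional output directory for CSV artifacts.
#' @return list of class `netgain_report` with elements `descriptives`,
#'   `lmm`, `dose_contrast`, `subgroups` (or a skip reason), `fit` (the
#'   [netgain()] object), `threshold`, `semiparametric`, `log` (character
#'   vector of decisions taken).
#' @export
run_full_analysis <- function(data, required_weeks = NULL, cutoff = 30,
                              alpha = 0.05, level = 0.95,
                              include_time = TRUE,
                              bandwidths = c(0.6, 0.8),
                              kernel = kernel_spec(),
                              mapping = NULL, unit = "ng/ml",
                              out_dir = NULL) {
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  if (is.character(data)) {
    note("ingest: reading CSV ", data, " (unit ", unit, ")")
    data <- read_trial_csv(data, mapping = mapping, unit = unit)
  }
  stopifnot(inherits(data, "trial_dataset"))
  if (is.null(required_weeks)) {
    required_weeks <- c(0, max(data$records$visit_week))
  }
  n_before <- data$n
  data <- withCallingHandlers(
    complete_cases(data, required_weeks),
    message = function(m) {
      note(sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  note("completers: ", data$n, " of ", n_before, " participants retained ",
       "(required weeks ", paste(required_weeks, collapse = ","), ")")
  descr <- describe_trial(data)
  tab <- to_analysis_table(data)
  lmm <- fit_lmm(tab, include_time = include_time)
  dc <- dose_contrast(lmm, level = level)
  note(sprintf("dose contrast: %.2f ng/ml [%.2f, %.2f], p = %.3f",
               dc["estimate"], dc["ci_low"], dc["ci_high"], dc["p_value"]))
  subgroups <- tryCatch(
    subgroup_analysis(tab, cutoff = cutoff, alpha = alpha,
                      include_time = include_time),
    error = function(e) {
      note("subgroup analysis skipped: ", conditionMessage(e))
      structure(conditionMessage(e), class = "subgroup_skip")
    })
  fit <- netgain(tab, level = level, kernel = kernel,
                 bandwidths = bandwidths)
  thr <- fit$threshold
  note("benefit threshold (upper): ",
       if (is.na(thr["upper"])) "none in observed range"
       else paste0(format(thr["upper"], digits = 4), " ng/ml"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(descr$by_arm_week,
                     file.path(out_dir, "descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(fit$curve),
                     file.path(out_dir, "netgain_parametric.csv"),
                     row.names = FALSE)
    if (!inherits(subgroups, "subgroup_skip")) {
      utils::write.csv(subgroups, file.path(out_dir, "subgroups.csv"),
                       row.names = FALSE)
    }
    for (h in names(fit$semiparametric)) {
      utils::write.csv(as.data.frame(fit$semiparametric[[h]]),
                       file.path(out_dir,
                                 paste0("netgain_semiparametric_h",
                                        trimws(h), ".csv")),
                       row.names = FALSE)
    }
    note("artifacts written to ", out_dir)
  }
  structure(list(descriptives = descr, lmm = lmm, dose_contrast = dc,
                 subgroups = subgroups, fit = fit, threshold = thr,
                 semiparametric = fit$semiparametric, log = log),
            class = "netgain_report")
}

#' @export
print.netgain_report <- function(x, ...) {
  print(x$descriptives)
  cat("\n")
  cat(sprintf(
    "Dose contrast (experimental - standard): %.2f ng/ml [%.2f, %.2f], p = %.3f\n",
    x$dose_contrast["estimate"], x$dose_contrast["ci_low"],
    x$dose_contrast["ci_high"], x$dose_contrast["p_value"]))
  if (inherits(x$subgroups, "subgroup_skip")) {
    cat("Subgroup analysis skipped:", unclass(x$subgroups), "\n")
  } else {
    cat("Subgroup dose contrasts (Bonferroni-adjusted CIs):\n")
    print(transform(x$subgroups,
                    estimate = round(estimate, 2),
                    ci_low = round(ci_low, 2), ci_high = round(ci_high, 2),
                    p_value = round(p_value, 3)),
          row.names = FALSE)
  }
  cat("\n")
  print(x$fit)
  invisible(x)
}
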