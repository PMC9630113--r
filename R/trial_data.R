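#' Unit conversion for serum 25(OH)D concentrations
#'
#' Converts between the two conventional units for circulating
#' 25-hydroxyvitamin D: ng/ml and nmol/L. One ng/ml equals 2.5 nmol/L, so
#' nmol/L values are divided by 2.5 and ng/ml values multiplied by 2.5.
#'
#' @param value numeric vector of concentrations.
#' @param from,to unit strings, one of `"ng/ml"` or `"nmol/L"`.
#' @return numeric vector in the `to` unit.
#' @examples
#' convert_concentration(75, "nmol/L", "ng/ml") # 30
#' @export
convert_concentration <- function(value, from, to) {
  from <- match_unit(from)
  to <- match_unit(to)
  if (from == to) return(value)
  if (from == "nmol/L") value / 2.5 else value * 2.5
}

match_unit <- function(u) {
  known <- c("ng/ml", "nmol/L")
  hit <- known[tolower(known) == tolower(u)]
  if (length(hit) != 1L) {
    stop("unknown concentration unit: '", u, "' (expected ng/ml or nmol/L)",
         call. = FALSE)
  }
  hit
}

#' Unit conversion for cholecalciferol doses
#'
#' One microgram of vitamin D3 per day corresponds to 40 IU/day.
#'
#' @param value numeric vector of daily doses.
#' @param from,to unit strings, one of `"ug/day"` or `"IU/day"` (the
#'   micro sign is also accepted).
#' @return numeric vector in the `to` unit.
#' @examples
#' convert_dose(80, "ug/day", "IU/day") # 3200
#' @export
convert_dose <- function(value, from, to) {
  from <- match_dose_unit(from)
  to <- match_dose_unit(to)
  if (from == to) return(value)
  if (from == "ug/day") value * 40 else value / 40
}

match_dose_unit <- function(u) {
  u <- tolower(u)
  u <- gsub("µ", "u", u)
  if (u %in% c("ug/day", "mcg/day")) return("ug/day")
  if (u == "iu/day") return("IU/day")
  stop("unknown dose unit: '", u, "' (expected ug/day or IU/day)",
       call. = FALSE)
}

#' Construct a two-arm repeated-measures trial dataset
#'
#' Bundles long-format participant records with unit and dosing metadata.
#' Records must contain one row per participant per visit with the serum
#' 25(OH)D outcome and baseline covariates. Arm labels are mapped onto the
#' canonical levels `standard` (reference) and `experimental`.
#'
#' @param records data frame with columns `participant_id`, `arm`,
#'   `visit_week`, `serum_25ohd`, `age`, `sex`, `body_size` (extra columns
#'   are kept).
#' @param concentration_unit unit of the `serum_25ohd` column.
#' @param dose_by_arm named numeric vector, IU/day per arm
#'   (names `standard`, `experimental`); optional metadata.
#' @param body_size_tag `"weight_kg"` or `"bmi"`, recording what the
#'   `body_size` column measures.
#' @return object of class `trial_dataset`: a list with elements
#'   `records`, `concentration_unit`, `dose_by_arm`, `body_size_tag`, `n`.
#' @export
trial_dataset <- function(records, concentration_unit = "ng/ml",
                          dose_by_arm = NULL, body_size_tag = "weight_kg") {
  stopifnot(is.data.frame(records))
  needed <- c("participant_id", "arm", "visit_week", "serum_25ohd",
              "age", "sex", "body_size")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records lack required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  body_size_tag <- match.arg(body_size_tag, c("weight_kg", "bmi"))
  records$participant_id <- as.character(records$participant_id)
  records$arm <- canonical_arm(records$arm)
  records$sex <- factor(as.character(records$sex), levels = c("male", "female"))
  if (anyNA(records$sex)) {
    stop("sex must be coded 'male'/'female'", call. = FALSE)
  }
  records <- records[order(records$participant_id, records$visit_week), ,
                     drop = FALSE]
  rownames(records) <- NULL
  ds <- structure(
    list(records = records,
         concentration_unit = match_unit(concentration_unit),
         dose_by_arm = dose_by_arm,
         body_size_tag = body_size_tag,
         n = length(unique(records$participant_id))),
    class = "trial_dataset")
  validate_trial_dataset(ds)
  ds
}

canonical_arm <- function(arm) {
  if (is.factor(arm)) arm <- as.character(arm)
  if (is.numeric(arm)) {
    arm <- c("standard", "experimental")[arm]
  } else {
    arm <- tolower(arm)
    arm[arm %in% c("1", "control", "low", "standard")] <- "standard"
    arm[arm %in% c("2", "treatment", "high", "experimental")] <- "experimental"
  }
  bad <- setdiff(unique(arm), c("standard", "experimental"))
  if (length(bad)) {
    stop("unrecognized arm label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(arm, levels = c("standard", "experimental"))
}

validate_trial_dataset <- function(ds) {
  r <- ds$records
  obs <- r[!is.na(r$serum_25ohd), , drop = FALSE]
  if (nrow(obs) && any(obs$serum_25ohd <= 0)) {
    stop("serum 25(OH)D concentrations must be positive", call. = FALSE)
  }
  arms_per_id <- tapply(as.character(r$arm), r$participant_id,
                        function(a) length(unique(a)))
  if (any(arms_per_id > 1)) {
    stop("arm must be constant within participant", call. = FALSE)
  }
  if (nlevels(droplevels(r$arm)) != 2L) {
    stop("trial must contain exactly two arms", call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.trial_dataset <- function(x, ...) {
  r <- x$records
  cat("Two-arm trial dataset:", x$n, "participants,",
      nrow(r), "records (", x$concentration_unit, ")\n")
  cat("  visit weeks:", paste(sort(unique(r$visit_week)), collapse = ", "), "\n")
  cat("  per arm:",
      paste(names(table(r$arm[!duplicated(r$participant_id)])),
            table(r$arm[!duplicated(r$participant_id)]),
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$dose_by_arm)) {
    cat("  dose (IU/day):",
        paste(names(x$dose_by_arm), x$dose_by_arm, sep = "=", collapse = ", "),
        "\n")
  }
  cat("  body size measured as:", x$body_size_tag, "\n")
  invisible(x)
}

#' Read a two-arm trial from CSV
#'
#' Generic CSV ingestion with a user-supplied column mapping so that
#' differently labelled deposited datasets can be read without reshaping.
#' Rows whose outcome value cannot be parsed as a positive number are
#' dropped with a message. Concentrations are converted to ng/ml on read
#' if declared in nmol/L.
#'
#' @param path path to a comma-separated file with a header row (UTF-8).
#' @param mapping named character vector mapping canonical names
#'   (`participant_id`, `arm`, `visit_week`, `serum_25ohd`, `age`, `sex`,
#'   `body_size`) to the file's column names.
#' @param unit concentration unit of the outcome column in the file.
#' @param dose_by_arm optional named numeric, IU/day per arm.
#' @param body_size_tag `"weight_kg"` or `"bmi"`.
#' @return a [trial_dataset()] in ng/ml.
#' @export
read_trial_csv <- function(path, mapping = NULL, unit = "ng/ml",
                           dose_by_arm = NULL, body_size_tag = "weight_kg") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  canonical <- c("participant_id", "arm", "visit_week", "serum_25ohd",
                 "age", "sex", "body_size")
  if (is.null(mapping)) {
    mapping <- stats::setNames(canonical, canonical)
  }
  missing_map <- setdiff(canonical, names(mapping))
  if (length(missing_map)) {
    stop("mapping lacks entries for: ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(unname(mapping[canonical]), names(raw))
  if (length(absent)) {
    stop("mapped column(s) absent from file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  rec <- stats::setNames(raw[, unname(mapping[canonical]), drop = FALSE],
                         canonical)
  rec$visit_week <- as.numeric(rec$visit_week)
  y <- suppressWarnings(as.numeric(rec$serum_25ohd))
  bad <- !is.na(rec$serum_25ohd) & is.na(y)
  unusable <- is.na(y) | y <= 0
  if (any(unusable)) {
    message("read_trial_csv: excluding ", sum(unusable),
            " row(s) with missing or unparseable outcome",
            if (any(bad)) paste0(" (", sum(bad), " unparseable)") else "")
    rec <- rec[!unusable, , drop = FALSE]
    y <- y[!unusable]
  }
  if (!nrow(rec) || !any(rec$visit_week > 0)) {
    stop("no usable post-baseline outcome rows: empty trial", call. = FALSE)
  }
  rec$serum_25ohd <- convert_concentration(y, unit, "ng/ml")
  rec$age <- as.numeric(rec$age)
  rec$body_size <- as.numeric(rec$body_size)
  trial_dataset(rec, concentration_unit = "ng/ml",
                dose_by_arm = dose_by_arm, body_size_tag = body_size_tag)
}

#' Restrict a trial to completers
#'
#' Keeps only participants with an observed outcome at every required
#' week (the completer analysis set). Idempotent; the number of excluded
#' participants is reported with a message.
#'
#' @param dataset a [trial_dataset()].
#' @param required_weeks numeric vector of weeks each retained participant
#'   must have an outcome for, e.g. `c(0, 12)`.
#' @return a filtered [trial_dataset()].
#' @export
complete_cases <- function(dataset, required_weeks) {
  stopifnot(inherits(dataset, "trial_dataset"), length(required_weeks) >= 1)
  r <- dataset$records
  ok_id <- vapply(split(r, r$participant_id), function(d) {
    all(required_weeks %in% d$visit_week[!is.na(d$serum_25ohd)])
  }, logical(1))
  keep <- names(ok_id)[ok_id]
  dropped <- dataset$n - length(keep)
  if (dropped > 0) {
    message("complete_cases: excluded ", dropped,
            " participant(s) without outcomes at all required weeks")
  }
  out <- r[r$participant_id %in% keep, , drop = FALSE]
  trial_dataset(out, concentration_unit = dataset$concentration_unit,
                dose_by_arm = dataset$dose_by_arm,
                body_size_tag = dataset$body_size_tag)
}

#' Reshape a trial into the modelling table
#'
#' Produces one row per participant per post-baseline visit, carrying the
#' visit outcome, the week-0 value as the `baseline` covariate, the
#' change from baseline, and a combined `week_arm` factor (visit week
#' crossed with arm) used by the interaction models.
#'
#' @param dataset a [trial_dataset()], complete-case filtered so every
#'   participant has a baseline record.
#' @return data frame of class `c("netgain_table", "data.frame")` with
#'   columns `participant_id`, `arm`, `visit_week`, `outcome`, `baseline`,
#'   `change`, `week_arm`, `age`, `sex`, `body_size`; the body-size tag is
#'   kept as attribute `body_size_tag`.
#' @export
to_analysis_table <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  r <- dataset$records
  base <- r[r$visit_week == 0 & !is.na(r$serum_25ohd), , drop = FALSE]
  post <- r[r$visit_week > 0 & !is.na(r$serum_25ohd), , drop = FALSE]
  no_base <- setdiff(unique(post$participant_id), base$participant_id)
  if (length(no_base)) {
    stop("participant(s) lack a baseline record: ",
         paste(utils::head(no_base, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(post$participant_id, base$participant_id)
  tab <- data.frame(
    participant_id = post$participant_id,
    arm = post$arm,
    visit_week = post$visit_week,
    outcome = post$serum_25ohd,
    baseline = base$serum_25ohd[idx],
    age = post$age,
    sex = post$sex,
    body_size = post$body_size,
    stringsAsFactors = FALSE)
  tab$change <- tab$outcome - tab$baseline
  tab$week_arm <- interaction(tab$visit_week, tab$arm, sep = ":", drop = TRUE)
  attr(tab, "body_size_tag") <- dataset$body_size_tag
  class(tab) <- c("netgain_table", class(tab))
  tab
}
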