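#' Construct an N-of-1 trial dataset
#'
#' Bundles long-format observations from a series of single-subject crossover
#' trials into a validated container. Each row is one measurement occasion for
#' one subject: an opaque subject label, a 1-based within-subject time index,
#' a condition label, and a continuous outcome (possibly missing). One
#' condition is designated the reference (control/baseline); every other
#' condition receives its own 0/1 indicator when a design matrix is built.
#'
#' Missing outcomes are retained in the container but excluded from all model
#' fits (complete-case per observation); no imputation is performed.
#'
#' @param data A data.frame with columns `subject`, `time`, `condition`,
#'   `outcome` (extra columns are dropped). `time` must be a positive integer,
#'   unique within subject. `outcome` may be `NA`.
#' @param conditions Optional character vector declaring the condition set and
#'   its order. Defaults to first-appearance order in `data`.
#' @param reference Optional reference condition; defaults to the first element
#'   of `conditions`. Moved to the front of the condition set.
#' @return An object of class `trial_dataset`: a list with elements `data`
#'   (the cleaned observation table, ordered by subject then time),
#'   `conditions` (reference first) and `subjects` (first-appearance order).
#' @examples
#' d <- trial_dataset(data.frame(
#'   subject = c("a", "a", "b", "b"), time = c(1, 2, 1, 2),
#'   condition = c("control", "treatment", "control", "treatment"),
#'   outcome = c(5, 3, 6, 4)))
#' n_subjects(d)
#' @export
trial_dataset <- function(data, conditions = NULL, reference = NULL) {
  req <- c("subject", "time", "condition", "outcome")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- data.frame(subject = as.character(data$subject),
                  time = data$time,
                  condition = as.character(data$condition),
                  outcome = as.numeric(data$outcome),
                  stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("dataset must contain at least one observation")
  if (any(is.na(d$subject)) || any(is.na(d$condition))) {
    stop("subject and condition labels must be non-missing")
  }
  if (any(is.na(d$time)) || any(d$time < 1) || any(d$time != round(d$time))) {
    stop("time must be an integer >= 1")
  }
  d$time <- as.integer(d$time)

  subjects <- unique(d$subject)
  for (s in subjects) {
    ti <- d$time[d$subject == s]
    if (anyDuplicated(ti)) stop("duplicate time index within subject '", s, "'")
  }
  n_nonmiss <- tapply(!is.na(d$outcome), d$subject, sum)
  if (any(n_nonmiss == 0)) {
    stop("every subject needs at least one non-missing outcome; violated by: ",
         paste(names(n_nonmiss)[n_nonmiss == 0], collapse = ", "))
  }

  seen <- unique(d$condition)
  if (is.null(conditions)) conditions <- seen
  conditions <- as.character(conditions)
  extra <- setdiff(seen, conditions)
  if (length(extra) > 0) {
    stop("condition(s) not in the declared condition set: ",
         paste(extra, collapse = ", "))
  }
  if (is.null(reference)) reference <- conditions[1]
  if (!reference %in% conditions) {
    stop("reference condition '", reference, "' is not in the condition set")
  }
  conditions <- c(reference, setdiff(conditions, reference))

  ord <- order(match(d$subject, subjects), d$time)
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL

  structure(list(data = d, conditions = conditions, subjects = subjects),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$data$outcome))
  cat(sprintf("N-of-1 trial dataset: %d subjects, %d observations (%d missing)\n",
              length(x$subjects), nrow(x$data), n_miss))
  cat("conditions:", paste(x$conditions, collapse = ", "),
      sprintf("(reference: %s)\n", x$conditions[1]))
  invisible(x)
}

#' Number of subjects in a trial dataset
#' @param dataset A `trial_dataset`.
#' @return Integer subject count.
#' @export
n_subjects <- function(dataset) length(dataset$subjects)

#' Condition set of a trial dataset (reference first)
#' @param dataset A `trial_dataset`.
#' @return Character vector of condition labels.
#' @export
condition_levels <- function(dataset) dataset$conditions

#' Reference (control/baseline) condition of a trial dataset
#' @param dataset A `trial_dataset`.
#' @return Character scalar.
#' @export
reference_condition <- function(dataset) dataset$conditions[1]

#' Read an N-of-1 trial dataset from a long-format CSV file
#'
#' The canonical on-disk layout is a tidy CSV with a header row and one row
#' per measurement occasion. Empty outcome cells are read as missing
#' observations and retained; any non-empty outcome that fails to parse as a
#' number is an error reported with its file row.
#'
#' @param path Path to a CSV file.
#' @param columns Named character vector mapping the required roles
#'   `subject`, `time`, `condition`, `outcome` to column names in the file,
#'   for files whose headers differ from the defaults.
#' @param conditions,reference Optional declared condition set / reference,
#'   as in [trial_dataset()].
#' @return A `trial_dataset`.
#' @export
read_trial_csv <- function(path,
                           columns = c(subject = "subject", time = "time",
                                       condition = "condition",
                                       outcome = "outcome"),
                           conditions = NULL, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  defaults <- c(subject = "subject", time = "time", condition = "condition",
                outcome = "outcome")
  defaults[names(columns)] <- columns
  columns <- defaults
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols) > 0) {
    stop("format error: column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  out_raw <- trimws(raw[[columns[["outcome"]]]])
  outcome <- rep(NA_real_, length(out_raw))
  nonempty <- !is.na(out_raw) & out_raw != ""
  parsed <- suppressWarnings(as.numeric(out_raw[nonempty]))
  if (anyNA(parsed)) {
    bad <- which(nonempty)[which(is.na(parsed))[1]]
    stop("parse error: non-numeric outcome '", out_raw[bad],
         "' at data row ", bad, " of ", path)
  }
  outcome[nonempty] <- parsed
  trial_dataset(data.frame(subject = raw[[columns[["subject"]]]],
                           time = as.integer(raw[[columns[["time"]]]]),
                           condition = raw[[columns[["condition"]]]],
                           outcome = outcome,
                           stringsAsFactors = FALSE),
                conditions = conditions, reference = reference)
}

#' Write an N-of-1 trial dataset to CSV
#'
#' Inverse of [read_trial_csv()]: `read_trial_csv(write_trial_csv(d, f))`
#' reproduces `d` exactly, including missingness and row order. Outcomes are
#' written with 17 significant digits so doubles round-trip bit-exactly;
#' missing outcomes become empty cells, never sentinel numbers.
#'
#' @param dataset A `trial_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  d <- dataset$data
  out <- ifelse(is.na(d$outcome), "", sprintf("%.17g", d$outcome))
  tab <- data.frame(subject = d$subject, time = d$time,
                    condition = d$condition, outcome = out,
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Build the fixed-effects design from a trial dataset
#'
#' Dummy-codes conditions against the reference: one 0/1 indicator column per
#' non-reference condition (the reference rows are all zeros). Rows with a
#' missing outcome are dropped; remaining rows are ordered by subject (first
#' appearance) then time index. Indicators depend only on condition labels,
#' never on calendar position, so subjects that received conditions in a
#' different order map identically.
#'
#' @param dataset A `trial_dataset`.
#' @return A list with `y` (outcome vector), `X` (indicator matrix, one
#'   column per non-reference condition, named by condition), `subject` and
#'   `time` (aligned vectors).
#' @export
design_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  d <- dataset$data[!is.na(dataset$data$outcome), , drop = FALSE]
  nonref <- dataset$conditions[-1]
  X <- matrix(0, nrow = nrow(d), ncol = length(nonref),
              dimnames = list(NULL, nonref))
  for (k in nonref) X[, k] <- as.numeric(d$condition == k)
  list(y = d$outcome, X = X, subject = d$subject, time = d$time)
}
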