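# Cohort container and CSV/JSON I/O.
#
# A cohort is one record per patient-period instance: an instance id, typed
# feature columns, a binary outcome ("bad"/"good"), and an optional predicted
# risk score. Feature typing and plausibility bounds come from a feature
# specification table.

.OUTCOME_LEVELS <- c("bad", "good")

#' Describe the features of a cohort
#'
#' The feature specification fixes, for every feature column, its kind
#' (continuous or categorical), optional plausibility bounds used by
#' [mask_implausible()], and the importance weight assigned by the upstream
#' risk model (used by [select_top_features()]).
#'
#' @param name Character vector of unique feature names.
#' @param kind Character vector, each `"continuous"` or `"categorical"`
#'   (recycled).
#' @param lower_bound,upper_bound Numeric plausibility bounds; `NA` means
#'   unbounded on that side. `lower_bound <= upper_bound` where both present.
#' @param importance Nonnegative importance weights (default 0).
#' @return A `data.frame` of class `rg_features`.
#' @export
#' @examples
#' feature_spec(c("age", "sex"), c("continuous", "categorical"),
#'              lower_bound = c(0, NA), upper_bound = c(120, NA),
#'              importance = c(2, 1))
feature_spec <- function(name, kind, lower_bound = NA_real_,
                         upper_bound = NA_real_, importance = 0) {
  stopifnot(is.character(name), length(name) >= 1L)
  if (anyDuplicated(name)) stop("feature names must be unique")
  if (any(grepl("[:=&]", name))) {
    stop("feature names must not contain ':', '=' or '&' ",
         "(reserved by the canonical item-key syntax)")
  }
  n <- length(name)
  kind <- rep_len(as.character(kind), n)
  if (!all(kind %in% c("continuous", "categorical"))) {
    stop("kind must be 'continuous' or 'categorical'")
  }
  lower_bound <- rep_len(as.numeric(lower_bound), n)
  upper_bound <- rep_len(as.numeric(upper_bound), n)
  importance <- rep_len(as.numeric(importance), n)
  if (any(importance < 0, na.rm = TRUE)) stop("importance must be >= 0")
  both <- !is.na(lower_bound) & !is.na(upper_bound)
  if (any(lower_bound[both] > upper_bound[both])) {
    stop("lower_bound must not exceed upper_bound")
  }
  structure(data.frame(name = name, kind = kind, lower_bound = lower_bound,
                       upper_bound = upper_bound, importance = importance,
                       stringsAsFactors = FALSE),
            class = c("rg_features", "data.frame"))
}

#' Construct a cohort from a data frame
#'
#' @param data A `data.frame` with columns `instance_id`, one column per
#'   feature in `features`, `outcome` (values `"bad"`/`"good"`), and optionally
#'   `risk_score`.
#' @param features An [feature_spec()] table describing the feature columns.
#' @return An object of class `rg_cohort`: a list with elements `features`
#'   and `data`.
#' @export
cohort <- function(data, features) {
  stopifnot(is.data.frame(data), inherits(features, "rg_features"))
  if (!"instance_id" %in% names(data)) stop("cohort needs an instance_id column")
  if (!"outcome" %in% names(data)) stop("cohort is missing the outcome column")
  data$instance_id <- as.character(data$instance_id)
  if (anyDuplicated(data$instance_id)) stop("duplicate instance_id values")
  known <- c("instance_id", features$name, "outcome", "risk_score")
  extra <- setdiff(names(data), known)
  if (length(extra)) {
    stop("columns not in the feature specification: ",
         paste(extra, collapse = ", "))
  }
  missing_feat <- setdiff(features$name, names(data))
  if (length(missing_feat)) {
    stop("feature columns absent from the data: ",
         paste(missing_feat, collapse = ", "))
  }
  out <- as.character(data$outcome)
  bad_lab <- setdiff(unique(out[!is.na(out)]), .OUTCOME_LEVELS)
  if (length(bad_lab) || anyNA(out)) {
    stop("outcome must be 'bad' or 'good'; found: ",
         paste(unique(c(bad_lab, if (anyNA(out)) NA)), collapse = ", "))
  }
  data$outcome <- out
  # enforce column types per spec
  for (i in seq_len(nrow(features))) {
    f <- features$name[i]
    if (features$kind[i] == "continuous") {
      v <- data[[f]]
      if (!is.numeric(v)) {
        parsed <- suppressWarnings(as.numeric(as.character(v)))
        bad_cells <- !is.na(v) & v != "" & is.na(parsed)
        if (any(bad_cells)) {
          warning(sum(bad_cells), " unparseable numeric cell(s) in feature '",
                  f, "' set to missing")
        }
        v <- parsed
      }
      data[[f]] <- v
    } else {
      v <- as.character(data[[f]])
      v[!is.na(v) & v == ""] <- NA_character_
      data[[f]] <- v
    }
  }
  if ("risk_score" %in% names(data)) data$risk_score <- as.numeric(data$risk_score)
  cols <- c("instance_id", features$name, "outcome",
            intersect("risk_score", names(data)))
  structure(list(features = features, data = data[, cols, drop = FALSE]),
            class = "rg_cohort")
}

#' Read a cohort from a delimited text file
#'
#' The file is comma-separated UTF-8 with a header row; the empty string
#' denotes a missing value. Columns must be exactly `instance_id`, the
#' features named in `schema`, `outcome`, and optionally `risk_score`; any
#' unknown column or a missing outcome column is a fatal schema mismatch.
#' Unparseable numeric cells in continuous columns become missing with a
#' warning.
#'
#' @param path Path to the CSV file.
#' @param schema An [feature_spec()] table, or a path to a feature-spec JSON
#'   file (see [read_feature_spec()]).
#' @return An `rg_cohort`.
#' @export
read_cohort <- function(path, schema) {
  if (is.character(schema)) schema <- read_feature_spec(schema)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE,
                         fileEncoding = "UTF-8")
  cohort(raw, schema)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: comma-separated UTF-8, header row, empty
#' string for missing, so that a load-write-load round trip reproduces an
#' identical cohort.
#'
#' @param x An `rg_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "rg_cohort"))
  df <- x$data
  for (i in seq_len(nrow(x$features))) {
    f <- x$features$name[i]
    if (x$features$kind[i] == "continuous") df[[f]] <- .num_fmt_na(df[[f]])
  }
  if ("risk_score" %in% names(df)) df$risk_score <- .num_fmt_na(df$risk_score)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

.num_fmt_na <- function(x) ifelse(is.na(x), NA_character_, .num_fmt(x))

#' Read / write a feature specification as JSON
#'
#' The schema file is a JSON array of records with fields `name`, `kind`,
#' optional `lower_bound` / `upper_bound`, and optional `importance`.
#'
#' @param path Path to the JSON file.
#' @return `read_feature_spec` returns an `rg_features` table.
#' @export
read_feature_spec <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(recs)) stop("empty feature specification")
  grab <- function(r, f, default) if (is.null(r[[f]])) default else r[[f]]
  feature_spec(
    name = vapply(recs, function(r) as.character(r$name), character(1L)),
    kind = vapply(recs, function(r) as.character(r$kind), character(1L)),
    lower_bound = vapply(recs, grab, numeric(1L), f = "lower_bound",
                         default = NA_real_),
    upper_bound = vapply(recs, grab, numeric(1L), f = "upper_bound",
                         default = NA_real_),
    importance = vapply(recs, grab, numeric(1L), f = "importance", default = 0)
  )
}

#' @rdname read_feature_spec
#' @param x An `rg_features` table.
#' @export
write_feature_spec <- function(x, path) {
  stopifnot(inherits(x, "rg_features"))
  recs <- lapply(seq_len(nrow(x)), function(i) {
    r <- list(name = x$name[i], kind = x$kind[i], importance = x$importance[i])
    if (!is.na(x$lower_bound[i])) r$lower_bound <- x$lower_bound[i]
    if (!is.na(x$upper_bound[i])) r$upper_bound <- x$upper_bound[i]
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mask biologically implausible values
#'
#' Every continuous value falling outside its feature's plausibility bounds
#' (`[lower_bound, upper_bound]` from the feature specification) is replaced
#' by missing, emulating the preprocessing step in which out-of-range
#' measurements are treated as recording errors. Features without bounds are
#' untouched; the operation is idempotent and never changes the number of
#' instances or features.
#'
#' @param x An `rg_cohort`.
#' @param quiet Suppress the masked-cell count message.
#' @return The cohort with implausible values set to `NA`; the number of
#'   masked cells is attached as attribute `"n_masked"`.
#' @export
mask_implausible <- function(x, quiet = FALSE) {
  stopifnot(inherits(x, "rg_cohort"))
  n_masked <- 0L
  for (i in seq_len(nrow(x$features))) {
    if (x$features$kind[i] != "continuous") next
    lo <- x$features$lower_bound[i]
    hi <- x$features$upper_bound[i]
    if (is.na(lo) && is.na(hi)) next
    f <- x$features$name[i]
    v <- x$data[[f]]
    bad <- (!is.na(v)) & ((!is.na(lo) & v < lo) | (!is.na(hi) & v > hi))
    if (any(bad)) {
      v[bad] <- NA_real_
      x$data[[f]] <- v
      n_masked <- n_masked + sum(bad)
    }
  }
  if (!quiet && n_masked > 0L) {
    message("mask_implausible: ", n_masked, " implausible cell(s) set to missing")
  }
  attr(x, "n_masked") <- n_masked
  x
}

#' @export
print.rg_cohort <- function(x, ...) {
  n <- nrow(x$data)
  nb <- sum(x$data$outcome == "bad")
  cat("<cohort> ", n, " instances, ", nrow(x$features), " features (",
      sum(x$features$kind == "continuous"), " continuous), bad outcome: ",
      nb, " (", sprintf("%.2f%%", 100 * nb / max(1L, n)), ")",
      if ("risk_score" %in% names(x$data)) ", with risk scores" else "",
      "\n", sep = "")
  invisible(x)
}
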