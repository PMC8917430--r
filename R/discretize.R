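# Supervised discretization of continuous features.
#
# Each continuous feature is converted into a partition of interval items by
# recursive entropy-minimizing binary splitting with the minimum description
# length (MDL) stopping criterion of Fayyad & Irani. Cut points are placed at
# the midpoint between adjacent distinct values; intervals follow the
# half-open convention [a, b), unbounded at both extremes. Categorical
# features contribute one equality item per level observed at fit time.

.entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(0)
  p <- counts[counts > 0L] / n
  -sum(p * log2(p))
}

# One recursion step: find the entropy-minimizing cut of (x, y) and accept it
# iff information gain exceeds the MDL threshold. x sorted ascending, y in
# {1L, 2L}. Returns accepted cut points (numeric, possibly empty).
.mdl_split <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric())
  # candidate boundaries between adjacent distinct values
  distinct_end <- which(x[-n] != x[-1L])     # last index of each value run
  if (!length(distinct_end)) return(numeric())
  # cumulative class counts up to each candidate boundary
  c1 <- cumsum(y == 1L)[distinct_end]
  c2 <- cumsum(y == 2L)[distinct_end]
  nl <- distinct_end
  nr <- n - nl
  t1 <- sum(y == 1L); t2 <- sum(y == 2L)
  ent <- function(a, b) {
    tot <- a + b
    p1 <- ifelse(tot > 0 & a > 0, a / tot, NA)
    p2 <- ifelse(tot > 0 & b > 0, b / tot, NA)
    e <- numeric(length(tot))
    e <- e - ifelse(is.na(p1), 0, p1 * log2(pmax(p1, .Machine$double.xmin)))
    e <- e - ifelse(is.na(p2), 0, p2 * log2(pmax(p2, .Machine$double.xmin)))
    e
  }
  e_all <- .entropy(c(t1, t2))
  e_left <- ent(c1, c2)
  e_right <- ent(t1 - c1, t2 - c2)
  wce <- (nl / n) * e_left + (nr / n) * e_right
  gain <- e_all - wce
  best <- which.max(gain)                    # ties -> lowest cut, deterministic
  # MDL acceptance test at the best cut
  k <- sum(c(t1, t2) > 0L)
  kl <- sum(c(c1[best], c2[best]) > 0L)
  kr <- sum(c(t1 - c1[best], t2 - c2[best]) > 0L)
  delta <- log2(3^k - 2) -
    (k * e_all - kl * e_left[best] - kr * e_right[best])
  threshold <- (log2(n - 1) + delta) / n
  if (gain[best] <= threshold) return(numeric())
  i <- distinct_end[best]
  cut <- (x[i] + x[i + 1L]) / 2
  left <- seq_len(i)
  c(.mdl_split(x[left], y[left]), cut, .mdl_split(x[-left], y[-left]))
}

# Full MDL discretization of one feature: sorted, NA-free inputs not required.
.mdl_cuts <- function(values, outcome) {
  ok <- !is.na(values)
  x <- values[ok]
  y <- ifelse(outcome[ok] == "bad", 1L, 2L)
  if (!length(x)) return(NULL)               # all missing
  o <- order(x)
  sort(.mdl_split(x[o], y[o]))
}

.equal_freq_cuts <- function(values, k_bins) {
  x <- values[!is.na(values)]
  if (!length(x)) return(NULL)
  qs <- stats::quantile(x, probs = seq_len(k_bins - 1L) / k_bins,
                        names = FALSE, type = 7)
  sort(unique(qs[qs > min(x) & qs < max(x)]))
}

.cuts_to_items <- function(feature, cuts) {
  bounds <- c(-Inf, cuts, Inf)
  lapply(seq_len(length(bounds) - 1L), function(i) {
    item_interval(feature, bounds[i], bounds[i + 1L])
  })
}

#' Fit a discretization scheme on a training cohort
#'
#' For every continuous feature, accepted cuts are found by recursive
#' entropy-minimizing binary splits under the MDL stopping criterion,
#' computed against the binary outcome on the training set only. A feature
#' on which no cut is accepted (e.g. a constant feature, or one carrying no
#' class information) yields a single all-range item. Categorical features
#' yield one equality item per observed level. The procedure is
#' deterministic given the data.
#'
#' @param x An `rg_cohort` (the training set).
#' @param features Optional character vector restricting which features are
#'   discretized/itemized (default: all features in the cohort).
#' @param method `"mdl"` (default, supervised) or `"frequency"` (unsupervised
#'   equal-frequency binning with `k_bins` bins).
#' @param k_bins Number of bins for `method = "frequency"`.
#' @return An object of class `rg_scheme`: list with `cuts` (named list of
#'   numeric cut vectors), `items` (named list of item lists per feature),
#'   and `index` (flat named list of all items by canonical key).
#' @export
fit_discretization <- function(x, features = NULL,
                               method = c("mdl", "frequency"), k_bins = 4L) {
  stopifnot(inherits(x, "rg_cohort"))
  method <- match.arg(method)
  spec <- x$features
  if (!is.null(features)) {
    spec <- spec[spec$name %in% features, , drop = FALSE]
    if (!nrow(spec)) stop("no matching features to discretize")
  }
  cuts <- list()
  items <- list()
  for (i in seq_len(nrow(spec))) {
    f <- spec$name[i]
    v <- x$data[[f]]
    if (spec$kind[i] == "continuous") {
      cc <- if (method == "mdl") .mdl_cuts(v, x$data$outcome)
            else .equal_freq_cuts(v, k_bins)
      if (is.null(cc)) {
        warning("feature '", f, "' has only missing values; no items emitted")
        next
      }
      cuts[[f]] <- cc
      items[[f]] <- .cuts_to_items(f, cc)
    } else {
      lev <- sort(unique(v[!is.na(v)]))
      if (!length(lev)) {
        warning("feature '", f, "' has only missing values; no items emitted")
        next
      }
      items[[f]] <- lapply(lev, function(l) item_equals(f, l))
    }
  }
  index <- .item_index(unlist(items, recursive = FALSE, use.names = FALSE))
  structure(list(cuts = cuts, items = items, index = index,
                 method = method),
            class = "rg_scheme")
}

#' Convert cohort instances into item sets
#'
#' Each non-missing feature value maps to exactly one item of the scheme's
#' partition for that feature (interval membership for continuous features,
#' level equality for categorical ones); missing values, features absent
#' from the scheme, and categorical levels unseen at fit time map to no item.
#' Consequently an itemized instance carries at most one item per feature.
#'
#' @param x An `rg_cohort`.
#' @param scheme An `rg_scheme` fitted by [fit_discretization()] on a cohort
#'   with the same feature specification.
#' @return An object of class `rg_itemized`: list with `instance_id`
#'   (character), `items` (list of character key vectors), `outcome`
#'   (character), and `risk_score` (numeric or `NULL`).
#' @export
itemize <- function(x, scheme) {
  stopifnot(inherits(x, "rg_cohort"), inherits(scheme, "rg_scheme"))
  n <- nrow(x$data)
  key_cols <- list()
  n_unseen <- 0L
  for (f in names(scheme$items)) {
    v <- x$data[[f]]
    if (is.null(v)) next
    its <- scheme$items[[f]]
    keys <- item_key(its)
    if (its[[1L]]$kind == "interval") {
      cc <- scheme$cuts[[f]]
      bin <- findInterval(v, cc) + 1L        # NA propagates
      key_cols[[f]] <- keys[bin]
    } else {
      lev <- vapply(its, function(it) it$value, character(1L))
      idx <- match(v, lev)
      n_unseen <- n_unseen + sum(!is.na(v) & is.na(idx))
      key_cols[[f]] <- keys[idx]
    }
  }
  if (n_unseen > 0L) {
    message("itemize: ", n_unseen,
            " categorical value(s) unseen at fit time produced no item")
  }
  m <- if (length(key_cols)) do.call(cbind, key_cols) else
    matrix(character(), nrow = n, ncol = 0L)
  items <- lapply(seq_len(n), function(i) {
    r <- m[i, ]
    unname(r[!is.na(r)])
  })
  structure(list(instance_id = x$data$instance_id,
                 items = items,
                 outcome = x$data$outcome,
                 risk_score = x$data$risk_score),
            class = "rg_itemized")
}

#' Read / write a discretization scheme as JSON
#'
#' Serialized form: an object with `cuts` (feature -> numeric cut array) and
#' `levels` (feature -> observed categorical levels).
#'
#' @param path Path to the JSON file.
#' @return `read_scheme` returns an `rg_scheme`.
#' @export
read_scheme <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cuts <- lapply(doc$cuts, as.numeric)
  items <- lapply(names(cuts), function(f) .cuts_to_items(f, cuts[[f]]))
  names(items) <- names(cuts)
  for (f in names(doc$levels)) {
    items[[f]] <- lapply(as.character(doc$levels[[f]]),
                         function(l) item_equals(f, l))
  }
  index <- .item_index(unlist(items, recursive = FALSE, use.names = FALSE))
  structure(list(cuts = cuts, items = items, index = index, method = "mdl"),
            class = "rg_scheme")
}

#' @rdname read_scheme
#' @param scheme An `rg_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "rg_scheme"))
  lev <- list()
  for (f in names(scheme$items)) {
    its <- scheme$items[[f]]
    if (its[[1L]]$kind == "equals") {
      lev[[f]] <- vapply(its, function(it) it$value, character(1L))
    }
  }
  jsonlite::write_json(list(cuts = scheme$cuts, levels = lev), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Scheme item containing a given value
#'
#' Utility lookup: returns the unique item of `scheme` on `feature` that the
#' value satisfies, or `NULL` when none does (missing value, unseen level).
#'
#' @param scheme An `rg_scheme`.
#' @param feature Feature name.
#' @param value A single feature value.
#' @return An `rg_item` or `NULL`.
#' @export
scheme_item_for <- function(scheme, feature, value) {
  its <- scheme$items[[feature]]
  if (is.null(its) || is.na(value)) return(NULL)
  for (it in its) if (item_satisfied(it, value)) return(it)
  NULL
}

#' @export
print.rg_scheme <- function(x, ...) {
  ncont <- sum(vapply(x$items, function(l) l[[1L]]$kind == "interval",
                      logical(1L)))
  cat("<discretization scheme> ", length(x$items), " feature(s) (", ncont,
      " continuous), ", length(x$index), " items, method = ", x$method,
      "\n", sep = "")
  invisible(x)
}

#' @export
print.rg_itemized <- function(x, ...) {
  cat("<itemized instances> n = ", length(x$items), ", bad outcome: ",
      sum(x$outcome == "bad"), ", mean items per instance: ",
      sprintf("%.2f", mean(lengths(x$items))), "\n", sep = "")
  invisible(x)
}
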