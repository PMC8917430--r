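# Items: feature-value pairs, the atoms of association rules.
# An item either asserts equality with a categorical level or membership in a
# half-open numeric interval [lower, upper); the topmost interval of a
# partition has upper = Inf and therefore contains every value >= lower.

.num_fmt <- function(x) {
  ifelse(is.finite(x), sprintf("%.12g", x), ifelse(x > 0, "Inf", "-Inf"))
}

#' Create an equality item on a categorical feature
#'
#' An item is a feature-value pair: the elementary condition that appears on
#' the left-hand side of a class-based association rule. An equality item is
#' satisfied by an instance whose value on `feature` equals `value`.
#'
#' @param feature Feature name (single string).
#' @param value Categorical level the feature must equal (coerced to character).
#' @param display Optional human-readable rendering of the condition; a default
#'   of the form `"feature = value"` is generated when absent.
#' @return An object of class `rg_item`.
#' @seealso [item_interval()], [item_satisfied()], [item_key()]
#' @export
#' @examples
#' item_equals("race", "Black or African American")
item_equals <- function(feature, value, display = NULL) {
  stopifnot(is.character(feature), length(feature) == 1L, nzchar(feature),
            length(value) == 1L, !is.na(value))
  value <- as.character(value)
  if (is.null(display)) display <- paste0(feature, " = ", value)
  structure(list(feature = feature, kind = "equals", value = value,
                 display = display),
            class = "rg_item")
}

#' Create an interval item on a continuous feature
#'
#' The condition is half-open membership `lower <= x < upper`. Intervals with
#' `upper = Inf` behave as closed at the top (every finite value above `lower`
#' satisfies them), matching the topmost bin of a discretization partition.
#'
#' @param feature Feature name (single string).
#' @param lower,upper Interval endpoints; `lower < upper` is required and
#'   either end may be infinite.
#' @inheritParams item_equals
#' @return An object of class `rg_item`.
#' @export
#' @examples
#' item_interval("days_since_exacerbation", -Inf, 81.4)
item_interval <- function(feature, lower, upper, display = NULL) {
  stopifnot(is.character(feature), length(feature) == 1L, nzchar(feature),
            is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L,
            !is.na(lower), !is.na(upper))
  if (!(lower < upper)) {
    stop("malformed interval on feature '", feature, "': lower (", lower,
         ") must be strictly less than upper (", upper, ")")
  }
  if (is.null(display)) {
    display <- if (!is.finite(lower) && is.finite(upper)) {
      paste0(feature, " < ", .num_fmt(upper))
    } else if (is.finite(lower) && !is.finite(upper)) {
      paste0(feature, " >= ", .num_fmt(lower))
    } else {
      paste0(feature, " in [", .num_fmt(lower), ", ", .num_fmt(upper), ")")
    }
  }
  structure(list(feature = feature, kind = "interval",
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 display = display),
            class = "rg_item")
}

#' Canonical string key of an item
#'
#' Keys are the identity used everywhere items are compared: rule left-hand
#' sides, knowledge-base lookup, and instance itemization all agree on this
#' canonical form, so an item defined in a knowledge-base file matches the
#' corresponding discretizer bin bit-exactly.
#'
#' @param item An `rg_item`, or a list of them (returns a character vector).
#' @return Character key(s), e.g. `"age:[65,Inf)"` or `"sex=Female"`.
#' @export
item_key <- function(item) {
  if (inherits(item, "rg_item")) item <- list(item)
  vapply(item, function(it) {
    if (it$kind == "equals") {
      paste0(it$feature, "=", it$value)
    } else {
      paste0(it$feature, ":[", .num_fmt(it$lower), ",", .num_fmt(it$upper), ")")
    }
  }, character(1L))
}

#' Does a value satisfy an item?
#'
#' Missing values never satisfy any item: a rule's left-hand side is a
#' conjunction of satisfied conditions, and an unknown value cannot be
#' asserted to meet one.
#'
#' @param item An `rg_item`.
#' @param value A vector of feature values (numeric for interval items,
#'   anything coercible to character for equality items). `NA` yields `FALSE`.
#' @return Logical vector the length of `value`.
#' @export
item_satisfied <- function(item, value) {
  stopifnot(inherits(item, "rg_item"))
  if (item$kind == "equals") {
    out <- !is.na(value) & as.character(value) == item$value
  } else {
    v <- suppressWarnings(as.numeric(value))
    out <- !is.na(v) & v >= item$lower & v < item$upper
  }
  out
}

#' @export
format.rg_item <- function(x, ...) x$display

#' @export
print.rg_item <- function(x, ...) {
  cat("<item> ", format(x), "   [", item_key(x), "]\n", sep = "")
  invisible(x)
}

# Internal: list of items -> named list keyed by canonical key.
.item_index <- function(items) {
  keys <- item_key(items)
  if (anyDuplicated(keys)) stop("duplicate items: ",
                                paste(keys[duplicated(keys)], collapse = ", "))
  stats::setNames(items, keys)
}

# Internal: feature name of each item key given an index.
.item_features <- function(index) {
  vapply(index, function(it) it$feature, character(1L))
}
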