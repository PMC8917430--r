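# Rule-set reduction.
#
# Three techniques keep the rule set small enough for sub-second retrieval at
# prediction time: (1) restrict mining to the top-ranked features (see
# select_top_features); (2) subsumption pruning under a confidence-difference
# tolerance; (3) keep only rules built entirely from items the expert labeled
# positively correlated with the bad outcome.

#' Drop rules subsumed by a more general rule of similar confidence
#'
#' A rule `r1` is dropped when another rule `r2` satisfies three conditions:
#' both share the same right-hand side; the left-hand-side items of `r2` are
#' a proper subset of those of `r1` (`r2` is more general); and the
#' confidence of `r2` is greater than or equal to `confidence(r1) -
#' conf_diff_upper`.
#'
#' Under the default witness policy (`"any"`) `r2` may be any rule of the
#' input set, which makes the drop decision for each rule independent of the
#' others; the number of survivors is then provably nonincreasing in the
#' tolerance, the qualitative shape of the remaining-rules curve. The
#' alternative policy (`"retained"`) processes rules in increasing
#' left-hand-side size and accepts only already-retained rules as witnesses,
#' which instead guarantees that every dropped rule has a *surviving* more
#' general witness within the tolerance; the two guarantees cannot hold
#' simultaneously in general.
#'
#' @param rules An `rg_rules` table (all rules must share one `rhs`).
#' @param conf_diff_upper Tolerance in [0, 1] on the confidence difference.
#' @param witness `"any"` (default) or `"retained"`; see Details.
#' @return The retained rules, in canonical order.
#' @export
prune_subsumed <- function(rules, conf_diff_upper,
                           witness = c("any", "retained")) {
  stopifnot(inherits(rules, "rg_rules"),
            conf_diff_upper >= 0, conf_diff_upper <= 1)
  witness <- match.arg(witness)
  if (nrow(rules) <= 1L) return(rules)
  if (length(unique(rules$rhs)) != 1L) {
    stop("prune_subsumed expects rules sharing one right-hand side")
  }
  ord <- order(rules$k, rules$lhs_key)
  rules <- rules[ord, , drop = FALSE]
  pool <- new.env(parent = emptyenv())       # lhs_key -> best confidence
  if (witness == "any") {
    for (i in seq_len(nrow(rules))) {
      key <- rules$lhs_key[i]
      prev <- get0(key, envir = pool, inherits = FALSE)
      pool[[key]] <- max(prev, rules$confidence[i])
    }
  }
  keep <- logical(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    lhs <- rules$lhs[[i]]
    k <- rules$k[i]
    drop_it <- FALSE
    if (k > 1L) {
      floor_conf <- rules$confidence[i] - conf_diff_upper
      for (sz in seq_len(k - 1L)) {
        subs <- utils::combn(lhs, sz, paste, collapse = " & ")
        for (s in subs) {
          c2 <- get0(s, envir = pool, inherits = FALSE)
          if (!is.null(c2) && c2 >= floor_conf) { drop_it <- TRUE; break }
        }
        if (drop_it) break
      }
    }
    if (!drop_it) {
      keep[i] <- TRUE
      if (witness == "retained") pool[[rules$lhs_key[i]]] <- rules$confidence[i]
    }
  }
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only rules made of positively correlated items
#'
#' Retains exactly the rules whose every left-hand-side item is labeled
#' positively correlated with the bad outcome in the knowledge base.
#' Unannotated items carry the default label `FALSE`, so a rule containing
#' any unlabeled item is dropped; with an empty knowledge base the result is
#' empty.
#'
#' @param rules An `rg_rules` table.
#' @param kb An `rg_kb`.
#' @return The retained rules.
#' @export
filter_positive_correlation <- function(rules, kb) {
  stopifnot(inherits(rules, "rg_rules"), inherits(kb, "rg_kb"))
  pos <- positive_item_keys(kb)
  keep <- vapply(rules$lhs, function(l) all(l %in% pos), logical(1L))
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remaining-rules curve over a tolerance grid
#'
#' Evaluates [prune_subsumed()] at each tolerance of the grid and reports the
#' number of surviving rules. The count is nonincreasing in the tolerance:
#' a larger allowed confidence difference can only drop more rules.
#'
#' @param rules An `rg_rules` table.
#' @param grid Ascending numeric vector of tolerances
#'   (default `seq(0, 0.5, by = 0.01)`).
#' @return A `data.frame` with columns `tolerance` and `remaining`.
#' @export
rule_count_curve <- function(rules, grid = seq(0, 0.5, by = 0.01)) {
  stopifnot(inherits(rules, "rg_rules"), !is.unsorted(grid))
  remaining <- vapply(grid, function(t) nrow(prune_subsumed(rules, t)),
                      integer(1L))
  data.frame(tolerance = grid, remaining = remaining)
}

#' Suggest a tolerance at the knee of the remaining-rules curve
#'
#' The tolerance is normally set where a further increase in the confidence
#' difference has only a minor impact on the number of remaining rules. This
#' helper formalizes that reading as the grid point with the maximum
#' perpendicular distance to the chord joining the curve's endpoints. It is
#' advisory: the configured `conf_diff_upper` always wins.
#'
#' @param curve A `data.frame` as returned by [rule_count_curve()] (>= 3
#'   points).
#' @return The suggested tolerance (a grid point).
#' @export
suggest_elbow <- function(curve) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 3L,
            all(c("tolerance", "remaining") %in% names(curve)))
  x <- curve$tolerance
  y <- curve$remaining
  n <- length(x)
  if (all(y == y[1L])) {
    warning("flat remaining-rules curve; returning the smallest tolerance")
    return(x[1L])
  }
  # distance from each point to the chord through the endpoints
  dx <- x[n] - x[1L]
  dy <- y[n] - y[1L]
  d <- abs(dy * x - dx * y + x[n] * y[1L] - y[n] * x[1L]) / sqrt(dx^2 + dy^2)
  x[which.max(d)]
}
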