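# Explanation-coverage metrics.
#
# Two coverage figures summarize the explanation power of the rule set:
#   coverage_tp      - fraction of correctly predicted bad-outcome instances
#                      (true positives) matched by >= 1 rule;
#   coverage_outcome - fraction of ALL bad-outcome instances matched by >= 1
#                      rule, regardless of the model's prediction.
# Alongside, the distributions of the number of matching (actionable) rules
# and of unique actionable items per explained true positive.

.dist_stats <- function(x) {
  if (!length(x)) {
    return(list(mean = NA_real_, sd = NA_real_, median = NA_real_,
                max = NA_real_))
  }
  list(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
       max = max(x))
}

.equal_width_hist <- function(x, bin_width = NULL, n_bins = 20L) {
  if (!length(x)) {
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      count = integer()))
  }
  if (is.null(bin_width)) bin_width <- max(max(x) / n_bins, 1)
  lo <- 0
  hi <- max(x)
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  cnt <- as.integer(table(cut(x, breaks = breaks, right = FALSE,
                              include.lowest = TRUE)))
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             count = cnt)
}

# Internal: per-instance table from a list of rg_explanation objects.
.explanation_table <- function(explanations) {
  data.frame(
    instance_id = vapply(explanations, `[[`, character(1L), "instance_id"),
    n_matching = vapply(explanations, `[[`, integer(1L), "n_matching"),
    n_matching_actionable = vapply(explanations, function(e)
      as.integer(e$n_matching_actionable), integer(1L)),
    unique_actionable_items = vapply(explanations, function(e)
      as.integer(e$unique_actionable_items), integer(1L)),
    stringsAsFactors = FALSE
  )
}

#' Explanation coverage of a test cohort
#'
#' An instance counts as "explained" iff at least one rule matches it.
#' `coverage_tp` is computed over instances with `predicted_bad` prediction
#' and `bad` outcome; `coverage_outcome` over all instances with `bad`
#' outcome regardless of the prediction (with a strong upstream model the
#' former typically exceeds the latter, since misclassified positives tend
#' to be hard cases for the rules too, but neither ordering is guaranteed).
#' With zero true positives `coverage_tp` is reported as `NA`.
#'
#' @param predictions Named character vector of `"predicted_bad"` /
#'   `"predicted_good"` (see [binarize_top_fraction()]).
#' @param outcomes Named character vector of `"bad"` / `"good"`.
#' @param explanations List of [explain_instance()] results covering at least
#'   every bad-outcome and every predicted-bad instance.
#' @param bin_width Optional histogram bin width (default: max/20 per
#'   distribution).
#' @return An object of class `rg_coverage` with counts, the two coverage
#'   fractions, summary statistics of the matching-rule and
#'   unique-actionable-item distributions over explained true positives
#'   (both all-matching and actionable-only rule counts), and equal-width
#'   histograms.
#' @export
explanation_coverage <- function(predictions, outcomes, explanations,
                                 bin_width = NULL) {
  tab <- .explanation_table(explanations)
  ids <- tab$instance_id
  if (is.null(names(predictions)) || is.null(names(outcomes))) {
    stop("predictions and outcomes must be named by instance id")
  }
  pred <- predictions[ids]
  out <- outcomes[ids]
  if (anyNA(pred) || anyNA(out)) {
    stop("every explained instance needs a prediction and an outcome")
  }
  explained <- tab$n_matching >= 1L
  is_tp <- pred == "predicted_bad" & out == "bad"
  is_pos <- out == "bad"
  # outcome-positives missing from the explanation list are unexplained only
  # if truly absent; require full coverage of positives instead
  n_pos_total <- sum(outcomes == "bad")
  if (sum(is_pos) < n_pos_total) {
    stop("explanations must cover every bad-outcome instance (",
         sum(is_pos), " of ", n_pos_total, " provided)")
  }
  n_tp <- sum(is_tp)
  n_tp_exp <- sum(is_tp & explained)
  n_pos <- sum(is_pos)
  n_pos_exp <- sum(is_pos & explained)
  tp_tab <- tab[is_tp & explained, , drop = FALSE]
  dists <- match_distributions(explanations[is_tp & explained],
                               bin_width = bin_width)
  structure(list(
    n_true_positive = n_tp,
    n_true_positive_explained = n_tp_exp,
    coverage_tp = if (n_tp > 0L) n_tp_exp / n_tp else NA_real_,
    n_outcome_positive = n_pos,
    n_outcome_positive_explained = n_pos_exp,
    coverage_outcome = if (n_pos > 0L) n_pos_exp / n_pos else NA_real_,
    rule_count_stats = .dist_stats(tp_tab$n_matching_actionable),
    rule_count_stats_all = .dist_stats(tp_tab$n_matching),
    actionable_item_stats = .dist_stats(tp_tab$unique_actionable_items),
    histograms = dists
  ), class = "rg_coverage")
}

#' Distributions of matching rules and unique actionable items
#'
#' For a set of explained, correctly predicted positives, returns equal-width
#' histograms (default bin width: max/20) and summary statistics of (1) the
#' number of actionable rules matching an instance and (2) the number of
#' unique actionable items in those rules.
#'
#' @param explanations List of `rg_explanation` objects (restricted to
#'   explained true positives by the caller).
#' @param bin_width Optional common bin width; default max/20 per
#'   distribution.
#' @return List with `rule_hist`, `item_hist` (data frames `bin_lo`,
#'   `bin_hi`, `count`) and `rule_stats`, `item_stats` (mean, sd, median,
#'   max).
#' @export
match_distributions <- function(explanations, bin_width = NULL) {
  tab <- if (length(explanations)) .explanation_table(explanations) else
    data.frame(n_matching_actionable = integer(),
               unique_actionable_items = integer())
  rules_n <- tab$n_matching_actionable
  items_n <- tab$unique_actionable_items
  list(rule_hist = .equal_width_hist(rules_n, bin_width),
       item_hist = .equal_width_hist(items_n, bin_width),
       rule_stats = .dist_stats(rules_n),
       item_stats = .dist_stats(items_n))
}

#' @export
print.rg_coverage <- function(x, ...) {
  pct <- function(p) if (is.na(p)) "NA" else sprintf("%.1f%%", 100 * p)
  cat("Explanation coverage\n",
      "  correctly predicted positives: ", pct(x$coverage_tp), " (",
      x$n_true_positive_explained, "/", x$n_true_positive, ")\n",
      "  all outcome positives:         ", pct(x$coverage_outcome), " (",
      x$n_outcome_positive_explained, "/", x$n_outcome_positive, ")\n",
      sep = "")
  rs <- x$rule_count_stats; as <- x$actionable_item_stats
  if (!is.na(rs$mean)) {
    cat(sprintf("  matching actionable rules per explained TP: mean %.2f (SD %.2f), median %s, max %s\n",
                rs$mean, rs$sd, format(rs$median), format(rs$max)))
    cat(sprintf("  unique actionable items per explained TP:   mean %.2f (SD %.2f), median %s, max %s\n",
                as$mean, as$sd, format(as$median), format(as$max)))
  }
  invisible(x)
}
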