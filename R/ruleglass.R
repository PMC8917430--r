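# The fitted explanation model: discretize -> mine -> prune -> filter,
# packaged as one classed object with the usual modelling-idiom methods.

#' Fit a rule-based explanation model on a training cohort
#'
#' Runs the full rule-construction pipeline: plausibility masking, selection
#' of the highest-importance features, supervised discretization of the
#' continuous ones, Apriori mining of class-based association rules under
#' the commonality and confidence floors, subsumption pruning under the
#' confidence-difference tolerance, and (when the knowledge base labels any
#' item) restriction to rules built from positively correlated items. The
#' result is a second model used to explain the predictions of any upstream
#' risk model, never to make predictions itself.
#'
#' @param data An `rg_cohort` training set (see [read_cohort()],
#'   [simulate_cohort()]).
#' @param kb An `rg_kb` knowledge base. With the default empty base no
#'   correlation filter is applied and no rule is actionable.
#' @param config An [mining_config()] with the five control parameters.
#' @param weights An [ranking_weights()] used at prediction time.
#' @param mask Apply [mask_implausible()] before fitting (default `TRUE`).
#' @param prefilter_correlated Restrict the allowed items to positively
#'   correlated ones already at mining time instead of filtering mined rules
#'   afterwards; cheaper, same final semantics up to pruning witnesses
#'   (default `FALSE`, i.e. mine, prune, then filter).
#' @param filter_correlated Apply the positive-correlation filter. Default
#'   (`NULL`) applies it iff the knowledge base labels at least one item
#'   positively correlated.
#' @param keep_mined Keep the full pre-pruning rule set on the object (needed
#'   by [plot.ruleglass()]'s remaining-rules curve; default `TRUE`).
#' @return An object of class `ruleglass`: list with `rules` (final rule
#'   set, actionability-annotated), `rules_mined` (optional), `scheme`,
#'   `features` (selected), `kb`, `config`, `weights`, `n_mined`,
#'   `n_after_prune`, `n_after_filter`, and `call`.
#' @seealso [predict.ruleglass()], [plot.ruleglass()]
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_instances = 600, n_features = 8,
#'                                   planted_rules = list(
#'                                     planted_rule(list(item_equals("c01", "high")),
#'                                                  0.15, 0.8)),
#'                                   seed = 42))
#' fit <- ruleglass(sim$cohort, config = mining_config(top_k_features = 8,
#'                                                     max_lhs_items = 2))
#' print(fit)
ruleglass <- function(data, kb = knowledge_base(), config = mining_config(),
                      weights = ranking_weights(), mask = TRUE,
                      prefilter_correlated = FALSE, filter_correlated = NULL,
                      keep_mined = TRUE) {
  stopifnot(inherits(data, "rg_cohort"), inherits(kb, "rg_kb"),
            inherits(config, "rg_config"))
  cl <- match.call()
  if (mask) data <- mask_implausible(data, quiet = TRUE)
  feats <- if (config$top_k_features < nrow(data$features)) {
    select_top_features(data$features, config$top_k_features)
  } else data$features
  scheme <- fit_discretization(data, features = feats$name)
  itemized <- itemize(data, scheme)
  allowed <- names(scheme$index)
  pos <- positive_item_keys(kb)
  do_filter <- if (is.null(filter_correlated)) length(pos) > 0L
               else isTRUE(filter_correlated)
  if (prefilter_correlated && do_filter) allowed <- intersect(allowed, pos)
  mined <- mine_rules(itemized, allowed, config)
  pruned <- prune_subsumed(mined, config$conf_diff_upper)
  final <- if (do_filter && !prefilter_correlated) {
    filter_positive_correlation(pruned, kb)
  } else pruned
  final <- annotate_actionability(final, kb)
  structure(list(rules = final,
                 rules_mined = if (keep_mined) mined else NULL,
                 scheme = scheme, features = feats, kb = kb,
                 config = config, weights = weights,
                 n_mined = nrow(mined), n_after_prune = nrow(pruned),
                 n_after_filter = nrow(final), call = cl),
            class = "ruleglass")
}

#' @export
print.ruleglass <- function(x, ...) {
  cat("Rule-based explanation model\n")
  cat("  features used: ", nrow(x$features), " | items: ",
      length(x$scheme$index), "\n", sep = "")
  cat("  rules mined: ", x$n_mined, " -> after subsumption pruning (tol ",
      x$config$conf_diff_upper, "): ", x$n_after_prune,
      " -> final: ", x$n_after_filter, "\n", sep = "")
  cat("  thresholds: commonality >= ", x$config$min_commonality,
      ", confidence >= ", x$config$min_confidence,
      ", max LHS items: ", x$config$max_lhs_items, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ruleglass <- function(object, ...) {
  r <- object$rules
  s <- list(n_rules = nrow(r),
            n_actionable = sum(r$actionable),
            lhs_size = if (nrow(r)) table(r$k) else table(integer()),
            confidence = if (nrow(r)) summary(r$confidence) else NULL,
            commonality = if (nrow(r)) summary(r$commonality) else NULL,
            counts = c(mined = object$n_mined,
                       after_prune = object$n_after_prune,
                       final = object$n_after_filter))
  class(s) <- "summary.ruleglass"
  s
}

#' @export
print.summary.ruleglass <- function(x, ...) {
  cat("Rule set: ", x$n_rules, " rule(s), ", x$n_actionable, " actionable\n",
      sep = "")
  cat("  pipeline counts: mined ", x$counts["mined"], ", after pruning ",
      x$counts["after_prune"], ", final ", x$counts["final"], "\n", sep = "")
  if (x$n_rules) {
    cat("  LHS size distribution:\n")
    print(x$lhs_size)
    cat("  confidence:\n"); print(x$confidence)
    cat("  commonality:\n"); print(x$commonality)
  }
  invisible(x)
}

#' Explain the predictions of an upstream model on a test cohort
#'
#' Itemizes the new cohort under the fitted discretization scheme, flags the
#' top fraction of predicted risks as positive, and produces a ranked,
#' intervention-annotated explanation for every flagged instance. Instances
#' predicted good still get their matching counts computed (needed by the
#' outcome-level coverage metric).
#'
#' @param object A fitted [ruleglass()] model.
#' @param newdata An `rg_cohort` with a `risk_score` column (or supply
#'   `risk_scores`).
#' @param top_fraction Fraction of instances flagged positive
#'   (default 0.10).
#' @param n_top Ranked rules presented per explanation (default 3).
#' @param risk_scores Optional named numeric vector overriding the cohort's
#'   `risk_score` column.
#' @param mask Apply plausibility masking to `newdata` first
#'   (default `TRUE`).
#' @param ... Unused.
#' @return An object of class `ruleglass_explanations`: list with
#'   `explanations` (list of `rg_explanation`, one per instance),
#'   `predictions`, `outcomes`.
#' @export
predict.ruleglass <- function(object, newdata, top_fraction = 0.10,
                              n_top = 3L, risk_scores = NULL, mask = TRUE,
                              ...) {
  stopifnot(inherits(newdata, "rg_cohort"))
  if (mask) newdata <- mask_implausible(newdata, quiet = TRUE)
  if (is.null(risk_scores)) {
    if (!"risk_score" %in% names(newdata$data)) {
      stop("newdata has no risk_score column and no risk_scores supplied")
    }
    risk_scores <- stats::setNames(newdata$data$risk_score,
                                   newdata$data$instance_id)
  }
  preds <- binarize_top_fraction(risk_scores, top_fraction)
  itemized <- itemize(newdata, object$scheme)
  insts <- itemized_instances(itemized)
  expl <- lapply(insts, function(inst) {
    explain_instance(inst, preds[[inst$instance_id]], object$rules,
                     kb = object$kb, n_top = n_top,
                     weights = object$weights,
                     max_lhs = object$config$max_lhs_items)
  })
  outcomes <- stats::setNames(newdata$data$outcome, newdata$data$instance_id)
  structure(list(explanations = expl, predictions = preds,
                 outcomes = outcomes),
            class = "ruleglass_explanations")
}

#' @export
print.ruleglass_explanations <- function(x, n = 3L, ...) {
  flagged <- Filter(function(e) e$prediction == "predicted_bad",
                    x$explanations)
  cat("Explanations for ", length(flagged), " flagged instance(s) of ",
      length(x$explanations), "\n", sep = "")
  shown <- utils::head(flagged, n)
  for (e in shown) { cat("\n"); print(e) }
  if (length(flagged) > n) {
    cat("\n... and ", length(flagged) - n, " more flagged instance(s)\n",
        sep = "")
  }
  invisible(x)
}

#' Coverage metrics of a set of explanations
#'
#' @param object A `ruleglass_explanations` result from
#'   [predict.ruleglass()].
#' @param ... Passed to [explanation_coverage()].
#' @return An `rg_coverage` report.
#' @export
summary.ruleglass_explanations <- function(object, ...) {
  explanation_coverage(object$predictions, object$outcomes,
                       object$explanations, ...)
}

#' Remaining-rules curve of a fitted model
#'
#' Plots the number of rules surviving subsumption pruning against the
#' confidence-difference tolerance, the curve used to choose the tolerance
#' (set where further increases have only minor impact). Requires the fit to
#' have kept the mined rule set (`keep_mined = TRUE`).
#'
#' @param x A fitted [ruleglass()] model.
#' @param grid Tolerance grid (default `seq(0, 0.5, by = 0.01)`).
#' @param mark Tolerance to mark with a vertical line (default the
#'   configured one).
#' @param ... Passed to [graphics::plot()].
#' @return The curve data frame, invisibly.
#' @export
plot.ruleglass <- function(x, grid = seq(0, 0.5, by = 0.01),
                           mark = x$config$conf_diff_upper, ...) {
  if (is.null(x$rules_mined)) {
    stop("model was fitted with keep_mined = FALSE; no curve available")
  }
  curve <- rule_count_curve(x$rules_mined, grid)
  graphics::plot(curve$tolerance, curve$remaining, type = "b", pch = 16,
                 xlab = "upper limit of the confidence difference",
                 ylab = "number of remaining rules", ...)
  if (!is.null(mark)) graphics::abline(v = mark, lty = 2)
  invisible(curve)
}
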