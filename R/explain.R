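# Prediction-time explanation.
#
# For an instance flagged high-risk by the upstream model, the matching rules
# (left-hand side fully satisfied by the instance) are ranked iteratively by
# a five-factor score and presented with the interventions attached to their
# actionable items. The five factors: confidence, commonality, left-hand-side
# length, actionability, and information redundancy with the higher-ranked
# rules.

#' Weights of the five ranking factors
#'
#' The rule-scoring function is linear in five factors:
#' \deqn{score = w_c \cdot confidence + w_m \cdot commonality
#'   - w_l \cdot (k - 1)/\max(1, K - 1) + w_a \cdot [actionable]
#'   - w_r \cdot redundancy}
#' where `k` is the rule's left-hand-side length, `K` the configured maximum,
#' and `redundancy` the maximum Jaccard overlap between the rule's left-hand
#' side and those of the already-selected rules (0 for the first selection).
#' The linear form and its default weights are this package's design choice:
#' the five factors and the iterative ranking are fixed, their exact
#' combination is configurable.
#'
#' @param w_confidence,w_commonality,w_length,w_actionable,w_redundancy
#'   Nonnegative weights (defaults 1.0, 0.5, 0.25, 0.5, 1.0).
#' @return An object of class `rg_weights`.
#' @export
ranking_weights <- function(w_confidence = 1.0, w_commonality = 0.5,
                            w_length = 0.25, w_actionable = 0.5,
                            w_redundancy = 1.0) {
  w <- c(w_confidence = w_confidence, w_commonality = w_commonality,
         w_length = w_length, w_actionable = w_actionable,
         w_redundancy = w_redundancy)
  stopifnot(all(w >= 0))
  structure(as.list(w), class = "rg_weights")
}

.jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Rules matching an instance
#'
#' A rule matches an instance iff the instance satisfies every item on the
#' rule's left-hand side; missing feature values satisfy nothing, so an
#' instance with no items matches no rule.
#'
#' @param instance A single itemized instance: any list with an `items`
#'   element (character vector of item keys), e.g. one element of
#'   [itemized_instances()].
#' @param rules An `rg_rules` table.
#' @return The matching subset of `rules`.
#' @export
match_rules <- function(instance, rules) {
  stopifnot(inherits(rules, "rg_rules"))
  its <- instance$items
  keep <- vapply(rules$lhs, function(l) all(l %in% its), logical(1L))
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract single instances from an itemized set
#'
#' @param data An `rg_itemized`.
#' @param i Optional indices; default all.
#' @return A list of instances, each a list with `instance_id`, `items`,
#'   `outcome`, and `risk_score` (if present).
#' @export
itemized_instances <- function(data, i = seq_along(data$items)) {
  stopifnot(inherits(data, "rg_itemized"))
  lapply(i, function(j) {
    list(instance_id = data$instance_id[j], items = data$items[[j]],
         outcome = data$outcome[j],
         risk_score = if (is.null(data$risk_score)) NA_real_
                      else data$risk_score[j])
  })
}

#' Score one rule against the already-selected rules
#'
#' Implements the five-factor linear score of [ranking_weights()]. The
#' redundancy term is the maximum Jaccard overlap between the rule's
#' left-hand side and the left-hand sides of `selected` (0 when `selected`
#' is empty), so re-scoring a rule after an identical-LHS rule has been
#' selected lowers its score by exactly `w_redundancy`.
#'
#' @param rule A single-row `rg_rules` table (with `actionable` column; absent
#'   means not actionable).
#' @param selected An `rg_rules` table of already-selected rules (possibly
#'   empty).
#' @param weights An [ranking_weights()].
#' @param max_lhs The configured maximum left-hand-side length used to
#'   normalize the length penalty (default 5).
#' @return The numeric score.
#' @export
score_rule <- function(rule, selected = NULL, weights = ranking_weights(),
                       max_lhs = 5L) {
  stopifnot(inherits(rule, "rg_rules"), nrow(rule) == 1L)
  act <- if (!is.null(rule$actionable)) isTRUE(rule$actionable[1L]) else FALSE
  red <- 0
  if (!is.null(selected) && nrow(selected) > 0L) {
    red <- max(vapply(selected$lhs, .jaccard, numeric(1L), a = rule$lhs[[1L]]))
  }
  weights$w_confidence * rule$confidence[1L] +
    weights$w_commonality * rule$commonality[1L] -
    weights$w_length * (rule$k[1L] - 1) / max(1L, max_lhs - 1L) +
    weights$w_actionable * as.numeric(act) -
    weights$w_redundancy * red
}

#' Iteratively rank matching rules by the five-factor score
#'
#' Greedy selection: all unselected rules are scored against the current
#' selection, the maximum is selected (ties broken by higher confidence,
#' then fewer left-hand-side items, then lexicographic left-hand side), and
#' the process repeats. The reported score of each rule is its score at
#' selection time. The result is deterministic and invariant to the input
#' order of the rules.
#'
#' @param matching An `rg_rules` table of rules matching one instance.
#' @param weights An [ranking_weights()].
#' @param max_lhs Maximum left-hand-side length for the length penalty.
#' @param n_top Stop after selecting this many rules (default: rank all).
#' @return `matching` reordered by selection, with a `score` column.
#' @export
rank_rules <- function(matching, weights = ranking_weights(), max_lhs = 5L,
                       n_top = Inf) {
  stopifnot(inherits(matching, "rg_rules"))
  m <- nrow(matching)
  if (m == 0L) { matching$score <- numeric(); return(matching) }
  # static part of the score; redundancy updated incrementally
  act <- if (!is.null(matching$actionable)) matching$actionable else
    rep(FALSE, m)
  static <- weights$w_confidence * matching$confidence +
    weights$w_commonality * matching$commonality -
    weights$w_length * (matching$k - 1) / max(1L, max_lhs - 1L) +
    weights$w_actionable * as.numeric(act)
  red <- rep(0, m)
  picked <- integer()
  scores <- numeric()
  avail <- rep(TRUE, m)
  n_sel <- min(m, n_top)
  while (length(picked) < n_sel) {
    sc <- static - weights$w_redundancy * red
    sc[!avail] <- -Inf
    best <- which(sc == max(sc[avail]) & avail)
    if (length(best) > 1L) {     # deterministic tie-break
      o <- order(-matching$confidence[best], matching$k[best],
                 matching$lhs_key[best])
      best <- best[o[1L]]
    }
    picked <- c(picked, best)
    scores <- c(scores, sc[best])
    avail[best] <- FALSE
    if (any(avail)) {
      new_lhs <- matching$lhs[[best]]
      jac <- vapply(matching$lhs, .jaccard, numeric(1L), b = new_lhs)
      red <- pmax(red, jac)
    }
  }
  out <- matching[picked, , drop = FALSE]
  out$score <- scores
  rownames(out) <- NULL
  out
}

#' Flag the top fraction of predicted risks as positive
#'
#' Emulates a top-decile style operating point: exactly
#' `ceiling(fraction * n)` instances with the largest risk scores are flagged
#' `"predicted_bad"`, the rest `"predicted_good"`. Ties at the boundary are
#' broken by instance id (lexicographic), with a note when the tie actually
#' crosses the boundary.
#'
#' @param risk_scores Named numeric vector (names = instance ids).
#' @param fraction Fraction in (0, 1] of instances to flag (default 0.10).
#' @return Named character vector of `"predicted_bad"` / `"predicted_good"`.
#' @export
binarize_top_fraction <- function(risk_scores, fraction = 0.10) {
  stopifnot(is.numeric(risk_scores), fraction > 0, fraction <= 1)
  n <- length(risk_scores)
  if (n == 0L) return(stats::setNames(character(), character()))
  ids <- names(risk_scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (anyNA(risk_scores)) stop("risk scores must not be missing")
  m <- as.integer(ceiling(fraction * n))
  ord <- order(-risk_scores, ids)
  flagged <- ord[seq_len(m)]
  if (m < n && risk_scores[ord[m]] == risk_scores[ord[m + 1L]]) {
    message("binarize_top_fraction: tie at the risk cutoff broken by ",
            "instance id")
  }
  out <- rep("predicted_good", n)
  out[flagged] <- "predicted_bad"
  stats::setNames(out, ids)
}

#' Explain one prediction
#'
#' For an instance flagged `"predicted_bad"`: match the pruned rules, rank
#' them with [rank_rules()], keep the top `n_top`, and attach per-item
#' interpretations and interventions from the knowledge base (plus any
#' combination-level interventions whose item set the rule contains). For a
#' `"predicted_good"` instance the ranked list is empty but the matching
#' counts are still computed, as required by the outcome-level coverage
#' metric.
#'
#' @param instance A single itemized instance (see [itemized_instances()]).
#' @param prediction `"predicted_bad"` or `"predicted_good"`.
#' @param rules An `rg_rules` table with rhs = bad (ideally pruned and
#'   actionability-annotated).
#' @param kb An `rg_kb`.
#' @param n_top Number of ranked rules to present (default 3).
#' @param weights An [ranking_weights()].
#' @param max_lhs Maximum left-hand-side length for the length penalty.
#' @return An object of class `rg_explanation`: `instance_id`, `prediction`,
#'   `ranked` (list of entries with `rule`, `score`, `items` each carrying
#'   `display`, `interpretation`, `interventions`, plus
#'   `combination_interventions`), `n_matching`, `n_matching_actionable`,
#'   `unique_actionable_items`.
#' @export
explain_instance <- function(instance, prediction, rules, kb = knowledge_base(),
                             n_top = 3L, weights = ranking_weights(),
                             max_lhs = 5L) {
  stopifnot(inherits(rules, "rg_rules"),
            prediction %in% c("predicted_bad", "predicted_good"))
  if (length(unique(rules$rhs)) > 1L) {
    stop("explanation rules must share the bad right-hand side")
  }
  if (is.null(rules$actionable)) rules <- annotate_actionability(rules, kb)
  matched <- match_rules(instance, rules)
  all_items <- unique(unlist(matched$lhs, use.names = FALSE))
  act_items <- all_items[is_actionable(kb, as.list(all_items))]
  ranked <- list()
  if (prediction == "predicted_bad" && nrow(matched) > 0L) {
    top <- rank_rules(matched, weights = weights, max_lhs = max_lhs,
                      n_top = n_top)
    ranked <- lapply(seq_len(nrow(top)), function(i) {
      lhs <- top$lhs[[i]]
      per_item <- lapply(lhs, function(k) {
        a <- .kb_lookup(kb, k)
        disp <- if (!is.null(a$item)) format(a$item) else k
        list(key = k, display = disp, interpretation = a$interpretation,
             interventions = a$interventions)
      })
      list(rule = top[i, , drop = FALSE], score = top$score[i],
           items = per_item,
           combination_interventions = .combination_interventions(kb, lhs))
    })
  }
  structure(list(instance_id = instance$instance_id,
                 prediction = prediction,
                 ranked = ranked,
                 n_matching = nrow(matched),
                 n_matching_actionable = sum(matched$actionable),
                 unique_actionable_items = length(act_items)),
            class = "rg_explanation")
}

#' @export
print.rg_explanation <- function(x, ...) {
  cat("Explanation for instance ", x$instance_id, " (", x$prediction, ")\n",
      "  matching rules: ", x$n_matching, " (", x$n_matching_actionable,
      " actionable), unique actionable items: ", x$unique_actionable_items,
      "\n", sep = "")
  if (!length(x$ranked)) {
    if (x$prediction == "predicted_bad" && x$n_matching == 0L) {
      cat("  no rule matches this instance: prediction left unexplained\n")
    }
    return(invisible(x))
  }
  for (i in seq_along(x$ranked)) {
    e <- x$ranked[[i]]
    r <- e$rule
    cat("\n  Rank ", i, " (score ", sprintf("%.4f", e$score),
        ", confidence ", sprintf("%.3f", r$confidence),
        ", commonality ", sprintf("%.3f", r$commonality), "):\n    ",
        paste(vapply(e$items, `[[`, character(1L), "display"),
              collapse = " AND "),
        " -> ", r$rhs, " outcome\n", sep = "")
    for (it in e$items) {
      cat("      * ", it$display, "\n", sep = "")
      if (nzchar(it$interpretation)) {
        cat("        interpretation: ", it$interpretation, "\n", sep = "")
      }
      for (v in it$interventions) {
        cat("        intervention:  ", v, "\n", sep = "")
      }
    }
    for (v in e$combination_interventions) {
      cat("      combination intervention: ", v, "\n", sep = "")
    }
  }
  invisible(x)
}
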