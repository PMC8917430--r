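# Class-based association rule mining.
#
# Rules have the form  p_1 AND p_2 AND ... AND p_k -> z  where each p_i is a
# feature-value item and z is the bad outcome class. Two quality measures:
#   commonality = n(LHS & z) / n(z)   (within-class support / rule coverage)
#   confidence  = n(LHS & z) / n(LHS) (rule precision)
# Enumeration is level-wise Apriori. Commonality is anti-monotone, so
# candidate generation prunes on commonality computed from within-class
# instance lists only; the confidence floor is applied at output, never for
# candidate pruning.

#' Mining configuration: the five control parameters
#'
#' The mining-and-pruning process is controlled by five parameters: the
#' number of top-ranked features used to form rules, the upper limit on
#' left-hand-side length, the commonality floor, the confidence floor, and
#' the confidence-difference tolerance used by subsumption pruning. Defaults
#' follow common practice for class-based association rules on imbalanced
#' clinical data: top 80 features, at most 5 items per rule, commonality
#' >= 1%, confidence >= 50%, confidence difference 0.15.
#'
#' @param top_k_features Number of highest-importance features used to form
#'   rules (default 80).
#' @param max_lhs_items Upper limit on the number of left-hand-side items
#'   (default 5).
#' @param min_commonality Commonality floor in (0, 1] (default 0.01).
#' @param min_confidence Confidence floor in (0, 1] (default 0.5).
#' @param conf_diff_upper Confidence-difference tolerance in [0, 1] used by
#'   [prune_subsumed()] (default 0.15).
#' @param target_class Outcome value forming the right-hand side
#'   (default `"bad"`).
#' @param max_candidates Hard budget on the per-level candidate queue; the
#'   miner fails fast when exceeded with an instruction to lower
#'   `top_k_features` (default `5e6`).
#' @return An object of class `rg_config`.
#' @export
mining_config <- function(top_k_features = 80L, max_lhs_items = 5L,
                          min_commonality = 0.01, min_confidence = 0.5,
                          conf_diff_upper = 0.15, target_class = "bad",
                          max_candidates = 5e6) {
  stopifnot(top_k_features >= 1L, max_lhs_items >= 1L,
            min_commonality > 0, min_commonality <= 1,
            min_confidence > 0, min_confidence <= 1,
            conf_diff_upper >= 0, conf_diff_upper <= 1,
            is.character(target_class), length(target_class) == 1L)
  structure(list(top_k_features = as.integer(top_k_features),
                 max_lhs_items = as.integer(max_lhs_items),
                 min_commonality = min_commonality,
                 min_confidence = min_confidence,
                 conf_diff_upper = conf_diff_upper,
                 target_class = target_class,
                 max_candidates = max_candidates),
            class = "rg_config")
}

#' @export
print.rg_config <- function(x, ...) {
  cat("<mining config> top features: ", x$top_k_features,
      ", max LHS items: ", x$max_lhs_items,
      ", commonality >= ", x$min_commonality,
      ", confidence >= ", x$min_confidence,
      ", confidence-difference tolerance: ", x$conf_diff_upper,
      ", target class: ", x$target_class, "\n", sep = "")
  invisible(x)
}

#' Select the highest-importance features
#'
#' Keeps the `k` features with the largest importance weights from the
#' upstream model; ties are broken by feature name (lexicographic) so the
#' selection is deterministic. When `k` exceeds the number of features, all
#' are returned with a warning.
#'
#' @param features An `rg_features` table.
#' @param k Number of features to keep.
#' @return An `rg_features` table with at most `k` rows.
#' @export
select_top_features <- function(features, k) {
  stopifnot(inherits(features, "rg_features"), k >= 1L)
  if (k > nrow(features)) {
    warning("k = ", k, " exceeds the ", nrow(features),
            " available features; returning all")
    k <- nrow(features)
  }
  ord <- order(-features$importance, features$name)
  out <- features[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal constructor for the canonical rule table.
.rules_df <- function(lhs, rhs, n_lhs, n_lhs_and_z, n_z) {
  lhs <- lapply(lhs, function(l) sort(as.character(l)))
  lhs_key <- vapply(lhs, paste, character(1L), collapse = " & ")
  k <- lengths(lhs)
  rhs <- rep_len(rhs, length(lhs))
  df <- data.frame(lhs_key = lhs_key, k = as.integer(k), rhs = rhs,
                   n_lhs = as.integer(n_lhs),
                   n_lhs_and_z = as.integer(n_lhs_and_z),
                   n_z = as.integer(n_z),
                   stringsAsFactors = FALSE)
  df$lhs <- lhs
  df$commonality <- df$n_lhs_and_z / df$n_z
  df$confidence <- df$n_lhs_and_z / df$n_lhs
  ord <- order(df$k, df$lhs_key)
  df <- df[ord, c("lhs", "lhs_key", "k", "rhs", "n_lhs", "n_lhs_and_z",
                  "n_z", "commonality", "confidence"), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("rg_rules", "data.frame")
  df
}

.empty_rules <- function(rhs = "bad") {
  .rules_df(list(), character(), integer(), integer(), integer())
}

#' Mine class-based association rules with Apriori
#'
#' Enumerates every rule over `allowed_items` with at most
#' `cfg$max_lhs_items` left-hand-side items, commonality at or above
#' `cfg$min_commonality` and confidence at or above `cfg$min_confidence`,
#' with the target class as right-hand side. Enumeration is level-wise:
#' candidates whose within-class support falls below the commonality floor
#' are pruned (commonality is anti-monotone); the confidence floor is a pure
#' output filter. Left-hand sides never contain two items on the same
#' feature, since the partition convention makes such conjunctions
#' unsatisfiable. Output order is canonical: LHS size ascending, then
#' lexicographic LHS key.
#'
#' @param data An `rg_itemized` training set (see [itemize()]).
#' @param allowed_items Items eligible to appear on left-hand sides: a list
#'   of `rg_item` objects or a character vector of canonical keys.
#' @param cfg An [mining_config()].
#' @return An `rg_rules` data frame with list-column `lhs` (sorted item
#'   keys), `lhs_key`, `k`, `rhs`, exact counts `n_lhs`, `n_lhs_and_z`,
#'   `n_z`, and `commonality`, `confidence`.
#' @export
mine_rules <- function(data, allowed_items, cfg = mining_config()) {
  stopifnot(inherits(data, "rg_itemized"), inherits(cfg, "rg_config"))
  keys <- if (is.character(allowed_items)) allowed_items
          else item_key(allowed_items)
  feat_of <- sub("[:=].*$", "", keys)          # canonical key starts with name
  names(feat_of) <- keys
  z <- cfg$target_class
  is_z <- data$outcome == z
  n_z <- sum(is_z)
  if (n_z == 0L) stop("no instances of target class '", z, "' in the data")
  if (!length(keys)) return(.empty_rules(z))

  # inverted index: item key -> sorted instance indices (full cohort)
  lens <- lengths(data$items)
  inst <- rep.int(seq_along(data$items), lens)
  flat <- unlist(data$items, use.names = FALSE)
  keep <- flat %in% keys
  supp_full <- split(inst[keep], factor(flat[keep], levels = keys))
  supp_z <- lapply(supp_full, function(s) s[is_z[s]])

  comm_ok <- function(n_both) n_both / n_z >= cfg$min_commonality

  # frequent level 1
  freq <- list()
  lvl <- list()
  for (key in sort(keys)) {
    sz <- supp_z[[key]]
    if (comm_ok(length(sz))) {
      lvl[[length(lvl) + 1L]] <- list(lhs = key, sz = sz,
                                      sf = supp_full[[key]])
    }
  }
  freq[[1L]] <- lvl

  lk <- 1L
  while (lk < cfg$max_lhs_items && length(freq[[lk]]) > 1L) {
    prev <- freq[[lk]]
    prev_keys <- vapply(prev, function(e) paste(e$lhs, collapse = " & "),
                        character(1L))
    prev_set <- new.env(parent = emptyenv())
    for (pk in prev_keys) assign(pk, TRUE, envir = prev_set)
    nxt <- list()
    n_cand <- 0L
    # join step: pairs sharing the first lk-1 items (lexicographic order)
    prefix <- vapply(prev, function(e)
      paste(e$lhs[-lk], collapse = " & "), character(1L))
    groups <- split(seq_along(prev), prefix)
    for (g in groups) {
      if (length(g) < 2L) next
      for (a in seq_len(length(g) - 1L)) {
        for (b in seq((a + 1L), length(g))) {
          ea <- prev[[g[a]]]; eb <- prev[[g[b]]]
          new_item <- eb$lhs[lk]
          lhs <- c(ea$lhs, new_item)           # stays sorted
          if (anyDuplicated(feat_of[lhs])) next
          # Apriori subset check: all lk-subsets frequent
          if (lk >= 2L) {
            ok <- TRUE
            for (drop_i in seq_len(lk - 1L)) {
              sub <- paste(lhs[-drop_i], collapse = " & ")
              if (!exists(sub, envir = prev_set, inherits = FALSE)) {
                ok <- FALSE; break
              }
            }
            if (!ok) next
          }
          n_cand <- n_cand + 1L
          if (n_cand > cfg$max_candidates) {
            stop("candidate budget (", cfg$max_candidates, ") exceeded at LHS ",
                 "size ", lk + 1L, "; lower top_k_features or raise ",
                 "min_commonality")
          }
          sz <- ea$sz[ea$sz %in% supp_z[[new_item]]]
          if (!comm_ok(length(sz))) next
          sf <- ea$sf[ea$sf %in% supp_full[[new_item]]]
          nxt[[length(nxt) + 1L]] <- list(lhs = lhs, sz = sz, sf = sf)
        }
      }
    }
    freq[[lk + 1L]] <- nxt
    lk <- lk + 1L
    if (!length(nxt)) break
  }

  all_freq <- unlist(freq, recursive = FALSE)
  if (!length(all_freq)) return(.empty_rules(z))
  n_lhs <- vapply(all_freq, function(e) length(e$sf), integer(1L))
  n_both <- vapply(all_freq, function(e) length(e$sz), integer(1L))
  conf <- n_both / n_lhs
  keep <- n_lhs > 0L & conf >= cfg$min_confidence
  .rules_df(lapply(all_freq[keep], `[[`, "lhs"), z,
            n_lhs[keep], n_both[keep], rep.int(n_z, sum(keep)))
}

#' Exact counts and quality measures of one candidate left-hand side
#'
#' An instance satisfies the left-hand side iff it satisfies every item
#' (missing feature values satisfy nothing). A left-hand side satisfied by
#' no instance has undefined confidence; such a rule is never emitted by the
#' miner, and here yields `confidence = NA`.
#'
#' @param lhs Character vector of item keys (or a list of `rg_item`).
#' @param data An `rg_itemized` set.
#' @param z Target outcome class (default `"bad"`).
#' @return A list with `n_lhs`, `n_lhs_and_z`, `n_z`, `commonality`,
#'   `confidence`.
#' @export
rule_stats <- function(lhs, data, z = "bad") {
  stopifnot(inherits(data, "rg_itemized"))
  if (!is.character(lhs)) lhs <- item_key(lhs)
  sat <- vapply(data$items, function(it) all(lhs %in% it), logical(1L))
  is_z <- data$outcome == z
  n_z <- sum(is_z)
  stopifnot(n_z > 0L)
  n_lhs <- sum(sat)
  n_both <- sum(sat & is_z)
  list(n_lhs = n_lhs, n_lhs_and_z = n_both, n_z = n_z,
       commonality = n_both / n_z,
       confidence = if (n_lhs > 0L) n_both / n_lhs else NA_real_)
}

#' Flag actionable rules against a knowledge base
#'
#' A rule is actionable iff at least one of its left-hand-side items is
#' actionable (carries >= 1 intervention in the knowledge base).
#'
#' @param rules An `rg_rules` table.
#' @param kb An `rg_kb`.
#' @return The rules with a logical `actionable` column added/updated.
#' @export
annotate_actionability <- function(rules, kb) {
  stopifnot(inherits(rules, "rg_rules"), inherits(kb, "rg_kb"))
  act_keys <- names(kb$annotations)[vapply(kb$annotations, function(a)
    length(a$interventions) > 0L, logical(1L))]
  rules$actionable <- vapply(rules$lhs, function(l) any(l %in% act_keys),
                             logical(1L))
  rules
}

#' Render rules in the canonical "p1 AND p2 -> z" form
#'
#' @param rules An `rg_rules` table.
#' @param index Optional named item list (e.g. `scheme$index`) used to render
#'   item displays instead of raw keys.
#' @return Character vector, one string per rule.
#' @export
format_rules <- function(rules, index = NULL) {
  stopifnot(inherits(rules, "rg_rules"))
  vapply(seq_len(nrow(rules)), function(i) {
    parts <- rules$lhs[[i]]
    if (!is.null(index)) {
      parts <- vapply(parts, function(k) {
        it <- index[[k]]
        if (is.null(it)) k else format(it)
      }, character(1L))
    }
    sprintf("%s -> %s  (confidence %.3f, commonality %.3f)",
            paste(parts, collapse = " AND "), rules$rhs[i],
            rules$confidence[i], rules$commonality[i])
  }, character(1L))
}

#' @export
print.rg_rules <- function(x, n = 10L, ...) {
  cat("<rules> ", nrow(x), " class-based association rule(s)\n", sep = "")
  if (nrow(x)) {
    shown <- utils::head(seq_len(nrow(x)), n)
    cat(paste0("  ", format_rules(x[shown, , drop = FALSE])), sep = "\n")
    if (nrow(x) > n) cat("  ... and ", nrow(x) - n, " more\n", sep = "")
  }
  invisible(x)
}

#' Read / write rules as JSON lines
#'
#' One JSON object per line with fields `lhs` (item keys), `rhs`, `n_lhs`,
#' `n_lhs_and_z`, `n_z`, `commonality`, `confidence`.
#'
#' @param path Path to the `.jsonl` file.
#' @return `read_rules` returns an `rg_rules` table.
#' @export
read_rules <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  if (!length(recs)) return(.empty_rules())
  .rules_df(lapply(recs, function(r) as.character(r$lhs)),
            vapply(recs, function(r) r$rhs, character(1L)),
            vapply(recs, function(r) r$n_lhs, numeric(1L)),
            vapply(recs, function(r) r$n_lhs_and_z, numeric(1L)),
            vapply(recs, function(r) r$n_z, numeric(1L)))
}

#' @rdname read_rules
#' @param rules An `rg_rules` table.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rg_rules"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(rules))) {
    rec <- list(lhs = rules$lhs[[i]], rhs = rules$rhs[i],
                n_lhs = rules$n_lhs[i], n_lhs_and_z = rules$n_lhs_and_z[i],
                n_z = rules$n_z[i], commonality = rules$commonality[i],
                confidence = rules$confidence[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
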