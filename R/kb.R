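# Knowledge base: expert annotations per feature-value item.
#
# For every item an expert may record whether the item could be positively
# correlated with the bad outcome, a one-line clinical interpretation, and a
# list of interventions. An item with >= 1 intervention is "actionable"; a
# rule whose left-hand side contains >= 1 actionable item is an actionable
# rule. Unannotated items default to not-positively-correlated with no
# interventions.

#' Annotate one item
#'
#' @param item An [item_equals()] or [item_interval()] object.
#' @param positively_correlated Did the expert judge this feature-value pair
#'   as possibly positively correlated with the bad outcome?
#' @param interpretation One-line clinical reading of the item.
#' @param interventions Character vector of intervention texts (possibly
#'   empty). The item is actionable iff this is non-empty.
#' @return An object of class `rg_kb_annotation`.
#' @export
kb_annotation <- function(item, positively_correlated = FALSE,
                          interpretation = "", interventions = character()) {
  stopifnot(inherits(item, "rg_item"),
            is.logical(positively_correlated),
            length(positively_correlated) == 1L)
  structure(list(item = item,
                 positively_correlated = positively_correlated,
                 interpretation = as.character(interpretation),
                 interventions = as.character(interventions)),
            class = "rg_kb_annotation")
}

#' Build a knowledge base from annotations
#'
#' @param annotations A list of [kb_annotation()] objects. Two annotations on
#'   the same item (same canonical key) are a fatal error.
#' @param combinations Optional list of combination-level entries, each a list
#'   with `items` (a list of `rg_item`) and `interventions` (character).
#'   Interventions recorded here are attached to a presented rule whenever its
#'   left-hand side contains the whole combination.
#' @return An object of class `rg_kb`.
#' @export
knowledge_base <- function(annotations = list(), combinations = list()) {
  keys <- vapply(annotations, function(a) item_key(a$item), character(1L))
  if (anyDuplicated(keys)) {
    stop("duplicate knowledge-base entries for item(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  combos <- lapply(combinations, function(cb) {
    stopifnot(is.list(cb$items), length(cb$items) >= 2L)
    list(keys = sort(item_key(cb$items)),
         interventions = as.character(cb$interventions))
  })
  structure(list(annotations = stats::setNames(annotations, keys),
                 combinations = combos),
            class = "rg_kb")
}

# Internal: canonical-key lookup; returns the default annotation when absent.
.kb_lookup <- function(kb, key) {
  a <- kb$annotations[[key]]
  if (is.null(a)) {
    list(item = NULL, positively_correlated = FALSE, interpretation = "",
         interventions = character())
  } else a
}

.kb_key_of <- function(item) {
  if (inherits(item, "rg_item")) item_key(item) else as.character(item)
}

#' Is an item actionable?
#'
#' An item is actionable iff its knowledge-base annotation carries at least
#' one intervention. Unannotated items are not actionable.
#'
#' @param kb An `rg_kb`.
#' @param item An `rg_item` or a canonical item key string.
#' @return Logical scalar (vectorized over a list/vector of items).
#' @export
is_actionable <- function(kb, item) {
  stopifnot(inherits(kb, "rg_kb"))
  keys <- if (is.list(item) && !inherits(item, "rg_item")) {
    vapply(item, .kb_key_of, character(1L))
  } else .kb_key_of(item)
  vapply(keys, function(k) length(.kb_lookup(kb, k)$interventions) > 0L,
         logical(1L), USE.NAMES = FALSE)
}

#' Keys of items labeled positively correlated
#' @param kb An `rg_kb`.
#' @return Character vector of canonical item keys.
#' @export
positive_item_keys <- function(kb) {
  stopifnot(inherits(kb, "rg_kb"))
  pos <- vapply(kb$annotations, function(a) isTRUE(a$positively_correlated),
                logical(1L))
  names(kb$annotations)[pos]
}

#' Interventions attached to each item of a rule's left-hand side
#'
#' Returns the per-item intervention lists in left-hand-side order; items
#' without interventions map to empty lists. The same intervention text may
#' legitimately appear under several distinct items and is not deduplicated
#' here (deduplication is a presentation choice).
#'
#' @param kb An `rg_kb`.
#' @param items A list of `rg_item` objects or a character vector of keys.
#' @return A named list (by canonical key) of character vectors.
#' @export
interventions_for <- function(kb, items) {
  stopifnot(inherits(kb, "rg_kb"))
  keys <- if (is.character(items)) items else item_key(items)
  out <- lapply(keys, function(k) .kb_lookup(kb, k)$interventions)
  stats::setNames(out, keys)
}

# Internal: combination-level interventions whose item set is contained in
# the given LHS keys.
.combination_interventions <- function(kb, lhs_keys) {
  hits <- Filter(function(cb) all(cb$keys %in% lhs_keys), kb$combinations)
  unlist(lapply(hits, `[[`, "interventions"), use.names = FALSE)
}

.condition_to_item <- function(feature, condition) {
  if (!is.null(condition$equals)) {
    item_equals(feature, condition$equals)
  } else if (!is.null(condition$interval)) {
    iv <- condition$interval
    lo <- if (is.null(iv$lower)) -Inf else as.numeric(iv$lower)
    hi <- if (is.null(iv$upper)) Inf else as.numeric(iv$upper)
    item_interval(feature, lo, hi)
  } else {
    stop("knowledge-base condition must contain 'equals' or 'interval'")
  }
}

#' Read / write a knowledge base as JSON
#'
#' The file holds an object with an `annotations` array (records with
#' `feature`, `condition` = `{"equals": level}` or
#' `{"interval": {"lower": a, "upper": b}}`, `positively_correlated`,
#' `interpretation`, `interventions`) and an optional `combinations` array.
#' A top-level JSON array is accepted as the annotations list. Duplicate
#' items and malformed intervals (`lower >= upper`) are fatal.
#'
#' @param path Path to the JSON file.
#' @return `read_kb` returns an `rg_kb`.
#' @export
read_kb <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(names(doc)) && ("annotations" %in% names(doc))) {
    ann_recs <- doc$annotations
    cmb_recs <- if (is.null(doc$combinations)) list() else doc$combinations
  } else {
    ann_recs <- doc
    cmb_recs <- list()
  }
  anns <- lapply(ann_recs, function(r) {
    kb_annotation(
      item = .condition_to_item(r$feature, r$condition),
      positively_correlated = isTRUE(r$positively_correlated),
      interpretation = if (is.null(r$interpretation)) "" else r$interpretation,
      interventions = unlist(r$interventions, use.names = FALSE)
    )
  })
  combos <- lapply(cmb_recs, function(r) {
    list(items = lapply(r$items,
                        function(x) .condition_to_item(x$feature, x$condition)),
         interventions = unlist(r$interventions, use.names = FALSE))
  })
  knowledge_base(anns, combos)
}

.item_to_record <- function(it) {
  cond <- if (it$kind == "equals") {
    list(equals = it$value)
  } else {
    iv <- list()
    if (is.finite(it$lower)) iv$lower <- it$lower
    if (is.finite(it$upper)) iv$upper <- it$upper
    list(interval = iv)
  }
  list(feature = it$feature, condition = cond)
}

#' @rdname read_kb
#' @param kb An `rg_kb`.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "rg_kb"))
  anns <- lapply(kb$annotations, function(a) {
    c(.item_to_record(a$item),
      list(positively_correlated = a$positively_correlated,
           interpretation = a$interpretation,
           interventions = as.list(a$interventions)))
  })
  combos <- lapply(kb$combinations, function(cb) {
    list(items = lapply(cb$keys, function(k) {
      # keys are canonical; reconstruct via the annotated item when available
      a <- kb$annotations[[k]]
      if (is.null(a)) stop("combination references unannotated item: ", k)
      .item_to_record(a$item)
    }), interventions = as.list(cb$interventions))
  })
  jsonlite::write_json(list(annotations = unname(anns), combinations = combos),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.rg_kb <- function(x, ...) {
  n <- length(x$annotations)
  cat("<knowledge base> ", n, " annotated item(s); ",
      length(positive_item_keys(x)), " positively correlated; ",
      sum(vapply(x$annotations, function(a) length(a$interventions) > 0L,
                 logical(1L))), " actionable; ",
      length(x$combinations), " combination entr(ies)\n", sep = "")
  invisible(x)
}
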