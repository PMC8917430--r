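# Synthetic cohort generator with planted rules.
#
# Emulates the statistical shape of an imbalanced EHR-derived cohort: mixed
# continuous/categorical features, a rare bad outcome (a few percent off any
# planted rule), and planted conjunctive rules of known carrier fraction and
# confidence. Each planted rule controls the columns of its left-hand-side
# features so that exactly its carriers satisfy the conjunction; the outcome
# is then drawn as bad with probability confidence_target for instances
# satisfying a planted left-hand side (the maximum over matching rules) and
# background_rate otherwise. Everything is deterministic given the seed.

#' Describe one planted rule
#'
#' @param lhs A list of `rg_item` objects, at most one per feature.
#'   Continuous items must be upper-tail intervals `[lower, Inf)` with
#'   `lower >= 2`; the planted feature is generated as an integer count
#'   (like visit or prescription counts): carriers draw uniformly from
#'   `{ceiling(lower) + 1, ..., ceiling(lower) + 5}` and non-carriers from
#'   `{0, ..., ceiling(lower) - 2}`, leaving an empty margin band around
#'   `lower` so the supervised discretizer can recover an equivalent cut.
#' @param carrier_fraction Fraction in (0, 1) of instances made to satisfy
#'   the whole left-hand side.
#' @param confidence_target Probability in (0, 1] of the bad outcome for
#'   instances satisfying the left-hand side.
#' @return An object of class `rg_planted`.
#' @export
planted_rule <- function(lhs, carrier_fraction, confidence_target) {
  stopifnot(is.list(lhs), length(lhs) >= 1L,
            carrier_fraction > 0, carrier_fraction < 1,
            confidence_target > 0, confidence_target <= 1)
  feats <- vapply(lhs, function(it) it$feature, character(1L))
  if (anyDuplicated(feats)) stop("planted rule has two items on one feature")
  for (it in lhs) {
    if (it$kind == "interval") {
      if (!(is.finite(it$lower) && !is.finite(it$upper))) {
        stop("continuous planted items must be upper-tail intervals [lower, Inf)")
      }
      if (it$lower < 2) stop("continuous planted items need lower >= 2")
    }
  }
  structure(list(lhs = lhs, features = feats,
                 carrier_fraction = carrier_fraction,
                 confidence_target = confidence_target),
            class = "rg_planted")
}

#' Simulation configuration
#'
#' Defaults mirror an imbalanced clinical cohort: a bad-outcome background
#' rate of 5% (outcome prevalence in the absence of planted rules), mixed
#' continuous/categorical features, and no injected missingness unless
#' requested.
#'
#' @param n_instances Number of instances.
#' @param n_features Number of features; continuous features are named
#'   `x01, x02, ...` and categorical ones `c01, c02, ...`.
#' @param continuous_fraction Fraction of features that are continuous
#'   (default 0.5).
#' @param background_rate Bad-outcome probability off any planted rule
#'   (default 0.05).
#' @param planted_rules List of [planted_rule()] objects; two rules may not
#'   plant items on the same feature. Default: none.
#' @param missing_rate Probability of masking any feature cell to missing
#'   (default 0; the outcome column is never masked).
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return An object of class `rg_simconfig`.
#' @export
sim_config <- function(n_instances = 5000L, n_features = 20L,
                       continuous_fraction = 0.5, background_rate = 0.05,
                       planted_rules = list(), missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_instances >= 2L, n_features >= 1L,
            continuous_fraction >= 0, continuous_fraction <= 1,
            background_rate > 0, background_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  if (length(planted_rules)) {
    confs <- vapply(planted_rules, `[[`, numeric(1L), "confidence_target")
    if (background_rate >= min(confs)) {
      stop("background_rate must be below every planted confidence target")
    }
    feats <- unlist(lapply(planted_rules, `[[`, "features"))
    if (anyDuplicated(feats)) {
      stop("infeasible planted rules: two rules plant items on feature(s) ",
           paste(unique(feats[duplicated(feats)]), collapse = ", "))
    }
  }
  structure(list(n_instances = as.integer(n_instances),
                 n_features = as.integer(n_features),
                 continuous_fraction = continuous_fraction,
                 background_rate = background_rate,
                 planted_rules = planted_rules,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "rg_simconfig")
}

.sim_feature_names <- function(cfg) {
  n_cont <- round(cfg$continuous_fraction * cfg$n_features)
  n_cat <- cfg$n_features - n_cont
  list(continuous = sprintf("x%02d", seq_len(n_cont)),
       categorical = sprintf("c%02d", seq_len(n_cat)))
}

.CAT_LEVELS <- c("low", "mid", "high")

#' Default planted-rule set for a cohort
#'
#' Five conjunctive rules with confidences spanning 0.6-0.9 and carrier
#' fractions 0.05-0.2, mixing categorical equality items and upper-tail
#' continuous items across left-hand sides of 1-3 items. Intended as the
#' standard signal configuration for recovery studies.
#'
#' @param nm Feature-name lists as produced internally; normally leave
#'   default and pass `cfg` instead.
#' @param cfg An [sim_config()] (used for feature names); planted features
#'   are taken from the front of the name lists.
#' @param carrier_fractions,confidences Numeric vectors of length 5.
#' @return A list of five [planted_rule()] objects.
#' @export
default_planted_rules <- function(cfg,
                                  carrier_fractions = c(0.05, 0.08, 0.12,
                                                        0.16, 0.20),
                                  confidences = c(0.90, 0.825, 0.75,
                                                  0.675, 0.60),
                                  nm = .sim_feature_names(cfg)) {
  stopifnot(length(carrier_fractions) == 5L, length(confidences) == 5L)
  if (length(nm$continuous) < 5L || length(nm$categorical) < 3L) {
    stop("default planted rules need >= 5 continuous and >= 3 categorical features")
  }
  xt <- function(i) item_interval(nm$continuous[i], 7, Inf)
  ct <- function(i) item_equals(nm$categorical[i], "high")
  lhss <- list(list(xt(1L)),
               list(ct(1L)),
               list(xt(2L), ct(2L)),
               list(xt(3L), xt(4L)),
               list(xt(5L), ct(3L)))
  Map(planted_rule, lhss, as.list(carrier_fractions), as.list(confidences))
}

#' Generate a synthetic cohort with planted rules
#'
#' Feature columns are drawn independently except those named by planted
#' left-hand sides. For a planted continuous item `[lower, Inf)` the feature
#' is an integer count: carriers draw uniformly from the block
#' `{ceiling(lower) + 1, ..., ceiling(lower) + 5}` and everyone else from
#' `{0, ..., ceiling(lower) - 2}`, so the satisfier set of the item equals
#' its carrier set exactly and an empty margin band separates the two value
#' blocks.
#' For a planted equality item, carriers get the planted level and everyone
#' else one of the remaining levels. Carrier sets of different rules are
#' disjoint (carrier fractions must sum below 1), so every planted rule's
#' bad-outcome probability is exactly its own confidence target; in general
#' the outcome probability of an instance is the maximum confidence target
#' over the planted left-hand sides it satisfies, or the background rate
#' when it satisfies none.
#' Missing values are then injected uniformly over feature cells (never the
#' outcome), and a predicted risk score correlated with the generating
#' probability is attached.
#'
#' @param cfg An [sim_config()].
#' @return A list with `cohort` (an `rg_cohort` including a `risk_score`
#'   column), and `truth`: the planted rules augmented with realized
#'   `carrier_count`, `empirical_confidence` and `empirical_commonality`
#'   (measured before missingness injection).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "rg_simconfig"))
  set.seed(cfg$seed)
  n <- cfg$n_instances
  nm <- .sim_feature_names(cfg)
  planted_items <- list()
  for (pr in cfg$planted_rules) {
    for (it in pr$lhs) planted_items[[it$feature]] <- it
  }
  unknown <- setdiff(names(planted_items), c(nm$continuous, nm$categorical))
  if (length(unknown)) {
    stop("planted items reference unknown feature(s): ",
         paste(unknown, collapse = ", "))
  }
  data <- list()
  # background columns
  for (f in nm$continuous) {
    data[[f]] <- if (is.null(planted_items[[f]])) stats::runif(n) else NA_real_
  }
  for (f in nm$categorical) {
    data[[f]] <- if (is.null(planted_items[[f]])) {
      sample(.CAT_LEVELS, n, replace = TRUE)
    } else NA_character_
  }
  # planted columns: satisfier set == carrier set, by construction.
  # Carrier sets are disjoint across rules so every planted rule's outcome
  # probability equals its own confidence target exactly.
  if (length(cfg$planted_rules)) {
    total_cf <- sum(vapply(cfg$planted_rules, `[[`, numeric(1L),
                           "carrier_fraction"))
    if (total_cf >= 1) {
      stop("infeasible planted rules: carrier fractions sum to ", total_cf,
           " >= 1")
    }
  }
  satisfies <- matrix(FALSE, nrow = n, ncol = length(cfg$planted_rules))
  pool <- seq_len(n)
  for (j in seq_along(cfg$planted_rules)) {
    pr <- cfg$planted_rules[[j]]
    m <- max(1L, round(pr$carrier_fraction * n))
    carriers <- sort(sample(pool, m))
    pool <- setdiff(pool, carriers)
    in_c <- seq_len(n) %in% carriers
    satisfies[, j] <- in_c
    for (it in pr$lhs) {
      if (it$kind == "interval") {
        L <- ceiling(it$lower)
        v <- numeric(n)
        v[in_c] <- sample(seq(L + 1L, L + 5L), m, replace = TRUE)
        v[!in_c] <- sample(seq(0L, L - 2L), n - m, replace = TRUE)
        data[[it$feature]] <- v
      } else {
        other <- setdiff(.CAT_LEVELS, it$value)
        if (!length(other)) other <- paste0("not_", it$value)
        v <- character(n)
        v[in_c] <- it$value
        v[!in_c] <- sample(other, n - m, replace = TRUE)
        data[[it$feature]] <- v
      }
    }
  }
  # outcome: max planted confidence among satisfied LHSs, else background
  p_bad <- rep(cfg$background_rate, n)
  if (length(cfg$planted_rules)) {
    confs <- vapply(cfg$planted_rules, `[[`, numeric(1L), "confidence_target")
    for (j in order(confs)) p_bad[satisfies[, j]] <- confs[j]
    p_bad <- pmax(p_bad, cfg$background_rate)
  }
  outcome <- ifelse(stats::runif(n) < p_bad, "bad", "good")
  # empirical quality of each planted rule, pre-missingness
  n_bad <- sum(outcome == "bad")
  truth <- lapply(seq_along(cfg$planted_rules), function(j) {
    pr <- cfg$planted_rules[[j]]
    sat <- satisfies[, j]
    pr$carrier_count <- sum(sat)
    pr$empirical_confidence <- if (any(sat)) mean(outcome[sat] == "bad")
                               else NA_real_
    pr$empirical_commonality <- if (n_bad > 0L) sum(sat & outcome == "bad") / n_bad
                                else NA_real_
    pr
  })
  # risk score: noisy monotone transform of the generating probability
  risk <- stats::plogis(stats::qlogis(pmin(pmax(p_bad, 1e-4), 1 - 1e-4)) +
                   stats::rnorm(n, 0, 1))
  # inject missingness on feature cells only
  feats <- c(nm$continuous, nm$categorical)
  if (cfg$missing_rate > 0) {
    for (f in feats) {
      hit <- stats::runif(n) < cfg$missing_rate
      data[[f]][hit] <- NA
    }
  }
  df <- data.frame(instance_id = sprintf("inst%06d", seq_len(n)),
                   data, outcome = outcome, risk_score = risk,
                   stringsAsFactors = FALSE, check.names = FALSE)
  # importance: planted features rank highest (the upstream model would find
  # the real signal), others lower; deterministic given the seed
  imp <- stats::setNames(stats::runif(length(feats), 0, 0.5), feats)
  imp[names(planted_items)] <- stats::runif(length(planted_items), 0.5, 1)
  spec <- feature_spec(feats,
                       ifelse(feats %in% nm$continuous, "continuous",
                              "categorical"),
                       importance = unname(imp[feats]))
  list(cohort = cohort(df, spec), truth = truth)
}

#' Synthetic knowledge base for a simulated cohort
#'
#' Builds a knowledge base annotating, for every planted item, the
#' extensionally matching item of the fitted discretization scheme as
#' positively correlated with the bad outcome and attaches two generic
#' synthetic interventions. This stands in for the expert labeling step when
#' exercising the pipeline on generated data; the annotations are synthetic
#' placeholders, not clinical content.
#'
#' @param scheme An `rg_scheme` fitted on the generated cohort.
#' @param cohort The generated `rg_cohort`.
#' @param truth The planted-rule list (`truth` element of
#'   [simulate_cohort()], or a plain list of [planted_rule()]s).
#' @return An `rg_kb` with one annotation per distinct planted item.
#' @export
synthetic_kb <- function(scheme, cohort, truth) {
  stopifnot(inherits(scheme, "rg_scheme"), inherits(cohort, "rg_cohort"))
  anns <- list()
  seen <- character()
  for (pr in truth) {
    for (it in pr$lhs) {
      want <- which(item_satisfied(it, cohort$data[[it$feature]]))
      hit <- NULL
      for (cand in scheme$items[[it$feature]]) {
        got <- which(item_satisfied(cand, cohort$data[[it$feature]]))
        if (length(got) == length(want) && all(got == want)) {
          hit <- cand
          break
        }
      }
      if (is.null(hit)) {
        warning("no scheme item matches planted item ", item_key(it),
                "; skipped")
        next
      }
      key <- item_key(hit)
      if (key %in% seen) next
      seen <- c(seen, key)
      anns[[length(anns) + 1L]] <- kb_annotation(
        hit, positively_correlated = TRUE,
        interpretation = paste0("Elevated risk indicator on feature ",
                                it$feature, " (synthetic annotation)"),
        interventions = c(
          paste0("Review and address the driver behind ", it$feature,
                 " (synthetic intervention)"),
          paste0("Schedule focused follow-up for ", it$feature,
                 " (synthetic intervention)")))
    }
  }
  knowledge_base(anns)
}

#' Check recovery of planted rules by the mining pipeline
#'
#' For each planted rule whose empirical commonality and confidence (as
#' realized in the generated cohort) meet the mining thresholds, checks
#' whether its exact left-hand side appears among the mined rules. Matching
#' is extensional: a mined item matches a planted item when it sits on the
#' same feature and is satisfied by exactly the same instances of the
#' cohort, which is the faithful notion of "exact" for interval items whose
#' recovered cut points land inside the planted margin band.
#'
#' @param mined An `rg_rules` table mined from the generated cohort.
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @param cohort The generated `rg_cohort`.
#' @param scheme The `rg_scheme` used to itemize the cohort before mining.
#' @param min_commonality,min_confidence The mining thresholds defining
#'   eligibility.
#' @return List with `eligible` (logical per planted rule), `recovered`
#'   (logical, `NA` for ineligible rules), `recovery` (fraction of eligible
#'   rules recovered; 1 when there are none), and `matched_lhs_keys` (the
#'   mined keys matched to each planted rule).
#' @export
recovery_check <- function(mined, truth, cohort, scheme,
                           min_commonality = 0.01, min_confidence = 0.5) {
  stopifnot(inherits(mined, "rg_rules"), inherits(cohort, "rg_cohort"),
            inherits(scheme, "rg_scheme"))
  sat_set <- function(item) which(item_satisfied(item, cohort$data[[item$feature]]))
  eligible <- logical(length(truth))
  recovered <- rep(NA, length(truth))
  matched_keys <- vector("list", length(truth))
  for (j in seq_along(truth)) {
    pr <- truth[[j]]
    eligible[j] <- !is.na(pr$empirical_commonality) &&
      pr$empirical_commonality >= min_commonality &&
      !is.na(pr$empirical_confidence) &&
      pr$empirical_confidence >= min_confidence
    if (!eligible[j]) next
    # extensionally equivalent scheme item per planted item
    keys <- character(length(pr$lhs))
    ok <- TRUE
    for (i in seq_along(pr$lhs)) {
      it <- pr$lhs[[i]]
      want <- sat_set(it)
      hit <- NULL
      for (cand in scheme$items[[it$feature]]) {
        got <- sat_set(cand)
        if (length(got) == length(want) && all(got == want)) { hit <- cand; break }
      }
      if (is.null(hit)) { ok <- FALSE; break }
      keys[i] <- item_key(hit)
    }
    if (!ok) { recovered[j] <- FALSE; next }
    key <- paste(sort(keys), collapse = " & ")
    recovered[j] <- key %in% mined$lhs_key
    matched_keys[[j]] <- sort(keys)
  }
  n_elig <- sum(eligible)
  list(eligible = eligible,
       recovered = recovered,
       recovery = if (n_elig > 0L) mean(recovered[eligible]) else 1,
       matched_lhs_keys = matched_keys)
}
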