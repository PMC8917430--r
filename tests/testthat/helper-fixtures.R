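# Shared fixtures and independent oracles. The oracles deliberately use the
# most naive correct method (full enumeration, direct counting, table-based
# entropy) so they share no code path with the implementation they check.

# ---- T8 toy: 8 instances, bad = i1..i4; A on {1,2,3,5}, B on {1,2,6},
#      C on {3,4,5,7} ----
make_t8 <- function() {
  item_sets <- list(c("fA=1", "fB=1"), c("fA=1", "fB=1"), c("fA=1", "fC=1"),
                    c("fC=1"), c("fA=1", "fC=1"), c("fB=1"), c("fC=1"),
                    character())
  structure(list(instance_id = paste0("i", 1:8),
                 items = item_sets,
                 outcome = c(rep("bad", 4), rep("good", 4)),
                 risk_score = NULL),
            class = "rg_itemized")
}
t8_keys <- c("fA=1", "fB=1", "fC=1")
t8_feats <- stats::setNames(c("fA", "fB", "fC"), t8_keys)

# ---- brute-force class-association-rule oracle: enumerate every item
#      subset, count directly on a logical membership matrix ----
oracle_mine <- function(data, keys, feat_of, max_lhs, min_comm, min_conf,
                        z = "bad") {
  M <- sapply(keys, function(k)
    vapply(data$items, function(it) k %in% it, logical(1L)))
  M <- matrix(M, nrow = length(data$items), ncol = length(keys),
              dimnames = list(NULL, keys))
  nz <- sum(data$outcome == z)
  out <- list()
  for (k in seq_len(min(max_lhs, length(keys)))) {
    combs <- utils::combn(seq_along(keys), k)
    for (j in seq_len(ncol(combs))) {
      s <- combs[, j]
      if (anyDuplicated(feat_of[keys[s]])) next
      sat <- rowSums(M[, s, drop = FALSE]) == k
      nl <- sum(sat)
      if (nl == 0L) next
      nb <- sum(sat & data$outcome == z)
      if (nb / nz >= min_comm && nb / nl >= min_conf) {
        lhs <- sort(keys[s])
        out[[paste(lhs, collapse = " & ")]] <-
          list(lhs = lhs, n_lhs = nl, n_lhs_and_z = nb, n_z = nz)
      }
    }
  }
  out
}

# random itemized datasets for oracle-equivalence checks; some items share a
# feature (mutually exclusive bins) to exercise the one-item-per-feature rule
random_itemized <- function(seed, n_inst = 120L, n_items = 8L,
                            shared_features = TRUE) {
  set.seed(seed)
  feats <- if (shared_features && n_items >= 4L) {
    c(paste0("g", 1:2), paste0("f", seq_len(n_items - 2L)))
  } else paste0("f", seq_len(n_items))
  keys <- paste0(feats, "=v", seq_len(n_items))
  # items on the same feature must be mutually exclusive
  by_feat <- split(seq_len(n_items), feats)
  sets <- vector("list", n_inst)
  for (i in seq_len(n_inst)) {
    chosen <- integer()
    for (g in by_feat) {
      pick <- g[stats::runif(length(g)) < 0.4]
      if (length(pick) > 1L) pick <- sample(pick, 1L)
      chosen <- c(chosen, pick)
    }
    sets[[i]] <- sort(keys[chosen])
  }
  outcome <- sample(c("bad", "good"), n_inst, replace = TRUE,
                    prob = c(0.35, 0.65))
  if (!any(outcome == "bad")) outcome[1L] <- "bad"
  list(data = structure(list(instance_id = as.character(seq_len(n_inst)),
                             items = sets, outcome = outcome,
                             risk_score = NULL),
                        class = "rg_itemized"),
       keys = keys,
       feat_of = stats::setNames(feats, keys))
}

# ---- naive recursive entropy/MDL discretization oracle ----
oracle_entropy <- function(y) {
  tt <- table(y)
  p <- tt[tt > 0] / length(y)
  -sum(p * log2(p))
}

oracle_mdlp <- function(x, y) {
  n <- length(x)
  ux <- sort(unique(x))
  if (n < 2L || length(ux) < 2L) return(numeric())
  cands <- (ux[-1L] + ux[-length(ux)]) / 2
  best <- NA_real_
  bg <- -Inf
  for (cc in cands) {
    l <- y[x < cc]
    r <- y[x >= cc]
    g <- oracle_entropy(y) -
      length(l) / n * oracle_entropy(l) - length(r) / n * oracle_entropy(r)
    if (g > bg + 1e-12) { bg <- g; best <- cc }
  }
  l <- y[x < best]
  r <- y[x >= best]
  k <- length(unique(y)); kl <- length(unique(l)); kr <- length(unique(r))
  delta <- log2(3^k - 2) -
    (k * oracle_entropy(y) - kl * oracle_entropy(l) - kr * oracle_entropy(r))
  if (bg <= (log2(n - 1) + delta) / n) return(numeric())
  sort(c(oracle_mdlp(x[x < best], l), best, oracle_mdlp(x[x >= best], r)))
}

# ---- small cohort/kb builders ----
tiny_cohort <- function(values, outcomes, feature = "f",
                        kind = "continuous", ...) {
  df <- data.frame(instance_id = paste0("p", seq_along(values)),
                   f = values, outcome = outcomes,
                   stringsAsFactors = FALSE)
  names(df)[2L] <- feature
  cohort(df, feature_spec(feature, kind, ...))
}

rules_from_specs <- function(specs, n_z = 4L) {
  # specs: list of list(lhs=keys, conf=, comm=) -> synthetic rg_rules with
  # consistent integer counts (n_lhs_and_z = comm * n_z)
  lhs <- lapply(specs, `[[`, "lhs")
  nb <- vapply(specs, function(s) as.integer(round(s$comm * n_z)), integer(1L))
  nl <- vapply(seq_along(specs), function(i)
    as.integer(round(nb[i] / specs[[i]]$conf)), integer(1L))
  ruleglass:::.rules_df(lhs, "bad", nl, nb, rep.int(as.integer(n_z),
                                                    length(specs)))
}
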