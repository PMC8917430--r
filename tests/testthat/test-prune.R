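two_rules <- function() {
  # general rule A (conf 0.75) and specific rule A&B (conf 1.0), as in the toy
  rules_from_specs(list(
    list(lhs = "fA=1", conf = 0.75, comm = 0.75),
    list(lhs = c("fA=1", "fB=1"), conf = 1.0, comm = 0.5)))
}

test_that("subsumption pruning applies the three drop conditions at the boundary", {
  r <- two_rules()
  # tolerance 0.30: 0.75 >= 1.0 - 0.30, specific rule dropped
  expect_identical(prune_subsumed(r, 0.30)$lhs_key, "fA=1")
  # tolerance 0.15: 0.75 < 0.85, both retained
  expect_equal(nrow(prune_subsumed(r, 0.15)), 2L)
  # tolerance 0 with equal confidence: "greater than or equal" drops the
  # specific rule
  eq <- rules_from_specs(list(
    list(lhs = "fA=1", conf = 0.75, comm = 0.75),
    list(lhs = c("fA=1", "fB=1"), conf = 0.75, comm = 0.75)))
  expect_identical(prune_subsumed(eq, 0)$lhs_key, "fA=1")
})

test_that("witness policies differ exactly on dropped-witness chains", {
  # A (0.5), AB (0.8), ABC (0.9) at tolerance 0.3: A drops AB; under the
  # any-witness reading AB still drops ABC, under the retained-witness sweep
  # ABC survives because its only retained more-general rule is too weak.
  r <- rules_from_specs(list(
    list(lhs = "a=1", conf = 0.5, comm = 0.8),
    list(lhs = c("a=1", "b=1"), conf = 0.8, comm = 0.6),
    list(lhs = c("a=1", "b=1", "c=1"), conf = 0.9, comm = 0.5)), n_z = 100L)
  expect_identical(prune_subsumed(r, 0.3, witness = "any")$lhs_key, "a=1")
  expect_setequal(prune_subsumed(r, 0.3, witness = "retained")$lhs_key,
                  c("a=1", "a=1 & b=1 & c=1"))
  # chain-free case: both policies agree
  r2 <- rules_from_specs(list(
    list(lhs = "a=1", conf = 0.55, comm = 0.8),
    list(lhs = c("a=1", "b=1"), conf = 0.9, comm = 0.6),
    list(lhs = c("a=1", "b=1", "c=1"), conf = 0.95, comm = 0.5)), n_z = 100L)
  expect_setequal(prune_subsumed(r2, 0.1, witness = "any")$lhs_key,
                  c("a=1", "a=1 & b=1"))
  expect_setequal(prune_subsumed(r2, 0.1, witness = "retained")$lhs_key,
                  c("a=1", "a=1 & b=1"))
})

test_that("each policy delivers its own soundness guarantee on mined sets", {
  for (seed in c(3, 17, 31)) {
    rd <- random_itemized(seed)
    mined <- mine_rules(rd$data, rd$keys,
                        mining_config(top_k_features = 10L,
                                      max_lhs_items = 3L,
                                      min_commonality = 0.05,
                                      min_confidence = 0.3))
    has_witness <- function(lhs, conf, pool, tol) {
      any(vapply(seq_len(nrow(pool)), function(j) {
        kl <- pool$lhs[[j]]
        length(kl) < length(lhs) && all(kl %in% lhs) &&
          pool$confidence[j] >= conf - tol
      }, logical(1L)))
    }
    for (tol in c(0, 0.1, 0.25)) {
      # any-witness: every dropped rule has a witness in the mined set
      kept <- prune_subsumed(mined, tol, witness = "any")
      dropped <- mined[!(mined$lhs_key %in% kept$lhs_key), ]
      for (i in seq_len(nrow(dropped))) {
        expect_true(has_witness(dropped$lhs[[i]], dropped$confidence[i],
                                mined, tol),
                    info = paste("any", seed, tol, dropped$lhs_key[i]))
      }
      # retained-witness: every dropped rule has a SURVIVING witness
      kept_r <- prune_subsumed(mined, tol, witness = "retained")
      dropped_r <- mined[!(mined$lhs_key %in% kept_r$lhs_key), ]
      for (i in seq_len(nrow(dropped_r))) {
        expect_true(has_witness(dropped_r$lhs[[i]], dropped_r$confidence[i],
                                kept_r, tol),
                    info = paste("retained", seed, tol, dropped_r$lhs_key[i]))
      }
      # pruning is idempotent under the default policy
      expect_equal(nrow(prune_subsumed(kept, tol)), nrow(kept))
    }
  }
})

test_that("positive-correlation filtering keeps only fully labeled rules", {
  kb <- knowledge_base(list(
    kb_annotation(item_equals("fA", "1"), positively_correlated = TRUE),
    kb_annotation(item_equals("fB", "1"), positively_correlated = TRUE),
    kb_annotation(item_equals("fC", "1"), positively_correlated = FALSE)))
  r <- rules_from_specs(list(
    list(lhs = "fA=1", conf = 0.7, comm = 0.5),
    list(lhs = c("fA=1", "fB=1"), conf = 0.8, comm = 0.5),
    list(lhs = c("fA=1", "fC=1"), conf = 0.9, comm = 0.5),   # fC labeled FALSE
    list(lhs = c("fA=1", "fD=1"), conf = 0.9, comm = 0.5)))  # fD unlabeled
  out <- filter_positive_correlation(r, kb)
  expect_setequal(out$lhs_key, c("fA=1", "fA=1 & fB=1"))
  # empty KB drops everything
  expect_equal(nrow(filter_positive_correlation(r, knowledge_base())), 0L)
})

test_that("filter and prune commute up to the combined postcondition", {
  rd <- random_itemized(5)
  mined <- mine_rules(rd$data, rd$keys,
                      mining_config(top_k_features = 10L, max_lhs_items = 3L,
                                    min_commonality = 0.05,
                                    min_confidence = 0.3))
  pos_keys <- rd$keys[seq_len(5L)]
  kb <- knowledge_base(lapply(pos_keys, function(k) {
    f <- sub("=.*$", "", k)
    v <- sub("^.*=", "", k)
    kb_annotation(item_equals(f, v), positively_correlated = TRUE)
  }))
  a <- filter_positive_correlation(prune_subsumed(mined, 0.15), kb)
  b <- prune_subsumed(filter_positive_correlation(mined, kb), 0.15)
  check <- function(out) {
    expect_true(all(vapply(out$lhs, function(l) all(l %in% pos_keys),
                           logical(1L))))
    expect_equal(nrow(prune_subsumed(out, 0.15)), nrow(out))
  }
  check(a)
  check(b)
})

test_that("the remaining-rules curve is nonincreasing and per-point exact", {
  r <- two_rules()
  curve <- rule_count_curve(r, c(0.0, 0.3))
  expect_equal(curve$remaining, c(2L, 1L))
  single <- rules_from_specs(list(list(lhs = "x=1", conf = 0.9, comm = 0.5)))
  expect_equal(unique(rule_count_curve(single)$remaining), 1L)
  rd <- random_itemized(13)
  mined <- mine_rules(rd$data, rd$keys,
                      mining_config(top_k_features = 10L, max_lhs_items = 3L,
                                    min_commonality = 0.05,
                                    min_confidence = 0.3))
  curve2 <- rule_count_curve(mined, seq(0, 0.5, by = 0.05))
  expect_true(all(diff(curve2$remaining) <= 0L))
})

test_that("the elbow heuristic finds the knee and warns on flat curves", {
  curve <- data.frame(tolerance = c(0, 0.1, 0.2, 0.3),
                      remaining = c(100L, 20L, 18L, 17L))
  expect_equal(suggest_elbow(curve), 0.1)
  flat <- data.frame(tolerance = c(0, 0.1, 0.2), remaining = c(5L, 5L, 5L))
  expect_warning(e <- suggest_elbow(flat), "flat")
  expect_equal(e, 0)
  # default configured tolerance when no curve is examined
  expect_equal(mining_config()$conf_diff_upper, 0.15)
})
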