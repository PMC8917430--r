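t8_cfg <- function(min_commonality = 0.25, min_confidence = 0.5, ...) {
  mining_config(top_k_features = 3L, max_lhs_items = 2L,
                min_commonality = min_commonality,
                min_confidence = min_confidence, ...)
}

test_that("the toy rule set reproduces hand-counted commonality and confidence", {
  d <- make_t8()
  rules <- mine_rules(d, t8_keys, t8_cfg())
  get <- function(key) rules[rules$lhs_key == key, ]
  a <- get("fA=1")
  expect_equal(c(a$n_lhs, a$n_lhs_and_z), c(4L, 3L))
  expect_equal(a$confidence, 0.75)
  expect_equal(a$commonality, 0.75)
  b <- get("fB=1")
  expect_equal(b$confidence, 2 / 3)
  expect_equal(b$commonality, 0.5)
  cc <- get("fC=1")
  expect_equal(cc$confidence, 0.5)
  expect_equal(cc$commonality, 0.5)
  ab <- get("fA=1 & fB=1")
  expect_equal(ab$confidence, 1.0)
  expect_equal(ab$commonality, 0.5)

  # raising the confidence floor to 0.8 leaves only the A&B conjunction
  high <- mine_rules(d, t8_keys, t8_cfg(min_confidence = 0.8))
  expect_identical(high$lhs_key, "fA=1 & fB=1")

  # no allowed items -> no rules
  expect_equal(nrow(mine_rules(d, character(), t8_cfg())), 0L)
})

test_that("rule_stats counts exactly and suppresses empty-support confidence", {
  d <- make_t8()
  s <- rule_stats("fA=1", d)
  expect_equal(unlist(s[1:3]), c(n_lhs = 4, n_lhs_and_z = 3, n_z = 4))
  expect_equal(s$commonality, 0.75)
  expect_equal(s$confidence, 0.75)
  s2 <- rule_stats(c("fA=1", "fB=1"), d)
  expect_equal(unlist(s2[1:3]), c(n_lhs = 2, n_lhs_and_z = 2, n_z = 4))
  expect_equal(s2$confidence, 1.0)
  # a never-satisfied LHS has undefined confidence and is never emitted
  s3 <- rule_stats(c("fB=1", "fC=1"), d)
  expect_equal(s3$n_lhs, 0L)
  expect_true(is.na(s3$confidence))
  rules <- mine_rules(d, t8_keys, t8_cfg(min_commonality = 0.01))
  expect_false("fB=1 & fC=1" %in% rules$lhs_key)
})

test_that("mining equals exhaustive enumeration with exact counts", {
  for (seed in 1:8) {
    rd <- random_itemized(seed)
    cfg <- mining_config(top_k_features = 10L, max_lhs_items = 3L,
                         min_commonality = 0.1, min_confidence = 0.4)
    mined <- mine_rules(rd$data, rd$keys, cfg)
    truth <- oracle_mine(rd$data, rd$keys, rd$feat_of, 3L, 0.1, 0.4)
    expect_setequal(mined$lhs_key, names(truth))
    for (i in seq_len(nrow(mined))) {
      tr <- truth[[mined$lhs_key[i]]]
      expect_equal(mined$n_lhs[i], tr$n_lhs)
      expect_equal(mined$n_lhs_and_z[i], tr$n_lhs_and_z)
      expect_equal(mined$n_z[i], tr$n_z)
    }
  }
})

test_that("commonality is anti-monotone in the left-hand side", {
  rd <- random_itemized(99, n_inst = 80L, n_items = 6L)
  cfg <- mining_config(top_k_features = 6L, max_lhs_items = 3L,
                       min_commonality = 1e-9, min_confidence = 1e-9)
  mined <- mine_rules(rd$data, rd$keys, cfg)
  comm <- stats::setNames(mined$commonality, mined$lhs_key)
  for (i in which(mined$k > 1L)) {
    lhs <- mined$lhs[[i]]
    for (drop_j in seq_along(lhs)) {
      parent <- paste(lhs[-drop_j], collapse = " & ")
      expect_lte(mined$commonality[i], comm[[parent]])
    }
  }
})

test_that("raising either threshold never enlarges the rule set", {
  rd <- random_itemized(42)
  base <- mine_rules(rd$data, rd$keys,
                     mining_config(top_k_features = 10L, max_lhs_items = 3L,
                                   min_commonality = 0.05,
                                   min_confidence = 0.3))
  for (mc in c(0.1, 0.2, 0.4)) {
    higher <- mine_rules(rd$data, rd$keys,
                         mining_config(top_k_features = 10L,
                                       max_lhs_items = 3L,
                                       min_commonality = mc,
                                       min_confidence = 0.3))
    expect_true(all(higher$lhs_key %in% base$lhs_key))
  }
  for (cf in c(0.4, 0.6, 0.8)) {
    higher <- mine_rules(rd$data, rd$keys,
                         mining_config(top_k_features = 10L,
                                       max_lhs_items = 3L,
                                       min_commonality = 0.05,
                                       min_confidence = cf))
    expect_true(all(higher$lhs_key %in% base$lhs_key))
  }
})

test_that("output order is canonical and runs are deterministic", {
  rd <- random_itemized(7)
  cfg <- mining_config(top_k_features = 10L, max_lhs_items = 3L,
                       min_commonality = 0.05, min_confidence = 0.3)
  r1 <- mine_rules(rd$data, rd$keys, cfg)
  r2 <- mine_rules(rd$data, rev(rd$keys), cfg)   # item order must not matter
  expect_equal(r1, r2)
  expect_equal(order(r1$k, r1$lhs_key), seq_len(nrow(r1)))
})

test_that("mining without target-class instances is fatal, budget failure instructive", {
  d <- make_t8()
  d$outcome <- rep("good", 8L)
  expect_error(mine_rules(d, t8_keys, t8_cfg()), "target class")
  d2 <- make_t8()
  expect_error(
    mine_rules(d2, t8_keys, t8_cfg(min_commonality = 1e-6,
                                   max_candidates = 1L)),
    "top_k_features")
})

test_that("top-feature selection sorts by importance with lexicographic ties", {
  fs <- feature_spec(c("a", "b", "c"), "continuous", importance = c(3, 1, 2))
  expect_identical(select_top_features(fs, 2L)$name, c("a", "c"))
  tie <- feature_spec(c("b", "a"), "continuous", importance = c(2, 2))
  expect_identical(select_top_features(tie, 1L)$name, "a")
  expect_warning(all3 <- select_top_features(fs, 5L), "exceeds")
  expect_equal(nrow(all3), 3L)
})

test_that("rules serialize to JSON lines and back", {
  d <- make_t8()
  rules <- mine_rules(d, t8_keys, t8_cfg())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_rules(rules, path)
  rt <- read_rules(path)
  expect_equal(rt$lhs_key, rules$lhs_key)
  expect_equal(rt$n_lhs, rules$n_lhs)
  expect_equal(rt$confidence, rules$confidence)
})
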