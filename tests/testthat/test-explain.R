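mk_inst <- function(items, id = "p1") {
  list(instance_id = id, items = items, outcome = "bad", risk_score = NA_real_)
}

test_that("rule matching is the subset test with missing satisfying nothing", {
  rules <- rules_from_specs(list(
    list(lhs = "A=1", conf = 0.7, comm = 0.5),
    list(lhs = c("A=1", "B=1"), conf = 0.8, comm = 0.5),
    list(lhs = c("A=1", "D=1"), conf = 0.9, comm = 0.5)))
  m <- match_rules(mk_inst(c("A=1", "B=1", "C=1")), rules)
  expect_setequal(m$lhs_key, c("A=1", "A=1 & B=1"))
  expect_equal(nrow(match_rules(mk_inst(character()), rules)), 0L)
  # LHS equal to the full item set is a match
  m2 <- match_rules(mk_inst(c("A=1", "D=1")), rules)
  expect_true("A=1 & D=1" %in% m2$lhs_key)
})

test_that("the five-factor score evaluates the stated linear form", {
  r <- rules_from_specs(list(list(lhs = c("A=1", "B=1"), conf = 0.8,
                                  comm = 0.1)), n_z = 40L)
  r$actionable <- TRUE
  # 1.0*0.8 + 0.5*0.1 - 0.25*(1/4) + 0.5*1 - 0 = 1.2875
  expect_equal(score_rule(r, selected = NULL, max_lhs = 5L), 1.2875)
  # higher confidence scores strictly higher, all else equal
  lo <- rules_from_specs(list(list(lhs = c("A=1", "B=1"), conf = 0.6,
                                   comm = 0.1)), n_z = 40L)
  lo$actionable <- TRUE
  expect_gt(score_rule(r, NULL), score_rule(lo, NULL))
  # identical-LHS selected rule -> redundancy 1, score drops by w_redundancy
  w <- ranking_weights()
  expect_equal(score_rule(r, selected = r),
               score_rule(r, selected = NULL) - w$w_redundancy)
})

test_that("iterative ranking is permutation-invariant and penalizes redundancy", {
  specs <- list(
    list(lhs = c("A=1", "B=1"), conf = 0.9, comm = 0.30),
    list(lhs = c("A=1", "C=1"), conf = 0.85, comm = 0.25),
    list(lhs = "D=1", conf = 0.7, comm = 0.40),
    list(lhs = c("B=1", "C=1", "E=1"), conf = 0.95, comm = 0.10))
  rules <- rules_from_specs(specs, n_z = 20L)
  rules$actionable <- c(TRUE, FALSE, TRUE, FALSE)
  ref <- rank_rules(rules)
  perms <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2),
                c(4, 1, 3, 2), c(2, 3, 4, 1))
  for (p in perms) {
    out <- rank_rules(rules[p, ])
    expect_identical(out$lhs_key, ref$lhs_key)
    expect_equal(out$score, ref$score)
  }
  # disjoint LHSs: order purely by static score
  dis <- rules_from_specs(list(
    list(lhs = "A=1", conf = 0.9, comm = 0.2),
    list(lhs = "B=1", conf = 0.7, comm = 0.2),
    list(lhs = "C=1", conf = 0.5, comm = 0.2)), n_z = 10L)
  expect_identical(rank_rules(dis)$lhs_key, c("A=1", "B=1", "C=1"))
  # two identical-LHS rules: second selection scores lower by w_redundancy
  dup <- rules_from_specs(list(
    list(lhs = "A=1", conf = 0.8, comm = 0.2),
    list(lhs = "A=1", conf = 0.8, comm = 0.2)), n_z = 10L)
  rr <- rank_rules(dup)
  expect_equal(rr$score[1L] - rr$score[2L], ranking_weights()$w_redundancy)
})

test_that("raising a matched rule's confidence never lowers its rank", {
  base_specs <- list(
    list(lhs = "A=1", conf = 0.6, comm = 0.2),
    list(lhs = "B=1", conf = 0.7, comm = 0.2),
    list(lhs = "C=1", conf = 0.8, comm = 0.2))
  pos <- function(specs) {
    r <- rules_from_specs(specs, n_z = 100L)
    which(rank_rules(r)$lhs_key == "A=1")
  }
  before <- pos(base_specs)
  boosted <- base_specs
  boosted[[1L]]$conf <- 0.9
  expect_lte(pos(boosted), before)
})

test_that("the top-fraction cutoff flags exactly ceil(fraction * n) instances", {
  risks <- c(a = 0.9, b = 0.5, c = 0.1)
  out <- binarize_top_fraction(risks, 1 / 3)
  expect_identical(out[["a"]], "predicted_bad")
  expect_equal(sum(out == "predicted_bad"), 1L)
  expect_equal(sum(binarize_top_fraction(risks, 1.0) == "predicted_bad"), 3L)
  for (n in c(1L, 7L, 10L, 33L)) {
    for (fr in c(0.1, 0.25, 0.5, 0.999)) {
      set.seed(n)
      r <- stats::setNames(stats::runif(n), paste0("i", seq_len(n)))
      flagged <- sum(binarize_top_fraction(r, fr) == "predicted_bad")
      expect_equal(flagged, as.integer(ceiling(fr * n)),
                   info = paste(n, fr))
    }
  }
  # boundary tie broken by instance id, deterministically, with a note
  tied <- c(b = 0.5, a = 0.5, c = 0.1)
  expect_message(out2 <- binarize_top_fraction(tied, 1 / 3), "tie")
  expect_identical(out2[["a"]], "predicted_bad")
  expect_identical(out2[["b"]], "predicted_good")
})

test_that("explanations truncate, attach interventions, and count matches", {
  kb <- knowledge_base(list(
    kb_annotation(item_equals("A", "1"), positively_correlated = TRUE,
                  interpretation = "risk marker A",
                  interventions = c("do this", "do that")),
    kb_annotation(item_equals("B", "1"), positively_correlated = TRUE)))
  rules <- rules_from_specs(list(
    list(lhs = "A=1", conf = 0.9, comm = 0.3),
    list(lhs = c("A=1", "B=1"), conf = 0.8, comm = 0.2),
    list(lhs = "B=1", conf = 0.7, comm = 0.3),
    list(lhs = c("B=1", "C=1"), conf = 0.95, comm = 0.1)), n_z = 20L)
  rules <- annotate_actionability(rules, kb)
  inst <- mk_inst(c("A=1", "B=1", "C=1"))
  ex <- explain_instance(inst, "predicted_bad", rules, kb, n_top = 3L)
  expect_s3_class(ex, "rg_explanation")
  expect_equal(ex$n_matching, 4L)
  expect_length(ex$ranked, 3L)                 # truncated to top 3
  expect_equal(ex$n_matching_actionable, 2L)   # rules containing A=1
  expect_equal(ex$unique_actionable_items, 1L) # only A=1 is actionable
  first_items <- ex$ranked[[1L]]$items
  expect_true(any(vapply(first_items, function(it)
    length(it$interventions) > 0L, logical(1L))))
  # predicted-good instances keep counts but present no rules
  exg <- explain_instance(inst, "predicted_good", rules, kb)
  expect_equal(exg$n_matching, 4L)
  expect_length(exg$ranked, 0L)
  # unexplained positive prediction: empty ranked list, zero matches
  ex0 <- explain_instance(mk_inst("Z=9"), "predicted_bad", rules, kb)
  expect_equal(ex0$n_matching, 0L)
  expect_length(ex0$ranked, 0L)
  # every presented rule matches the instance
  for (e in ex$ranked) {
    expect_true(all(e$rule$lhs[[1L]] %in% inst$items))
  }
})

test_that("combination-level interventions attach when the LHS contains the set", {
  items <- list(item_equals("A", "1"), item_equals("B", "1"))
  kb <- knowledge_base(
    list(kb_annotation(items[[1L]], positively_correlated = TRUE),
         kb_annotation(items[[2L]], positively_correlated = TRUE)),
    combinations = list(list(items = items,
                             interventions = "joint counseling")))
  rules <- rules_from_specs(list(
    list(lhs = c("A=1", "B=1"), conf = 0.8, comm = 0.2),
    list(lhs = "A=1", conf = 0.7, comm = 0.3)), n_z = 10L)
  rules <- annotate_actionability(rules, kb)
  ex <- explain_instance(mk_inst(c("A=1", "B=1")), "predicted_bad", rules, kb)
  combo <- lapply(ex$ranked, `[[`, "combination_interventions")
  has_combo <- vapply(ex$ranked, function(e)
    e$rule$lhs_key == "A=1 & B=1", logical(1L))
  expect_identical(unlist(combo[has_combo]), "joint counseling")
  expect_length(unlist(combo[!has_combo]), 0L)
})
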