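test_that("MDL splitting accepts the informative cut and rejects noise", {
  # clean class boundary: one cut strictly inside (2, 3]
  co <- tiny_cohort(c(1, 2, 3, 4), c("bad", "bad", "good", "good"))
  s <- fit_discretization(co)
  expect_length(s$cuts$f, 1L)
  expect_gt(s$cuts$f, 2)
  expect_lte(s$cuts$f, 3)
  expect_length(s$items$f, 2L)

  # constant feature: zero information gain, single all-range item
  s2 <- fit_discretization(tiny_cohort(rep(5, 4), c("bad", "bad", "good", "good")))
  expect_length(s2$cuts$f, 0L)
  expect_length(s2$items$f, 1L)
  expect_equal(s2$items$f[[1L]]$lower, -Inf)
  expect_equal(s2$items$f[[1L]]$upper, Inf)

  # alternating classes: MDL rejects every cut
  s3 <- fit_discretization(tiny_cohort(c(1, 2, 3, 4),
                                       c("bad", "good", "bad", "good")))
  expect_length(s3$cuts$f, 0L)
  expect_length(s3$items$f, 1L)
})

test_that("accepted cuts equal the brute-force entropy/MDL oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(30:120, 1L)
    x <- as.numeric(sample(seq_len(sample(5:20, 1L)), n, replace = TRUE))
    p <- stats::plogis((x - mean(x)) * stats::runif(1L, 0, 2))
    y <- ifelse(stats::runif(n) < p, "bad", "good")
    if (length(unique(y)) < 2L) y[1:2] <- c("bad", "good")
    co <- tiny_cohort(x, y)
    s <- fit_discretization(co)
    expect_equal(s$cuts$f, oracle_mdlp(x, y),
                 info = paste("seed", seed))
  }
})

test_that("interval items partition the real line per feature", {
  set.seed(3)
  x <- c(stats::rnorm(60, 0), stats::rnorm(60, 4))
  y <- rep(c("good", "bad"), each = 60L)
  s <- fit_discretization(tiny_cohort(x, y))
  for (v in c(-1e6, -3.2, 0, 1.9999, 2.0, 7.5, 1e6)) {
    hits <- vapply(s$items$f, item_satisfied, logical(1L), value = v)
    expect_equal(sum(hits), 1L, info = paste("value", v))
  }
})

test_that("discretization is deterministic across runs", {
  set.seed(11)
  x <- stats::runif(200, 0, 10)
  y <- ifelse(stats::runif(200) < stats::plogis(x - 5), "bad", "good")
  co <- tiny_cohort(x, y)
  expect_identical(fit_discretization(co)$cuts, fit_discretization(co)$cuts)
})

test_that("itemize maps values to single items, missing and unseen to none", {
  df <- data.frame(instance_id = paste0("p", 1:4),
                   f = c(3.0, 1.0, NA, 2.5),
                   g = c("a", "b", "a", "zz"),
                   outcome = c("bad", "good", "bad", "good"))
  co <- cohort(df, feature_spec(c("f", "g"),
                                c("continuous", "categorical")))
  # freeze a scheme with one cut at 2.5 and levels {a, b}
  train <- cohort(data.frame(instance_id = paste0("t", 1:4),
                             f = c(1, 2, 3, 4), g = c("a", "b", "a", "b"),
                             outcome = c("bad", "bad", "good", "good")),
                  co$features)
  s <- fit_discretization(train)
  expect_equal(s$cuts$f, 2.5)
  suppressMessages(it <- itemize(co, s))
  expect_setequal(it$items[[1L]], c("f:[2.5,Inf)", "g=a"))  # 3.0 in top bin
  expect_setequal(it$items[[2L]], c("f:[-Inf,2.5)", "g=b"))
  expect_setequal(it$items[[3L]], "g=a")                    # missing f: no item
  expect_setequal(it$items[[4L]], "f:[2.5,Inf)")            # unseen level: none
  # at most one item per feature always
  expect_true(all(vapply(it$items, function(k)
    !anyDuplicated(sub("[:=].*$", "", k)), logical(1L))))
})

test_that("categorical values itemize as equality items on printed levels", {
  df <- data.frame(instance_id = c("p1", "p2"),
                   race = c("Black or African American", "White"),
                   outcome = c("bad", "good"))
  co <- cohort(df, feature_spec("race", "categorical"))
  s <- fit_discretization(co)
  it <- itemize(co, s)
  expect_true("race=Black or African American" %in% it$items[[1L]])
})

test_that("scheme JSON round-trips cuts and levels", {
  set.seed(5)
  df <- data.frame(instance_id = paste0("p", 1:40),
                   f = c(stats::rnorm(20, 0), stats::rnorm(20, 5)),
                   g = sample(c("u", "v"), 40, TRUE),
                   outcome = rep(c("good", "bad"), each = 20L))
  co <- cohort(df, feature_spec(c("f", "g"), c("continuous", "categorical")))
  s <- fit_discretization(co)
  path <- withr::local_tempfile(fileext = ".json")
  write_scheme(s, path)
  s2 <- read_scheme(path)
  expect_equal(s2$cuts, s$cuts)
  expect_identical(names(s2$index), names(s$index))
})

test_that("an all-missing continuous feature yields a warning and no items", {
  df <- data.frame(instance_id = c("p1", "p2"), f = c(NA_real_, NA_real_),
                   g = c(1, 2), outcome = c("bad", "good"))
  co <- cohort(df, feature_spec(c("f", "g"), "continuous"))
  expect_warning(s <- fit_discretization(co), "missing")
  expect_null(s$items$f)
  expect_gte(length(s$items$g), 1L)
})
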