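test_that("binomial tail matches closed forms from printed contingencies", {
  expect_equal(binomial_significance(0, 7, 0.3), 1.0)
  expect_equal(binomial_significance(4, 4, 0.23), 0.23^4, tolerance = 1e-15)
  expect_lt(binomial_significance(4, 4, 0.23), 0.01)
  expect_equal(binomial_significance(5, 5, 0.22), 0.22^5, tolerance = 1e-15)
  expect_lt(binomial_significance(5, 5, 0.22), 0.001)
  two_term <- 11 * 0.23^10 * 0.77 + 0.23^11
  expect_equal(binomial_significance(10, 11, 0.23), two_term,
               tolerance = 1e-12)
  expect_lt(binomial_significance(10, 11, 0.23), 0.001)
  expect_error(binomial_significance(2, 4, 0), "between 0 and 1")
})

test_that("binomial tail agrees with brute-force summation to 1e-12", {
  withr::with_seed(31, {
    for (i in 1:40) {
      n <- sample(1:30, 1)
      k <- sample(0:n, 1)
      p0 <- runif(1, 0.05, 0.95)
      expect_equal(binomial_significance(k, n, p0),
                   oracle_binom_tail(k, n, p0), tolerance = 1e-12)
    }
  })
  # and with the standard distribution function
  expect_equal(binomial_significance(10, 11, 0.23),
               pbinom(9, 11, 0.23, lower.tail = FALSE), tolerance = 1e-14)
})

test_that("binomial tail is monotone in k and in p0", {
  for (k in 1:9) {
    expect_gte(binomial_significance(k, 10, 0.3),
               binomial_significance(k + 1, 10, 0.3))
  }
  # with k/n above p0, increasing p0 never decreases the tail
  p_grid <- c(0.1, 0.2, 0.3, 0.4)
  tails <- vapply(p_grid, function(p) binomial_significance(8, 10, p),
                  numeric(1))
  expect_true(all(diff(tails) >= 0))
})

test_that("rule extraction walks root-to-leaf paths and collapses intervals", {
  ds <- tibble::tibble(gene = sprintf("g%d", 1:4), class = rep("ageing", 4),
                       x = 1:4)
  single <- extract_rules(tree_train(ds))
  expect_equal(nrow(single), 1)
  expect_equal(single$n_conditions, 0L)

  ds2 <- tibble::tibble(
    gene = sprintf("g%d", 1:12),
    class = rep(c("ageing", "non_ageing"), each = 6),
    b1 = rep(c("yes", "no"), each = 6))
  rules2 <- extract_rules(tree_train(ds2, use_pruning = FALSE))
  expect_equal(nrow(rules2), 2)
  expect_equal(rules2$n_conditions, c(1L, 1L))

  # nested conditions x > 5 then x > 8 collapse to the tightest bound
  cond <- tibble::tibble(attribute = c("x", "x"), op = c(">", ">"),
                         value = NA_character_, threshold = c(5, 8))
  collapsed <- agemine:::collapse_conditions(cond)
  expect_equal(nrow(collapsed), 1)
  expect_equal(collapsed$threshold, 8)
})

test_that("rule coverage counts trials and successes, excluding missing", {
  ds <- tibble::tibble(
    gene = sprintf("g%d", 1:6),
    class = c(rep("ageing", 3), rep("non_ageing", 3)),
    x = c(10, 12, NA, 3, 11, 2))
  none <- tibble::tibble(attribute = character(0), op = character(0),
                         value = character(0), threshold = numeric(0))
  expect_equal(rule_coverage(none, ds, "ageing"),
               c(n_trials = 6, n_successes = 3))
  cond <- tibble::tibble(attribute = "x", op = ">", value = NA_character_,
                         threshold = 5)
  # x > 5 satisfied by g1, g2, g5; g3 (missing) excluded
  expect_equal(rule_coverage(cond, ds, "ageing"),
               c(n_trials = 3, n_successes = 2))
  bad <- tibble::tibble(attribute = "zz", op = ">", value = NA_character_,
                        threshold = 1)
  expect_error(rule_coverage(bad, ds, "ageing"), "unknown attribute")
})

test_that("trial counts over a tree's rules partition the training set", {
  ds <- random_dataset(50, seed = 37)  # no missing values
  tr <- tree_train(ds, use_pruning = FALSE)
  scored <- score_rules(extract_rules(tr), ds)
  expect_equal(sum(scored$n_trials), nrow(ds))
  expect_true(all(scored$p_value > 0 & scored$p_value <= 1))
  expect_equal(attr(scored, "n_rules_tested"), nrow(scored))
})

test_that("attribute_value_pattern fills coverage against the class frequency", {
  ds <- tibble::tibble(
    gene = sprintf("g%d", 1:10),
    class = rep(c("ageing", "non_ageing"), c(3, 7)),
    b1 = c("yes", "yes", "no", rep("no", 7)))
  pat <- attribute_value_pattern(ds, "b1", "yes")
  expect_equal(pat$n_trials, 2L)
  expect_equal(pat$n_successes, 2L)
  expect_equal(pat$p0, 0.3)
  expect_equal(pat$p_value, binomial_significance(2, 2, 0.3))

  ds$b1 <- NA_character_
  empty <- attribute_value_pattern(ds, "b1", "yes")
  expect_equal(empty$n_trials, 0L)
  expect_equal(empty$p_value, 1.0)
})

test_that("root-attribute tallies count trees, single leaves under none", {
  expect_equal(nrow(tally_root_attributes(list())), 0)
  ds <- tibble::tibble(
    gene = sprintf("g%d", 1:12),
    class = rep(c("ageing", "non_ageing"), each = 6),
    WRN_interaction = rep(c("yes", "no"), each = 6))
  tr <- tree_train(ds, use_pruning = FALSE)
  expect_equal(root_attribute(tr), "WRN_interaction")
  tl <- tally_root_attributes(rep(list(tr), 6))
  expect_equal(tl$attribute, "WRN_interaction")
  expect_equal(tl$n, 6L)

  pure <- tree_train(tibble::tibble(gene = "g", class = "ageing", x = 1))
  tl2 <- tally_root_attributes(list(tr, pure))
  expect_setequal(tl2$attribute, c("WRN_interaction", "none"))
})

test_that("rule reports render IF-THEN text and serialise", {
  ds <- tibble::tibble(
    gene = sprintf("g%d", 1:12),
    class = rep(c("ageing", "non_ageing"), each = 6),
    b1 = rep(c("yes", "no"), each = 6))
  scored <- score_rules(extract_rules(tree_train(ds, use_pruning = FALSE)), ds)
  expect_true(any(grepl("^IF \\(b1 = yes\\) THEN class = ageing$",
                        scored$rule)))
  f_tsv <- tempfile(fileext = ".tsv")
  f_json <- tempfile(fileext = ".json")
  write_rule_report(scored, f_tsv, "tsv")
  write_rule_report(scored, f_json, "json")
  expect_equal(nrow(utils::read.delim(f_tsv)), nrow(scored))
  doc <- jsonlite::read_json(f_json)
  expect_equal(doc$n_rules_tested, nrow(scored))
})
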