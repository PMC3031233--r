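test_that("pure input yields a single leaf; single-class data is not an error", {
  ds <- tibble::tibble(gene = sprintf("g%d", 1:6), class = rep("ageing", 6),
                       x = 1:6)
  tr <- tree_train(ds)
  expect_true(tr$root$leaf)
  expect_equal(tr$root$class, "ageing")
  expect_true(is.na(root_attribute(tr)))
  expect_equal(predict(tr, ds, type = "class"),
               factor(rep("ageing", 6), levels = c("non_ageing", "ageing")))
})

test_that("a perfectly separating binary attribute becomes a depth-1 split", {
  ds <- tibble::tibble(
    gene = sprintf("g%d", 1:12),
    class = rep(c("ageing", "non_ageing"), each = 6),
    b1 = rep(c("yes", "no"), each = 6),
    b2 = rep(c("yes", "no"), 6))
  tr <- tree_train(ds, use_pruning = FALSE)
  expect_equal(root_attribute(tr), "b1")
  expect_true(all(vapply(tr$root$children, `[[`, logical(1), "leaf")))
})

test_that("numeric split lands at the midpoint of adjacent observed values", {
  ds <- tibble::tibble(
    gene = sprintf("g%d", 1:4),
    class = c("ageing", "ageing", "non_ageing", "non_ageing"),
    x = c(1, 2, 8, 9))
  tr <- tree_train(ds, use_pruning = FALSE)
  expect_equal(root_attribute(tr), "x")
  expect_equal(tr$root$threshold, (2 + 8) / 2)
})

test_that("root split agrees with exhaustive gain-ratio enumeration", {
  for (seed in c(3, 17, 29, 41)) {
    ds <- random_dataset(50, seed = seed, n_numeric = 2, n_binary = 2,
                         with_nominal = TRUE)
    tr <- tree_train(ds, use_pruning = FALSE)
    oracle <- oracle_best_split(ds)
    if (is.null(oracle)) {
      expect_true(tr$root$leaf, info = paste("seed", seed))
    } else {
      expect_equal(root_attribute(tr), oracle$attribute,
                   info = paste("seed", seed))
      if (!is.na(oracle$threshold)) {
        expect_equal(tr$root$threshold, oracle$threshold,
                     tolerance = 1e-12, info = paste("seed", seed))
      }
    }
  }
})

test_that("noiseless two-attribute labels are fit exactly without pruning", {
  withr::with_seed(7, {
    n <- 48
    ds <- tibble::tibble(
      gene = sprintf("g%02d", 1:n),
      x = round(runif(n, 0, 20), 1),
      b = sample(c("yes", "no"), n, replace = TRUE))
    ds$class <- ifelse(ds$x > 10 & ds$b == "yes", "ageing", "non_ageing")
  })
  tr <- tree_train(ds, use_pruning = FALSE)
  expect_equal(as.character(predict(tr, ds, type = "class")), ds$class)
})

test_that("pruning never increases the pessimistic training-error estimate", {
  for (seed in c(2, 8, 23)) {
    ds <- random_dataset(60, seed = seed)
    grown <- tree_train(ds, use_pruning = FALSE)
    pruned <- tree_train(ds, use_pruning = TRUE)
    expect_lte(pessimistic_tree_error(pruned),
               pessimistic_tree_error(grown) + 1e-9)
  }
})

test_that("instances beyond a learned threshold take the greater branch", {
  ds <- tibble::tibble(
    gene = sprintf("g%d", 1:20),
    class = rep(c("non_ageing", "ageing"), each = 10),
    n_partners = c(1:10, 16:25))  # separated around 15 partners
  tr <- tree_train(ds, use_pruning = FALSE)
  expect_equal(root_attribute(tr), "n_partners")
  expect_equal(tr$root$threshold, 13)  # midpoint of 10 and 16
  pred <- predict(tr, tibble::tibble(n_partners = 16), type = "class")
  expect_equal(as.character(pred), "ageing")
})

test_that("leaf probabilities carry the Laplace correction", {
  ds <- tibble::tibble(gene = sprintf("g%d", 1:5), class = rep("ageing", 5),
                       x = 1:5)
  tr <- tree_train(ds)
  p <- predict(tr, ds[1, ])
  expect_equal(p$ageing, 6 / 7)  # (5 + 1) / (5 + 2)
})

test_that("missing values route to the heavier child at prediction time", {
  ds <- tibble::tibble(
    gene = sprintf("g%d", 1:10),
    class = rep(c("ageing", "non_ageing"), c(7, 3)),
    b1 = rep(c("yes", "no"), c(7, 3)))
  tr <- tree_train(ds, use_pruning = FALSE, min_leaf = 1)
  expect_equal(root_attribute(tr), "b1")
  p_missing <- predict(tr, tibble::tibble(b1 = NA_character_))
  p_heavy <- predict(tr, tibble::tibble(b1 = "yes"))  # 7 > 3
  expect_identical(p_missing, p_heavy)
})

test_that("a serialised tree predicts bit-identically after reload", {
  ds <- random_dataset(40, seed = 31)
  tr <- tree_train(ds)
  f <- tempfile(fileext = ".json")
  tree_to_json(tr, f)
  tr2 <- tree_from_json(f)
  expect_identical(predict(tr, ds), predict(tr2, ds))
  expect_equal(root_attribute(tr2), root_attribute(tr))
})

test_that("the rendered tree mirrors the IF-THEN structure", {
  ds <- tibble::tibble(
    gene = sprintf("g%d", 1:12),
    class = rep(c("ageing", "non_ageing"), each = 6),
    b1 = rep(c("yes", "no"), each = 6))
  tr <- tree_train(ds, use_pruning = FALSE)
  txt <- format(tr)
  expect_match(txt, "b1 = yes: ageing")
  expect_match(txt, "b1 = no: non_ageing")
})
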