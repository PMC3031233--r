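#' Stratified fold assignment
#'
#' Assigns each instance to one of `k` cross-validation folds so that fold
#' sizes differ by at most one and each class's instances are spread across
#' folds as evenly as possible (per-class counts differ by at most one).
#' Deterministic given `seed`.
#'
#' @param data A dataset tibble with a `class` column.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold indices (1..k), one per row of `data`.
#' @export
stratified_folds <- function(data, k = 10, seed = 1) {
  n <- nrow(data)
  stopifnot(k >= 2)
  if (k > n) abort("more folds than instances")
  y <- as_class_factor(data$class)
  small <- table(y)[table(y) > 0 & table(y) < k]
  if (length(small) > 0) {
    warn(paste0("class(es) with fewer instances than folds: ",
                paste(names(small), collapse = ", "),
                "; stratification is best-effort"))
  }
  ord <- withr::with_seed(seed, unlist(lapply(CLASS_LEVELS, function(cl) {
    i <- which(y == cl)
    if (length(i) > 1) sample(i) else i
  }), use.names = FALSE))
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

builtin_learner <- function(learner) {
  if (is.list(learner)) {
    stopifnot(is.function(learner$fit), is.function(learner$score))
    return(learner)
  }
  switch(match.arg(learner, c("tree", "naive_bayes")),
    tree = list(
      fit = function(d) tree_train(d),
      score = function(m, d) predict(m, d)[[POSITIVE_CLASS]]),
    naive_bayes = list(
      fit = function(d) nb_train(d),
      score = function(m, d) predict(m, d)[[POSITIVE_CLASS]]))
}

#' Cross-validated out-of-fold predictions
#'
#' Stratified k-fold cross-validation: for each fold, the learner is
#' trained on the other folds and scores the held-out instances, so every
#' instance is scored exactly once by a model that never saw it.
#'
#' @param data A dataset tibble.
#' @param learner `"tree"`, `"naive_bayes"`, or a list with elements
#'   `fit(data) -> model` and `score(model, data) -> positive-class
#'   probabilities`.
#' @param k Number of folds.
#' @param seed Integer seed for the fold shuffle.
#' @return A tibble of class `repair_predictions` with columns `gene`,
#'   `class`, `p_ageing`, `fold`; the seed is attached as an attribute.
#' @export
cross_validate <- function(data, learner = "tree", k = 10, seed = 1) {
  check_dataset(data)
  lrn <- builtin_learner(learner)
  folds <- stratified_folds(data, k = k, seed = seed)
  p <- numeric(nrow(data))
  for (f in sort(unique(folds))) {
    test <- folds == f
    model <- lrn$fit(data[!test, , drop = FALSE])
    p[test] <- lrn$score(model, data[test, , drop = FALSE])
  }
  out <- tibble::tibble(gene = data$gene, class = as_class_factor(data$class),
                        p_ageing = p, fold = folds)
  class(out) <- c("repair_predictions", class(out))
  attr(out, "seed") <- seed
  attr(out, "learner") <- if (is.character(learner)) learner else "custom"
  out
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) AUC with midrank tie correction over pooled
#' scores: the probability that a random positive (`ageing`) instance
#' outranks a random negative one, ties counting one half. Computed once
#' on the predictions pooled across all test folds.
#'
#' @param predictions A `repair_predictions` tibble (or any data frame
#'   with `class` and `p_ageing` columns).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(predictions) {
  y <- as_class_factor(predictions$class)
  s <- predictions$p_ageing
  if (anyNA(s)) abort("missing prediction scores")
  pos <- y == POSITIVE_CLASS
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    abort("AUC undefined: only one class present among predictions")
  }
  r <- rank(s)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve of pooled cross-validated predictions
#'
#' @param object A `repair_predictions` tibble.
#' @param ... Unused.
#' @return A ggplot object showing the ROC curve with the pooled AUC in
#'   the subtitle.
#' @export
autoplot.repair_predictions <- function(object, ...) {
  y <- as_class_factor(object$class) == POSITIVE_CLASS
  ord <- order(object$p_ageing, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord]) / sum(y))
  fpr <- c(0, cumsum(!y[ord]) / sum(!y))
  df <- tibble::tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = "ROC, pooled over cross-validation folds",
      subtitle = sprintf("AUC = %.3f", auc_score(object))) +
    ggplot2::theme_minimal()
}

#' @export
glance.repair_predictions <- function(x, ...) {
  tibble::tibble(n = nrow(x), n_folds = dplyr::n_distinct(x$fold),
                 auc = auc_score(x),
                 learner = attr(x, "learner") %||% NA_character_,
                 seed = attr(x, "seed") %||% NA_integer_)
}
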