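#' Exact one-sided binomial enrichment tail
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`, the
#' significance test for a rule or attribute-value pattern predicting the
#' ageing-related class: `k` successes among `n` covered instances, under
#' the null that positives occur at the dataset's class frequency `p0`.
#' Terms are accumulated on the log scale (log-Gamma binomial
#' coefficients) for numerical stability; the test is one-sided because
#' only over-representation of the positive class is of interest.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability, strictly between 0 and 1.
#' @return The exact tail probability in `(0, 1]`.
#' @export
binomial_significance <- function(k, n, p0) {
  if (length(p0) != 1 || is.na(p0) || p0 <= 0 || p0 >= 1) {
    abort("p0 must lie strictly between 0 and 1")
  }
  stopifnot(length(k) == 1, length(n) == 1, k >= 0, n >= 0, k <= n)
  if (k == 0) return(1)
  i <- k:n
  log_terms <- lgamma(n + 1) - lgamma(i + 1) - lgamma(n - i + 1) +
    i * log(p0) + (n - i) * log1p(-p0)
  m <- max(log_terms)
  min(exp(m + log(sum(exp(log_terms - m)))), 1)
}

collapse_conditions <- function(cond) {
  if (nrow(cond) == 0) return(cond)
  keep <- rep(TRUE, nrow(cond))
  for (a in unique(cond$attribute)) {
    for (op in c("<=", ">")) {
      i <- which(cond$attribute == a & cond$op == op)
      if (length(i) > 1) {
        tight <- if (op == "<=") i[which.min(cond$threshold[i])]
                 else i[which.max(cond$threshold[i])]
        keep[setdiff(i, tight)] <- FALSE
      }
    }
  }
  cond[keep, , drop = FALSE]
}

walk_paths <- function(node, cond) {
  if (node$leaf) {
    return(list(list(conditions = collapse_conditions(cond),
                     predicted_class = node$class,
                     leaf_counts = node$counts)))
  }
  out <- list()
  for (b in seq_along(node$children)) {
    step <- if (node$kind == "numeric") {
      tibble::tibble(attribute = node$attribute,
                     op = c("<=", ">")[b],
                     value = NA_character_, threshold = node$threshold)
    } else {
      tibble::tibble(attribute = node$attribute, op = "=",
                     value = node$values[b], threshold = NA_real_)
    }
    out <- c(out, walk_paths(node$children[[b]], dplyr::bind_rows(cond, step)))
  }
  out
}

format_conditions <- function(cond) {
  if (nrow(cond) == 0) return("TRUE")
  paste(purrr::pmap_chr(cond, function(attribute, op, value, threshold) {
    rhs <- if (op == "=") value else format(threshold)
    paste0("(", attribute, " ", op, " ", rhs, ")")
  }), collapse = " AND ")
}

#' Render a rule in IF-THEN form
#'
#' @param conditions A condition tibble (`attribute`, `op`, `value`,
#'   `threshold`).
#' @param predicted_class The rule's consequent class.
#' @return A single string, e.g.
#'   `"IF (x > 5) AND (go = yes) THEN class = ageing"`.
#' @export
format_rule <- function(conditions, predicted_class) {
  paste0("IF ", format_conditions(conditions),
         " THEN class = ", predicted_class)
}

#' Extract classification rules from a decision tree
#'
#' One rule per root-to-leaf path: the conjunction of the node tests along
#' the path (in root-to-leaf order) predicting the leaf class. Redundant
#' numeric conditions on the same attribute are collapsed to the tightest
#' interval. Coverage counts are not filled; see [score_rules()].
#'
#' @param tree A `c45_tree`.
#' @return A tibble with columns `rule_id`, `predicted_class`,
#'   `n_conditions`, `conditions` (list column of condition tibbles) and
#'   `rule` (rendered text).
#' @export
extract_rules <- function(tree) {
  stopifnot(inherits(tree, "c45_tree"))
  empty <- tibble::tibble(attribute = character(0), op = character(0),
                          value = character(0), threshold = numeric(0))
  paths <- walk_paths(tree$root, empty)
  tibble::tibble(
    rule_id = seq_along(paths),
    predicted_class = vapply(paths, `[[`, character(1), "predicted_class"),
    n_conditions = vapply(paths, function(p) nrow(p$conditions), integer(1)),
    conditions = lapply(paths, `[[`, "conditions"),
    rule = vapply(paths, function(p)
      format_rule(p$conditions, p$predicted_class), character(1))
  )
}

satisfies <- function(conditions, data) {
  sat <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(conditions))) {
    a <- conditions$attribute[i]
    if (!a %in% names(data)) {
      abort(paste0("rule tests unknown attribute: ", a))
    }
    x <- data[[a]]
    hit <- switch(conditions$op[i],
      "=" = !is.na(x) & as.character(x) == conditions$value[i],
      "<=" = !is.na(x) & x <= conditions$threshold[i],
      ">" = !is.na(x) & x > conditions$threshold[i],
      abort(paste0("unknown operator: ", conditions$op[i])))
    sat <- sat & hit
  }
  sat
}

#' Coverage of a rule on a dataset
#'
#' `n_trials` is the number of instances satisfying every condition of the
#' rule (regardless of class); `n_successes` is the number of those in the
#' rule's predicted class. Instances with a missing value on any tested
#' attribute do not satisfy the rule and count in neither total.
#'
#' @param conditions A condition tibble (see [extract_rules()]).
#' @param data A dataset tibble.
#' @param predicted_class The rule's consequent class.
#' @return Named numeric vector `c(n_trials, n_successes)`.
#' @export
rule_coverage <- function(conditions, data, predicted_class) {
  sat <- satisfies(conditions, data)
  c(n_trials = sum(sat),
    n_successes = sum(sat & as.character(data$class) == predicted_class))
}

#' Score extracted rules on a dataset
#'
#' Fills coverage counts and the exact one-sided binomial p-value for each
#' rule. The null probability `p0` defaults to the relative frequency of
#' each rule's predicted class in `data`, recomputed per dataset. No
#' multiple-testing correction is applied; the number of rules tested is
#' attached as an attribute so callers can correct downstream.
#'
#' @param rules Tibble from [extract_rules()].
#' @param data A dataset tibble.
#' @param p0 Optional fixed null probability; default class frequency.
#' @return `rules` with added columns `n_trials`, `n_successes`, `p0`,
#'   `p_value`.
#' @export
score_rules <- function(rules, data, p0 = NULL) {
  cls_freq <- prop.table(table(as_class_factor(data$class)))
  out <- rules
  cov <- t(vapply(seq_len(nrow(rules)), function(i)
    rule_coverage(rules$conditions[[i]], data, rules$predicted_class[i]),
    numeric(2)))
  out$n_trials <- as.integer(cov[, "n_trials"])
  out$n_successes <- as.integer(cov[, "n_successes"])
  out$p0 <- if (is.null(p0)) as.numeric(cls_freq[rules$predicted_class])
            else rep(p0, nrow(rules))
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    if (out$n_trials[i] == 0) return(1)
    binomial_significance(out$n_successes[i], out$n_trials[i], out$p0[i])
  }, numeric(1))
  attr(out, "n_rules_tested") <- nrow(out)
  out
}

#' Single-attribute-value pattern with coverage and significance
#'
#' Builds the one-condition rule `attribute = value -> target_class`,
#' counts its coverage on `data` and computes the exact binomial tail
#' against `p0` (default: the target class's relative frequency in
#' `data`).
#'
#' @param data A dataset tibble.
#' @param attribute Attribute name.
#' @param value Attribute value tested for equality.
#' @param target_class Predicted class (default the positive class,
#'   `"ageing"`).
#' @param p0 Optional fixed null probability.
#' @return A one-row tibble with `rule`, `n_trials`, `n_successes`, `p0`,
#'   `p_value`.
#' @export
attribute_value_pattern <- function(data, attribute, value,
                                    target_class = POSITIVE_CLASS,
                                    p0 = NULL) {
  cond <- tibble::tibble(attribute = attribute, op = "=",
                         value = as.character(value), threshold = NA_real_)
  cov <- rule_coverage(cond, data, target_class)
  p0 <- p0 %||%
    unname(prop.table(table(as_class_factor(data$class)))[target_class])
  tibble::tibble(
    rule = format_rule(cond, target_class),
    predicted_class = target_class,
    n_trials = as.integer(cov[["n_trials"]]),
    n_successes = as.integer(cov[["n_successes"]]),
    p0 = p0,
    p_value = if (cov[["n_trials"]] == 0) 1 else
      binomial_significance(cov[["n_successes"]], cov[["n_trials"]], p0))
}

#' Tally root attributes over a collection of trees
#'
#' Counts how often each attribute labels the root node across the
#' supplied trees (one per experiment); single-leaf trees are counted
#' under `"none"`.
#'
#' @param trees A list of `c45_tree` objects.
#' @return Tibble with columns `attribute`, `n`, sorted by descending
#'   count then attribute name.
#' @export
tally_root_attributes <- function(trees) {
  if (length(trees) == 0) {
    return(tibble::tibble(attribute = character(0), n = integer(0)))
  }
  roots <- vapply(trees, root_attribute, character(1))
  roots[is.na(roots)] <- "none"
  dplyr::arrange(
    dplyr::count(tibble::tibble(attribute = roots), .data$attribute),
    dplyr::desc(.data$n), .data$attribute)
}

#' Write a scored rule report
#'
#' TSV (one row per rule: rendered IF-THEN text, coverage, `p0`, p-value)
#' or JSON including the structured conditions.
#'
#' @param rules Scored rule tibble from [score_rules()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_rule_report <- function(rules, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  flat <- rules[c("rule_id", "rule", "predicted_class", "n_trials",
                  "n_successes", "p0", "p_value")]
  if (format == "tsv") {
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    doc <- list(n_rules_tested = attr(rules, "n_rules_tested") %||%
                  nrow(rules),
                rules = lapply(seq_len(nrow(rules)), function(i)
                  c(as.list(flat[i, ]),
                    list(conditions = rules$conditions[[i]]))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "rows")
  }
  invisible(path)
}
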