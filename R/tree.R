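# Decision tree induction in the C4.5 family: gain-ratio splits with the
# mean-gain eligibility guard, binary numeric splits at midpoints between
# consecutive distinct observed values, multiway nominal splits, and
# pessimistic (confidence-bound) subtree-replacement pruning.

entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Upper confidence bound on the error rate of a leaf that made `e` errors
# on `n` instances; the exact beta-quantile form of the pessimistic bound.
pessimistic_error_rate <- function(e, n, confidence) {
  if (n == 0) return(0)
  if (e >= n) return(1)
  qbeta(1 - confidence, e + 1, n - e)
}

new_leaf <- function(counts) {
  counts <- as.numeric(counts)
  names(counts) <- CLASS_LEVELS
  cl <- CLASS_LEVELS[which.max(counts)]
  list(leaf = TRUE, class = cl, counts = counts, n = sum(counts))
}

# Best numeric split of x (NA allowed) against two-class labels y01.
# Missing instances are routed to the branch holding more non-missing
# instances (ties: the low branch). Returns NULL or a list with
# threshold, gain, gain_ratio and the per-instance branch assignment.
best_numeric_split <- function(x, y01, min_leaf, parent_h, n_total) {
  nm <- !is.na(x)
  xv <- x[nm]; yv <- y01[nm]
  if (length(unique(xv)) < 2) return(NULL)
  ord <- order(xv)
  xs <- xv[ord]; ys <- yv[ord]
  n_nm <- length(xs)
  cum_pos <- cumsum(ys)
  tot_pos <- cum_pos[n_nm]
  miss_pos <- sum(y01[!nm]); miss_n <- sum(!nm)
  cut_idx <- which(xs[-n_nm] < xs[-1])  # boundaries between distinct values
  if (length(cut_idx) == 0) return(NULL)
  left_n0 <- cut_idx
  right_n0 <- n_nm - left_n0
  to_left <- left_n0 >= right_n0
  left_n <- left_n0 + to_left * miss_n
  right_n <- right_n0 + (!to_left) * miss_n
  ok <- left_n >= min_leaf & right_n >= min_leaf
  if (!any(ok)) return(NULL)
  left_pos <- cum_pos[cut_idx] + to_left * miss_pos
  right_pos <- (tot_pos - cum_pos[cut_idx]) + (!to_left) * miss_pos
  h2 <- function(pos, n) {
    p <- ifelse(n > 0, pos / n, 0)
    ifelse(p <= 0 | p >= 1, 0, -(p * log2(p) + (1 - p) * log2(1 - p)))
  }
  child_h <- (left_n * h2(left_pos, left_n) +
                right_n * h2(right_pos, right_n)) / n_total
  gains <- ifelse(ok, parent_h - child_h, -Inf)
  best <- which.max(gains)  # ties: smallest threshold
  thr <- (xs[cut_idx[best]] + xs[cut_idx[best] + 1]) / 2
  split_h <- entropy_counts(c(left_n[best], right_n[best]))
  branch <- integer(length(x))
  branch[nm] <- ifelse(xv <= thr, 1L, 2L)
  branch[!nm] <- if (to_left[best]) 1L else 2L
  list(kind = "numeric", threshold = thr, gain = gains[best],
       gain_ratio = gains[best] / split_h, branch = branch, n_branches = 2L)
}

# Multiway nominal split over the attribute's full domain; missing
# instances are routed to the largest branch.
best_nominal_split <- function(x, y01, domain, min_leaf, parent_h, n_total) {
  f <- factor(as.character(x), levels = domain)
  sizes <- tabulate(f, nbins = length(domain))
  if (sum(sizes > 0) < 2) return(NULL)
  miss <- is.na(f)
  branch <- as.integer(f)
  if (any(miss)) {
    heavy <- which.max(sizes)
    branch[miss] <- heavy
    sizes[heavy] <- sizes[heavy] + sum(miss)
  }
  if (sum(sizes >= min_leaf) < 2) return(NULL)
  child_h <- 0
  for (b in which(sizes > 0)) {
    yb <- y01[branch == b]
    child_h <- child_h +
      sizes[b] * entropy_counts(c(sum(yb == 0), sum(yb == 1)))
  }
  gain <- parent_h - child_h / n_total
  split_h <- entropy_counts(sizes[sizes > 0])
  list(kind = "nominal", values = domain, gain = gain,
       gain_ratio = gain / split_h, branch = branch,
       n_branches = length(domain))
}

grow_tree <- function(x, y01, info, idx, excluded, min_leaf) {
  counts <- c(sum(y01[idx] == 0), sum(y01[idx] == 1))
  n <- length(idx)
  if (n == 0 || any(counts == n) || n < 2 * min_leaf) {
    return(new_leaf(counts))
  }
  parent_h <- entropy_counts(counts)
  cand <- list()
  for (i in seq_len(nrow(info))) {
    a <- info$name[i]
    if (a %in% excluded) next
    xi <- x[[a]][idx]
    s <- if (info$kind[i] == "numeric") {
      best_numeric_split(xi, y01[idx], min_leaf, parent_h, n)
    } else {
      best_nominal_split(xi, y01[idx], info$domain[[i]], min_leaf,
                         parent_h, n)
    }
    if (!is.null(s) && s$gain > 1e-12) {
      s$attribute <- a
      cand[[length(cand) + 1]] <- s
    }
  }
  if (length(cand) == 0) return(new_leaf(counts))
  gains <- vapply(cand, `[[`, numeric(1), "gain")
  eligible <- which(gains >= mean(gains) - 1e-9)
  ratios <- vapply(cand[eligible], `[[`, numeric(1), "gain_ratio")
  pick <- cand[[eligible[which.max(ratios)]]]  # ties: first attribute

  children <- vector("list", pick$n_branches)
  child_n <- numeric(pick$n_branches)
  excl_next <- if (pick$kind == "nominal") c(excluded, pick$attribute)
               else excluded
  majority <- new_leaf(counts)$class
  for (b in seq_len(pick$n_branches)) {
    sub <- idx[pick$branch == b]
    child_n[b] <- length(sub)
    if (length(sub) == 0) {
      empty <- new_leaf(c(0, 0))
      empty$class <- majority
      children[[b]] <- empty
    } else {
      children[[b]] <- grow_tree(x, y01, info, sub, excl_next, min_leaf)
    }
  }
  node <- list(leaf = FALSE, attribute = pick$attribute, kind = pick$kind,
               counts = setNames(counts, CLASS_LEVELS), n = n,
               children = children, child_n = child_n)
  if (pick$kind == "numeric") node$threshold <- pick$threshold
  else node$values <- pick$values
  node
}

prune_node <- function(node, confidence) {
  err_of <- function(counts, n) {
    (n - max(counts)) # raw errors
  }
  if (node$leaf) {
    node$est_err <- node$n *
      pessimistic_error_rate(err_of(node$counts, node$n), node$n, confidence)
    return(node)
  }
  node$children <- lapply(node$children, prune_node, confidence = confidence)
  subtree_est <- sum(vapply(node$children, `[[`, numeric(1), "est_err"))
  leaf_est <- node$n *
    pessimistic_error_rate(err_of(node$counts, node$n), node$n, confidence)
  if (leaf_est <= subtree_est + 1e-9) {
    lf <- new_leaf(node$counts)
    lf$est_err <- leaf_est
    return(lf)
  }
  node$est_err <- subtree_est
  node
}

#' Train a C4.5-style decision tree
#'
#' Recursive top-down induction. At each node, every attribute proposes
#' its best split (numeric: the midpoint threshold between consecutive
#' distinct observed values maximising information gain; nominal/binary:
#' the multiway split over the value domain). Among proposals whose gain
#' reaches the mean gain of all proposals, the one with the highest gain
#' ratio is chosen (ties broken by attribute column order). Recursion
#' stops on class purity, attribute exhaustion, absence of an admissible
#' split (at least two branches with `min_leaf` instances), or fewer than
#' `2 * min_leaf` instances. Instances with a missing value on the tested
#' attribute are assigned to the heavier branch. Optional pessimistic
#' subtree-replacement pruning compares confidence upper bounds on leaf
#' versus subtree training error.
#'
#' Single-class data yields a single leaf, not an error.
#'
#' @param data A dataset tibble (`gene`, `class`, attribute columns).
#' @param min_leaf Minimum instances per branch for an admissible split.
#' @param prune_confidence Confidence level of the pessimistic error bound.
#' @param use_pruning Whether to prune after growing.
#' @return An object of class `c45_tree`.
#' @export
tree_train <- function(data, min_leaf = 2, prune_confidence = 0.25,
                       use_pruning = TRUE) {
  check_dataset(data, require_both_classes = FALSE)
  stopifnot(min_leaf >= 1, prune_confidence > 0, prune_confidence < 1)
  info <- attribute_info(data)
  y01 <- as.integer(as_class_factor(data$class) == POSITIVE_CLASS)
  x <- data[info$name]
  root <- grow_tree(x, y01, info, seq_len(nrow(data)), character(0), min_leaf)
  if (use_pruning) root <- prune_node(root, prune_confidence)
  structure(
    list(root = root, attrs = info, n = nrow(data),
         params = list(min_leaf = min_leaf,
                       prune_confidence = prune_confidence,
                       use_pruning = use_pruning)),
    class = "c45_tree")
}

route_instance <- function(node, row) {
  while (!node$leaf) {
    v <- row[[node$attribute]]
    b <- NA_integer_
    if (node$kind == "numeric") {
      if (!is.na(v)) b <- if (v <= node$threshold) 1L else 2L
    } else {
      if (!is.na(v)) b <- match(as.character(v), node$values)
    }
    if (is.na(b)) b <- which.max(node$child_n)  # heavier child
    node <- node$children[[b]]
  }
  node
}

#' Predict with a decision tree
#'
#' Routes each instance to a leaf; the positive-class probability is the
#' Laplace-corrected leaf proportion `(n_ageing + 1) / (n + 2)`. Missing
#' (or unseen nominal) values at a tested node route to the child that
#' received more training instances.
#'
#' @param object A `c45_tree`.
#' @param newdata Tibble with the tree's attribute columns.
#' @param type `"prob"` for a tibble of per-class probabilities, `"class"`
#'   for the leaf class.
#' @param ... Unused.
#' @export
predict.c45_tree <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$attrs$name, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("attribute(s) missing from newdata: ",
                 paste(head(missing_cols, 5), collapse = ", ")))
  }
  leaves <- lapply(seq_len(nrow(newdata)), function(i)
    route_instance(object$root, newdata[i, , drop = FALSE]))
  if (type == "class") {
    return(factor(vapply(leaves, `[[`, character(1), "class"),
                  levels = CLASS_LEVELS))
  }
  p_pos <- vapply(leaves, function(lf)
    (lf$counts[[POSITIVE_CLASS]] + 1) / (lf$n + 2), numeric(1))
  tibble::tibble(non_ageing = 1 - p_pos, ageing = p_pos)
}

#' Root attribute of a tree
#'
#' @param tree A `c45_tree`.
#' @return The attribute name tested at the root, or `NA` for a
#'   single-leaf tree.
#' @export
root_attribute <- function(tree) {
  stopifnot(inherits(tree, "c45_tree"))
  if (tree$root$leaf) NA_character_ else tree$root$attribute
}

render_node <- function(node, prefix = "") {
  leaf_txt <- function(lf) {
    err <- lf$n - max(lf$counts)
    paste0(": ", lf$class, " (", format(lf$n), "/", format(err), ")")
  }
  out <- character(0)
  branches <- if (node$kind == "numeric") {
    c(paste0(node$attribute, " <= ", format(node$threshold)),
      paste0(node$attribute, " > ", format(node$threshold)))
  } else {
    paste0(node$attribute, " = ", node$values)
  }
  for (b in seq_along(node$children)) {
    ch <- node$children[[b]]
    if (ch$leaf) {
      out <- c(out, paste0(prefix, branches[b], leaf_txt(ch)))
    } else {
      out <- c(out, paste0(prefix, branches[b]),
               render_node(ch, paste0(prefix, "|   ")))
    }
  }
  out
}

#' @export
format.c45_tree <- function(x, ...) {
  if (x$root$leaf) {
    paste0(": ", x$root$class, " (", x$root$n, "/",
           x$root$n - max(x$root$counts), ")")
  } else {
    paste(render_node(x$root), collapse = "\n")
  }
}

#' @export
print.c45_tree <- function(x, ...) {
  cat("<c45_tree> trained on", x$n, "instances\n")
  cat(format(x), "\n")
  invisible(x)
}

count_nodes <- function(node) {
  if (node$leaf) return(c(internal = 0L, leaves = 1L))
  Reduce(`+`, lapply(node$children, count_nodes)) + c(internal = 1L,
                                                      leaves = 0L)
}

#' Tidy a decision tree into its rules
#'
#' One row per root-to-leaf path, with the rendered condition text,
#' predicted class and leaf counts; a thin wrapper over [extract_rules()].
#'
#' @param x A `c45_tree`.
#' @param ... Unused.
#' @export
tidy.c45_tree <- function(x, ...) {
  extract_rules(x)
}

#' @export
glance.c45_tree <- function(x, ...) {
  cn <- count_nodes(x$root)
  tibble::tibble(n = x$n, n_internal = cn[["internal"]],
                 n_leaves = cn[["leaves"]],
                 root_attribute = root_attribute(x),
                 pruned = x$params$use_pruning)
}

node_to_list <- function(node) {
  if (node$leaf) {
    list(leaf = TRUE, class = node$class, counts = as.numeric(node$counts),
         n = node$n)
  } else {
    out <- list(leaf = FALSE, attribute = node$attribute, kind = node$kind,
                counts = as.numeric(node$counts), n = node$n,
                child_n = node$child_n,
                children = lapply(node$children, node_to_list))
    if (node$kind == "numeric") out$threshold <- node$threshold
    else out$values <- node$values
    out
  }
}

node_from_list <- function(lst) {
  if (isTRUE(lst$leaf)) {
    list(leaf = TRUE, class = lst$class,
         counts = setNames(as.numeric(lst$counts), CLASS_LEVELS), n = lst$n)
  } else {
    out <- list(leaf = FALSE, attribute = lst$attribute, kind = lst$kind,
                counts = setNames(as.numeric(lst$counts), CLASS_LEVELS),
                n = lst$n, child_n = as.numeric(lst$child_n),
                children = lapply(lst$children, node_from_list))
    if (lst$kind == "numeric") out$threshold <- lst$threshold
    else out$values <- as.character(lst$values)
    out
  }
}

#' Serialise a decision tree to JSON
#'
#' @param tree A `c45_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
tree_to_json <- function(tree, path) {
  doc <- list(type = "c45_tree", n = tree$n, params = tree$params,
              attrs = list(name = tree$attrs$name, kind = tree$attrs$kind,
                           domain = tree$attrs$domain),
              root = node_to_list(tree$root))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Reload a decision tree written by [tree_to_json()]
#'
#' @param path Path to the JSON document.
#' @return A `c45_tree` predicting identically to the serialised one.
#' @export
tree_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  stopifnot(identical(doc$type, "c45_tree"))
  structure(
    list(root = node_from_list(doc$root),
         attrs = tibble::tibble(name = doc$attrs$name, kind = doc$attrs$kind,
                                domain = lapply(doc$attrs$domain, function(d)
                                  if (length(d) == 0) NULL else
                                    as.character(d))),
         n = doc$n, params = doc$params),
    class = "c45_tree")
}
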