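# Independent oracles and small fixture builders shared across tests.
# Each oracle is a deliberately naive re-derivation (fixpoint iteration,
# exhaustive enumeration, direct product evaluation) kept separate from
# the package's own code paths.

# --- ontology fixtures ------------------------------------------------

# diamond: D is_a {B, C}; B, C is_a A (all biological_process)
diamond_ontology <- function() {
  ontology(
    terms = tibble::tibble(
      id = c("A", "B", "C", "D"),
      name = paste("term", c("A", "B", "C", "D")),
      namespace = "biological_process"),
    edges = tibble::tibble(child = c("D", "D", "B", "C"),
                           parent = c("B", "C", "A", "A")))
}

# reachability by repeated parent-set expansion to fixpoint
oracle_ancestors <- function(graph, term) {
  anc <- character(0)
  repeat {
    grown <- unique(c(anc, unlist(graph$parents[c(term, anc)],
                                  use.names = FALSE)))
    if (setequal(grown, anc)) return(sort(anc))
    anc <- grown
  }
}

# --- statistics oracles -----------------------------------------------

# exact binomial upper tail by direct summation (safe for n <= 30)
oracle_binom_tail <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# AUC as the mean pairwise win rate (ties count one half)
oracle_auc <- function(class, score) {
  pos <- score[class == "ageing"]
  neg <- score[class == "non_ageing"]
  wins <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(wins)
}

# Naive Bayes posterior by direct product evaluation of the model's own
# tables (no log space), the definitional form of the classifier
oracle_nb_posterior <- function(model, row) {
  score <- model$priors
  for (i in seq_len(nrow(model$attrs))) {
    a <- model$attrs$name[i]
    v <- row[[a]]
    if (is.na(v)) next
    if (model$attrs$kind[i] == "numeric") {
      pars <- model$numeric[[a]]
      if (is.null(pars) || anyNA(pars["mean", ])) next
      for (k in names(score)) {
        score[k] <- score[k] * dnorm(v, pars["mean", k], pars["sd", k])
      }
    } else {
      tab <- model$nominal[[a]]
      if (!as.character(v) %in% rownames(tab)) next
      for (k in names(score)) {
        score[k] <- score[k] * tab[as.character(v), k]
      }
    }
  }
  score / sum(score)
}

# --- decision-tree split oracle ---------------------------------------

oracle_entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Exhaustive enumeration of all attributes and all numeric cut points
# (data without missing values), mirroring the stated split policy:
# admissible splits need >= 2 branches with min_leaf instances; among
# candidates with gain >= mean gain, pick max gain ratio; ties by
# attribute order, then smaller threshold.
oracle_best_split <- function(data, min_leaf = 2) {
  info <- attribute_info(data)
  y <- as.character(data$class)
  parent_h <- oracle_entropy(table(y))
  n <- nrow(data)
  cands <- list()
  for (i in seq_len(nrow(info))) {
    a <- info$name[i]
    x <- data[[a]]
    if (info$kind[i] == "numeric") {
      vals <- sort(unique(x))
      if (length(vals) < 2) next
      best <- NULL
      for (j in seq_len(length(vals) - 1)) {
        thr <- (vals[j] + vals[j + 1]) / 2
        left <- x <= thr
        if (sum(left) < min_leaf || sum(!left) < min_leaf) next
        child_h <- (sum(left) * oracle_entropy(table(y[left])) +
                      sum(!left) * oracle_entropy(table(y[!left]))) / n
        gain <- parent_h - child_h
        if (is.null(best) || gain > best$gain + 1e-12) {
          split_h <- oracle_entropy(c(sum(left), sum(!left)))
          best <- list(attribute = a, threshold = thr, gain = gain,
                       gain_ratio = gain / split_h)
        }
      }
      if (!is.null(best) && best$gain > 1e-12) {
        cands[[length(cands) + 1]] <- best
      }
    } else {
      dom <- info$domain[[i]]
      f <- factor(as.character(x), levels = dom)
      sizes <- table(f)
      if (sum(sizes > 0) < 2 || sum(sizes >= min_leaf) < 2) next
      child_h <- 0
      for (v in dom) {
        sel <- !is.na(f) & f == v
        child_h <- child_h + sum(sel) * oracle_entropy(table(y[sel]))
      }
      gain <- parent_h - child_h / n
      if (gain > 1e-12) {
        cands[[length(cands) + 1]] <- list(
          attribute = a, threshold = NA_real_, gain = gain,
          gain_ratio = gain / oracle_entropy(sizes[sizes > 0]))
      }
    }
  }
  if (length(cands) == 0) return(NULL)
  gains <- vapply(cands, `[[`, numeric(1), "gain")
  eligible <- which(gains >= mean(gains) - 1e-9)
  ratios <- vapply(cands[eligible], `[[`, numeric(1), "gain_ratio")
  cands[[eligible[which.max(ratios)]]]
}

# pessimistic training-set error estimate of a fitted tree (leaf sum of
# upper confidence bounds), recomputed from first principles
pessimistic_tree_error <- function(tree, confidence = 0.25) {
  walk <- function(node) {
    if (node$leaf) {
      n <- node$n
      if (n == 0) return(0)
      e <- n - max(node$counts)
      u <- if (e >= n) 1 else qbeta(1 - confidence, e + 1, n - e)
      return(n * u)
    }
    sum(vapply(node$children, walk, numeric(1)))
  }
  walk(tree$root)
}

# --- dataset fixtures -------------------------------------------------

random_dataset <- function(n, seed, n_numeric = 2, n_binary = 2,
                           with_nominal = TRUE) {
  withr::with_seed(seed, {
    out <- tibble::tibble(
      gene = sprintf("g%03d", seq_len(n)),
      class = sample(c("ageing", "non_ageing"), n, replace = TRUE,
                     prob = c(0.35, 0.65)))
    while (length(unique(out$class)) < 2) {
      out$class <- sample(c("ageing", "non_ageing"), n, replace = TRUE)
    }
    for (i in seq_len(n_numeric)) {
      out[[paste0("x", i)]] <- round(runif(n, 0, 20), 2) +
        2 * (out$class == "ageing") * (i == 1)
    }
    for (i in seq_len(n_binary)) {
      p <- ifelse(out$class == "ageing", 0.6, 0.3)
      out[[paste0("b", i)]] <- ifelse(runif(n) < p, "yes", "no")
    }
    if (with_nominal) {
      out$pathway <- sample(c("ber", "ner", "mmr"), n, replace = TRUE)
    }
    out
  })
}
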