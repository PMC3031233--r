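#' Train a Naive Bayes classifier
#'
#' Class priors are the unsmoothed class relative frequencies. Nominal and
#' binary attributes get pseudo-count-smoothed conditional tables,
#' `(count + smoothing) / (class count + smoothing * |domain|)`, where the
#' class count is the number of class-k instances with a non-missing value
#' on the attribute. Numeric attributes get per-class Gaussian parameters;
#' standard deviations are floored at `sqrt(1e-6 * global variance)` of
#' the attribute (never below 1e-9) so that a within-class constant value
#' cannot produce a degenerate density.
#'
#' @param data A dataset tibble (`gene`, `class`, attribute columns); both
#'   classes must be present.
#' @param smoothing Pseudo-count for nominal conditionals (default 1).
#' @return An object of class `nb_model`.
#' @export
nb_train <- function(data, smoothing = 1) {
  check_dataset(data)
  info <- attribute_info(data)
  y <- as_class_factor(data$class)
  n_k <- table(y)
  priors <- as.numeric(n_k) / length(y)
  names(priors) <- names(n_k)

  nominal <- list()
  numeric_params <- list()
  for (i in seq_len(nrow(info))) {
    a <- info$name[i]
    x <- data[[a]]
    if (info$kind[i] == "numeric") {
      gvar <- stats::var(x[!is.na(x)])
      if (!is.finite(gvar)) gvar <- 0
      floor_sd <- max(sqrt(1e-6 * gvar), 1e-9)
      pars <- vapply(CLASS_LEVELS, function(k) {
        xv <- x[y == k & !is.na(x)]
        m <- if (length(xv) > 0) mean(xv) else NA_real_
        s <- if (length(xv) > 1) stats::sd(xv) else 0
        c(mean = m, sd = max(s, floor_sd))
      }, numeric(2))
      numeric_params[[a]] <- pars  # 2 x n_classes matrix
    } else {
      dom <- info$domain[[i]]
      tab <- vapply(CLASS_LEVELS, function(k) {
        xv <- x[y == k & !is.na(x)]
        cnt <- table(factor(xv, levels = dom))
        (as.numeric(cnt) + smoothing) /
          (length(xv) + smoothing * length(dom))
      }, numeric(length(dom)))
      rownames(tab) <- dom
      nominal[[a]] <- tab
    }
  }
  structure(
    list(priors = priors, attrs = info, nominal = nominal,
         numeric = numeric_params, smoothing = smoothing, n = length(y)),
    class = "nb_model")
}

#' Predict with a Naive Bayes model
#'
#' Per-class scores are `prior * prod(conditionals)` over the non-missing
#' attributes of each instance, accumulated in log space and returned
#' normalised to sum to one. Missing attributes are skipped; a nominal
#' value unseen in the model's domain is treated as missing (with a
#' message).
#'
#' @param object An `nb_model`.
#' @param newdata Tibble with the model's attribute columns.
#' @param type `"prob"` for a tibble of per-class posteriors (columns
#'   `non_ageing`, `ageing`), `"class"` for the maximum-posterior class.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.nb_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  n <- nrow(newdata)
  logp <- matrix(rep(log(object$priors), each = n), nrow = n,
                 dimnames = list(NULL, names(object$priors)))
  for (i in seq_len(nrow(object$attrs))) {
    a <- object$attrs$name[i]
    if (!a %in% names(newdata)) {
      abort(paste0("attribute missing from newdata: ", a))
    }
    x <- newdata[[a]]
    if (object$attrs$kind[i] == "numeric") {
      pars <- object$numeric[[a]]
      if (is.null(pars) || anyNA(pars["mean", ])) next
      ok <- !is.na(x)
      for (k in CLASS_LEVELS) {
        logp[ok, k] <- logp[ok, k] +
          dnorm(x[ok], pars["mean", k], pars["sd", k], log = TRUE)
      }
    } else {
      tab <- object$nominal[[a]]
      x <- as.character(x)
      unseen <- !is.na(x) & !x %in% rownames(tab)
      if (any(unseen)) {
        inform(paste0("treating ", sum(unseen), " unseen value(s) of `", a,
                      "` as missing"))
        x[unseen] <- NA_character_
      }
      ok <- !is.na(x)
      for (k in CLASS_LEVELS) {
        logp[ok, k] <- logp[ok, k] + log(tab[x[ok], k])
      }
    }
  }
  # normalise in log space
  mx <- apply(logp, 1, max)
  post <- exp(logp - mx)
  post <- post / rowSums(post)
  if (type == "class") {
    return(factor(colnames(post)[max.col(post, ties.method = "first")],
                  levels = CLASS_LEVELS))
  }
  tibble::as_tibble(as.data.frame(post))
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model> Naive Bayes,", x$n, "training instances,",
      nrow(x$attrs), "attributes\n")
  cat("  priors:", paste(names(x$priors), round(x$priors, 4),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a Naive Bayes model
#'
#' One row per estimated parameter: class priors, nominal conditional
#' probabilities, and Gaussian means/standard deviations.
#'
#' @param x An `nb_model`.
#' @param ... Unused.
#' @return A tibble with columns `attribute`, `class`, `term`, `estimate`.
#' @export
tidy.nb_model <- function(x, ...) {
  rows <- list(tibble::tibble(attribute = "(prior)", class = names(x$priors),
                              term = "prior", estimate = as.numeric(x$priors)))
  for (a in names(x$nominal)) {
    tab <- x$nominal[[a]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      attribute = a,
      class = rep(colnames(tab), each = nrow(tab)),
      term = rep(rownames(tab), ncol(tab)),
      estimate = as.numeric(tab))
  }
  for (a in names(x$numeric)) {
    pars <- x$numeric[[a]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      attribute = a,
      class = rep(colnames(pars), each = 2),
      term = rep(c("mean", "sd"), ncol(pars)),
      estimate = as.numeric(pars))
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.nb_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_attributes = nrow(x$attrs),
                 smoothing = x$smoothing,
                 prior_ageing = unname(x$priors[POSITIVE_CLASS]))
}

#' Serialise a Naive Bayes model to JSON
#'
#' @param model An `nb_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
nb_to_json <- function(model, path) {
  doc <- list(
    type = "nb_model",
    priors = as.list(model$priors),
    smoothing = model$smoothing,
    n = model$n,
    attrs = list(name = model$attrs$name, kind = model$attrs$kind,
                 domain = model$attrs$domain),
    nominal = lapply(model$nominal, function(tab)
      list(values = rownames(tab), classes = colnames(tab),
           p = as.numeric(tab))),
    numeric = lapply(model$numeric, function(pars)
      list(classes = colnames(pars), mean = as.numeric(pars["mean", ]),
           sd = as.numeric(pars["sd", ])))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Reload a Naive Bayes model written by [nb_to_json()]
#'
#' @param path Path to the JSON document.
#' @return An `nb_model` predicting identically to the serialised one.
#' @export
nb_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  stopifnot(identical(doc$type, "nb_model"))
  nominal <- lapply(doc$nominal, function(e)
    matrix(e$p, nrow = length(e$values),
           dimnames = list(e$values, e$classes)))
  numeric_params <- lapply(doc$numeric, function(e)
    matrix(c(rbind(e$mean, e$sd)), nrow = 2,
           dimnames = list(c("mean", "sd"), e$classes)))
  structure(
    list(priors = unlist(doc$priors),
         attrs = tibble::tibble(name = doc$attrs$name, kind = doc$attrs$kind,
                                domain = lapply(doc$attrs$domain, function(d)
                                  if (length(d) == 0) NULL else
                                    as.character(d))),
         nominal = nominal, numeric = numeric_params,
         smoothing = doc$smoothing, n = doc$n),
    class = "nb_model")
}
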