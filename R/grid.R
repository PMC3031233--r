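#' Run the dataset-variant x GO-threshold experiment grid
#'
#' For every combination of dataset variant (D1-D5), GO term occurrence
#' threshold and learner, builds the dataset, estimates the pooled
#' cross-validated AUC, and (for the tree learner) records the root
#' attribute of a tree trained on the full dataset — the machine-readable
#' analogue of an AUC table plus a root-attribute tally.
#'
#' @param genes,annotations,edges,graph Cohort components (see
#'   [build_dataset()]); alternatively pass a `repair_cohort` as `genes`
#'   and leave the others `NULL`.
#' @param variants Character vector of dataset variants.
#' @param go_thresholds Integer vector of GO occurrence thresholds.
#' @param learners Character vector among `"tree"`, `"naive_bayes"`.
#' @param k Cross-validation fold count.
#' @param seed Integer seed (fold assignment).
#' @return A tibble of class `repair_grid` with one row per
#'   (variant, threshold, learner): `auc`, `root_attribute`,
#'   `n_instances`, `n_attributes`, `seed`. The full-data trees are
#'   attached as attribute `"trees"` (named `variant_t`), for
#'   [tally_root_attributes()].
#' @export
run_experiment_grid <- function(genes, annotations = NULL, edges = NULL,
                                graph = NULL,
                                variants = c("D1", "D2", "D3", "D4", "D5"),
                                go_thresholds = c(3, 7, 11),
                                learners = c("tree", "naive_bayes"),
                                k = 10, seed = 1) {
  if (inherits(genes, "repair_cohort")) {
    cohort <- genes
    genes <- cohort$genes
    annotations <- cohort$annotations
    edges <- cohort$interactions
    graph <- cohort$ontology
  }
  rows <- list()
  trees <- list()
  for (t in go_thresholds) {
    for (v in variants) {
      ds <- build_dataset(genes, annotations, edges, graph, variant = v,
                          go_threshold = t)
      full_tree <- if ("tree" %in% learners) tree_train(ds) else NULL
      if (!is.null(full_tree)) trees[[paste0(v, "_t", t)]] <- full_tree
      for (lrn in learners) {
        preds <- cross_validate(ds, learner = lrn, k = k, seed = seed)
        rows[[length(rows) + 1]] <- tibble::tibble(
          variant = v, go_threshold = t, learner = lrn,
          n_instances = nrow(ds),
          n_attributes = ncol(ds) - 2L,
          auc = auc_score(preds),
          root_attribute = if (lrn == "tree") root_attribute(full_tree)
                           else NA_character_,
          seed = seed)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("repair_grid", class(out))
  attr(out, "trees") <- trees
  out
}

#' Plot an experiment grid
#'
#' AUC against the GO occurrence threshold, one line per dataset variant,
#' facetted by learner.
#'
#' @param object A `repair_grid` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.repair_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$go_threshold, y = .data$auc,
                               colour = .data$variant,
                               group = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~learner) +
    ggplot2::scale_x_continuous(breaks = unique(object$go_threshold)) +
    ggplot2::labs(x = "GO term occurrence threshold", y = "Pooled CV AUC",
                  colour = "Dataset") +
    ggplot2::theme_minimal()
}

#' Write an evaluation report
#'
#' TSV or JSON rows of (variant, threshold, learner, AUC, root attribute,
#' seed) — the machine-readable analogue of the AUC tables.
#'
#' @param grid A `repair_grid` tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_grid_report <- function(grid, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  flat <- as.data.frame(grid)
  if (format == "tsv") {
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "rows")
  }
  invisible(path)
}
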