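#' Filter protein-protein interactions by cohort and evidence
#'
#' Keeps an edge iff at least one endpoint is in the gene cohort and the
#' evidence set includes a non-high-throughput experimental tag (`in_vivo`
#' or `in_vitro`). Duplicate unordered pairs are merged with their evidence
#' sets unioned, so edge multiplicity never inflates partner counts.
#'
#' @param edges Tibble with columns `protein_a`, `protein_b` and `evidence`
#'   (list of character vectors, or a comma-separated character column).
#' @param cohort Character vector of gene symbols in the dataset.
#' @return Tibble of retained edges with canonically ordered pairs
#'   (`protein_a` <= `protein_b` lexicographically).
#' @export
filter_interactions <- function(edges, cohort) {
  edges <- tibble::as_tibble(edges)
  if (!is.list(edges$evidence)) {
    edges$evidence <- lapply(strsplit(as.character(edges$evidence), ","),
                             trimws)
  }
  empty <- tibble::tibble(protein_a = character(0), protein_b = character(0),
                          evidence = list())
  if (nrow(edges) == 0) return(empty)
  # merge duplicate unordered pairs first, so evidence recorded on any
  # line of a repeated pair counts towards the evidence rule
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  key <- paste(a, b, sep = "\r")
  idx <- split(seq_along(key), factor(key, levels = unique(key)))
  merged <- tibble::tibble(
    protein_a = a[vapply(idx, `[[`, integer(1), 1)],
    protein_b = b[vapply(idx, `[[`, integer(1), 1)],
    evidence = unname(lapply(idx, function(i)
      sort(unique(unlist(edges$evidence[i], use.names = FALSE)))))
  )
  keep <- (merged$protein_a %in% cohort | merged$protein_b %in% cohort) &
    vapply(merged$evidence,
           function(e) any(c("in_vivo", "in_vitro") %in% e), logical(1))
  out <- merged[keep, , drop = FALSE]
  if (nrow(out) == 0) empty else out
}

#' Count distinct interaction partners of one protein
#'
#' @param symbol Protein symbol.
#' @param edges Filtered interaction tibble (see [filter_interactions()]).
#' @return Number of distinct partner symbols; a self-interaction
#'   contributes the protein itself once.
#' @export
count_partners <- function(symbol, edges) {
  hit_a <- edges$protein_a == symbol
  hit_b <- edges$protein_b == symbol
  length(unique(c(edges$protein_b[hit_a], edges$protein_a[hit_b])))
}

#' Distinct-partner counts for every protein in an edge list
#'
#' @param edges Filtered interaction tibble.
#' @return Tibble with columns `protein`, `n_partners`, sorted by
#'   descending count then protein symbol.
#' @export
partner_counts <- function(edges) {
  prot <- c(edges$protein_a, edges$protein_b)
  part <- c(edges$protein_b, edges$protein_a)
  df <- dplyr::distinct(tibble::tibble(protein = prot, partner = part))
  dplyr::arrange(dplyr::count(df, .data$protein, name = "n_partners"),
                 dplyr::desc(.data$n_partners), .data$protein)
}

#' Most frequent interactor proteins
#'
#' The `n` proteins with the greatest number of distinct interaction
#' partners among the filtered edges, ties broken lexicographically for
#' reproducibility. These name the binary protein-interaction (BPI)
#' attributes of the D3-D5 dataset variants.
#'
#' @param edges Filtered interaction tibble.
#' @param n Number of proteins to select.
#' @return Character vector of at most `n` protein symbols.
#' @export
select_top_bpi <- function(edges, n) {
  stopifnot(n >= 1)
  head(partner_counts(edges)$protein, n)
}

# ancestor closure for many genes, with per-term memoisation
closed_annotations <- function(annotations, graph) {
  terms <- unique(annotations$go_id)
  hit_alias <- terms %in% names(graph$aliases)
  canonical <- terms
  canonical[hit_alias] <- graph$aliases[terms[hit_alias]]
  known <- canonical %in% graph$terms$id
  if (any(!known)) {
    warn(paste0("skipping ", sum(!known),
                " annotation term(s) unknown to the ontology: ",
                paste(head(terms[!known], 5), collapse = ", ")))
  }
  closure <- setNames(vector("list", length(terms)), terms)
  for (i in seq_along(terms)) {
    if (!known[i]) {
      closure[[i]] <- character(0)
    } else {
      t <- canonical[i]
      anc <- c(t, go_ancestors(graph, t))
      closure[[i]] <- anc[graph$namespace[anc] == "biological_process"]
    }
  }
  split_terms <- split(annotations$go_id, annotations$gene)
  lapply(split_terms, function(tt)
    sort(unique(unlist(closure[unique(tt)], use.names = FALSE))))
}

#' Build the block of binary GO-term attributes
#'
#' Each gene's specific biological-process annotations are extended with
#' all `is_a` ancestors; each surviving term becomes one binary column
#' (`yes` iff the term is in the gene's closed annotation). A term
#' survives iff its `yes` count across all genes is at least
#' `go_threshold` (the GO term occurrence threshold). Columns are ordered
#' by term identifier.
#'
#' @param genes Gene tibble with at least a `gene` column.
#' @param annotations Tibble with columns `gene`, `go_id` (specific terms).
#' @param graph An [ontology].
#' @param go_threshold Minimum `yes` occurrence count (>= 1).
#' @return Tibble with a `gene` column and one `yes`/`no` column per
#'   surviving GO term.
#' @export
build_go_block <- function(genes, annotations, graph, go_threshold = 3) {
  stopifnot(go_threshold >= 1)
  closed <- closed_annotations(
    annotations[annotations$gene %in% genes$gene, , drop = FALSE], graph)
  all_terms <- sort(unique(unlist(closed, use.names = FALSE)))
  counts <- table(factor(unlist(closed, use.names = FALSE),
                         levels = all_terms))
  surviving <- all_terms[counts >= go_threshold]
  out <- tibble::tibble(gene = genes$gene)
  for (t in surviving) {
    out[[t]] <- ifelse(
      vapply(genes$gene, function(g) t %in% (closed[[g]] %||% character(0)),
             logical(1), USE.NAMES = FALSE),
      "yes", "no")
  }
  out
}

#' Remove duplicated instances from a dataset
#'
#' Among instances identical on every attribute value and on the class,
#' only the first (in input order) is kept. Attribute-identical instances
#' with conflicting classes are all retained, with a warning, since they
#' carry genuine label information. Idempotent.
#'
#' @param data A dataset tibble (columns `gene`, `class`, attributes).
#' @return The deduplicated dataset tibble.
#' @export
deduplicate_instances <- function(data) {
  attrs <- setdiff(names(data), c("gene", "class"))
  cells <- lapply(data[attrs], function(x) {
    x <- if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
    x[is.na(x)] <- "\r?"
    x
  })
  key <- if (length(attrs) == 0) rep("", nrow(data)) else
    do.call(paste, c(cells, sep = "\r"))
  full_key <- paste(key, as.character(data$class), sep = "\r\r")
  keep <- !duplicated(full_key)
  conflict <- tapply(as.character(data$class), key,
                     function(cl) length(unique(cl)) > 1)
  if (any(conflict)) {
    n_conf <- sum(key[keep] %in% names(conflict)[conflict])
    warn(paste0(n_conf, " attribute-identical instance(s) with conflicting ",
                "classes retained"))
  }
  data[keep, , drop = FALSE]
}

#' Build a classification dataset (variants D1-D5)
#'
#' Assembles the instances-by-attributes table: DNA repair `pathway`
#' (nominal), `ka_ki` evolutionary rate (numeric, missing allowed), the
#' binary GO-term block at occurrence threshold `go_threshold`, and a
#' variant-dependent PPI block:
#' \describe{
#'   \item{D1}{no PPI attributes}
#'   \item{D2}{`n_partners`, the distinct interaction partner count}
#'   \item{D3/D4/D5}{`n_partners` plus 10/20/30 binary protein-interaction
#'     (BPI) columns named `<protein>_interaction`, `yes` iff the gene's
#'     product interacts with that protein}
#' }
#' Interactions are evidence- and cohort-filtered first; the finished
#' table is deduplicated.
#'
#' @param genes Gene tibble (`gene`, `class`, `pathway`, `ka_ki`).
#' @param annotations Tibble (`gene`, `go_id`).
#' @param edges Raw or filtered interaction tibble.
#' @param graph An [ontology].
#' @param variant One of `"D1"` ... `"D5"`.
#' @param go_threshold GO term occurrence threshold (>= 1).
#' @param n_bpi Number of BPI columns; defaults to 10/20/30 for D3/D4/D5.
#' @return A dataset tibble.
#' @export
build_dataset <- function(genes, annotations, edges, graph,
                          variant = c("D1", "D2", "D3", "D4", "D5"),
                          go_threshold = 3, n_bpi = NULL) {
  variant <- match.arg(variant)
  genes <- tibble::as_tibble(genes)
  if (nrow(genes) == 0) abort("no gene records supplied")
  genes$class <- as_class_factor(genes$class)
  if (dplyr::n_distinct(genes$class) < 2) {
    abort("both classes (ageing, non_ageing) must be present")
  }
  out <- tibble::tibble(gene = genes$gene, class = genes$class,
                        pathway = genes$pathway, ka_ki = genes$ka_ki)
  go <- build_go_block(genes, annotations, graph, go_threshold)
  out <- dplyr::left_join(out, go, by = "gene")
  if (variant != "D1") {
    fedges <- filter_interactions(edges, genes$gene)
    pc <- partner_counts(fedges)
    out$n_partners <- pc$n_partners[match(genes$gene, pc$protein)]
    out$n_partners[is.na(out$n_partners)] <- 0L
    if (variant %in% c("D3", "D4", "D5")) {
      n_bpi <- n_bpi %||% c(D3 = 10L, D4 = 20L, D5 = 30L)[[variant]]
      top <- select_top_bpi(fedges, n_bpi)
      for (p in top) {
        partners_of_p <- unique(c(fedges$protein_b[fedges$protein_a == p],
                                  fedges$protein_a[fedges$protein_b == p]))
        out[[paste0(p, "_interaction")]] <-
          ifelse(genes$gene %in% partners_of_p, "yes", "no")
      }
    }
  }
  deduplicate_instances(out)
}

#' Build the expression-only dataset
#'
#' One numeric column per anatomy category; each cell is the arithmetic
#' mean of all of that gene's probe values in that category (probes from
#' different array generations are never mixed upstream, so averaging
#' across probes pools all available measurements). A gene with no probe
#' in a category gets a missing value. Genes present in the probe table
#' but absent from `genes` are dropped; the result is deduplicated.
#'
#' @param probes Tibble (`gene`, `probe`, `anatomy_category`, `value`).
#' @param genes Gene tibble with `gene` and `class` columns.
#' @return A dataset tibble (`gene`, `class`, one column per category).
#' @export
build_expression_dataset <- function(probes, genes) {
  probes <- tibble::as_tibble(probes)
  if (nrow(probes) == 0) abort("empty probe table")
  probes <- probes[probes$gene %in% genes$gene, , drop = FALSE]
  means <- dplyr::summarise(
    dplyr::group_by(probes, .data$gene, .data$anatomy_category),
    value = mean(.data$value), .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "anatomy_category",
                             values_from = "value", names_sort = TRUE)
  out <- dplyr::inner_join(
    tibble::tibble(gene = genes$gene, class = as_class_factor(genes$class)),
    wide, by = "gene")
  if (nrow(out) == 0) abort("no overlap between probe table and gene table")
  deduplicate_instances(out)
}
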