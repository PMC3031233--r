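#' Construct an ontology graph
#'
#' An `ontology` holds a set of terms, their direct `is_a` parents, the
#' namespace of each term and a human-readable label. Only `is_a` edges are
#' represented: annotation closure over the biological-process branch uses
#' the `is_a` relation exclusively, so other relationship types
#' (`part_of`, `regulates`, ...) are out of scope by design.
#'
#' @param terms Tibble or data frame with columns `id`, `name`, `namespace`
#'   (one of `biological_process`, `molecular_function`,
#'   `cellular_component`).
#' @param edges Tibble or data frame with columns `child`, `parent`: direct
#'   `is_a` links.
#' @param aliases Optional tibble with columns `alt_id`, `id` mapping
#'   secondary identifiers to canonical terms.
#'
#' @return An object of class `ontology`: a list with elements `terms`
#'   (tibble), `edges` (tibble), `parents` (named list of character
#'   vectors), `namespace` (named character), `label` (named character),
#'   `aliases` (named character).
#' @export
ontology <- function(terms, edges, aliases = NULL) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (nrow(edges) > 0) stopifnot(all(c("child", "parent") %in% names(edges)))
  if (anyDuplicated(terms$id)) {
    abort("duplicate term ids in ontology")
  }
  bad_ns <- setdiff(unique(terms$namespace),
                    c("biological_process", "molecular_function",
                      "cellular_component"))
  if (length(bad_ns) > 0) {
    abort(paste0("unknown namespace(s): ", paste(bad_ns, collapse = ", ")))
  }
  missing_ref <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing_ref) > 0) {
    abort(paste0("edge references unknown term(s): ",
                 paste(head(missing_ref, 5), collapse = ", ")))
  }
  parents <- split(edges$parent, factor(edges$child, levels = terms$id))
  parents <- lapply(parents, unique)
  obj <- structure(
    list(
      terms = terms,
      edges = edges,
      parents = parents,
      namespace = setNames(terms$namespace, terms$id),
      label = setNames(terms$name, terms$id),
      aliases = if (is.null(aliases) || nrow(aliases) == 0) {
        character(0)
      } else {
        setNames(aliases$id, aliases$alt_id)
      }
    ),
    class = "ontology"
  )
  cyc <- find_cycle(obj)
  if (!is.null(cyc)) {
    abort(paste0("is_a graph contains a cycle: ",
                 paste(cyc, collapse = " -> ")))
  }
  obj
}

#' @export
print.ontology <- function(x, ...) {
  ns <- table(x$terms$namespace)
  cat("<ontology> ", nrow(x$terms), " terms, ", nrow(x$edges),
      " is_a edges\n", sep = "")
  cat("  namespaces:",
      paste(names(ns), ns, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Kahn-style peeling; returns one cycle (as a term path) or NULL if acyclic.
find_cycle <- function(graph) {
  ids <- graph$terms$id
  out_deg <- vapply(graph$parents[ids], length, integer(1))
  children <- split(graph$edges$child, factor(graph$edges$parent, levels = ids))
  queue <- ids[out_deg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    t <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[t]]) {
      out_deg[[ch]] <- out_deg[[ch]] - 1L
      if (out_deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk parent links inside the residual set until a repeat gives the cycle
  residual <- ids[out_deg > 0L]
  path <- residual[[1]]
  repeat {
    nxt <- intersect(graph$parents[[path[length(path)]]], residual)[[1]]
    if (nxt %in% path) {
      return(c(path[seq(match(nxt, path), length(path))], nxt))
    }
    path <- c(path, nxt)
  }
}

#' Read an OBO flat file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file. Only the tags `id`,
#' `name`, `namespace`, `is_a`, `alt_id` and `is_obsolete` are interpreted;
#' every other tag is ignored. Obsolete terms are dropped together with
#' their edges. `alt_id` lines are recorded as aliases resolving to the
#' canonical term.
#'
#' @param path Path to an OBO file.
#' @return An [ontology] object.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (length(starts) == 0) abort("no stanzas found in OBO file")
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); names_ <- character(0); ns <- character(0)
  edges_child <- character(0); edges_parent <- character(0)
  alt_from <- character(0); alt_to <- character(0)
  default_ns <- NA_character_
  hdr <- lines[seq_len(starts[1] - 1L)]
  m <- grep("^default-namespace:", hdr, value = TRUE)
  if (length(m) > 0) default_ns <- trimws(sub("^default-namespace:", "", m[1]))
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    body <- lines[seq(starts[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    get1 <- function(tag) {
      hit <- grep(paste0("^", tag, ":"), body, value = TRUE)
      if (length(hit) == 0) return(NA_character_)
      trimws(sub(paste0("^", tag, ":"), "", hit[1]))
    }
    id <- get1("id")
    if (is.na(id) || !nzchar(id)) {
      abort(paste0("malformed [Term] stanza starting at line ", starts[i],
                   ": missing id"))
    }
    obs <- get1("is_obsolete")
    if (!is.na(obs) && grepl("^true", obs)) next
    ids <- c(ids, id)
    names_ <- c(names_, get1("name") %||% NA_character_)
    ns_i <- get1("namespace")
    ns <- c(ns, if (is.na(ns_i)) default_ns else ns_i)
    isa <- grep("^is_a:", body, value = TRUE)
    if (length(isa) > 0) {
      # "is_a: GO:0000001 ! comment"
      par <- trimws(sub("!.*$", "", sub("^is_a:", "", isa)))
      edges_child <- c(edges_child, rep(id, length(par)))
      edges_parent <- c(edges_parent, par)
    }
    alts <- grep("^alt_id:", body, value = TRUE)
    if (length(alts) > 0) {
      a <- trimws(sub("^alt_id:", "", alts))
      alt_from <- c(alt_from, a)
      alt_to <- c(alt_to, rep(id, length(a)))
    }
  }
  keep <- edges_parent %in% ids  # drop edges into obsolete/unknown parents
  ontology(
    terms = tibble::tibble(id = ids, name = names_, namespace = ns),
    edges = tibble::tibble(child = edges_child[keep],
                           parent = edges_parent[keep]),
    aliases = tibble::tibble(alt_id = alt_from, id = alt_to)
  )
}

#' Proper ancestors of a term
#'
#' All terms reachable from `term` by following `is_a` edges transitively,
#' excluding `term` itself.
#'
#' @param graph An [ontology].
#' @param term A term identifier known to the graph.
#' @return Character vector of ancestor term ids (unordered).
#' @export
go_ancestors <- function(graph, term) {
  stopifnot(inherits(graph, "ontology"))
  if (!term %in% graph$terms$id) {
    abort(paste0("unknown term: ", term))
  }
  out <- character(0)
  frontier <- graph$parents[[term]]
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    frontier <- setdiff(
      unique(unlist(graph$parents[frontier], use.names = FALSE)), out)
  }
  unique(out)
}

#' Biological-process ancestor closure of an annotation set
#'
#' Extends a gene's specific term set with all `is_a` ancestors, then
#' restricts the result to the biological_process namespace. Terms unknown
#' to the graph are skipped with a warning (ontology releases drift), after
#' alias resolution. Closing an already-closed set returns it unchanged.
#'
#' @param graph An [ontology].
#' @param specific_terms Character vector of term ids (a gene's specific
#'   annotations).
#' @return Character vector of biological_process term ids, sorted.
#' @export
close_annotation <- function(graph, specific_terms) {
  stopifnot(inherits(graph, "ontology"))
  specific_terms <- unique(as.character(specific_terms))
  if (length(specific_terms) == 0) return(character(0))
  hit_alias <- specific_terms %in% names(graph$aliases)
  specific_terms[hit_alias] <- graph$aliases[specific_terms[hit_alias]]
  known <- specific_terms %in% graph$terms$id
  if (any(!known)) {
    warn(paste0("skipping ", sum(!known), " term(s) unknown to the ontology: ",
                paste(head(specific_terms[!known], 5), collapse = ", ")))
  }
  terms <- unique(specific_terms[known])
  closed <- terms
  frontier <- terms
  while (length(frontier) > 0) {
    frontier <- setdiff(
      unique(unlist(graph$parents[frontier], use.names = FALSE)), closed)
    closed <- c(closed, frontier)
  }
  sort(closed[graph$namespace[closed] == "biological_process"])
}

#' Write an ontology to an OBO flat file
#'
#' Emits a minimal OBO 1.2 document (`id`, `name`, `namespace`, `is_a`)
#' readable by [read_obo()]. Terms are written in their stored order.
#'
#' @param graph An [ontology].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    writeLines(c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", graph$terms$name[i]),
      paste0("namespace: ", graph$terms$namespace[i]),
      if (length(graph$parents[[id]]) > 0)
        paste0("is_a: ", sort(graph$parents[[id]])),
      ""
    ), con)
  }
  invisible(path)
}
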