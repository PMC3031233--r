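#' Read the per-gene table
#'
#' Tab-separated file with columns `gene`, `class`, `pathway`, `ka_ki`.
#' `class` must be `ageing` or `non_ageing`; `ka_ki` may be empty or `?`
#' for genes without an evolutionary-rate measurement (human-chimp
#' orthologue Ka/Ki ratio).
#'
#' @param path Path to a TSV file with a header row.
#' @return Tibble with columns `gene` (chr), `class` (factor), `pathway`
#'   (chr), `ka_ki` (dbl, NA allowed).
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "?"))
  stopifnot(all(c("gene", "class", "pathway", "ka_ki") %in% names(df)))
  if (anyDuplicated(df$gene)) abort("duplicate gene symbols in gene table")
  tibble::tibble(
    gene = as.character(df$gene),
    class = as_class_factor(df$class),
    pathway = as.character(df$pathway),
    ka_ki = as.numeric(df$ka_ki)
  )
}

#' Read gene-to-GO annotations
#'
#' Two layouts are accepted.  A plain TSV with header columns `gene` and
#' `go_id` (one pair per row), or, with `format = "gaf"`, a GAF 2.x file
#' from which column 3 (gene symbol), column 5 (GO id) and column 9
#' (aspect) are taken; only rows whose aspect is `P` (biological process)
#' or whose aspect is missing are kept, since the pipeline annotates genes
#' with specific terms before namespace filtering happens at closure time.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` (default) or `"gaf"`.
#' @return Tibble with columns `gene`, `go_id`, one row per annotation.
#' @export
read_annotation_table <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "go_id") %in% names(df)))
    out <- tibble::tibble(gene = as.character(df$gene),
                          go_id = as.character(df$go_id))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    parts <- parts[lengths(parts) >= 9]
    out <- tibble::tibble(
      gene = vapply(parts, `[[`, character(1), 3),
      go_id = vapply(parts, `[[`, character(1), 5),
      aspect = vapply(parts, `[[`, character(1), 9)
    )
    out <- dplyr::filter(out, .data$aspect %in% c("P", ""))
    out$aspect <- NULL
  }
  dplyr::distinct(out)
}

#' Read a protein-protein interaction edge list
#'
#' Tab-separated file with header columns `protein_a`, `protein_b`,
#' `evidence`; `evidence` is a comma-separated list of evidence tags
#' (e.g. `in_vivo`, `in_vitro`, `yeast_two_hybrid`, `high_throughput`).
#' The same column subset can be produced from PSI-MI TAB by mapping
#' interactor aliases to columns 1-2 and interaction-detection terms to
#' the evidence tags.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `protein_a`, `protein_b` (chr) and
#'   `evidence` (list of character vectors).
#' @export
read_ppi_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_a", "protein_b", "evidence") %in% names(df)))
  if (any(!nzchar(df$protein_a)) || any(!nzchar(df$protein_b))) {
    abort("empty protein symbol in PPI table")
  }
  tibble::tibble(
    protein_a = as.character(df$protein_a),
    protein_b = as.character(df$protein_b),
    evidence = lapply(strsplit(as.character(df$evidence), ","), trimws)
  )
}

#' Read a probe-level expression table
#'
#' Tab-separated file with header columns `gene`, `probe`,
#' `anatomy_category`, `value`; one row per probe per anatomy category.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene`, `probe`, `anatomy_category` (chr)
#'   and `value` (dbl, non-negative).
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "probe", "anatomy_category", "value") %in% names(df)))
  out <- tibble::tibble(
    gene = as.character(df$gene),
    probe = as.character(df$probe),
    anatomy_category = as.character(df$anatomy_category),
    value = as.numeric(df$value)
  )
  if (any(out$value < 0, na.rm = TRUE)) {
    abort("negative expression values in probe table")
  }
  out
}
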