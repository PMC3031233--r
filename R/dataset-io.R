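#' Describe the attributes of a classification dataset
#'
#' A dataset is a plain tibble with a `gene` identifier column, a `class`
#' column (`ageing` / `non_ageing`) and one column per predictor attribute.
#' Attribute kinds are derived from column content: numeric columns are
#' `numeric`; character/factor columns whose non-missing values lie in
#' `{yes, no}` are `binary` (domain fixed to `no`, `yes` regardless of
#' which values were observed); all other character columns are `nominal`
#' with the observed value vocabulary as domain.
#'
#' @param data A dataset tibble.
#' @return Tibble with columns `name`, `kind`, `domain` (list column;
#'   `NULL` for numeric attributes).
#' @export
attribute_info <- function(data) {
  attrs <- setdiff(names(data), c("gene", "class"))
  rows <- lapply(attrs, function(a) {
    x <- data[[a]]
    if (is.numeric(x)) {
      tibble::tibble(name = a, kind = "numeric", domain = list(NULL))
    } else {
      vals <- sort(unique(as.character(x[!is.na(x)])))
      if (all(vals %in% c("yes", "no"))) {
        tibble::tibble(name = a, kind = "binary", domain = list(c("no", "yes")))
      } else {
        tibble::tibble(name = a, kind = "nominal", domain = list(vals))
      }
    }
  })
  dplyr::bind_rows(rows)
}

check_dataset <- function(data, require_both_classes = TRUE) {
  if (!all(c("gene", "class") %in% names(data))) {
    abort("a dataset needs `gene` and `class` columns")
  }
  if (nrow(data) == 0) abort("empty dataset")
  cls <- as_class_factor(data$class)
  if (require_both_classes && dplyr::n_distinct(cls) < 2) {
    abort("both classes (ageing, non_ageing) must be present")
  }
  invisible(data)
}

fmt_cell <- function(x) {
  # %.17g round-trips doubles exactly; integers print without exponent
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "?" else sprintf("%.17g", v)
    }, character(1))
  } else {
    out <- as.character(x)
    out[is.na(out)] <- "?"
  }
  out
}

#' Write a dataset to CSV
#'
#' Header row; missing values written as `?`. Numeric cells use a
#' formatting that round-trips doubles exactly, so
#' `read_dataset_csv(write_dataset_csv(x, f))` restores identical values.
#'
#' @param data A dataset tibble (see [attribute_info()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  cols <- lapply(data, fmt_cell)
  m <- do.call(cbind, cols)
  lines <- c(paste(names(data), collapse = ","),
             apply(m, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dataset written by [write_dataset_csv()]
#'
#' `?` cells become missing. A column is restored as numeric when every
#' non-missing cell parses as a number; otherwise it stays character.
#' The `class` column is restored as a factor with levels
#' `non_ageing`, `ageing`.
#'
#' @param path Path to the CSV file.
#' @return A dataset tibble.
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "?",
                        colClasses = "character", check.names = FALSE)
  out <- tibble::as_tibble(df)
  for (nm in names(out)) {
    if (nm %in% c("gene", "class")) next
    x <- out[[nm]]
    num <- suppressWarnings(as.numeric(x))
    if (all(is.na(num) == is.na(x))) out[[nm]] <- num
  }
  if ("class" %in% names(out)) out$class <- as_class_factor(out$class)
  out
}

#' Write a dataset in ARFF format
#'
#' Nominal and binary attributes are declared with their domains, numeric
#' attributes as `numeric`, the gene identifier as a `string` attribute
#' and the class as the last attribute. Missing values are `?`. Provided
#' for interoperability with Java data-mining tools.
#'
#' @param data A dataset tibble.
#' @param path Output path.
#' @param relation Relation name for the `@relation` header.
#' @return `path`, invisibly.
#' @export
write_dataset_arff <- function(data, path, relation = "agemine") {
  check_dataset(data, require_both_classes = FALSE)
  info <- attribute_info(data)
  quote_arff <- function(v) {
    needs <- grepl("[ ,{}%']", v)
    v[needs] <- paste0("'", gsub("'", "\\\\'", v[needs]), "'")
    v
  }
  decls <- c(
    "@attribute gene string",
    purrr::pmap_chr(info, function(name, kind, domain) {
      if (kind == "numeric") {
        paste0("@attribute ", quote_arff(name), " numeric")
      } else {
        paste0("@attribute ", quote_arff(name), " {",
               paste(quote_arff(domain), collapse = ","), "}")
      }
    }),
    paste0("@attribute class {", paste(CLASS_LEVELS, collapse = ","), "}")
  )
  ordered <- data[, c("gene", info$name, "class")]
  cells <- lapply(names(ordered), function(nm) {
    x <- fmt_cell(ordered[[nm]])
    if (!is.numeric(ordered[[nm]])) x[x != "?"] <- quote_arff(x[x != "?"])
    x
  })
  rows <- apply(do.call(cbind, cells), 1, paste, collapse = ",")
  writeLines(c(paste0("@relation ", relation), "", decls, "", "@data", rows),
             path)
  invisible(path)
}
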