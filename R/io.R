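#' Read an expression matrix from TSV or GCT 1.2
#'
#' TSV: a header row of sample ids with the first column holding gene ids.
#' GCT 1.2: a `#1.2` version line, a `rows<TAB>columns` dimension line, then a
#' header with `Name` and `Description` columns before the sample columns.
#' Missing values are `NA` or empty cells. Duplicate gene ids and non-numeric
#' cells are hard errors naming the offenders (with row/column coordinates for
#' cells), so malformed compendia fail loudly rather than propagate.
#'
#' @param path file path.
#' @param format `"auto"` (GCT sniffed from the `#1.2` first line or `.gct`
#'   extension), `"tsv"`, or `"gct"`.
#' @return Numeric genes x samples matrix with gene-id rownames and a
#'   `provenance` attribute recording the source path.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) validation_error("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (format == "auto") {
    format <- if (startsWith(first, "#1.2") || grepl("\\.gct$", path, ignore.case = TRUE)) {
      "gct"
    } else {
      "tsv"
    }
  }
  if (format == "gct") {
    lines <- readLines(path)
    if (!startsWith(lines[1L], "#1.2")) validation_error("%s: missing GCT 1.2 version line", path)
    dims <- as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][1:2])
    body <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                              colClasses = "character", na.strings = c("NA", ""))
    if (!all(c("Name", "Description") %in% names(body)[1:2])) {
      validation_error("%s: GCT header must start with Name and Description", path)
    }
    if (nrow(body) != dims[1L] || ncol(body) - 2L != dims[2L]) {
      validation_error("%s: declared dimensions %d x %d do not match data %d x %d",
                       path, dims[1L], dims[2L], nrow(body), ncol(body) - 2L)
    }
    ids <- body$Name
    raw <- body[, -(1:2), drop = FALSE]
  } else {
    body <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                              na.strings = c("NA", ""))
    if (ncol(body) < 2L) validation_error("%s: expected gene-id column plus sample columns", path)
    ids <- body[[1L]]
    raw <- body[, -1L, drop = FALSE]
  }
  if (anyDuplicated(ids)) {
    validation_error("%s: duplicate gene identifiers: %s", path,
                     paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = list(ids, names(raw)))
  for (j in seq_len(ncol(raw))) {
    cell <- raw[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell))
    if (length(bad) > 0L) {
      validation_error("%s: non-numeric value '%s' at gene '%s', sample '%s'",
                       path, cell[bad[1L]], ids[bad[1L]], names(raw)[j])
    }
    m[, j] <- num
  }
  if (nrow(m) == 0L || ncol(m) == 0L) validation_error("%s: empty matrix", path)
  attr(m, "provenance") <- path
  m
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' @param x expression matrix (or data frame with gene-id first column).
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  m <- as_expression_matrix(x)
  df <- as.data.frame(m, check.names = FALSE)
  if (format == "gct") {
    con <- file(path, open = "wt")
    on.exit(close(con), add = TRUE)
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    out <- cbind(Name = rownames(m), Description = rownames(m), df)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  } else {
    out <- cbind(gene_id = rownames(m), df)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read a sample-annotation or pairing table
#'
#' Thin TSV readers with schema validation. Annotations need `sample_id` and
#' `phenotype` (optional `condition_category`, `pair_id`); pairing tables need
#' `pair_id`, `tumor_sample`, `normal_sample`, each pair mapping to exactly
#' one tumor and one normal sample.
#'
#' @param path TSV file path.
#' @param phenotype_column column holding the phenotype labels; renamed to
#'   `phenotype` on read.
#' @param require columns that must be present (checked after the rename).
#' @return A tibble.
#' @export
read_annotations <- function(path, phenotype_column = "phenotype",
                             require = c("sample_id", "phenotype")) {
  if (!file.exists(path)) validation_error("file not found: %s", path)
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (phenotype_column != "phenotype" && phenotype_column %in% names(tb)) {
    tb <- dplyr::rename(tb, phenotype = dplyr::all_of(phenotype_column))
  }
  missing_cols <- setdiff(require, names(tb))
  if (length(missing_cols) > 0L) {
    validation_error("%s: annotations need column(s) %s", path,
                     paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tb$sample_id)) validation_error("%s: duplicate sample_id values", path)
  tb
}

#' @rdname read_annotations
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) validation_error("file not found: %s", path)
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("pair_id", "tumor_sample", "normal_sample")
  if (!all(need %in% names(tb))) {
    validation_error("%s: pairing table needs columns %s", path, paste(need, collapse = ", "))
  }
  if (anyDuplicated(tb$pair_id)) validation_error("%s: duplicate pair_id values", path)
  tb
}

# required columns per known results schema
results_schema <- list(
  scores = c("gene_id", "n_used", "delta_aic", "rank"),
  calls = c("gene_id", "delta_aic", "D", "passed_screen"),
  infogain = c("gene_id", "H_X", "H_X_given_Y", "gain_percent"),
  enrichment = c("gene_id", "mode", "category", "p_value", "adjusted_p")
)

#' Write a results table with a provenance header
#'
#' Serializes a results tibble (scores, switch calls, information gains,
#' enrichments) deterministically: a `#` comment line records the package
#' version, seed and config hash; rows are ordered by rank (when present) then
#' gene id; floats are rendered with 6 significant digits. Two runs with
#' identical inputs and seed produce byte-identical files.
#'
#' @param table results tibble.
#' @param path output path.
#' @param schema one of `"scores"`, `"calls"`, `"infogain"`, `"enrichment"`,
#'   or `NULL` to skip schema validation.
#' @param seed,config seed and configuration recorded in the header.
#' @export
write_results <- function(table, path, schema = NULL, seed = NA, config = list()) {
  if (!is.null(schema)) {
    need <- results_schema[[match.arg(schema, names(results_schema))]]
    missing_cols <- setdiff(need, names(table))
    if (length(missing_cols) > 0L) {
      validation_error("results table missing required column(s): %s",
                       paste(missing_cols, collapse = ", "))
    }
  }
  ord <- if ("rank" %in% names(table)) {
    order(table$rank, table$gene_id)
  } else if ("gene_id" %in% names(table)) {
    order(table$gene_id)
  } else {
    seq_len(nrow(table))
  }
  table <- table[ord, , drop = FALSE]
  table <- dplyr::mutate(table, dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# switchscan %s | seed=%s | config=%s",
                     as.character(utils::packageVersion("switchscan")),
                     as.character(seed), config_hash(config)), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @return `read_results()`: the tibble (header comment skipped).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) validation_error("file not found: %s", path)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
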