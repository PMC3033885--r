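#' Read an expression dataset from delimited text or ARFF
#'
#' Delimited files (CSV/TSV, chosen by extension or `sep`) must carry a header.
#' With `orientation = "samples_as_rows"` each row is a sample, one column
#' (named by `label_field`) holds the class label, and an optional
#' `sample_id`/`id` column holds sample names. With
#' `orientation = "genes_as_rows"` the first column holds gene ids, the header
#' holds sample ids, and the row whose id equals `label_field` holds the class
#' labels. ARFF files (`.arff`) must declare one nominal class attribute named
#' by `label_field`. Decimal points only; no thousands separators.
#'
#' @param path File path.
#' @param orientation `"samples_as_rows"` (default) or `"genes_as_rows"`.
#' @param label_field Name of the label column / label row (default
#'   `"label"`; for ARFF, the nominal class attribute, default `"class"` if
#'   `label_field` is absent).
#' @param sep Field separator; by default `","` for `.csv`, tab otherwise.
#' @return An `expr_dataset`.
#' @export
load_dataset <- function(path, orientation = c("samples_as_rows", "genes_as_rows"),
                         label_field = "label", sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.arff$", path, ignore.case = TRUE)) {
    return(load_arff(path, label_field))
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("file has no data rows: ", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop("ragged row: line ", bad, " has ", widths[bad],
         " fields, expected ", widths[1])
  }
  header <- trimws(cells[[1]])
  body <- lapply(cells[-1], trimws)
  tab <- do.call(rbind, body)

  if (orientation == "samples_as_rows") {
    lab_col <- match(label_field, header)
    if (is.na(lab_col)) stop("label column '", label_field, "' not found in header")
    id_col <- match(c("sample_id", "id"), header)
    id_col <- id_col[!is.na(id_col)][1]
    labels <- tab[, lab_col]
    keep <- setdiff(seq_along(header), c(lab_col, id_col))
    values <- parse_numeric_block(tab[, keep, drop = FALSE], offset_row = 1L)
    expression_dataset(values, labels,
                       sample_ids = if (!is.na(id_col) && length(id_col)) tab[, id_col] else NULL,
                       gene_ids = header[keep])
  } else {
    row_ids <- tab[, 1]
    lab_row <- match(label_field, row_ids)
    if (is.na(lab_row)) stop("label row '", label_field, "' not found in first column")
    labels <- tab[lab_row, -1]
    gene_rows <- setdiff(seq_len(nrow(tab)), lab_row)
    values <- parse_numeric_block(tab[gene_rows, -1, drop = FALSE], offset_row = 1L)
    expression_dataset(t(values), labels,
                       sample_ids = header[-1],
                       gene_ids = row_ids[gene_rows])
  }
}

parse_numeric_block <- function(chr_mat, offset_row = 0L) {
  suppressWarnings(num <- matrix(as.numeric(chr_mat), nrow = nrow(chr_mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", chr_mat[bad[1], bad[2]], "' at data row ",
         bad[1] + offset_row - 1L, ", column ", bad[2])
  }
  num
}

load_arff <- function(path, label_field = "class") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*%", lines)]
  attr_lines <- grep("^\\s*@attribute", lines, ignore.case = TRUE, value = TRUE)
  data_at <- grep("^\\s*@data", lines, ignore.case = TRUE)
  if (!length(attr_lines) || !length(data_at)) stop("not a valid ARFF file: ", path)
  attr_names <- sub("^\\s*@attribute\\s+('?)([^'\\s]+)\\1.*$", "\\2",
                    attr_lines, ignore.case = TRUE)
  nominal <- grepl("\\{", attr_lines)
  lab_idx <- match(label_field, attr_names)
  if (is.na(lab_idx)) lab_idx <- match("class", attr_names)
  if (is.na(lab_idx)) lab_idx <- which(nominal)[sum(nominal)]  # last nominal
  if (!length(lab_idx) || is.na(lab_idx)) stop("no nominal class attribute found in ", path)
  rows <- lines[(data_at[1] + 1):length(lines)]
  cells <- strsplit(rows, ",", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != length(attr_names))) {
    bad <- which(widths != length(attr_names))[1]
    stop("ragged row: ARFF data line ", bad, " has ", widths[bad],
         " fields, expected ", length(attr_names))
  }
  tab <- do.call(rbind, lapply(cells, trimws))
  labels <- gsub("^'|'$", "", tab[, lab_idx])
  keep <- setdiff(seq_along(attr_names), which(nominal))
  values <- parse_numeric_block(tab[, keep, drop = FALSE], offset_row = 1L)
  expression_dataset(values, labels, gene_ids = attr_names[keep])
}

#' Write an expression dataset as delimited text
#'
#' Emits the same dialect that [load_dataset()] reads, so write/reload
#' round-trips values to full precision and labels exactly.
#'
#' @param data An `expr_dataset`.
#' @param path Output path (`.csv` writes commas, otherwise tabs).
#' @param orientation Row layout, as in [load_dataset()].
#' @param label_field Label column/row name.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, orientation = c("samples_as_rows", "genes_as_rows"),
                          label_field = "label") {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  if (orientation == "samples_as_rows") {
    header <- c("sample_id", data$gene_ids, label_field)
    rows <- vapply(seq_len(n_samples(data)), function(i) {
      paste(c(data$sample_ids[i], fmt(data$values[i, ]), data$labels[i]),
            collapse = sep)
    }, character(1))
    writeLines(c(paste(header, collapse = sep), rows), path)
  } else {
    header <- c("id", data$sample_ids)
    rows <- vapply(seq_len(n_genes(data)), function(j) {
      paste(c(data$gene_ids[j], fmt(data$values[, j])), collapse = sep)
    }, character(1))
    lab <- paste(c(label_field, data$labels), collapse = sep)
    writeLines(c(paste(header, collapse = sep), rows, lab), path)
  }
  invisible(path)
}
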