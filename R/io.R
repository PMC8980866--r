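# Readers/writers for the tab-separated formats every module consumes.
# All tables are TSV, UTF-8, "." decimal point; order preserved exactly.

#' Load an expression table from TSV
#'
#' @param path delimited text file: header row of sample IDs, first column
#'   feature IDs, numeric cells.
#' @param sample_sheet data.frame with columns `sample_id`, `stage`,
#'   `replicate` covering every sample in the header.
#' @param kind value kind flag, see [expression_matrix()].
#' @return an `expression_matrix`.
#' @export
load_expression_table <- function(path, sample_sheet,
                                  kind = c("counts", "fpkm", "protein_intensity")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("no features in ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature ID in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  num <- df[, -1, drop = FALSE]
  vals <- matrix(NA_real_, nrow(num), ncol(num),
                 dimnames = list(ids, colnames(num)))
  for (j in seq_len(ncol(num))) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s at row %d (feature %s), column %s",
                   path, bad[1], ids[bad[1]], colnames(num)[j]))
    vals[, j] <- v
  }
  expression_matrix(vals, sample_sheet, kind)
}

#' Write an expression matrix to TSV
#' @param x an `expression_matrix`.
#' @param path output file.
#' @param id_column name for the first (feature ID) column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, id_column = "feature_id") {
  df <- data.frame(feature_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a sample sheet TSV (columns sample_id, stage, replicate)
#' @param path TSV file.
#' @return data.frame with character `sample_id`/`stage` and integer
#'   `replicate`.
#' @export
load_sample_sheet <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("sample_id", "stage", "replicate")
  if (!all(req %in% names(df)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$stage <- as.character(df$stage)
  df$replicate <- as.integer(df$replicate)
  df
}

#' Write a sample sheet TSV
#' @param meta data.frame with `sample_id`, `stage`, `replicate`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(meta, path) {
  utils::write.table(meta[, c("sample_id", "stage", "replicate")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file.
#' @return a `gene_set_collection`.
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT set with zero members at line ", bad[1], " of ", path)
  nms <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  gene_set_collection(sets, stats::setNames(desc, nms))
}

#' Write gene sets to a GMT file
#' @param gsc a `gene_set_collection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Load a gene length table from TSV (columns feature_id, length)
#' @param path TSV file with two columns; header required.
#' @return a `gene_length_table`.
#' @export
load_gene_lengths <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  gene_length_table(as.character(df[[1]]), df[[2]])
}

#' Write a gene length table to TSV
#' @param lengths a `gene_length_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_lengths <- function(lengths, path) {
  utils::write.table(
    data.frame(feature_id = names(lengths), length = as.numeric(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a gene-protein ID map from a 2-column TSV
#'
#' @param path TSV with columns gene_id, protein_id.
#' @param header does the file carry a header row? Default `TRUE`.
#' @param collapse policy for 1:many violations, see [id_map()].
#' @return an `id_map`. An empty file (header only, or zero bytes with
#'   `header = FALSE`) yields an empty map.
#' @export
load_id_map <- function(path, header = TRUE, collapse = c("error", "first", "drop")) {
  collapse <- match.arg(collapse)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = header,
                      colClasses = "character"),
    error = function(e) data.frame(gene_id = character(), protein_id = character()))
  if (ncol(df) < 2L && nrow(df) > 0L) stop("ID map needs two columns: ", path)
  if (nrow(df) == 0L) return(id_map(character(), character()))
  id_map(df[[1]], df[[2]], collapse = collapse)
}

#' Write an ID map to TSV
#' @param map an `id_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_id_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
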