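#' Expression matrix with sample metadata
#'
#' The central container of the package: a features x samples numeric matrix
#' plus per-sample stage/replicate metadata and a `kind` flag saying whether
#' the values are raw counts, FPKM, or (TMT-style relative) protein
#' intensities. Feature and sample order is preserved exactly as given and is
#' never sorted silently.
#'
#' @param values numeric matrix (features x samples) with rownames = feature
#'   IDs and colnames = sample IDs; all values finite and >= 0.
#' @param sample_meta data.frame with columns `sample_id`, `stage`,
#'   `replicate`, one row per sample, covering every column of `values`.
#' @param kind one of `"counts"`, `"fpkm"`, `"protein_intensity"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `sample_meta` (rows ordered as the columns of `values`),
#'   `kind`, and `stages` (ordered unique stage levels).
#' @examples
#' v <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    stage = rep(c("A", "B"), each = 2), replicate = c(1, 2, 1, 2))
#' em <- expression_matrix(v, meta, "counts")
#' dim(em)
#' @export
expression_matrix <- function(values, sample_meta, kind = c("counts", "fpkm", "protein_intensity")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature rownames and sample colnames")
  if (nrow(values) == 0L) stop("no features")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ID: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ID: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("values must be non-negative")
  req <- c("sample_id", "stage", "replicate")
  if (!all(req %in% names(sample_meta)))
    stop("sample_meta needs columns: ", paste(req, collapse = ", "))
  missing_meta <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(missing_meta))
    stop("sample(s) missing from sample sheet: ", paste(missing_meta, collapse = ", "))
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), req, drop = FALSE]
  rownames(sample_meta) <- NULL
  sample_meta$stage <- as.character(sample_meta$stage)
  stages <- unique(sample_meta$stage)
  structure(
    list(values = values, sample_meta = sample_meta, kind = kind, stages = stages),
    class = "expression_matrix"
  )
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d features x %d samples, stages: %s\n",
              x$kind, nrow(x$values), ncol(x$values),
              paste(x$stages, collapse = ", ")))
  invisible(x)
}

#' Feature IDs of an expression matrix
#' @param x an `expression_matrix`.
#' @return character vector of feature IDs, in matrix order.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Sample IDs of an expression matrix
#' @param x an `expression_matrix`.
#' @return character vector of sample IDs, in matrix order.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by features and/or samples
#' @param x an `expression_matrix`.
#' @param features character vector of feature IDs to keep (default all).
#' @param samples character vector of sample IDs to keep (default all).
#' @return an `expression_matrix` restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(v))
    if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, x$sample_meta[x$sample_meta$sample_id %in% colnames(v), ], x$kind)
}

#' Per-stage replicate-mean matrix
#'
#' Averages replicate columns within each stage. Used throughout the package
#' wherever the analysis operates on stage profiles rather than individual
#' replicates (temporal clustering, mRNA-protein correlation).
#'
#' @param x an `expression_matrix`.
#' @param log2p1 if `TRUE`, apply `log2(value + 1)` before averaging.
#' @return numeric matrix, features x stages, stage columns in `x$stages`
#'   order.
#' @export
stage_means <- function(x, log2p1 = FALSE) {
  v <- x$values
  if (log2p1) v <- log2(v + 1)
  out <- vapply(x$stages, function(s) {
    cols <- x$sample_meta$stage == s
    rowMeans(v[, cols, drop = FALSE])
  }, numeric(nrow(v)))
  dimnames(out) <- list(rownames(v), x$stages)
  out
}

#' Compute FPKM from a count matrix
#'
#' FPKM (fragments per kilobase of exon per million mapped fragments) is
#' computed per cell as `count * 1e9 / (length * N_j)` where `N_j` is the
#' total count of sample `j`. The per-sample total is the within-matrix column
#' sum: the aligner's mapped-fragment total is not available at the matrix
#' level, and the column-sum convention keeps the computation self-contained
#' (see the methods vignette).
#'
#' @param counts an `expression_matrix` of kind `"counts"`.
#' @param lengths a `gene_length_table` (see [gene_length_table()]) covering
#'   every feature of `counts`.
#' @return an `expression_matrix` of kind `"fpkm"` with the same dimensions.
#' @export
compute_fpkm <- function(counts, lengths) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$kind != "counts") stop("compute_fpkm expects a counts matrix")
  len <- lengths[feature_ids(counts)]
  if (anyNA(len))
    stop("gene length missing for: ",
         paste(utils::head(feature_ids(counts)[is.na(len)], 5), collapse = ", "))
  n_j <- colSums(counts$values)
  if (any(n_j == 0))
    stop("sample(s) with zero total count (no mapped fragments): ",
         paste(colnames(counts$values)[n_j == 0], collapse = ", "))
  fpkm <- sweep(counts$values / len, 2, n_j, "/") * 1e9
  expression_matrix(fpkm, counts$sample_meta, "fpkm")
}

#' Expressed-gene filter on FPKM
#'
#' A gene is called expressed when its FPKM exceeds `threshold` (strictly) in
#' at least one sample. The default 0.3 is the conventional low-expression
#' cutoff for ripening-flesh RNA-seq; the any-sample rule (rather than
#' all-samples) keeps stage-specific genes.
#'
#' @param fpkm an `expression_matrix` of kind `"fpkm"`.
#' @param threshold strict FPKM cutoff (default 0.3).
#' @return character vector of expressed feature IDs, in matrix order.
#' @export
filter_expressed <- function(fpkm, threshold = 0.3) {
  stopifnot(inherits(fpkm, "expression_matrix"))
  if (fpkm$kind != "fpkm") stop("filter_expressed expects an FPKM matrix")
  keep <- apply(fpkm$values, 1, max) > threshold
  feature_ids(fpkm)[keep]
}

#' Gene length table
#'
#' @param feature_id character vector of feature IDs (unique).
#' @param length_bp positive integer lengths in base pairs.
#' @return named numeric vector of class `gene_length_table`.
#' @export
gene_length_table <- function(feature_id, length_bp) {
  if (anyDuplicated(feature_id))
    stop("duplicate feature ID in gene length table")
  length_bp <- as.numeric(length_bp)
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stop("gene lengths must be positive")
  structure(stats::setNames(length_bp, feature_id), class = "gene_length_table")
}

#' @export
`[.gene_length_table` <- function(x, i) unclass(x)[i]

#' Gene-to-protein identifier map
#'
#' Stores ordered (gene_id, protein_id) pairs, resolvable in both directions.
#' Maps are 1:1 by default; 1:many rows are rejected unless a collapse policy
#' is supplied (`"first"` keeps the first pair seen, `"drop"` removes every
#' ambiguous ID).
#'
#' @param gene_id,protein_id character vectors of equal length.
#' @param collapse `"error"` (default), `"first"`, or `"drop"`.
#' @return data.frame of class `id_map` with columns `gene_id`, `protein_id`.
#' @export
id_map <- function(gene_id, protein_id, collapse = c("error", "first", "drop")) {
  collapse <- match.arg(collapse)
  df <- data.frame(gene_id = as.character(gene_id),
                   protein_id = as.character(protein_id),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  dup_g <- unique(df$gene_id[duplicated(df$gene_id)])
  dup_p <- unique(df$protein_id[duplicated(df$protein_id)])
  offenders <- c(dup_g, dup_p)
  if (length(offenders)) {
    if (collapse == "error")
      stop("ID map is not 1:1; offending IDs: ", paste(offenders, collapse = ", "),
           " (pass collapse = \"first\" or \"drop\")")
    if (collapse == "first")
      df <- df[!duplicated(df$gene_id) & !duplicated(df$protein_id), , drop = FALSE]
    if (collapse == "drop")
      df <- df[!(df$gene_id %in% dup_g) & !(df$protein_id %in% dup_p), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("id_map", "data.frame")
  df
}

#' Look up the protein for a gene (or vice versa)
#' @param map an `id_map`.
#' @param ids character vector of IDs to resolve.
#' @param from `"gene"` or `"protein"`: the namespace of `ids`.
#' @return character vector of mapped IDs (`NA` where unmapped).
#' @export
map_ids <- function(map, ids, from = c("gene", "protein")) {
  from <- match.arg(from)
  if (from == "gene") map$protein_id[match(ids, map$gene_id)]
  else map$gene_id[match(ids, map$protein_id)]
}

#' Gene set collection
#'
#' @param sets named list of character vectors (member feature IDs);
#'   duplicate members within a set are removed with a warning.
#' @param descriptions optional named character vector of set descriptions.
#' @return list of class `gene_set_collection` with elements `sets` and
#'   `descriptions`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0L)) stop("gene set with zero members")
  sets <- lapply(stats::setNames(names(sets), names(sets)), function(nm) {
    m <- sets[[nm]]
    if (anyDuplicated(m)) {
      warning("duplicate members in set ", nm, " deduplicated")
      m <- unique(m)
    }
    as.character(m)
  })
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}
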