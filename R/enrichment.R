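# Over-representation analysis: two-tailed Fisher exact test of DE features
# against annotation categories, BH correction, and the enrichment-matrix
# z-score clustering used for category heatmaps.

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(i) = min_{j >= i} min(1, p_(j) * m / j)` over the sorted p-values,
#' returned in the input order. This is the single shared BH implementation
#' used by every module.
#'
#' @param p numeric vector of p-values between 0 and 1 (NA not allowed).
#' @return numeric vector of adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  padj_sorted <- pmin(1, p[o] * m / seq_len(m))
  padj_sorted <- rev(cummin(rev(padj_sorted)))
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

# Two-tailed hypergeometric p by the minimum-likelihood rule: sum of
# probabilities of all tables with the same margins whose point probability
# does not exceed the observed one (with a small relative tolerance against
# floating-point ties, the convention of standard exact-test code).
hyper_two_tailed <- function(k, K, n, N) {
  support <- max(0L, n - (N - K)):min(n, K)
  d <- stats::dhyper(support, K, N - K, n)
  obs <- stats::dhyper(k, K, N - K, n)
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Two-tailed Fisher over-representation test
#'
#' For each category, the 2x2 table is (k = DE in category, n - k = DE not in
#' category, K - k, N - n - K + k) over a background of N tested features.
#' The two-tailed p sums hypergeometric point probabilities no larger than
#' the observed table's (minimum-likelihood rule). The odds ratio is the
#' sample odds ratio with a 0.5 continuity correction when any cell is zero;
#' the `enriched` flag additionally requires OR > 1 so depletion is never
#' reported as enrichment.
#'
#' @param de_set character vector of DE feature IDs (must be a subset of
#'   `background`; violations are dropped with a warning).
#' @param background character vector: the tested universe.
#' @param categories a `gene_set_collection`; members are intersected with
#'   `background` before testing, and categories with zero overlap are
#'   skipped with a warning.
#' @param alpha adjusted-p cutoff for the `enriched` flag (default 0.05).
#' @return data.frame of class `enrichment_table`: columns `category`, `k`,
#'   `n`, `K`, `N`, `odds_ratio`, `p`, `padj`, `enriched`.
#' @export
fisher_enrichment_test <- function(de_set, background, categories, alpha = 0.05) {
  de_set <- unique(de_set)
  background <- unique(background)
  if (length(de_set) == 0L) stop("empty DE set")
  outside <- setdiff(de_set, background)
  if (length(outside)) {
    warning(length(outside), " DE feature(s) outside the background dropped")
    de_set <- intersect(de_set, background)
    if (length(de_set) == 0L) stop("empty DE set after background restriction")
  }
  N <- length(background); n <- length(de_set)
  rows <- lapply(names(categories$sets), function(nm) {
    members <- intersect(categories$sets[[nm]], background)
    K <- length(members)
    if (K == 0L) {
      warning("category ", nm, " has zero background overlap; skipped")
      return(NULL)
    }
    k <- length(intersect(de_set, members))
    a <- k; b <- n - k; cc <- K - k; d <- N - n - K + k
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    data.frame(category = nm, k = k, n = n, K = K, N = N,
               odds_ratio = (a * d) / (b * cc),
               p = hyper_two_tailed(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows)) stop("no testable category")
  rows$padj <- bh_adjust(rows$p)
  rows$enriched <- rows$padj < alpha & rows$odds_ratio > 1
  rownames(rows) <- NULL
  class(rows) <- c("enrichment_table", "data.frame")
  rows
}

#' Enrichment-matrix clustering across groups
#'
#' Collates per-group enrichment tables into a categories x groups p-value
#' matrix, keeps only categories with raw p < `p_filter` in at least one
#' group, imputes p = 1 where a category was untested in a group, transforms
#' to `x = -log10(p)`, z-scores each category row (rows with zero variance
#' become all-zero), and orders rows by average-linkage (UPGMA) hierarchical
#' clustering on Euclidean distance.
#'
#' @param tables named list of `enrichment_table` objects, one per group.
#' @param p_filter raw-p retention threshold (default 0.05).
#' @return list of class `enrichment_matrix` with elements `p` (retained
#'   categories x groups), `x` (-log10 p), `z` (row z-scores), `row_order`
#'   (dendrogram leaf order, integer indices into the rows), and `hclust`
#'   (the `stats::hclust` tree, `NULL` when fewer than 3 rows). Empty (no
#'   category retained) yields zero-row matrices with a warning.
#' @export
enrichment_heatmap_cluster <- function(tables, p_filter = 0.05) {
  if (length(tables) < 2L) stop("need >= 2 groups")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list (group names)")
  cats <- unique(unlist(lapply(tables, function(t) t$category)))
  p <- matrix(1, length(cats), length(tables),
              dimnames = list(cats, names(tables)))
  for (g in names(tables)) {
    t <- tables[[g]]
    p[t$category, g] <- t$p
  }
  keep <- apply(p, 1, min) < p_filter
  if (!any(keep)) {
    warning("no category passes the p < ", p_filter, " filter")
    empty <- p[0, , drop = FALSE]
    return(structure(list(p = empty, x = empty, z = empty,
                          row_order = integer(0), hclust = NULL),
                     class = "enrichment_matrix"))
  }
  p <- p[keep, , drop = FALSE]
  x <- -log10(p)
  z <- t(apply(x, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(x)
  if (nrow(z) >= 3L) {
    hc <- stats::hclust(stats::dist(z), method = "average")
    ord <- hc$order
  } else {
    hc <- NULL
    ord <- seq_len(nrow(z))
  }
  structure(list(p = p, x = x, z = z, row_order = ord, hclust = hc),
            class = "enrichment_matrix")
}

#' Write an enrichment table to TSV
#' @param table an `enrichment_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an enrichment matrix (z-scores, in dendrogram leaf order) to TSV
#' @param em an `enrichment_matrix`.
#' @param path output TSV of z-scores; a companion `<path>.order` file lists
#'   the leaf order (category names, one per line).
#' @return `path`, invisibly.
#' @export
write_enrichment_matrix <- function(em, path) {
  z <- em$z[em$row_order, , drop = FALSE]
  df <- data.frame(category = rownames(z), z, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(rownames(z), paste0(path, ".order"))
  invisible(path)
}
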