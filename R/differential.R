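# Per-contrast differential expression (genes) and differential abundance
# (proteins). Counts are normalized by median-of-ratios size factors; the
# test engine is a two-sided Welch t on log2-transformed replicate values.
# Thresholds follow the study design this package reimplements: genes are
# gated on BH-adjusted p (padj < 0.05, |log2FC| > 1), proteins on raw p
# (p < 0.05, FC > 1.3 or < 1/1.3) — the gene/protein asymmetry is deliberate.

#' Median-of-ratios size factors
#'
#' DESeq-style estimator: a pseudo-reference is the per-gene geometric mean
#' across samples over genes with no zero count; each sample's factor is its
#' median ratio to the reference. The factor vector is then rescaled by its
#' own geometric mean so that `prod(s)^(1/n) == 1` exactly (this preserves
#' all between-sample ratios and pins the overall scale).
#'
#' @param counts an `expression_matrix` of kind `"counts"`.
#' @return named numeric vector of class `size_factors`, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(inherits(counts, "expression_matrix"))
  v <- counts$values
  usable <- rowSums(v == 0) == 0L
  if (!any(usable))
    stop("no gene with non-zero counts in all samples; consider a ",
         "pseudo-reference fallback (add a pseudo-count upstream)")
  vu <- v[usable, , drop = FALSE]
  ref <- exp(rowMeans(log(vu)))             # per-gene geometric mean
  s <- apply(vu / ref, 2, stats::median)    # median on the ratio scale
  s <- s / exp(mean(log(s)))                # unit geometric mean
  structure(s, class = "size_factors")
}

#' Divide each sample by its size factor
#' @param counts an `expression_matrix`.
#' @param s a `size_factors` vector covering all samples of `counts`.
#' @return an `expression_matrix` of the same kind with normalized values.
#' @export
normalize_counts <- function(counts, s) {
  missing <- setdiff(sample_ids(counts), names(s))
  if (length(missing))
    stop("size factor missing for sample(s): ", paste(missing, collapse = ", "))
  out <- counts
  out$values <- sweep(counts$values, 2, unclass(s)[sample_ids(counts)], "/")
  out
}

# Vectorized two-sided Welch t-test over matrix rows (a, b: replicate
# columns of the two groups). Zero-variance-in-both with equal means -> p 1.
row_welch_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate & ma == mb] <- 1
  p[degenerate & ma != mb] <- 0
  list(p = p, mean_a = ma, mean_b = mb, degenerate = degenerate)
}

new_contrast_result <- function(df, contrast, omics) {
  structure(df, class = c("contrast_result", "data.frame"),
            contrast = contrast, omics = omics)
}

#' Differential expression between two stages (genes)
#'
#' Replicate columns of the two stages are compared by a two-sided Welch t
#' on `log2(normalized count + 1)`. `log2FC = log2((mean_B + 1)/(mean_A + 1))`
#' on the normalized scale (pseudo-count 1 keeps fold changes finite at zero
#' counts). p-values are BH-adjusted across all tested genes, and status is
#' `up` iff `padj < alpha` and `log2FC > lfc_min`, `down` iff `padj < alpha`
#' and `log2FC < -lfc_min` (strict inequalities).
#'
#' @param norm an `expression_matrix` of normalized counts.
#' @param stage_a,stage_b stage labels; the contrast is B vs A.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_min strict |log2FC| cutoff (default 1).
#' @return a `contrast_result` data.frame with columns `feature_id`,
#'   `mean_A`, `mean_B`, `log2FC`, `p`, `padj`, `status`.
#' @export
test_differential_expression <- function(norm, stage_a, stage_b,
                                         alpha = 0.05, lfc_min = 1.0) {
  stopifnot(inherits(norm, "expression_matrix"))
  ca <- norm$sample_meta$stage == stage_a
  cb <- norm$sample_meta$stage == stage_b
  if (sum(ca) < 2L || sum(cb) < 2L)
    stop("each group needs >= 2 replicates (", stage_a, ": ", sum(ca),
         ", ", stage_b, ": ", sum(cb), ")")
  a <- norm$values[, ca, drop = FALSE]
  b <- norm$values[, cb, drop = FALSE]
  w <- row_welch_t(log2(a + 1), log2(b + 1))
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  lfc <- log2((mean_b + 1) / (mean_a + 1))
  padj <- bh_adjust(w$p)
  status <- rep("unchanged", nrow(a))
  status[padj < alpha & lfc > lfc_min] <- "up"
  status[padj < alpha & lfc < -lfc_min] <- "down"
  new_contrast_result(
    data.frame(feature_id = feature_ids(norm), mean_A = mean_a, mean_B = mean_b,
               log2FC = lfc, p = w$p, padj = padj, status = status,
               stringsAsFactors = FALSE, row.names = NULL),
    contrast = paste0(stage_b, "vs", stage_a), omics = "rna")
}

#' Differential abundance between two stages (proteins)
#'
#' Fold change is `mean_B / mean_A` on the intensity scale; p is a two-sided
#' Welch t on log2 intensities. Status is gated on the raw p-value:
#' `up` iff `p < alpha` and `FC > fc_min`, `down` iff `p < alpha` and
#' `FC < 1/fc_min` (strict). BH-adjusted p-values are reported but do not
#' gate status — the raw-p protein criterion is preserved deliberately.
#'
#' @param prot an `expression_matrix` of kind `"protein_intensity"`; all
#'   intensities must be strictly positive.
#' @param stage_a,stage_b stage labels; the contrast is B vs A.
#' @param alpha raw-p cutoff (default 0.05).
#' @param fc_min strict fold-change cutoff (default 1.3).
#' @return a `contrast_result` data.frame with columns `feature_id`,
#'   `mean_A`, `mean_B`, `FC`, `log2FC`, `p`, `padj`, `status`.
#' @export
test_differential_abundance <- function(prot, stage_a, stage_b,
                                        alpha = 0.05, fc_min = 1.3) {
  stopifnot(inherits(prot, "expression_matrix"))
  if (any(prot$values <= 0))
    stop("non-positive intensity: log2 fold change undefined")
  ca <- prot$sample_meta$stage == stage_a
  cb <- prot$sample_meta$stage == stage_b
  if (sum(ca) < 2L || sum(cb) < 2L)
    stop("each group needs >= 2 replicates")
  a <- prot$values[, ca, drop = FALSE]
  b <- prot$values[, cb, drop = FALSE]
  w <- row_welch_t(log2(a), log2(b))
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  fc <- mean_b / mean_a
  status <- rep("unchanged", nrow(a))
  status[w$p < alpha & fc > fc_min] <- "up"
  status[w$p < alpha & fc < 1 / fc_min] <- "down"
  new_contrast_result(
    data.frame(feature_id = feature_ids(prot), mean_A = mean_a, mean_B = mean_b,
               FC = fc, log2FC = log2(fc), p = w$p, padj = bh_adjust(w$p),
               status = status, stringsAsFactors = FALSE, row.names = NULL),
    contrast = paste0(stage_b, "vs", stage_a), omics = "protein")
}

#' Feature IDs called up/down/differential in a contrast result
#' @param result a `contrast_result`.
#' @param direction `"up"`, `"down"`, or `"any"` (up or down).
#' @return character vector of feature IDs.
#' @export
de_features <- function(result, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "any") result$status %in% c("up", "down")
          else result$status == direction
  result$feature_id[keep]
}

#' Three-way Venn region counts
#'
#' Classifies the union of three feature-ID sets into the seven disjoint
#' Venn regions.
#'
#' @param set1,set2,set3 character vectors of feature IDs.
#' @param names names for the three sets (used in region labels).
#' @return named integer vector of length 7 with names `"100"`, `"010"`,
#'   `"001"`, `"110"`, `"101"`, `"011"`, `"111"` (membership pattern in
#'   set1/set2/set3 order); attribute `set_names` carries `names`.
#' @export
venn_regions <- function(set1, set2, set3, names = c("A", "B", "C")) {
  u <- unique(c(set1, set2, set3))
  pattern <- paste0(as.integer(u %in% set1),
                    as.integer(u %in% set2),
                    as.integer(u %in% set3))
  keys <- c("100", "010", "001", "110", "101", "011", "111")
  out <- stats::setNames(integer(7), keys)
  tab <- table(pattern)
  out[names(tab)] <- as.integer(tab)
  attr(out, "set_names") <- names
  out
}

#' Write a contrast result as a fixed-column TSV
#' @param result a `contrast_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contrast_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
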