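# Pairing of mRNA and protein measurements and the correlation analyses:
# per-stage across-gene correlation (the correlation-decay readout) and
# per-gene correlation across stages (the GSEA ranking statistic).

#' Pair mRNA and protein matrices through an ID map
#'
#' One record per mapped gene present in both matrices. Values are
#' log2(x + 1)-transformed; stage means are computed per omics, and per-gene
#' mean-centred versions (profile minus its own across-stage mean) are kept
#' for co-clustering. Centring never enters the correlation computations:
#' across-gene Pearson at a stage is invariant to the across-gene display
#' centring of a scatter, and per-gene Pearson is invariant to per-gene
#' centring.
#'
#' @param rna an `expression_matrix` (counts or normalized counts).
#' @param prot an `expression_matrix` of protein intensities.
#' @param map an `id_map` (gene_id -> protein_id).
#' @return list of class `paired_omics`: `gene_id`, `protein_id`, `stages`,
#'   `mrna`/`protein` (genes x stages log2 stage means), `mrna_centred`/
#'   `protein_centred` (per-gene mean-centred), `r` (per-gene Pearson, `NA`
#'   until [per_gene_correlation()] fills it).
#' @export
pair_omics <- function(rna, prot, map) {
  if (!identical(rna$stages, prot$stages))
    stop("stage labels disagree between omics: ",
         paste(rna$stages, collapse = ","), " vs ",
         paste(prot$stages, collapse = ","))
  genes <- intersect(map$gene_id, feature_ids(rna))
  genes <- genes[map_ids(map, genes, "gene") %in% feature_ids(prot)]
  if (length(genes) == 0L) stop("zero overlap between omics after mapping")
  prots <- map_ids(map, genes, "gene")
  m_sm <- stage_means(rna, log2p1 = TRUE)[genes, , drop = FALSE]
  p_sm <- stage_means(prot, log2p1 = TRUE)[prots, , drop = FALSE]
  rownames(p_sm) <- genes
  structure(list(
    gene_id = genes, protein_id = prots, stages = rna$stages,
    mrna = m_sm, protein = p_sm,
    mrna_centred = m_sm - rowMeans(m_sm),
    protein_centred = p_sm - rowMeans(p_sm),
    r = stats::setNames(rep(NA_real_, length(genes)), genes)),
    class = "paired_omics")
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf("paired_omics: %d genes x %d stages (per-gene r %s)\n",
              length(x$gene_id), length(x$stages),
              if (all(is.na(x$r))) "not yet computed" else "computed"))
  invisible(x)
}

#' Across-gene mRNA-protein correlation at one stage
#'
#' Pearson correlation across genes between replicate-mean log2 mRNA and
#' protein values at the given stage; the scatter-plot statistic whose decay
#' over ripening is the central integrative readout.
#'
#' @param paired a `paired_omics`.
#' @param stage stage label.
#' @return list with `r` and `r_squared` (`= r^2`).
#' @export
stage_correlation <- function(paired, stage) {
  if (!stage %in% paired$stages) stop("unknown stage: ", stage)
  x <- paired$mrna[, stage]; y <- paired$protein[, stage]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 genes with defined values")
  r <- stats::cor(x[ok], y[ok])
  list(r = r, r_squared = r^2)
}

#' Per-stage correlation summary across all stages
#' @param paired a `paired_omics`.
#' @return data.frame with columns `stage`, `r`, `r_squared`.
#' @export
stage_correlation_profile <- function(paired) {
  rows <- lapply(paired$stages, function(s) {
    sc <- stage_correlation(paired, s)
    data.frame(stage = s, r = sc$r, r_squared = sc$r_squared,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-gene mRNA-protein correlation and its summary
#'
#' Pearson correlation of each gene's mRNA and protein profiles. The default
#' correlates the S stage means (replicate means, matching the scatter-plot
#' convention); `level = "replicate"` uses all stage-replicate samples
#' instead. Genes with zero variance in either profile get an undefined
#' (`NA`) correlation and are excluded from the summary denominators —
#' never coerced to 0.
#'
#' @param paired a `paired_omics`.
#' @param level `"stage_mean"` (default) or `"replicate"`.
#' @param rna,prot the full expression matrices; required only for
#'   `level = "replicate"`.
#' @return list with `paired` (the input with `r` filled in) and `summary`
#'   (list: `fraction_positive`, `mean_r`, `n_defined`).
#' @export
per_gene_correlation <- function(paired, level = c("stage_mean", "replicate"),
                                 rna = NULL, prot = NULL) {
  level <- match.arg(level)
  if (length(paired$stages) < 3L) stop("need >= 3 stages")
  if (level == "stage_mean") {
    xm <- paired$mrna; ym <- paired$protein
  } else {
    if (is.null(rna) || is.null(prot))
      stop("replicate-level correlation needs the rna and prot matrices")
    xm <- log2(rna$values[paired$gene_id, , drop = FALSE] + 1)
    ym <- log2(prot$values[paired$protein_id, , drop = FALSE] + 1)
    if (!identical(rna$sample_meta$stage, prot$sample_meta$stage))
      stop("replicate-level correlation needs matching sample layouts")
  }
  r <- vapply(seq_along(paired$gene_id), function(i) {
    x <- xm[i, ]; y <- ym[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  names(r) <- paired$gene_id
  paired$r <- r
  defined <- r[!is.na(r)]
  list(paired = paired,
       summary = list(fraction_positive = mean(defined > 0),
                      mean_r = mean(defined),
                      n_defined = length(defined)))
}

#' Per-gene-set mean fold change (Stat.mean)
#'
#' Arithmetic mean of the set members' log2 fold changes in a contrast: the
#' averaged magnitude and direction of change at the gene-set level.
#'
#' @param contrast a `contrast_result`.
#' @param set character vector of member feature IDs.
#' @return list with `stat_mean`, `direction` (sign of the mean), `n_used`.
#' @export
set_stat_mean <- function(contrast, set) {
  idx <- contrast$feature_id %in% set
  if (!any(idx)) stop("set has no overlap with tested features")
  sm <- mean(contrast$log2FC[idx])
  list(stat_mean = sm, direction = sign(sm), n_used = sum(idx))
}
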