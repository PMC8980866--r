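# Correlation-ranked gene set enrichment analysis: weighted
# Kolmogorov-Smirnov enrichment score with a gene-set permutation null.
# The ranking statistic here is a per-gene quantity (mRNA-protein Pearson
# correlation), so phenotype-label permutation is meaningless; the null
# resamples size-matched random gene sets instead.

# Enrichment score from sorted scores and hit positions. Hits increment the
# running sum by |score|^p / sum_hits |score|^p, misses decrement it by
# 1/(N - N_hits); the ES is the running-sum value of maximal absolute
# deviation. Extrema can only occur at a hit (local maxima) or just before a
# hit (local minima), which is all this computes - O(N_hits) per call.
es_from_positions <- function(sorted_scores, hits, weight_p = 1) {
  N <- length(sorted_scores)
  nh <- length(hits)
  w <- abs(sorted_scores[hits])^weight_p
  sw <- sum(w)
  if (sw == 0) w <- rep(1 / nh, nh) else w <- w / sw
  P <- cumsum(w)
  miss_step <- 1 / (N - nh)
  misses_before <- hits - seq_len(nh)
  at_hit <- P - misses_before * miss_step
  before_hit <- c(0, P[-nh]) - misses_before * miss_step
  cand <- unname(c(at_hit, before_hit))
  es <- cand[which.max(abs(cand))]
  list(es = es, at_hit = at_hit, before_hit = before_hit)
}

#' GSEA enrichment score for one gene set
#'
#' Classic weighted Kolmogorov-Smirnov running sum over a ranked gene list:
#' genes in the set ("hits") push the sum up in proportion to
#' `|score|^weight_p`, genes outside pull it down uniformly; the ES is the
#' maximal signed deviation, and the leading edge is the set members at or
#' before the extremum (at or after it, for negative ES).
#'
#' @param scores named numeric vector of ranking scores (e.g. per-gene
#'   mRNA-protein correlations); sorted into decreasing order internally
#'   (ties broken by name for determinism).
#' @param set character vector of member gene IDs; must overlap the ranked
#'   genes and be a proper subset of them.
#' @param weight_p weight exponent (default 1, the published default).
#' @return list with `es`, `running` (full running-sum vector, one value per
#'   ranked gene), `leading_edge` (character vector), `n_hits`.
#' @export
gsea_enrichment_score <- function(scores, set, weight_p = 1) {
  if (is.null(names(scores))) stop("scores must be named by gene")
  scores <- scores[!is.na(scores)]
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  genes <- names(s)
  hits <- which(genes %in% set)
  N <- length(s)
  if (length(hits) == 0L) stop("set has no overlap with the ranked genes")
  if (length(hits) == N) stop("set covers every ranked gene")
  w <- abs(s[hits])^weight_p
  sw <- sum(w)
  inc <- if (sw == 0) rep(1 / length(hits), length(hits)) else w / sw
  step <- rep(-1 / (N - length(hits)), N)
  step[hits] <- inc
  running <- cumsum(step)
  es_i <- which.max(abs(running))
  es <- running[es_i]
  leading <- if (es >= 0) genes[hits[hits <= es_i]]
             else genes[hits[hits > es_i]]
  list(es = es, running = stats::setNames(running, genes),
       leading_edge = leading, n_hits = length(hits))
}

#' Correlation-ranked GSEA with a gene-set permutation null
#'
#' Computes each set's ES on the ranked list, then builds a size-matched
#' null by drawing `n_perm` random gene sets of the same (post-filter) size
#' from the ranked genes. The nominal p uses the plus-one permutation
#' estimator over same-sign permutations,
#' `NOM p = (1 + #{same sign, |perm ES| >= |ES|}) / (1 + #same-sign perms)`,
#' so it is never below `1/(n_perm + 1)`; `NES = ES / mean(|same-sign perm
#' ES|)`. Deterministic given `seed`.
#'
#' @param scores named numeric vector of ranking scores (`NA` dropped).
#' @param sets a `gene_set_collection`; each set is intersected with the
#'   ranked genes, then filtered to `size_bounds`.
#' @param n_perm number of random-set permutations (default 1000).
#' @param seed RNG seed.
#' @param size_bounds inclusive set-size bounds after intersection
#'   (default c(5, 500)).
#' @param weight_p weight exponent (default 1).
#' @return data.frame of class `gsea_result` with columns `set`, `size`,
#'   `es`, `nes`, `nom_p`, `leading_edge` (comma-joined); attributes
#'   `n_perm`, `seed`, `weight_p`.
#' @export
gsea <- function(scores, sets, n_perm = 1000L, seed = 1L,
                 size_bounds = c(5L, 500L), weight_p = 1) {
  scores <- scores[!is.na(scores)]
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  genes <- names(s)
  N <- length(s)
  members <- lapply(sets$sets, function(m) which(genes %in% m))
  sizes <- lengths(members)
  keep <- sizes >= size_bounds[1] & sizes <= size_bounds[2] & sizes < N
  if (!any(keep)) stop("no gene set survives the size filter")
  members <- members[keep]
  set.seed(seed)
  rows <- lapply(names(members), function(nm) {
    hits <- sort(members[[nm]])
    obs <- gsea_enrichment_score(s, genes[hits], weight_p = weight_p)
    nh <- length(hits)
    perm_es <- vapply(seq_len(n_perm), function(i) {
      es_from_positions(s, sort(sample.int(N, nh)), weight_p)$es
    }, numeric(1))
    same <- perm_es[sign(perm_es) == sign(obs$es)]
    nom_p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = nh, es = obs$es, nes = nes, nom_p = nom_p,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("gsea_result", "data.frame"),
            n_perm = n_perm, seed = seed, weight_p = weight_p)
}

#' Write a GSEA result to TSV
#' @param result a `gsea_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gsea_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
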