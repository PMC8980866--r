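# Temporal clustering of stage profiles: fuzzy c-means (soft, shape-based),
# Ward hierarchical co-clustering, and the PCA / sample-correlation
# reproducibility summaries.

#' Per-item standardization of stage profiles
#'
#' z-scores each row across stages, the convention for shape-based temporal
#' clustering (raw-scale clustering would group by abundance, not shape).
#' Rows with zero variance are dropped with a warning.
#'
#' @param profiles items x stages numeric matrix.
#' @return standardized matrix, possibly with fewer rows.
#' @export
standardize_profiles <- function(profiles) {
  s <- apply(profiles, 1, stats::sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " zero-variance item(s) excluded before standardization")
    profiles <- profiles[s > 0, , drop = FALSE]
    s <- s[s > 0]
  }
  (profiles - rowMeans(profiles)) / s
}

#' Fuzzy c-means clustering
#'
#' Standard alternating (Bezdek) iteration: given memberships `u`, centers
#' are the `u^m`-weighted means; given centers, `u_ij` is proportional to
#' `d_ij^(-2/(m-1))`. Input profiles are standardized per item first (see
#' [standardize_profiles()]; disable with `standardize = FALSE` for
#' pre-standardized input). Memberships are initialized from a symmetric
#' Dirichlet draw under the given seed, so runs are deterministic.
#'
#' @param profiles items x stages numeric matrix with rownames.
#' @param c number of clusters (>= 1).
#' @param m fuzzifier (> 1, default 2).
#' @param tol convergence tolerance on the objective decrease (default 1e-5).
#' @param max_iter iteration cap (default 300).
#' @param seed RNG seed for the membership initialization.
#' @param standardize standardize rows before clustering (default `TRUE`).
#' @return list of class `fcm_result`: `centers` (c x stages), `membership`
#'   (items x c, rows summing to 1), `m`, `objective` (per-iteration trace,
#'   non-increasing), `items` (row names clustered, after any zero-variance
#'   exclusion).
#' @export
fuzzy_cmeans <- function(profiles, c, m = 2, tol = 1e-5, max_iter = 300L,
                         seed = 1L, standardize = TRUE) {
  if (m <= 1) stop("fuzzifier m must be > 1")
  x <- if (standardize) standardize_profiles(profiles) else profiles
  n <- nrow(x)
  if (c > n) stop("more clusters (", c, ") than items (", n, ")")
  if (c < 1L) stop("c must be >= 1")
  if (c == 1L) {
    centers <- matrix(colMeans(x), 1, ncol(x),
                      dimnames = list("C1", colnames(x)))
    u <- matrix(1, n, 1, dimnames = list(rownames(x), "C1"))
    obj <- sum(sweep(x, 2, centers[1, ])^2)
    return(structure(list(centers = centers, membership = u, m = m,
                          objective = obj, items = rownames(x)),
                     class = "fcm_result"))
  }
  set.seed(seed)
  g <- matrix(stats::rexp(n * c), n, c)   # symmetric Dirichlet(1) rows
  u <- g / rowSums(g)
  obj_trace <- numeric(0)
  obj_prev <- Inf
  for (iter in seq_len(max_iter)) {
    um <- u^m
    centers <- t(um) %*% x / colSums(um)
    # squared Euclidean distances items x centers
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    obj <- sum(um * d2)
    obj_trace <- c(obj_trace, obj)
    zero <- d2 < 1e-12
    inv <- d2^(-1 / (m - 1))
    u_new <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u_new[hit, ] <- 0
      u_new[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    u <- u_new
    if (is.finite(obj_prev) && abs(obj_prev - obj) < tol) break
    obj_prev <- obj
  }
  dimnames(centers) <- list(paste0("C", seq_len(c)), colnames(x))
  dimnames(u) <- list(rownames(x), paste0("C", seq_len(c)))
  structure(list(centers = centers, membership = u, m = m,
                 objective = obj_trace, items = rownames(x)),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("fcm_result: %d items, %d clusters, m = %g, %d iterations\n",
              nrow(x$membership), ncol(x$membership), x$m, length(x$objective)))
  invisible(x)
}

#' Hard cluster assignment from fuzzy memberships
#'
#' An item is assigned to its argmax cluster iff the maximum membership
#' strictly exceeds `tau`, else it stays unassigned (`NA`). Ties in the
#' argmax are broken toward the lowest cluster index.
#'
#' @param result an `fcm_result`.
#' @param tau membership threshold in [1/c, 1]; default 0.5. An item is only
#'   assigned when its maximum membership strictly exceeds `tau`.
#' @return named integer vector (cluster index or `NA`), one per item.
#' @export
assign_fuzzy_clusters <- function(result, tau = 0.5) {
  u <- result$membership
  c <- ncol(u)
  if (c > 1 && (tau < 1 / c || tau > 1))
    stop("tau must lie in [1/c, 1]")
  best <- apply(u, 1, which.max)          # which.max breaks ties low
  maxu <- u[cbind(seq_len(nrow(u)), best)]
  best[maxu <= tau] <- NA_integer_
  stats::setNames(as.integer(best), rownames(u))
}

#' Ward hierarchical clustering with a cut
#'
#' Classic "ward.D" linkage (the Lance-Williams Ward update applied to plain
#' Euclidean distances, not the squared-distance "ward.D2" variant), via
#' `stats::hclust`, plus a cut into `k` clusters.
#'
#' @param profiles items x features numeric matrix with rownames.
#' @param k number of clusters for the cut.
#' @return list of class `dendrogram_result`: `merge`, `height`, `order`
#'   (leaf order), `labels`, `clusters` (named integer vector from
#'   `cutree(k)`), `hclust` (the underlying tree).
#' @export
ward_hierarchical <- function(profiles, k) {
  n <- nrow(profiles)
  if (k > n) stop("k (", k, ") exceeds number of items (", n, ")")
  hc <- stats::hclust(stats::dist(profiles), method = "ward.D")
  cl <- stats::cutree(hc, k = k)
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, clusters = cl, k = k, hclust = hc),
            class = "dendrogram_result")
}

#' PCA scores of samples
#'
#' Samples are the observations (rows of the transposed expression matrix);
#' features are centered (and optionally unit-scaled), and scores come from
#' the singular value decomposition.
#'
#' @param x an `expression_matrix`.
#' @param scale. unit-scale features? Default `FALSE`.
#' @param log2p1 apply `log2(value + 1)` first (default `TRUE`; the usual
#'   variance stabilization for counts/intensities).
#' @return list with `scores` (samples x components), `var_explained`
#'   (fractions summing to 1 over all components), `sdev`.
#' @export
pca_scores <- function(x, scale. = FALSE, log2p1 = TRUE) {
  v <- t(x$values)
  if (log2p1) v <- log2(v + 1)
  keep <- apply(v, 2, stats::sd) > 0
  if (!any(keep)) stop("constant matrix: PCA undefined")
  v <- v[, keep, drop = FALSE]
  pc <- stats::prcomp(v, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, var_explained = ve, sdev = pc$sdev)
}

#' Pearson correlation matrix between samples
#'
#' Computed on `log2(value + 1)` by default. Zero-variance samples yield an
#' `NA` row/column with a warning.
#'
#' @param x an `expression_matrix`.
#' @param log2p1 apply `log2(value + 1)` first (default `TRUE`).
#' @return symmetric samples x samples matrix with unit diagonal.
#' @export
sample_correlation_matrix <- function(x, log2p1 = TRUE) {
  if (nrow(x$values) < 2L) stop("need >= 2 features")
  v <- x$values
  if (log2p1) v <- log2(v + 1)
  s <- apply(v, 2, stats::sd)
  if (any(s == 0))
    warning("zero-variance sample(s): ",
            paste(colnames(v)[s == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(v))
  diag(r) <- 1
  r
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items;
#' 1 = identical partitions, ~0 = chance agreement.
#'
#' @param a,b vectors of cluster labels of equal length (`NA` pairs are
#'   dropped).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no jointly labelled items")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
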