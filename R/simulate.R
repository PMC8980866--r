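# Paired multi-omics simulator: negative-binomial RNA-seq counts and
# log-normal TMT-style protein intensities over a staged time course, with
# planted temporal templates, planted gene sets, and a stage-decaying
# mRNA-protein coupling schedule rho_s. The generator is the ground-truth
# oracle for every downstream recovery test.

#' Names of the six temporal templates
#' @return character vector of template labels.
#' @export
template_names <- function() {
  c("monotone_up", "monotone_down", "early_peak", "late_peak",
    "transient_dip", "flat")
}

# Template shapes in log2 units for S stages; `effect` is the planted
# per-adjacent-contrast log2 fold change (every adjacent-stage step is either
# 0 or +/- effect, so differential truth is never on the decision boundary).
template_shapes <- function(n_stages, effect) {
  if (n_stages < 2L) stop("need >= 2 stages")
  idx <- seq_len(n_stages) - 1L
  up <- idx * effect
  peak1 <- rep(0, n_stages); peak1[2L] <- effect
  peakL <- rep(0, n_stages); peakL[max(3L, n_stages - 1L)] <- effect
  dip <- rep(0, n_stages)
  mid <- 2:(max(2L, n_stages - 1L))
  dip[mid] <- -effect
  shapes <- rbind(monotone_up = up,
                  monotone_down = rev(up),
                  early_peak = peak1,
                  late_peak = peakL,
                  transient_dip = dip,
                  flat = rep(0, n_stages))
  # centre each shape so templates modulate shape, not total abundance
  sweep(shapes, 1, rowMeans(shapes))
}

#' Simulation configuration
#'
#' All knobs of the paired-omics generator, with defaults describing a
#' four-stage (10/18/26/34 DAP) by three-replicate ripening time course:
#' 2,000 genes, 600 mapped proteins, six temporal templates, negative
#' binomial counts at dispersion 0.1, log-normal protein replicate noise of
#' 0.25 log2 units, and a coupling schedule rho = (0.8, 0.7, 0.55, 0.40)
#' that makes the across-gene mRNA-protein correlation decay over ripening.
#'
#' @param n_genes number of simulated genes G.
#' @param n_proteins number of quantified proteins P (mapped 1:1 to a random
#'   subset of genes), P <= G.
#' @param stages ordered character vector of stage labels.
#' @param n_replicates replicates per stage.
#' @param template_fractions named numeric vector over [template_names()]
#'   summing to 1; fraction of genes assigned each temporal template.
#' @param effect_size planted log2 fold change of every non-flat template's
#'   changing adjacent-stage steps (default 2).
#' @param dispersion negative binomial dispersion phi (variance
#'   `mu + phi*mu^2`); 0 gives the Poisson limit.
#' @param lib_size expected library size per sample; each sample draws a
#'   uniform +/-10 percent jitter around it.
#' @param protein_sigma replicate-level protein noise, log2 scale.
#' @param rho per-stage mRNA-protein coupling (across-gene correlation of the
#'   standardized latents), one value per stage, each between 0 and 1.
#' @param protein_base_log2,protein_scale location and spread of log2 protein
#'   intensities (`log2 intensity = base + scale * z + noise`).
#' @param n_background_sets number of random background gene sets.
#' @param set_size_range integer range of background set sizes.
#' @param aligned_set_size size of each planted template-aligned set (>= 90
#'   percent of members drawn from that template's genes).
#' @param decoupled_set_size size of the planted decoupled set, whose member
#'   genes have their coupling forced to rho = 0 at every stage.
#' @param seed integer RNG seed; the full output is a pure function of the
#'   configuration including this seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_proteins = 600L,
                              stages = c("10DAP", "18DAP", "26DAP", "34DAP"),
                              n_replicates = 3L,
                              template_fractions = c(
                                monotone_up = 0.15, monotone_down = 0.15,
                                early_peak = 0.15, late_peak = 0.15,
                                transient_dip = 0.15, flat = 0.25),
                              effect_size = 2.0,
                              dispersion = 0.1,
                              lib_size = 2e6,
                              protein_sigma = 0.25,
                              rho = c(0.8, 0.7, 0.55, 0.40),
                              protein_base_log2 = 10,
                              protein_scale = 1.5,
                              n_background_sets = 40L,
                              set_size_range = c(15L, 60L),
                              aligned_set_size = 40L,
                              decoupled_set_size = 15L,
                              seed = 20260910L) {
  cfg <- list(n_genes = as.integer(n_genes), n_proteins = as.integer(n_proteins),
              stages = as.character(stages), n_replicates = as.integer(n_replicates),
              template_fractions = template_fractions, effect_size = effect_size,
              dispersion = dispersion, lib_size = lib_size,
              protein_sigma = protein_sigma, rho = rho,
              protein_base_log2 = protein_base_log2, protein_scale = protein_scale,
              n_background_sets = as.integer(n_background_sets),
              set_size_range = as.integer(set_size_range),
              aligned_set_size = as.integer(aligned_set_size),
              decoupled_set_size = as.integer(decoupled_set_size),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_proteins > cfg$n_genes) stop("n_proteins must be <= n_genes")
  tf <- cfg$template_fractions
  if (!setequal(names(tf), template_names()))
    stop("template_fractions must be named over: ",
         paste(template_names(), collapse = ", "))
  if (abs(sum(tf) - 1) > 1e-8) stop("template fractions must sum to 1")
  if (any(tf < 0)) stop("template fractions must be non-negative")
  if (length(cfg$rho) != length(cfg$stages))
    stop("rho must have one value per stage")
  if (any(cfg$rho < 0 | cfg$rho > 1)) stop("rho values must lie in [0, 1]")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (length(cfg$stages) < 2L) stop("need >= 2 stages")
  if (cfg$n_replicates < 1L) stop("need >= 1 replicate")
  if (cfg$decoupled_set_size > cfg$n_proteins)
    stop("decoupled set larger than the protein space")
  if (max(cfg$set_size_range, cfg$aligned_set_size) > cfg$n_genes)
    stop("infeasible gene set geometry: set size exceeds n_genes")
  invisible(cfg)
}

# Exact template allocation: floor of each fraction, remainder distributed by
# largest fractional part (ties by template order), then a seeded permutation.
allocate_templates <- function(n_genes, fractions) {
  fractions <- fractions[template_names()]
  raw <- fractions * n_genes
  base <- floor(raw)
  rem <- n_genes - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  labels <- rep(names(base), base)
  sample(labels)
}

#' Simulate a negative-binomial count matrix from latent log2 means
#'
#' Each stage's latent log2 abundance is converted to a per-sample expected
#' count by scaling relative abundances `2^latent` to the sample's jittered
#' library size; counts are drawn NB with variance `mu + phi*mu^2`
#' (Poisson when `dispersion = 0`).
#'
#' @param latent genes x stages matrix of latent log2 relative abundances
#'   (rownames = gene IDs, colnames = stage labels).
#' @param config a `simulation_config` (uses dispersion, lib_size,
#'   n_replicates, stages).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return an `expression_matrix` of kind `"counts"`, samples named
#'   `<stage>_R<rep>`.
#' @export
simulate_counts <- function(latent, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # -Inf encodes a zero-abundance gene; NA/NaN/+Inf are invalid
  if (any(is.na(latent) | latent == Inf)) stop("latent means must be finite")
  S <- length(config$stages); R <- config$n_replicates
  G <- nrow(latent)
  w <- 2^latent                     # relative abundances per stage
  w[latent == -Inf] <- 0
  samples <- as.vector(t(outer(config$stages, seq_len(R),
                               function(s, r) paste0(s, "_R", r))))
  lib <- config$lib_size * stats::runif(S * R, 0.9, 1.1)
  counts <- matrix(0L, G, S * R, dimnames = list(rownames(latent), samples))
  k <- 0L
  for (s in seq_len(S)) {
    p <- w[, s] / sum(w[, s])
    for (r in seq_len(R)) {
      k <- k + 1L
      mu <- lib[k] * p
      counts[, k] <- if (config$dispersion > 0)
        stats::rnbinom(G, size = 1 / config$dispersion, mu = mu)
      else stats::rpois(G, lambda = mu)
    }
  }
  meta <- data.frame(sample_id = samples,
                     stage = rep(config$stages, each = R),
                     replicate = rep(seq_len(R), times = S))
  expression_matrix(counts, meta, "counts")
}

#' Simulate protein intensities coupled to an mRNA latent
#'
#' The mRNA latent is standardized per stage across genes (z-scores), the
#' protein latent is the coupled mixture
#' `z_p = rho_s * z_mRNA + sqrt(1 - rho_s^2) * eps` with fresh standard
#' normal `eps` per gene and stage, and replicate intensities are
#' `2^(base + scale * z_p + N(0, protein_sigma))`. The coupling is injected on
#' the standardized scale so that `rho_s` is exactly the target across-gene
#' mRNA-protein correlation at stage s — the quantity the stage-correlation
#' analysis estimates.
#'
#' @param mrna_latent proteins-mapped genes x stages latent log2 matrix
#'   (standardized internally; standardization is idempotent).
#' @param config a `simulation_config`.
#' @param rho_gene optional per-gene coupling override: a genes x stages
#'   matrix (or per-gene vector recycled across stages) replacing the
#'   schedule in `config$rho`; used to decouple planted set members.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list with `protein` (an `expression_matrix` of kind
#'   `"protein_intensity"`, rows named by protein IDs = rownames of
#'   `mrna_latent`), `z_mrna` and `z_protein` (the standardized latents).
#' @export
simulate_proteins <- function(mrna_latent, config, rho_gene = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(config$stages); R <- config$n_replicates
  P <- nrow(mrna_latent)
  z <- scale(mrna_latent)           # per-stage (column) standardization
  z[is.nan(z)] <- 0
  rho <- matrix(rep(config$rho, each = P), P, S)
  if (!is.null(rho_gene)) {
    if (is.matrix(rho_gene)) rho <- rho_gene
    else rho <- matrix(rep(rho_gene, S), P, S)
  }
  eps <- matrix(stats::rnorm(P * S), P, S)
  zp <- rho * z + sqrt(pmax(0, 1 - rho^2)) * eps
  prot_log2 <- config$protein_base_log2 + config$protein_scale * zp
  samples <- as.vector(t(outer(config$stages, seq_len(R),
                               function(s, r) paste0(s, "_R", r))))
  vals <- matrix(0, P, S * R, dimnames = list(rownames(mrna_latent), samples))
  k <- 0L
  for (s in seq_len(S)) for (r in seq_len(R)) {
    k <- k + 1L
    vals[, k] <- 2^(prot_log2[, s] + stats::rnorm(P, 0, config$protein_sigma))
  }
  meta <- data.frame(sample_id = samples,
                     stage = rep(config$stages, each = R),
                     replicate = rep(seq_len(R), times = S))
  list(protein = expression_matrix(vals, meta, "protein_intensity"),
       z_mrna = matrix(z, P, S, dimnames = dimnames(mrna_latent)),
       z_protein = matrix(zp, P, S, dimnames = dimnames(mrna_latent)),
       protein_latent_log2 = matrix(prot_log2, P, S,
                                    dimnames = dimnames(mrna_latent)))
}

#' Plant gene sets over the simulated gene universe
#'
#' Builds background random sets of configured sizes, one template-aligned
#' set per temporal template (at least 90 percent of members drawn from that
#' template's genes — the over-representation recovery targets), and one
#' decoupled set whose members are the genes with coupling forced to zero
#' (the GSEA negative-correlation target).
#'
#' @param templates named character vector: per-gene template label.
#' @param decoupled_genes character vector of decoupled (rho = 0) gene IDs.
#' @param config a `simulation_config`.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return a `gene_set_collection`; planted sets are named
#'   `SET_aligned_<template>` and `SET_decoupled`, background sets `BG###`.
#' @export
plant_gene_sets <- function(templates, decoupled_genes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- names(templates)
  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  config$n_background_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("BG%03d", seq_along(sets))
  for (tmpl in template_names()) {
    pool <- genes[templates == tmpl]
    if (length(pool) == 0L) next   # template absent from this world
    k <- config$aligned_set_size
    k_in <- ceiling(0.9 * k)
    if (length(pool) < k_in)
      stop("infeasible gene set geometry: template ", tmpl,
           " has only ", length(pool), " genes")
    out_pool <- setdiff(genes, pool)
    members <- c(sample(pool, k_in),
                 sample(out_pool, min(k - k_in, length(out_pool))))
    sets[[paste0("SET_aligned_", tmpl)]] <- members
  }
  if (length(decoupled_genes)) sets[["SET_decoupled"]] <- decoupled_genes
  desc <- stats::setNames(rep("synthetic", length(sets)), names(sets))
  desc[grep("^SET_", names(sets))] <- "planted"
  gene_set_collection(sets, desc)
}

#' Generate a complete paired multi-omics dataset with ground truth
#'
#' Runs the full generator: template assignment, gene baselines and lengths,
#' latent stage profiles, NB counts, coupled protein intensities, ID map and
#' planted gene sets. Output is a pure function of the configuration
#' (including its seed): the same config yields bit-identical results.
#'
#' @param config a `simulation_config`.
#' @return list with elements `counts`, `protein` (both
#'   `expression_matrix`), `lengths` (`gene_length_table`), `map` (`id_map`),
#'   `gene_sets` (`gene_set_collection`) and `truth` (`synthetic_truth`, see
#'   Details).
#' @details `truth` contains: `templates` (per-gene label), `de_mrna` and
#'   `de_protein` (genes x contrasts status matrices; protein statuses are
#'   scored on the realized noise-free latent and may be `"borderline"` in a
#'   margin around the fold-change boundary — see the methods vignette),
#'   `rho` (schedule), `decoupled_genes`, `planted_sets`, `map`,
#'   `mrna_latent` and `protein_latent_log2`, and `contrasts` (labels
#'   `"<B>vs<A>"` for adjacent stage pairs).
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  G <- config$n_genes; S <- length(config$stages); R <- config$n_replicates
  genes <- sprintf("gene%04d", seq_len(G))

  templates <- stats::setNames(allocate_templates(G, config$template_fractions), genes)
  shapes <- template_shapes(S, config$effect_size)
  baseline <- stats::runif(G, log2(50), log2(2000))
  lengths <- gene_length_table(genes, round(2^stats::runif(G, log2(500), log2(10000))))

  latent <- baseline + shapes[templates, , drop = FALSE]
  dimnames(latent) <- list(genes, config$stages)

  mapped <- sort(sample(genes, config$n_proteins))
  proteins <- sub("^gene", "prot", mapped)
  map <- id_map(mapped, proteins)
  # decoupling is only observable for genes whose mRNA varies: a flat gene
  # has r ~ 0 whether coupled or not, so the planted decoupled set (the GSEA
  # negative-correlation target) is drawn from shaped mapped genes
  decoupled <- character(0)
  if (config$decoupled_set_size > 0L) {
    shaped_mapped <- mapped[templates[mapped] != "flat"]
    if (length(shaped_mapped) < config$decoupled_set_size)
      stop("not enough shaped mapped genes for the decoupled set")
    decoupled <- sort(sample(shaped_mapped, config$decoupled_set_size))
  }

  counts <- simulate_counts(latent, config)

  rho_gene <- matrix(rep(config$rho, each = config$n_proteins),
                     config$n_proteins, S)
  rho_gene[mapped %in% decoupled, ] <- 0
  prot_sim <- simulate_proteins(latent[mapped, , drop = FALSE], config,
                                rho_gene = rho_gene)
  prot <- prot_sim$protein
  rownames(prot$values) <- proteins

  gene_sets <- plant_gene_sets(templates, decoupled, config)

  contrasts <- paste0(config$stages[-1], "vs", config$stages[-S])
  de_mrna <- mrna_truth_status(templates, shapes, contrasts)
  de_protein <- protein_truth_status(prot_sim$protein_latent_log2, config, contrasts)

  truth <- structure(list(
    templates = templates,
    de_mrna = de_mrna,
    de_protein = de_protein,
    rho = stats::setNames(config$rho, config$stages),
    decoupled_genes = decoupled,
    planted_sets = grep("^SET_", names(gene_sets$sets), value = TRUE),
    map = map,
    mrna_latent = latent,
    protein_latent_log2 = prot_sim$protein_latent_log2,
    contrasts = contrasts,
    config = config), class = "synthetic_truth")

  list(counts = counts, protein = prot, lengths = lengths, map = map,
       gene_sets = gene_sets, truth = truth)
}

# mRNA truth: planted adjacent-stage latent steps are exactly 0 or
# +/- effect_size, so the label follows the sign of the step.
mrna_truth_status <- function(templates, shapes, contrasts) {
  genes <- names(templates)
  S <- ncol(shapes)
  out <- matrix("unchanged", length(genes), S - 1L,
                dimnames = list(genes, contrasts))
  diffs <- shapes[, -1, drop = FALSE] - shapes[, -S, drop = FALSE]
  for (j in seq_len(S - 1L)) {
    d <- diffs[templates, j]
    out[d > 1, j] <- "up"
    out[d < -1, j] <- "down"
  }
  out
}

# Protein truth: scored on the realized replicate-shared latent against the
# paper's FC thresholds, with a "borderline" band of one minimal detectable
# margin around the boundary (see methods vignette).
protein_truth_status <- function(prot_latent_log2, config, contrasts) {
  thr <- log2(1.3)
  R <- config$n_replicates
  margin <- stats::qt(0.975, df = max(1L, 2L * R - 2L)) *
    config$protein_sigma * sqrt(2 / R)
  S <- ncol(prot_latent_log2)
  d <- prot_latent_log2[, -1, drop = FALSE] - prot_latent_log2[, -S, drop = FALSE]
  out <- matrix("borderline", nrow(d), ncol(d),
                dimnames = list(rownames(prot_latent_log2), contrasts))
  out[abs(d) <= thr] <- "unchanged"
  out[d >= thr + margin] <- "up"
  out[d <= -(thr + margin)] <- "down"
  out
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d genes, %d proteins, %d contrasts, rho = %s\n",
              length(x$templates), nrow(x$de_protein), length(x$contrasts),
              paste(format(x$rho), collapse = "/")))
  invisible(x)
}

#' Score differential calls against the planted truth
#'
#' Sensitivity = called-DE fraction of truly DE (up or down) features;
#' false-discovery proportion = truly-unchanged fraction of called-DE
#' features. Protein truth rows labelled `"borderline"` (realized effect
#' within one minimal-detectable margin of the fold-change boundary, where no
#' test has power by construction) are excluded from both numerators and
#' denominators.
#'
#' @param result a `contrast_result` (see [test_differential_expression()]).
#' @param truth_status character vector of truth labels (`up`, `down`,
#'   `unchanged`, `borderline`) named by feature ID.
#' @return list with `sensitivity`, `fdp`, `n_true_de`, `n_called`.
#' @export
de_recovery_metrics <- function(result, truth_status) {
  truth <- truth_status[result$feature_id]
  keep <- !is.na(truth) & truth != "borderline"
  called <- result$status %in% c("up", "down")
  true_de <- truth %in% c("up", "down")
  sens <- sum(called & true_de & keep) / sum(true_de & keep)
  fdp <- if (sum(called & keep) == 0) 0
         else sum(called & !true_de & keep) / sum(called & keep)
  list(sensitivity = sens, fdp = fdp,
       n_true_de = sum(true_de & keep), n_called = sum(called & keep))
}
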