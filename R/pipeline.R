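# End-to-end orchestration: simulate (or load) -> expressed-gene filter ->
# normalization -> DE/DEP per contrast -> over-representation + enrichment
# matrix -> temporal and co-clustering -> correlation analyses -> GSEA ->
# TSV outputs plus a machine-readable run manifest. One seed in the config
# fans out to fixed per-module offsets so each module is independently
# reproducible.

#' Pipeline configuration
#'
#' @param simulate a `simulation_config` describing the synthetic dataset to
#'   generate, or `NULL` to load data from `paths`.
#' @param paths named list of input files (`counts`, `protein`, `lengths`,
#'   `map`, `gene_sets`, `sample_sheet`) used when `simulate` is `NULL`.
#' @param contrasts list of `c(stage_A, stage_B)` pairs (B vs A); default the
#'   three adjacent ripening contrasts.
#' @param alpha_gene,lfc_min gene DE thresholds (padj, |log2FC|).
#' @param alpha_protein,fc_min protein DE thresholds (raw p, FC).
#' @param fpkm_threshold expressed-gene FPKM cutoff.
#' @param fcm_clusters,fcm_m,fcm_tau fuzzy c-means parameters.
#' @param ward_clusters co-clustering cut size.
#' @param gsea_n_perm,gsea_size_bounds,gsea_weight_p GSEA parameters.
#' @param seed master seed; per-module seeds are derived at fixed offsets.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            paths = NULL,
                            contrasts = NULL,
                            alpha_gene = 0.05, lfc_min = 1.0,
                            alpha_protein = 0.05, fc_min = 1.3,
                            fpkm_threshold = 0.3,
                            fcm_clusters = 6L, fcm_m = 2, fcm_tau = 0.5,
                            ward_clusters = 6L,
                            gsea_n_perm = 1000L,
                            gsea_size_bounds = c(5L, 500L),
                            gsea_weight_p = 1,
                            seed = 1L,
                            out_dir = "ripeomics_out") {
  cfg <- list(simulate = simulate, paths = paths, contrasts = contrasts,
              alpha_gene = alpha_gene, lfc_min = lfc_min,
              alpha_protein = alpha_protein, fc_min = fc_min,
              fpkm_threshold = fpkm_threshold,
              fcm_clusters = as.integer(fcm_clusters), fcm_m = fcm_m,
              fcm_tau = fcm_tau, ward_clusters = as.integer(ward_clusters),
              gsea_n_perm = as.integer(gsea_n_perm),
              gsea_size_bounds = as.integer(gsea_size_bounds),
              gsea_weight_p = gsea_weight_p,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

# Fixed per-module seed offsets (kept < 2^31 - offset).
derive_seed <- function(seed, module) {
  offsets <- c(simulate = 101L, fcm = 211L, gsea = 307L)
  (seed %% 1000000L) * 1000L + offsets[[module]]
}

#' Load a pipeline configuration from a plain-text file
#'
#' Accepts a YAML file (when the `yaml` package is available) or a JSON
#' file; keys mirror the arguments of [pipeline_config()], with a nested
#' `simulate:` block mirroring [simulation_config()].
#'
#' @param path config file (.yaml/.yml or .json).
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else if (requireNamespace("yaml", quietly = TRUE)) yaml::read_yaml(path)
  else stop("yaml package unavailable; provide a .json config")
  sim <- if (!is.null(raw$simulate)) do.call(simulation_config, raw$simulate)
         else if (is.null(raw$paths)) simulation_config() else NULL
  args <- raw[setdiff(names(raw), "simulate")]
  args$simulate <- sim
  do.call(pipeline_config, args)
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_cfg <- cfg$simulate
    sim_cfg$seed <- as.integer(derive_seed(cfg$seed, "simulate"))
    d <- generate_dataset(sim_cfg)
    return(d)
  }
  p <- cfg$paths
  sheet <- load_sample_sheet(p$sample_sheet)
  list(counts = load_expression_table(p$counts, sheet, "counts"),
       protein = load_expression_table(p$protein, sheet, "protein_intensity"),
       lengths = load_gene_lengths(p$lengths),
       map = load_id_map(p$map),
       gene_sets = load_gene_sets(p$gene_sets),
       truth = NULL)
}

#' Run the full integrative pipeline
#'
#' Executes every analysis stage on simulated or loaded data and writes all
#' result tables plus a JSON manifest under `config$out_dir`. Re-running
#' with the same config reproduces every numeric output bit-identically.
#' Any stage failure aborts with the failing stage named; outputs written so
#' far are retained next to a `FAILED` marker file.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) a list with every in-memory result: `data`,
#'   `expressed`, `size_factors`, `de_rna`, `de_protein` (per contrast),
#'   `venn`, `enrichment`, `enrichment_matrix`, `fcm`, `assignments`,
#'   `ward`, `pca`, `sample_cor`, `paired`, `stage_cor`, `gene_cor_summary`,
#'   `gsea`, `stat_mean`, `manifest`.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  res <- list()
  tryCatch({
    stage <- "inputs"
    message("[ripeomics] stage: ", stage)
    d <- load_pipeline_inputs(config)
    res$data <- d
    contrasts <- config$contrasts
    if (is.null(contrasts)) {
      st <- d$counts$stages
      contrasts <- lapply(seq_len(length(st) - 1L), function(i) c(st[i], st[i + 1L]))
    }
    bad <- unlist(contrasts)[!unlist(contrasts) %in% d$counts$stages]
    if (length(bad)) stop("unknown stage in contrast: ", paste(bad, collapse = ", "))
    clab <- vapply(contrasts, function(ct) paste0(ct[2], "vs", ct[1]), "")

    stage <- "expression filtering"
    message("[ripeomics] stage: ", stage)
    fpkm <- compute_fpkm(d$counts, d$lengths)
    res$expressed <- filter_expressed(fpkm, config$fpkm_threshold)
    s <- estimate_size_factors(d$counts)
    res$size_factors <- s
    norm <- normalize_counts(d$counts, s)
    norm_expr <- subset_expression(norm, features = res$expressed)

    stage <- "differential testing"
    message("[ripeomics] stage: ", stage)
    res$de_rna <- lapply(contrasts, function(ct)
      test_differential_expression(norm_expr, ct[1], ct[2],
                                   alpha = config$alpha_gene,
                                   lfc_min = config$lfc_min))
    res$de_protein <- lapply(contrasts, function(ct)
      test_differential_abundance(d$protein, ct[1], ct[2],
                                  alpha = config$alpha_protein,
                                  fc_min = config$fc_min))
    names(res$de_rna) <- names(res$de_protein) <- clab
    for (i in seq_along(clab)) {
      write_contrast_result(res$de_rna[[i]],
                            file.path(out, paste0("deg_", clab[i], ".tsv")))
      write_contrast_result(res$de_protein[[i]],
                            file.path(out, paste0("dep_", clab[i], ".tsv")))
    }
    if (length(clab) == 3L) {
      res$venn <- list(
        rna_up = venn_regions(de_features(res$de_rna[[1]], "up"),
                              de_features(res$de_rna[[2]], "up"),
                              de_features(res$de_rna[[3]], "up"), clab),
        rna_down = venn_regions(de_features(res$de_rna[[1]], "down"),
                                de_features(res$de_rna[[2]], "down"),
                                de_features(res$de_rna[[3]], "down"), clab),
        protein_up = venn_regions(de_features(res$de_protein[[1]], "up"),
                                  de_features(res$de_protein[[2]], "up"),
                                  de_features(res$de_protein[[3]], "up"), clab),
        protein_down = venn_regions(de_features(res$de_protein[[1]], "down"),
                                    de_features(res$de_protein[[2]], "down"),
                                    de_features(res$de_protein[[3]], "down"), clab))
      venn_df <- data.frame(region = names(res$venn$rna_up),
                            do.call(cbind, lapply(res$venn, as.integer)))
      utils::write.table(venn_df, file.path(out, "venn_regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "over-representation"
    message("[ripeomics] stage: ", stage)
    background <- res$expressed
    res$enrichment <- lapply(clab, function(ci) {
      de <- de_features(res$de_rna[[ci]], "any")
      if (length(de) == 0L) return(NULL)
      fisher_enrichment_test(de, background, d$gene_sets)
    })
    names(res$enrichment) <- clab
    ok <- !vapply(res$enrichment, is.null, TRUE)
    for (ci in clab[ok])
      write_enrichment_table(res$enrichment[[ci]],
                             file.path(out, paste0("enrichment_", ci, ".tsv")))
    if (sum(ok) >= 2L) {
      res$enrichment_matrix <- enrichment_heatmap_cluster(res$enrichment[ok])
      if (nrow(res$enrichment_matrix$z) > 0L)
        write_enrichment_matrix(res$enrichment_matrix,
                                file.path(out, "enrichment_matrix.tsv"))
    }

    stage <- "clustering"
    message("[ripeomics] stage: ", stage)
    deps <- unique(unlist(lapply(res$de_protein, de_features, "any")))
    if (length(deps) > config$fcm_clusters) {
      prof <- stage_means(subset_expression(d$protein, features = deps),
                          log2p1 = TRUE)
      res$fcm <- fuzzy_cmeans(prof, c = config$fcm_clusters, m = config$fcm_m,
                              seed = derive_seed(config$seed, "fcm"))
      res$assignments <- assign_fuzzy_clusters(res$fcm, tau = config$fcm_tau)
      utils::write.table(
        data.frame(item = rownames(res$fcm$membership), res$fcm$membership,
                   assigned = res$assignments),
        file.path(out, "fcm_membership.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(cluster = rownames(res$fcm$centers), res$fcm$centers),
        file.path(out, "fcm_centers.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res$pca <- list(rna = pca_scores(d$counts), protein = pca_scores(d$protein))
    res$sample_cor <- list(rna = sample_correlation_matrix(d$counts),
                           protein = sample_correlation_matrix(d$protein))
    utils::write.table(res$sample_cor$rna, file.path(out, "sample_cor_rna.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(res$sample_cor$protein,
                       file.path(out, "sample_cor_protein.tsv"),
                       sep = "\t", quote = FALSE)

    stage <- "integration"
    message("[ripeomics] stage: ", stage)
    paired <- pair_omics(norm, d$protein, d$map)
    res$stage_cor <- stage_correlation_profile(paired)
    utils::write.table(res$stage_cor, file.path(out, "stage_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pg <- per_gene_correlation(paired)
    res$paired <- pg$paired
    res$gene_cor_summary <- pg$summary
    utils::write.table(
      data.frame(gene_id = names(res$paired$r), r = res$paired$r),
      file.path(out, "per_gene_correlation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

    # paired co-clustering on per-gene-centred profiles (both omics side by side)
    co <- cbind(res$paired$mrna_centred, res$paired$protein_centred)
    colnames(co) <- c(paste0("mrna_", res$paired$stages),
                      paste0("prot_", res$paired$stages))
    if (nrow(co) >= config$ward_clusters) {
      res$ward <- ward_hierarchical(co, k = config$ward_clusters)
      utils::write.table(
        data.frame(gene_id = names(res$ward$clusters),
                   cluster = res$ward$clusters),
        file.path(out, "ward_clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "gsea"
    message("[ripeomics] stage: ", stage)
    res$gsea <- gsea(res$paired$r, d$gene_sets,
                     n_perm = config$gsea_n_perm,
                     seed = derive_seed(config$seed, "gsea"),
                     size_bounds = config$gsea_size_bounds,
                     weight_p = config$gsea_weight_p)
    write_gsea_result(res$gsea, file.path(out, "gsea.tsv"))
    res$stat_mean <- lapply(res$de_rna, function(cr) {
      vapply(names(d$gene_sets$sets), function(nm) {
        tryCatch(set_stat_mean(cr, d$gene_sets$sets[[nm]])$stat_mean,
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    sm_df <- data.frame(set = names(d$gene_sets$sets),
                        do.call(cbind, res$stat_mean), check.names = FALSE)
    utils::write.table(sm_df, file.path(out, "stat_mean.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "manifest"
    message("[ripeomics] stage: ", stage)
    manifest <- list(
      seed = config$seed,
      contrasts = clab,
      parameters = config[c("alpha_gene", "lfc_min", "alpha_protein", "fc_min",
                            "fpkm_threshold", "fcm_clusters", "fcm_m",
                            "fcm_tau", "ward_clusters", "gsea_n_perm",
                            "gsea_weight_p")],
      n_expressed = length(res$expressed),
      outputs = sort(list.files(out)),
      checksums = file_checksums(out))
    res$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(res)
  }, error = function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

# md5-style numeric checksums without extra deps: sum of bytes per file.
file_checksums <- function(dir) {
  files <- sort(setdiff(list.files(dir), c("manifest.json", "FAILED")))
  vals <- vapply(files, function(f) {
    sum(as.integer(readBin(file.path(dir, f), "raw",
                           n = file.info(file.path(dir, f))$size)))
  }, numeric(1))
  as.list(vals)
}
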