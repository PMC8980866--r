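# Independent oracle: literal running-sum GSEA enrichment score.
es_oracle <- function(scores, set, p = 1) {
  s <- scores[order(-scores, names(scores))]
  hit <- names(s) %in% set
  w <- abs(s)^p
  run <- numeric(length(s)); cur <- 0
  for (i in seq_along(s)) {
    cur <- if (hit[i]) cur + w[i] / sum(w[hit]) else cur - 1 / sum(!hit)
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

test_that("pairing joins the two omics through the ID map", {
  d <- default_fixture()
  expect_identical(length(d$paired$gene_id), nrow(d$protein$values))
  expect_identical(map_ids(d$map, d$paired$gene_id, "gene"), d$paired$protein_id)
  # centred profiles have zero row means
  expect_equal(unname(rowMeans(d$paired$mrna_centred)),
               rep(0, length(d$paired$gene_id)), tolerance = 1e-12)

  # overlap count equals a set-intersection oracle when matrices are subset
  keep_rna <- feature_ids(d$norm)[1:1500]
  keep_prot <- feature_ids(d$protein)[1:400]
  sub <- pair_omics(subset_expression(d$norm, features = keep_rna),
                    subset_expression(d$protein, features = keep_prot), d$map)
  oracle <- intersect(d$map$gene_id[d$map$protein_id %in% keep_prot], keep_rna)
  expect_setequal(sub$gene_id, oracle)

  bad_map <- id_map("nope", "nothing")
  expect_error(pair_omics(d$norm, d$protein, bad_map), "zero overlap")
})

test_that("stage correlation: exact identities and guard rails", {
  d <- default_fixture()
  p <- d$paired
  p$protein <- p$mrna                   # protein identical to mRNA
  expect_equal(stage_correlation(p, "10DAP")$r, 1)
  p$protein <- -p$mrna           # negated (up to a constant) centred profile
  sc <- stage_correlation(p, "26DAP")
  expect_equal(sc$r, -1, tolerance = 1e-9)
  expect_equal(sc$r_squared, sc$r^2)
  p$mrna <- p$mrna[1:2, , drop = FALSE]
  p$protein <- p$protein[1:2, , drop = FALSE]
  expect_error(stage_correlation(p, "10DAP"), ">= 3 genes")
})

test_that("per-gene correlation: identities, zero variance, loop oracle", {
  d <- default_fixture()
  p <- d$paired
  # protein = affine transform of mRNA profile -> r = 1
  p$protein <- 2 * p$mrna + 3
  r1 <- per_gene_correlation(p)
  expect_true(all(abs(r1$paired$r - 1) < 1e-12))
  expect_equal(r1$summary$fraction_positive, 1)

  # constant protein profile -> undefined, excluded from summary
  p2 <- d$paired
  p2$protein[1, ] <- 5
  r2 <- per_gene_correlation(p2)
  expect_true(is.na(r2$paired$r[1]))
  expect_equal(r2$summary$n_defined, length(p2$gene_id) - 1L)

  # the real fixture against an independent correlation loop
  rp <- per_gene_correlation(d$paired)
  loop <- vapply(seq_along(d$paired$gene_id), function(i)
    cor(d$paired$mrna[i, ], d$paired$protein[i, ]), numeric(1))
  expect_equal(unname(rp$paired$r), loop, tolerance = 1e-12)
  expect_lt(abs(rp$summary$mean_r - mean(loop, na.rm = TRUE)), 1e-12)
})

test_that("enrichment score matches hand and brute-force oracles", {
  # hand-checked fixture: ES = 9/11
  scores <- c(gene1 = 0.9, gene2 = 0.5, gene3 = 0.1, gene4 = -0.2, gene5 = -0.6)
  es <- gsea_enrichment_score(scores, c("gene1", "gene4"))
  expect_equal(es$es, 9 / 11, tolerance = 1e-12)
  expect_identical(es$leading_edge, "gene1")

  # members occupying the whole top -> ES = 1
  es_top <- gsea_enrichment_score(scores, c("gene1", "gene2"))
  expect_equal(es_top$es, 1)

  # random small lists vs the literal running-sum oracle
  set.seed(51)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    sc <- setNames(rnorm(n), paste0("g", seq_len(n)))
    set <- sample(names(sc), sample(2:(n - 2), 1))
    p <- sample(c(0, 1, 1.5), 1)
    expect_equal(gsea_enrichment_score(sc, set, weight_p = p)$es,
                 es_oracle(sc, set, p), tolerance = 1e-12)
  }

  # invariance to uniform positive rescaling at p = 1
  sc <- setNames(rnorm(30), paste0("g", 1:30))
  set <- paste0("g", sample(30, 8))
  expect_equal(gsea_enrichment_score(sc, set)$es,
               gsea_enrichment_score(sc * 7, set)$es, tolerance = 1e-12)

  expect_error(gsea_enrichment_score(sc, names(sc)), "every ranked gene")
  expect_error(gsea_enrichment_score(sc, "absent"), "no overlap")
})

test_that("fast permutation ES agrees with the full running sum", {
  set.seed(52)
  sc <- sort(rnorm(200), decreasing = TRUE)
  names(sc) <- paste0("g", 1:200)
  for (i in 1:30) {
    hits <- sort(sample(200, sample(3:50, 1)))
    expect_equal(ripeomics:::es_from_positions(sc, hits)$es,
                 gsea_enrichment_score(sc, names(sc)[hits])$es,
                 tolerance = 1e-12)
  }
})

test_that("gsea: determinism, p-value floor, size filter", {
  d <- default_fixture()
  pg <- per_gene_correlation(d$paired)
  g1 <- gsea(pg$paired$r, d$gene_sets, n_perm = 200, seed = 7)
  g2 <- gsea(pg$paired$r, d$gene_sets, n_perm = 200, seed = 7)
  expect_identical(g1$es, g2$es)
  expect_identical(g1$nom_p, g2$nom_p)
  expect_true(all(g1$nom_p >= 1 / 201))
  expect_true(all(g1$nom_p <= 1))
  expect_true(all(sign(g1$nes) == sign(g1$es), na.rm = TRUE))
  expect_true(all(g1$size >= 5))
  small <- gene_set_collection(list(TINY = d$paired$gene_id[1:2]))
  expect_error(gsea(pg$paired$r, small, n_perm = 50, seed = 1),
               "size filter")
})

test_that("set Stat.mean equals the member mean of log2 fold changes", {
  d <- default_fixture()
  cr <- d$de_rna[[1]]
  two <- cr$feature_id[1:2]
  fake <- cr; fake$log2FC[1:2] <- c(1, -1)
  expect_equal(set_stat_mean(fake, two)$stat_mean, 0)
  expect_equal(set_stat_mean(fake, two)$direction, 0)
  one <- cr$feature_id[7]
  expect_equal(set_stat_mean(cr, one)$stat_mean, cr$log2FC[7])

  set.seed(53)
  for (i in 1:10) {
    members <- sample(cr$feature_id, 25)
    expect_equal(set_stat_mean(cr, members)$stat_mean,
                 mean(cr$log2FC[match(members, cr$feature_id)]),
                 tolerance = 1e-12)
  }
  expect_error(set_stat_mean(cr, "absent"), "no overlap")
})

test_that("mean per-gene correlation increases with the coupling level", {
  means <- vapply(c(0.2, 0.5, 0.8), function(rho) {
    d <- generate_dataset(simulation_config(
      n_genes = 800, n_proteins = 400, rho = rep(rho, 4),
      decoupled_set_size = 0, aligned_set_size = 20, n_background_sets = 5,
      seed = 77))
    norm <- normalize_counts(d$counts, estimate_size_factors(d$counts))
    pg <- per_gene_correlation(pair_omics(norm, d$protein, d$map))
    pg$summary$mean_r
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("stage-correlation decay is monotone across a 10-seed panel", {
  for (s in 101:110) {
    d <- generate_dataset(simulation_config(seed = s))
    norm <- normalize_counts(d$counts, estimate_size_factors(d$counts))
    sc <- stage_correlation_profile(pair_omics(norm, d$protein, d$map))
    expect_true(all(diff(sc$r) < 0))
  }
})
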