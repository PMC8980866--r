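test_that("generation is a pure function of the config", {
  cfg <- simulation_config(n_genes = 300, n_proteins = 100,
                           decoupled_set_size = 8, aligned_set_size = 15,
                           n_background_sets = 5, seed = 9)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$counts$values, d2$counts$values)
  expect_identical(d1$protein$values, d2$protein$values)
  expect_identical(d1$truth$templates, d2$truth$templates)
  expect_identical(d1$gene_sets$sets, d2$gene_sets$sets)

  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(generate_dataset(cfg2)$counts$values, d1$counts$values))
})

test_that("template allocation matches configured fractions exactly", {
  d <- default_fixture()
  fr <- d$truth$config$template_fractions
  tab <- table(d$truth$templates)
  for (tm in template_names())
    expect_equal(unname(tab[tm]), round(fr[[tm]] * 2000))
  # non-flat fraction is exact, not approximate
  expect_identical(sum(tab[setdiff(template_names(), "flat")]), 1500L)
})

test_that("simulated counts have negative binomial moments", {
  # 10,000 draws at mu ~= 100, phi = 0.1: variance within 15% of mu + phi mu^2
  cfg <- simulation_config(n_genes = 10000, lib_size = 1e6, dispersion = 0.1)
  latent <- matrix(5, 10000, 4, dimnames = list(sprintf("g%05d", 1:10000),
                                                cfg$stages))
  set.seed(11)
  cm <- simulate_counts(latent, cfg)
  x <- cm$values[, 1]
  mu_hat <- mean(x)
  expect_lt(abs(stats::var(x) - (mu_hat + 0.1 * mu_hat^2)) /
              (mu_hat + 0.1 * mu_hat^2), 0.15)

  # Poisson limit at dispersion 0: sample mean within 3 SE of mu
  cfg0 <- simulation_config(n_genes = 10000, lib_size = 1e6, dispersion = 0)
  set.seed(12)
  x0 <- simulate_counts(latent, cfg0)$values[, 1]
  mu0 <- mean(x0)
  expect_lt(abs(stats::var(x0) - mu0), 3 * sqrt(2 * mu0^2 / length(x0)) + 3)
  # zero latent weight -> zero row
  latent2 <- latent; latent2[1, ] <- -Inf
  set.seed(13)
  expect_true(all(simulate_counts(latent2, cfg)$values[1, ] == 0))
})

test_that("protein coupling hits its target correlations", {
  # exact coupling: rho = 1, sigma_p = 0 -> per-gene r between standardized
  # mRNA latent and log2 protein is exactly 1 for every non-constant gene
  cfg <- simulation_config(n_genes = 200, n_proteins = 200, protein_sigma = 0,
                           rho = c(1, 1, 1, 1))
  set.seed(14)
  latent <- matrix(rnorm(200 * 4, 8), 200, 4,
                   dimnames = list(sprintf("g%03d", 1:200), cfg$stages))
  ps <- simulate_proteins(latent, cfg, seed = 15)
  obs <- log2(stage_means(ps$protein))
  r <- vapply(1:200, function(i) cor(ps$z_mrna[i, ], obs[i, ]), numeric(1))
  expect_true(all(abs(r - 1) < 1e-9))

  # rho = 0: mean per-gene r over 2000 genes within 0.1 of 0
  cfg0 <- simulation_config(n_genes = 2000, n_proteins = 2000,
                            rho = c(0, 0, 0, 0))
  set.seed(16)
  latent0 <- matrix(rnorm(2000 * 4, 8), 2000, 4,
                    dimnames = list(sprintf("g%04d", 1:2000), cfg0$stages))
  ps0 <- simulate_proteins(latent0, cfg0, seed = 17)
  obs0 <- log2(stage_means(ps0$protein))
  r0 <- vapply(1:2000, function(i) cor(ps0$z_mrna[i, ], obs0[i, ]), numeric(1))
  expect_lt(abs(mean(r0)), 0.1)

  # default schedule: latent-level across-gene stage correlation recovers
  # each rho_s within 0.05 (the generator's parameter-recovery contract)
  cfgd <- simulation_config(n_genes = 2000, n_proteins = 2000)
  set.seed(18)
  latentd <- matrix(rnorm(2000 * 4, 8, 1.5), 2000, 4,
                    dimnames = list(sprintf("g%04d", 1:2000), cfgd$stages))
  psd <- simulate_proteins(latentd, cfgd, seed = 19)
  for (s in 1:4)
    expect_lt(abs(cor(psd$z_mrna[, s], psd$z_protein[, s]) - cfgd$rho[s]), 0.05)
})

test_that("planted gene sets respect their geometry and truth flags", {
  d <- default_fixture()
  cfg <- d$truth$config
  sizes <- lengths(d$gene_sets$sets[grep("^BG", names(d$gene_sets$sets))])
  expect_true(all(sizes >= cfg$set_size_range[1] & sizes <= cfg$set_size_range[2]))
  for (tm in template_names()) {
    members <- d$gene_sets$sets[[paste0("SET_aligned_", tm)]]
    expect_gte(mean(d$truth$templates[members] == tm), 0.9)
  }
  dec <- d$gene_sets$sets$SET_decoupled
  expect_setequal(dec, d$truth$decoupled_genes)
  # decoupled members are shaped genes with proteins
  expect_true(all(d$truth$templates[dec] != "flat"))
  expect_true(all(dec %in% d$map$gene_id))
  # infeasible geometry errors
  expect_error(simulation_config(n_genes = 10, n_proteins = 5,
                                 decoupled_set_size = 2,
                                 aligned_set_size = 40), "infeasible")
})

test_that("truth DE labels are consistent with the planted latents", {
  d <- default_fixture()
  tr <- d$truth
  # mRNA truth: flat genes unchanged everywhere; monotone_up up everywhere
  expect_true(all(tr$de_mrna[tr$templates == "flat", ] == "unchanged"))
  expect_true(all(tr$de_mrna[tr$templates == "monotone_up", ] == "up"))
  # protein truth labels match the realized latent against FC 1.3 with margin
  thr <- log2(1.3)
  margin <- qt(0.975, 4) * tr$config$protein_sigma * sqrt(2 / 3)
  dlat <- tr$protein_latent_log2[, 2] - tr$protein_latent_log2[, 1]
  lab <- tr$de_protein[, 1]
  expect_true(all(lab[dlat >= thr + margin] == "up"))
  expect_true(all(lab[abs(dlat) <= thr] == "unchanged"))
  expect_true(all(lab[dlat <= -(thr + margin)] == "down"))
})
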