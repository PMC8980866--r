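# Shared fixtures. The default synthetic dataset (fixture seed 42, committed
# before the final generator defaults were evaluated) is generated once per
# test run and cached, together with its normalized counts and paired omics.

fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(fixture_cache$d)) {
    d <- generate_dataset(simulation_config(seed = 42))
    d$size_factors <- estimate_size_factors(d$counts)
    d$norm <- normalize_counts(d$counts, d$size_factors)
    d$paired <- pair_omics(d$norm, d$protein, d$map)
    st <- d$counts$stages
    d$de_rna <- lapply(seq_len(3), function(i)
      test_differential_expression(d$norm, st[i], st[i + 1]))
    d$de_protein <- lapply(seq_len(3), function(i)
      test_differential_abundance(d$protein, st[i], st[i + 1]))
    fixture_cache$d <- d
  }
  fixture_cache$d
}

# Small expression matrix with a 2-stage x 2-replicate layout.
tiny_matrix <- function(values, kind = "counts",
                        stages = rep(c("A", "B"), each = ncol(values) / 2)) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  meta <- data.frame(sample_id = colnames(values), stage = stages,
                     replicate = stats::ave(seq_along(stages), stages,
                                            FUN = seq_along))
  expression_matrix(values, meta, kind)
}

random_matrix <- function(n, m, seed, lambda = 50) {
  set.seed(seed)
  matrix(rpois(n * m, lambda), n, m,
         dimnames = list(paste0("g", seq_len(n)), paste0("s", seq_len(m))))
}

# Protein-ID keyed truth labels for a contrast column of truth$de_protein.
protein_truth <- function(truth, contrast) {
  lab <- truth$de_protein[, contrast]
  names(lab) <- sub("^gene", "prot", rownames(truth$de_protein))
  lab
}
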