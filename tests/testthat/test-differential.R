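test_that("size factors follow median-of-ratios with unit geometric mean", {
  v <- random_matrix(30, 2, seed = 21)
  v <- cbind(v, v[, 1, drop = FALSE] + 0)  # s3 identical to s1
  colnames(v) <- c("s1", "s2", "s3")
  em <- tiny_matrix(v + 1, stages = c("A", "A", "B"))
  s <- estimate_size_factors(em)
  expect_equal(unname(s["s1"]), unname(s["s3"]))
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-6)

  # sample B exactly 2 x sample A -> (1/sqrt(2), sqrt(2))
  a <- rpois(40, 100) + 1
  em2 <- tiny_matrix(cbind(s1 = a, s2 = 2 * a), stages = c("A", "B"))
  s2 <- estimate_size_factors(em2)
  expect_equal(unname(s2), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # random 50 x 6 equals a literal median-of-ratios loop
  v <- random_matrix(50, 6, seed = 22) + 1
  em3 <- tiny_matrix(v, stages = rep(c("A", "B", "C"), each = 2))
  s3 <- estimate_size_factors(em3)
  geo <- apply(v, 1, function(r) exp(mean(log(r))))
  usable <- apply(v, 1, function(r) all(r > 0))
  oracle <- vapply(seq_len(6), function(j) median(v[usable, j] / geo[usable]),
                   numeric(1))
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(unclass(s3)), oracle, tolerance = 1e-12)

  # all genes touched by zeros -> error
  vz <- diag(5); dimnames(vz) <- list(paste0("g", 1:5), paste0("s", 1:5))
  expect_error(estimate_size_factors(
    tiny_matrix(vz, stages = c("A", "A", "B", "B", "B"))), "pseudo-reference")
})

test_that("normalization is exact and invertible", {
  v <- random_matrix(20, 4, seed = 23) + 1
  em <- tiny_matrix(v)
  s <- structure(setNames(rep(1, 4), colnames(v)), class = "size_factors")
  expect_identical(normalize_counts(em, s)$values, em$values)

  em2 <- em; em2$values[, 2] <- em2$values[, 2] * 2
  s2 <- structure(setNames(c(1, 2, 1, 1), colnames(v)), class = "size_factors")
  expect_equal(normalize_counts(em2, s2)$values, v, tolerance = 1e-12)

  a <- rpois(30, 80) + 1
  emb <- tiny_matrix(cbind(s1 = a, s2 = 2 * a), stages = c("A", "B"))
  nb <- normalize_counts(emb, estimate_size_factors(emb))
  expect_equal(sum(nb$values[, 1]), sum(nb$values[, 2]), tolerance = 1e-9)
})

test_that("Welch DE calling: identities, boundaries and label swap", {
  set.seed(24)
  v <- matrix(rpois(60, 200), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  v[, 4:6] <- v[, 1:3]   # B identical to A
  em <- tiny_matrix(v)
  res <- test_differential_expression(em, "A", "B")
  expect_true(all(res$log2FC == 0))
  expect_true(all(res$status == "unchanged"))
  expect_true(all(res$padj >= res$p))

  # exact log2FC = 1 with tiny p stays unchanged (strict >)
  v2 <- cbind(matrix(3, 2, 3), matrix(7, 2, 3))
  dimnames(v2) <- list(c("g1", "g2"), paste0("s", 1:6))
  r2 <- test_differential_expression(tiny_matrix(v2), "A", "B")
  expect_equal(r2$log2FC, c(1, 1))
  expect_true(all(r2$status == "unchanged"))

  # swapping group labels negates log2FC and swaps statuses
  d <- default_fixture()
  fwd <- d$de_rna[[1]]
  rev <- test_differential_expression(d$norm, "18DAP", "10DAP")
  expect_equal(rev$log2FC, -fwd$log2FC)
  expect_identical(rev$status == "up", fwd$status == "down")
  expect_equal(rev$p, fwd$p)

  # < 2 replicates errors
  em1 <- tiny_matrix(v[, c(1, 4, 5), drop = FALSE], stages = c("A", "B", "B"))
  expect_error(test_differential_expression(em1, "A", "B"), ">= 2 replicates")
})

test_that("row-wise Welch p-values agree with stats::t.test", {
  set.seed(25)
  a <- matrix(rnorm(50 * 3, 5), 50, 3)
  b <- matrix(rnorm(50 * 3, 5.5), 50, 3)
  w <- ripeomics:::row_welch_t(a, b)
  oracle <- vapply(1:50, function(i) t.test(b[i, ], a[i, ])$p.value, numeric(1))
  expect_equal(w$p, oracle, tolerance = 1e-12)
})

test_that("protein DA calling honours FC boundary and raw-p gating", {
  v <- cbind(matrix(10, 3, 3), matrix(13, 3, 3))
  dimnames(v) <- list(paste0("p", 1:3), paste0("s", 1:6))
  r <- test_differential_abundance(tiny_matrix(v, kind = "protein_intensity"),
                                   "A", "B")
  expect_equal(r$FC, rep(1.3, 3))
  expect_true(all(r$status == "unchanged"))  # FC exactly 1.3 is not "more than"

  v[, 4:6] <- v[, 1:3]
  r0 <- test_differential_abundance(tiny_matrix(v, kind = "protein_intensity"),
                                    "A", "B")
  expect_true(all(r0$status == "unchanged"))

  vneg <- v; vneg[1, 1] <- 0
  expect_error(test_differential_abundance(
    tiny_matrix(vneg, kind = "protein_intensity"), "A", "B"), "non-positive")

  # planted two-fold protein with low noise is called up
  set.seed(26)
  base <- matrix(2^(10 + rnorm(60 * 3, 0, 0.1)), 60, 3)
  fold <- rep(c(2, 1), each = 30)          # first half planted two-fold
  v2 <- cbind(base, base * fold * 2^rnorm(60 * 3, 0, 0.1))
  dimnames(v2) <- list(paste0("p", 1:60), paste0("s", 1:6))
  r2 <- test_differential_abundance(tiny_matrix(v2, kind = "protein_intensity"),
                                    "A", "B")
  expect_gt(mean(r2$status[1:30] == "up"), 0.9)
  expect_lt(mean(r2$status[31:60] != "unchanged"), 0.1)
})

test_that("venn regions partition the union", {
  s <- paste0("x", 1:7)
  r <- venn_regions(s, s, s)
  expect_equal(unname(r["111"]), 7L)
  expect_equal(sum(r), 7L)

  r2 <- venn_regions(c("a", "b"), c("c"), c("d", "e", "f"))
  expect_equal(unname(r2[c("100", "010", "001")]), c(2L, 1L, 3L))
  expect_equal(sum(r2[c("110", "101", "011", "111")]), 0L)

  set.seed(27)
  u <- paste0("g", 1:40)
  s1 <- sample(u, 15); s2 <- sample(u, 20); s3 <- sample(u, 10)
  r3 <- venn_regions(s1, s2, s3)
  oracle <- table(factor(paste0(
    as.integer(u %in% s1), as.integer(u %in% s2), as.integer(u %in% s3)),
    levels = c("100", "010", "001", "110", "101", "011", "111")))
  keep <- unique(c(u[u %in% c(s1, s2, s3)]))
  expect_equal(sum(r3), length(keep))
  expect_equal(as.integer(r3), as.integer(oracle))
})

test_that("DEG/DEP recovery on the default fixture is sane", {
  d <- default_fixture()
  m <- de_recovery_metrics(d$de_rna[[1]], d$truth$de_mrna[, 1])
  # BH-gated Welch at 3 replicates and phi = 0.1 has limited power (see the
  # methods vignette); false discoveries stay rare
  expect_gt(m$sensitivity, 0.5)
  expect_lt(m$fdp, 0.05)
  mp <- de_recovery_metrics(d$de_protein[[1]], protein_truth(d$truth, 1))
  expect_gt(mp$sensitivity, 0.9)
  expect_lt(mp$fdp, 0.1)
})

test_that("type-I error is calibrated on an all-flat null", {
  fr <- c(monotone_up = 0, monotone_down = 0, early_peak = 0, late_peak = 0,
          transient_dip = 0, flat = 1)
  dn <- generate_dataset(simulation_config(seed = 43, template_fractions = fr,
                                           decoupled_set_size = 0))
  nn <- normalize_counts(dn$counts, estimate_size_factors(dn$counts))
  den <- test_differential_expression(nn, "10DAP", "18DAP")
  expect_gte(mean(den$p < 0.05), 0.03)
  expect_lte(mean(den$p < 0.05), 0.07)
})
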