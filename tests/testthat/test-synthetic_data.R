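test_that("simulate_genome plants the promised structure, reproducibly", {
  sim <- simulate_genome(n_chrom = 2, genes_per_chrom = 60,
                         n_tandem_arrays = 1, tandem_array_len = 3,
                         n_segments = 0, n_noise_pairs = 0, seed = 3)
  truth_t <- sim$truth[sim$truth$true_type == "tandem", ]
  expect_equal(nrow(truth_t), 2)  # a run of 3 genes -> 2 consecutive pairs
  ra <- sim$registry$rank[match(truth_t$gene_a, sim$registry$gene_id)]
  rb <- sim$registry$rank[match(truth_t$gene_b, sim$registry$gene_id)]
  expect_true(all(abs(ra - rb) == 1))

  sim2 <- simulate_genome(n_chrom = 2, genes_per_chrom = 60,
                          n_tandem_arrays = 1, tandem_array_len = 3,
                          n_segments = 0, n_noise_pairs = 0, seed = 3)
  expect_identical(sim, sim2)
})

test_that("a planted 8-anchor segment with zero noise is recovered as one block", {
  sim <- simulate_genome(n_chrom = 3, genes_per_chrom = 100,
                         n_tandem_arrays = 0, n_segments = 1,
                         segment_anchors = 8, n_noise_pairs = 0, seed = 11)
  res <- chain_collinear_blocks(sim$registry, sim$pairs, min_block_size = 5)
  expect_equal(nrow(res$blocks), 1)
  expect_equal(res$blocks$n_anchors, 8)
})

test_that("segment recovery tolerates random noise anchors", {
  sim <- simulate_genome(n_chrom = 3, genes_per_chrom = 150,
                         n_tandem_arrays = 0, n_segments = 1,
                         segment_anchors = 8, n_noise_pairs = 50, seed = 13)
  res <- chain_collinear_blocks(sim$registry, sim$pairs, min_block_size = 5)
  key <- function(d) paste(pmin(d$gene_a, d$gene_b), pmax(d$gene_a, d$gene_b))
  truth_s <- sim$truth[sim$truth$true_type == "segmental", ]
  expect_gte(sum(key(res$anchors) %in% key(truth_s)), 7)
})

test_that("simulate_codon_pair: zero divergence, validation, determinism", {
  sim0 <- simulate_codon_pair(n_codons = 50, omega = 0.5, ks_target = 0,
                              seed = 2)
  expect_identical(sim0$a, sim0$b)
  r <- nei_gojobori(sim0$alignment)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_error(simulate_codon_pair(omega = 0), "omega")
  expect_error(simulate_codon_pair(ks_target = -1), "ks_target")
  s1 <- simulate_codon_pair(n_codons = 40, seed = 9)
  s2 <- simulate_codon_pair(n_codons = 40, seed = 9)
  expect_identical(s1, s2)
})

test_that("simulated divergence lands near the Ks target", {
  set.seed(1)
  ks <- vapply(1:20, function(i) {
    sim <- simulate_codon_pair(n_codons = 300, omega = 0.2, ks_target = 0.3,
                               seed = 100 + i)
    nei_gojobori(sim$alignment)$Ks
  }, 0)
  expect_gt(median(ks), 0.2)
  expect_lt(median(ks), 0.4)
})

test_that("simulate_ct_table: exact recovery at zero noise, flat reference, determinism", {
  lf <- matrix(c(0, 1, -2, 0, 0.5, 2), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("cal", "c1", "c2")))
  sim <- simulate_ct_table(lf, noise_sd = 0, seed = 4)
  folds <- delta_delta_ct(sim$table)
  expect_equal(log2(folds), lf[rownames(folds), colnames(folds)],
               ignore_attr = TRUE)
  expect_equal(folds["g1", "c1"], 2)

  # planted fold 1 everywhere -> all ns
  lf1 <- matrix(0, 2, 3, dimnames = dimnames(lf))
  calls <- call_regulation(delta_delta_ct(simulate_ct_table(lf1, noise_sd = 0,
                                                            seed = 5)$table))
  expect_true(all(calls$call == "ns"))

  expect_error(simulate_ct_table(lf, noise_sd = -1), "noise")
  bad <- lf; bad[1, 1] <- 1
  expect_error(simulate_ct_table(bad), "calibrator")

  a <- simulate_ct_table(lf, seed = 6)
  b <- simulate_ct_table(lf, seed = 6)
  expect_identical(a, b)
})

test_that("noisy Ct recovery is unbiased within 0.1 log2 at sd 0.2 (3x3 design)", {
  lf <- matrix(c(0, 1, -1.5, 0, 2, 0.58), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("cal", "c1", "c2")))
  errs <- numeric(0)
  for (i in 1:200) {
    sim <- simulate_ct_table(lf, n_bio = 3, n_tech = 3, noise_sd = 0.2,
                             seed = 5000 + i)
    est <- log2(delta_delta_ct(sim$table))
    diff <- est - lf[rownames(est), colnames(est)]
    errs <- c(errs, diff[, colnames(est) != "cal"])
  }
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("planted correlation classes are recovered from shared+independent profiles", {
  # profiles = sqrt(rho) * shared + sqrt(1-rho) * independent: E[r] = rho
  # profile length 40 = the combined abiotic (3x5) + hormone (5x5) series
  set.seed(21)
  for (rho in c(0.05, 0.8)) {
    hits <- 0; n <- 200
    for (i in 1:n) {
      z <- rnorm(40)
      a <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(40)
      b <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(40)
      want <- classify_divergence(rho)
      if (classify_divergence(pair_expression_correlation(a, b)) == want)
        hits <- hits + 1
    }
    expect_gte(hits / n, 0.9)
  }
})
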