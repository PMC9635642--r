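test_that("simulation configs validate their fractions and sizes", {
  expect_error(sim_config(h2_direct = 0.6, t2_mediated = 0.6, coupling = 1),
               "<= 1")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(generation_sizes = c(`1` = 10)), "sum")
  expect_error(sim_config(n_individuals = 0,
                          generation_sizes = c(`1` = 0)), "empty")
  cfg <- sim_config(n_individuals = 40, generation_sizes = c(`1` = 40))
  expect_s3_class(cfg, "sim_config")
})

test_that("genotype dosages have the configured frequency and are seeded", {
  cfg <- sim_config(n_individuals = 400, n_markers = 60,
                    maf_range = c(0.5, 0.5), ld_autocorr = 0,
                    family_fst = 0, generation_sizes = c(`1` = 400L),
                    seed = 3)
  X <- simulate_genotypes(cfg)
  expect_true(all(unclass(X) %in% 0:2))
  # binomial mean 2p = 1 within 3 SE of the mean over 400 x 60 draws
  se <- sqrt(0.5 / (400 * 60))
  expect_lt(abs(mean(unclass(X)) - 1), 3 * se)
  expect_identical(unclass(simulate_genotypes(cfg)), unclass(X))
})

test_that("the Markov copy rule induces adjacent-marker correlation", {
  cfg <- sim_config(n_individuals = 300, n_markers = 500,
                    ld_autocorr = 0.9, family_fst = 0,
                    generation_sizes = c(`1` = 300L), seed = 5)
  X <- unclass(simulate_genotypes(cfg))
  r <- vapply(2:500, function(j) {
    out <- suppressWarnings(stats::cor(X[, j - 1], X[, j]))
    if (is.na(out)) 0 else out
  }, numeric(1))
  expect_gt(mean(r), 0.5)
})

test_that("family structure induces within-litter genotype similarity", {
  cfg <- sim_config(n_individuals = 160, n_markers = 300, ld_autocorr = 0,
                    litter_size = 8, family_fst = 1/3,
                    generation_sizes = c(`1` = 160L), seed = 6)
  X <- simulate_genotypes(cfg)
  fam <- attr(X, "family")
  G <- build_genomic_kernel(center_standardize(X))$values
  same <- outer(fam, fam, "==") & upper.tri(G)
  diff_ <- (!outer(fam, fam, "==")) & upper.tri(G)
  # full-sib target relationship is ~0.5; unrelated pairs ~0
  expect_gt(mean(G[same]), 0.3)
  expect_lt(abs(mean(G[diff_])), 0.1)
})

test_that("transcript genetic share tracks prop_cis", {
  cfg0 <- sim_config(n_individuals = 150, n_markers = 40, n_genes = 50,
                     generation_sizes = c(`1` = 150L), prop_cis = 0,
                     seed = 7)
  Z <- rand_std(150, 40, seed = 70)
  tr0 <- simulate_transcripts(Z, cfg0)
  # prop_cis = 0: per-gene regression R2 on Z indistinguishable from a
  # permuted-genotype baseline
  r2_on <- function(W, Zv) {
    mean(vapply(seq_len(ncol(W)), function(j)
      summary(stats::lm(W[, j] ~ Zv))$r.squared, numeric(1)))
  }
  W0 <- unclass(tr0$transcripts)
  set.seed(71)
  Zperm <- Z$values[sample.int(150), ]
  expect_lt(abs(r2_on(W0, Z$values) - r2_on(W0, Zperm)), 0.05)

  cfg1 <- sim_config(n_individuals = 150, n_markers = 40, n_genes = 50,
                     generation_sizes = c(`1` = 150L), prop_cis = 1, seed = 7)
  tr1 <- simulate_transcripts(Z, cfg1)
  # pure genetic genes: rank-Z output is a monotone map of the genetic value
  cors <- vapply(1:50, function(j)
    stats::cor(unclass(tr1$transcripts)[, j], tr1$genetic_values[, j]),
    numeric(1))
  expect_gt(min(cors), 0.95)
})

test_that("empirical per-gene genetic R2 is near prop_cis = 0.5", {
  cfg <- sim_config(n_individuals = 200, n_markers = 60, n_genes = 200,
                    generation_sizes = c(`1` = 200L), prop_cis = 0.5,
                    seed = 8)
  Z <- rand_std(200, 60, seed = 80)
  tr <- simulate_transcripts(Z, cfg)
  r2 <- vapply(1:200, function(j)
    stats::cor(unclass(tr$transcripts)[, j], tr$genetic_values[, j])^2,
    numeric(1))
  expect_lt(abs(mean(r2) - 0.5), 0.1)
})

test_that("phenotype composition follows the configured fractions", {
  cfg <- sim_config(n_individuals = 200, n_markers = 50, n_genes = 40,
                    generation_sizes = c(`1` = 200L),
                    h2_direct = 1, t2_mediated = 0, gt2 = 0, coupling = 0,
                    seed = 9)
  Z <- rand_std(200, 50, seed = 90)
  tr <- simulate_transcripts(Z, cfg)
  ph <- simulate_phenotype(Z, tr$transcripts, cfg)
  # pure genetic trait: y reproducible from the recorded effects, no noise
  expect_equal(unname(ph$phenotype), unname(ph$truth$g_direct))
  expect_equal(stats::var(ph$truth$residual), 0)

  cfg2 <- sim_config(n_individuals = 200, n_markers = 50, n_genes = 40,
                     generation_sizes = c(`1` = 200L),
                     h2_direct = 0.3, t2_mediated = 0.4, coupling = 0,
                     seed = 9)
  ph2 <- simulate_phenotype(Z, tr$transcripts, cfg2)
  # severed transcript path: the mediated component is exactly zero
  expect_equal(stats::var(ph2$truth$t_effect), 0)
  expect_equal(unname(ph2$truth$fractions["t2_mediated"]), 0)
})

test_that("realized variance fractions match the configuration", {
  devs <- vapply(101:110, function(seed) {
    cfg <- sim_config(n_individuals = 400, n_markers = 80, n_genes = 50,
                      generation_sizes = c(`1` = 400L),
                      h2_direct = 0.25, t2_mediated = 0.4, coupling = 1,
                      gt2 = 0.1, seed = seed)
    st <- simulate_study(cfg)
    fr <- st$truth$fractions
    max(abs(fr[c("h2_direct", "t2_mediated", "gt2")] - c(0.25, 0.4, 0.1)))
  }, numeric(1))
  expect_lt(mean(devs), 0.05)
})

test_that("simulated studies have the configured generation sizes and seed", {
  st <- simulate_study(sim_config(n_individuals = 478, n_markers = 50,
                                  n_genes = 20, seed = 2))
  expect_equal(unname(table(st$generations)[c("4", "5", "7", "11")]),
               c(47L, 47L, 192L, 192L), ignore_attr = TRUE)
  expect_equal(length(st$phenotype), 478)
  st2 <- simulate_study(sim_config(n_individuals = 478, n_markers = 50,
                                   n_genes = 20, seed = 2))
  expect_identical(st$phenotype, st2$phenotype)
  expect_identical(unclass(st$genotypes), unclass(st2$genotypes))
  expect_identical(unclass(st$transcripts), unclass(st2$transcripts))
})
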