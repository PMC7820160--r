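no_miss <- function(n_loci, n_ind) {
  list(ml = rep(0, n_loci), mi = rep(0, n_ind))
}

test_that("identical config and seed give bit-identical datasets", {
  cfg <- sim_config(seed = 123, n_loci = 50, n_generations = 40)
  d1 <- simulate_metapopulation(cfg)
  d2 <- simulate_metapopulation(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_metapopulation(sim_config(seed = 124, n_loci = 50,
                                           n_generations = 40))
  expect_false(identical(d1$genotypes, d3$genotypes))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_islands = 1, island_positions = 0,
                          n_diploids_per_island = 5, model_abundance = 1,
                          females_per_island = 10), ">= 2")
  expect_error(sim_config(island_positions = c(0, 150, 150, 750, 765)),
               "increasing")
  # migration fractions exceeding 1
  expect_error(sim_config(n_islands = 2, island_positions = c(0, 1),
                          n_diploids_per_island = c(5, 5),
                          migration_rate_per_km = 3,
                          missing_locus_rates = rep(0, 240),
                          missing_individual_rates = rep(0, 10),
                          model_abundance = c(1, 1),
                          females_per_island = c(10, 10)), "exceed 1")
  expect_error(sim_config(n_diploids_per_island = c(101, 46, 12, 14, 12)),
               "effective size")
  expect_error(sim_config(missing_locus_rates = rep(1.5, 240)), "\\[0, 1\\]")
})

test_that("isolated demes drift to strong differentiation", {
  fst <- vapply(1:20, function(s) {
    cfg <- sim_config(n_islands = 2, island_positions = c(0, 100),
                      n_diploids_per_island = c(20, 20), n_loci = 100,
                      n_generations = 500, effective_size = 50,
                      migration_rate_per_km = 0, mutation_rate = 0,
                      missing_locus_rates = rep(0, 100),
                      missing_individual_rates = rep(0, 40),
                      model_abundance = c(5, 5),
                      females_per_island = c(20, 20), seed = 1000 + s)
    ds <- simulate_metapopulation(cfg)
    pi <- pairwise_pi(ds$genotypes, ds$islands)
    slatkin_fst(pi)["isl1", "isl2"]
  }, numeric(1))
  expect_gt(mean(fst), 0.5)
})

test_that("panmictic migration keeps F_ST near zero", {
  fst <- vapply(1:20, function(s) {
    cfg <- sim_config(n_islands = 2, island_positions = c(0, 1),
                      n_diploids_per_island = c(20, 20), n_loci = 100,
                      n_generations = 100, effective_size = 50,
                      migration_rate_per_km = 0.5,  # 0.5 each way: panmixia
                      missing_locus_rates = rep(0, 100),
                      missing_individual_rates = rep(0, 40),
                      model_abundance = c(5, 5),
                      females_per_island = c(20, 20), seed = 2000 + s)
    ds <- simulate_metapopulation(cfg)
    pi <- pairwise_pi(ds$genotypes, ds$islands)
    slatkin_fst(pi)["isl1", "isl2"]
  }, numeric(1))
  se <- sd(fst) / sqrt(length(fst))
  expect_lt(abs(mean(fst)), 3 * se + 1e-3)
})

test_that("without migration and mutation the allele count is a martingale", {
  n_rep <- 100
  final_mean <- vapply(1:n_rep, function(s) {
    cfg <- sim_config(n_islands = 2, island_positions = c(0, 100),
                      n_diploids_per_island = c(10, 10), n_loci = 20,
                      n_generations = 50, effective_size = 50,
                      migration_rate_per_km = 0, mutation_rate = 0,
                      missing_locus_rates = rep(0, 20),
                      missing_individual_rates = rep(0, 20),
                      model_abundance = c(5, 5),
                      females_per_island = c(20, 20), seed = 3000 + s)
    ds <- simulate_metapopulation(cfg)
    mean(ds$truth$allele_freq_final)
  }, numeric(1))
  se <- sd(final_mean) / sqrt(n_rep)
  expect_lt(abs(mean(final_mean) - 0.5), 3 * se)
})

test_that("phenotype assignment is Binomial(females, MR)", {
  expect_equal(assign_phenotypes(0, 50, 10, "a", seed = 1)$n_mimic, 0L)
  expect_equal(assign_phenotypes(1, 50, 10, "a", seed = 1)$n_mimic, 50L)
  ct <- assign_phenotypes(c(0.2, 0.8), c(100, 200), c(5, 10), seed = 2)
  expect_equal(ct$n_mimic + ct$n_nonmimic, c(100L, 200L))
  expect_equal(ct$n_model, c(5L, 10L))

  frac <- vapply(1:50, function(s) {
    assign_phenotypes(0.4, 1000, 1, "a", seed = s)$n_mimic / 1000
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.4), 3 * sqrt(0.4 * 0.6 / 1000))
  expect_error(assign_phenotypes(1.4, 10, 1), "\\[0, 1\\]")
})

test_that("missingness injection follows the per-cell product rule", {
  x <- random_snp_matrix(20, 30, seed = 6)
  expect_identical(inject_missingness(x, rep(0, 30), rep(0, 20), seed = 1), x)

  one_row <- inject_missingness(x, rep(0, 30), c(1, rep(0, 19)), seed = 1)
  expect_true(all(is.na(one_row[1, ])))
  expect_equal(sum(is.na(one_row)), 30L)

  big <- random_snp_matrix(200, 500, seed = 7)
  out <- inject_missingness(big, rep(0.2, 500), rep(0, 200), seed = 2)
  frac <- mean(is.na(out))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / (200 * 500)))

  expect_error(inject_missingness(x, rep(0, 10), rep(0, 20)), "match")
})

test_that("equilibrium mimic ratios track model abundance", {
  mr <- equilibrium_mr(c(5, 50, 500), c(100, 100, 100), noise_sd = 0,
                       seed = 1)
  expect_true(all(diff(mr) > 0))
  # noise-free fixed point MR = AI solves F*MR^2 + M*MR - M = 0
  M <- 5; F_ <- 100
  expect_equal(mr[1], (-M + sqrt(M^2 + 4 * F_ * M)) / (2 * F_),
               tolerance = 1e-8)
  expect_true(all(mr > 0 & mr < 1))
  # at the solution, MR and the realized AI are logit-linked exactly
  ai <- 50 / (100 * mr[2] + 50)
  expect_equal(qlogis(mr[2]), qlogis(ai), tolerance = 1e-8)
})

test_that("dataset labels are mutually consistent", {
  ds <- quick_dataset(seed = 21, n_loci = 40, n_generations = 40)
  expect_setequal(rownames(ds$genotypes), ds$islands$individual)
  expect_setequal(unique(ds$islands$island), rownames(ds$geography))
  expect_setequal(ds$counts$island, rownames(ds$geography))
  expect_true(all(ds$truth$equilibrium_mr >= 0 &
                    ds$truth$equilibrium_mr <= 1))
  paths <- write_simulated_dataset(ds, withr::local_tempdir(), "vcf")
  back <- read_genotypes(paths[["genotypes"]])
  expect_equal(unclass(back)[, ], unclass(ds$genotypes)[, ])
})
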