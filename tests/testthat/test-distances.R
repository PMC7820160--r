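test_that("pairwise differences match closed-form toys", {
  # identical monomorphic groups -> pi_XY = 0
  x <- snp_matrix(matrix(0L, 4, 3))
  pi0 <- pairwise_pi(x, two_island_table(x, 2))
  expect_equal(pi0$between["north", "south"], 0)

  # 4 sites, opposite fixation at exactly one -> pi_XY = 1, D_A = 1
  m <- matrix(0L, 4, 4)
  m[3:4, 1] <- 2L
  x1 <- snp_matrix(m)
  pi1 <- pairwise_pi(x1, two_island_table(x1, 2))
  expect_equal(pi1$between["north", "south"], 1)
  da <- nei_DA(pi1)
  expect_equal(da["north", "south"], 1)
  expect_equal(diag(da), c(north = 0, south = 0))
  # fixed-difference toy: Phi_ST = F_ST = 1, linearized infinite
  expect_equal(phi_st(pi1)["north", "south"], 1)
  expect_warning(lf <- slatkin_fst(pi1, linearize = TRUE), "infinite")
  expect_equal(lf["north", "south"], Inf)
})

test_that("frequency formula equals allele-pair enumeration on random toys", {
  for (s in 1:50) {
    x <- random_snp_matrix(6, 10, seed = 100 + s)
    isl <- two_island_table(x, 3)
    pi <- pairwise_pi(x, isl)
    X <- unclass(x)[1:3, , drop = FALSE]
    Y <- unclass(x)[4:6, , drop = FALSE]
    expect_equal(pi$between["north", "south"], brute_pi_between(X, Y),
                 tolerance = 1e-12)
    expect_equal(pi$between["north", "north"], brute_pi_within(X),
                 tolerance = 1e-12)
    da <- nei_DA(pi)
    expect_equal(da["north", "south"],
                 brute_pi_between(X, Y) -
                   (brute_pi_within(X) + brute_pi_within(Y)) / 2,
                 tolerance = 1e-12)
    expect_lte(da["north", "south"], pi$between["north", "south"] + 1e-12)
  }
})

test_that("Phi_ST is the stated ratio and handles degenerate pairs", {
  pi <- structure(list(
    labels = c("a", "b"),
    between = matrix(c(0.5, 1, 1, 0.5), 2, 2,
                     dimnames = list(c("a", "b"), c("a", "b"))),
    within_pair = matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
                         dimnames = list(c("a", "b"), c("a", "b"))),
    n_sites = matrix(4L, 2, 2), n_dropped = matrix(0L, 2, 2),
    per_site = FALSE), class = "pairwise_pi")
  expect_equal(phi_st(pi)["a", "b"], 0.5)

  # identical populations: D_A = 0, pi_XY = 0 handled by convention
  x <- snp_matrix(matrix(0L, 4, 2))
  pid <- pairwise_pi(x, two_island_table(x, 2))
  expect_equal(phi_st(pid)["north", "south"], 0)
})

test_that("F_ST linearization is F/(1-F) and negatives are not clamped", {
  x <- random_snp_matrix(10, 40, seed = 7)
  isl <- two_island_table(x, 5)
  pi <- pairwise_pi(x, isl)
  f <- slatkin_fst(pi)
  lf <- slatkin_fst(pi, linearize = TRUE)
  expect_equal(lf["north", "south"],
               f["north", "south"] / (1 - f["north", "south"]))
  # random split of one panmictic pool: small, possibly negative F_ST
  expect_lt(abs(f["north", "south"]), 0.2)
})

test_that("per-site scaling divides by the number of sites used", {
  x <- random_snp_matrix(6, 10, seed = 9)
  isl <- two_island_table(x, 3)
  pi_sum <- pairwise_pi(x, isl)
  pi_site <- pairwise_pi(x, isl, per_site = TRUE)
  expect_equal(pi_site$between["north", "south"],
               pi_sum$between["north", "south"] / 10)
})

test_that("split halves of a panmictic deme give D_A centered on zero", {
  # two demes exchanging half their copies each generation are one pool;
  # the sampled "islands" are then split halves of that pool. (Plain
  # uniform-call toys will not do: their heterozygote deficit biases the
  # distinct-copy within-pi estimator relative to the cross-group pi.)
  da <- vapply(seq_len(100), function(s) {
    cfg <- sim_config(n_islands = 2, island_positions = c(0, 1),
                      n_diploids_per_island = c(10, 10), n_loci = 20,
                      n_generations = 50, effective_size = 50,
                      migration_rate_per_km = 0.5,
                      missing_locus_rates = rep(0, 20),
                      missing_individual_rates = rep(0, 20),
                      model_abundance = c(5, 5),
                      females_per_island = c(20, 20), seed = 9000 + s)
    ds <- simulate_metapopulation(cfg)
    nei_DA(pairwise_pi(ds$genotypes, ds$islands))["isl1", "isl2"]
  }, numeric(1))
  se <- sd(da) / sqrt(length(da))
  expect_lt(abs(mean(da)), 3 * se)
})

test_that("differentiation rises as migration falls (two-island grid)", {
  mig_grid <- c(2, 0.5, 0.1, 0.02, 0.005)
  mean_fst <- vapply(mig_grid, function(mr) {
    mean(vapply(1:8, function(s) {
      cfg <- sim_config(n_islands = 2, island_positions = c(0, 10),
                       n_diploids_per_island = c(15, 15), n_loci = 80,
                       n_generations = 150, effective_size = 50,
                       migration_rate_per_km = mr,
                       missing_locus_rates = rep(0, 80),
                       missing_individual_rates = rep(0, 30),
                       model_abundance = c(10, 10),
                       females_per_island = c(50, 50), seed = s)
      ds <- simulate_metapopulation(cfg)
      pi <- pairwise_pi(ds$genotypes, ds$islands)
      slatkin_fst(pi)["isl1", "isl2"]
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(seq_along(mig_grid), mean_fst, method = "spearman"), 0.9)
})
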