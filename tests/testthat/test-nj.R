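test_that("three-leaf tree solves the closed-form branch lengths", {
  D <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  el <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(el[c("a", "b", "c")], c(a = 0, b = 2, c = 3))
})

test_that("NJ recovers a four-leaf additive tree exactly", {
  # tree ((a:1,b:2):1,c:3,d:4) -> additive distances
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 3
  D["a", "c"] <- D["c", "a"] <- 5
  D["a", "d"] <- D["d", "a"] <- 6
  D["b", "c"] <- D["c", "b"] <- 6
  D["b", "d"] <- D["d", "b"] <- 7
  D["c", "d"] <- D["d", "c"] <- 7
  tr <- neighbor_joining(D)
  expect_equal(tree_path_matrix(tr), D, tolerance = 1e-9)
  # a,b form a cherry
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))
})

test_that("NJ is exact on random additive matrices", {
  set.seed(20)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    D <- random_additive_matrix(n)
    tr <- neighbor_joining(D)
    expect_lt(max(abs(tree_path_matrix(tr) - D)), 1e-8)
  }
})

test_that("NJ agrees with an independent implementation on a generic matrix", {
  set.seed(31)
  D <- random_additive_matrix(7)
  D[upper.tri(D)] <- D[upper.tri(D)] + runif(21, 0, 0.05)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  ours <- neighbor_joining(D)
  ref <- ape::nj(as.dist(D))
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(tree_path_matrix(ours)), sort(tree_path_matrix(ref)),
               tolerance = 1e-8)
})

test_that("NJ input validation and clamping behave", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(D), ">= 3")
  Dbad <- random_additive_matrix(4)
  Dbad[1, 2] <- Dbad[1, 2] + 1  # asymmetric
  expect_error(neighbor_joining(Dbad), "symmetric")

  # near-degenerate matrix can yield negative branches; clamping zeroes them
  Dn <- matrix(c(0, 1, 1, 4, 1, 0, 1, 1, 1, 1, 0, 1, 4, 1, 1, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(Dn, clamp_negative = TRUE)
  expect_true(all(tr$edge.length >= 0))
})

test_that("single-replicate and constant-site bootstraps are degenerate", {
  ds <- quick_dataset(seed = 8, n_loci = 150, n_generations = 60,
                      ancestral_freq = "beta")
  x <- ds$genotypes_complete[1:12, ]
  builder <- function(m) neighbor_joining(k2p_matrix(
    concatenate_random_alleles(m, seed = 1)))
  b1 <- bootstrap_support(x, builder, n_reps = 1, seed = 3)
  expect_true(all(stats::na.omit(b1$supports) %in% c(0, 100)))

  # all sites identical (a monomorphic one, so distances stay defined):
  # every replicate equals the point tree
  mono <- which(apply(unclass(x), 2, function(v) length(unique(v)) == 1))[1]
  xid <- x[, rep(mono, 30)]
  b2 <- bootstrap_support(xid, builder, n_reps = 20, seed = 4)
  expect_true(all(stats::na.omit(b2$supports) == 100))
})

test_that("population tree separates the two ends of the island chain", {
  ends_split <- vapply(1:20, function(s) {
    ds <- simulate_metapopulation(sim_config(seed = 8000 + s))
    f <- filter_genotypes(ds$genotypes, ds$islands)
    tr <- neighbor_joining(nei_DA(pairwise_pi(f$matrix, f$islands)))
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    has_clade <- function(pair) any(vapply(pp, function(ix) {
      setequal(labs[ix], pair) || setequal(setdiff(labs, labs[ix]), pair)
    }, logical(1)))
    # northern pair and southern pair each form a side of some bipartition
    has_clade(c("isl1", "isl2")) && has_clade(c("isl4", "isl5"))
  }, logical(1))
  expect_gte(mean(ends_split), 0.8)
})

test_that("majority-rule consensus is available alongside the point tree", {
  ds <- quick_dataset(seed = 12, n_loci = 150, n_generations = 60,
                      ancestral_freq = "beta")
  x <- ds$genotypes_complete[1:10, ]
  builder <- function(m) neighbor_joining(k2p_matrix(
    concatenate_random_alleles(m, seed = 1)))
  b <- bootstrap_support(x, builder, n_reps = 30, seed = 6, consensus = TRUE)
  expect_s3_class(b$consensus, "phylo")
  expect_setequal(b$consensus$tip.label, rownames(x))
})

test_that("bootstrap supports lie in [0,100] and trees keep all labels", {
  ds <- quick_dataset(seed = 9, n_loci = 150, n_generations = 60,
                      ancestral_freq = "beta")
  x <- ds$genotypes_complete[seq(1, 95, by = 8), ]
  builder <- function(m) neighbor_joining(k2p_matrix(
    concatenate_random_alleles(m, seed = 1)))
  b <- bootstrap_support(x, builder, n_reps = 50, seed = 5)
  sup <- stats::na.omit(b$supports)
  expect_true(all(sup >= 0 & sup <= 100))
  expect_setequal(b$tree$tip.label, rownames(x))
  nwk <- ape::write.tree(b$tree)
  back <- ape::read.tree(text = nwk)
  expect_equal(ape::dist.topo(back, b$tree), 0, ignore_attr = TRUE)
})
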