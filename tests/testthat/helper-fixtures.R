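# Shared fixtures and independent oracles, built in code.

# random genotype matrix with optional missingness
random_snp_matrix <- function(n, L, miss = 0, loci = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  if (miss > 0) m[matrix(runif(n * L) < miss, n, L)] <- NA
  snp_matrix(m, loci = loci)
}

two_island_table <- function(x, split = nrow(x) / 2) {
  island_table(rownames(x),
               rep(c("north", "south"), c(split, nrow(x) - split)))
}

# Oracle: expand a diploid call column into allele copies
allele_copies <- function(calls) {
  calls <- calls[!is.na(calls)]
  unlist(lapply(calls, function(g) c(as.integer(g >= 1), as.integer(g == 2))))
}

# Oracle: between-group average pairwise difference by full enumeration of
# inter-group allele-copy pairs, summed over sites
brute_pi_between <- function(X, Y) {
  stopifnot(ncol(X) == ncol(Y))
  sum(vapply(seq_len(ncol(X)), function(s) {
    a <- allele_copies(X[, s]); b <- allele_copies(Y[, s])
    if (!length(a) || !length(b)) return(0)
    mean(outer(a, b, "!="))
  }, numeric(1)))
}

# Oracle: within-group average difference over distinct copy pairs
brute_pi_within <- function(X) {
  sum(vapply(seq_len(ncol(X)), function(s) {
    a <- allele_copies(X[, s])
    if (length(a) < 2) return(0)
    d <- outer(a, a, "!=")
    sum(d[upper.tri(d)]) / choose(length(a), 2)
  }, numeric(1)))
}

# random additive distance matrix from a random tree, with the tree's
# path-length matrix as the oracle
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 3)
  D <- ape::cophenetic.phylo(tr)
  D[order(rownames(D)), order(colnames(D))]
}

# path-length matrix of a phylo tree, labels sorted
tree_path_matrix <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D[order(rownames(D)), order(colnames(D))]
}

random_distance_matrix <- function(n, labels = sprintf("p%d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

# Oracle: plain-loop exact Mantel / partial Mantel p-values by full
# enumeration, independent of the package's vectorized machinery
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (p in perms_of(n - 1L)) out[[length(out) + 1L]] <- c(k, rest[p])
  }
  out
}

oracle_mantel_exact <- function(A, B, alternative = "greater") {
  ut <- upper.tri(A)
  r_obs <- cor(A[ut], B[ut])
  stats <- vapply(perms_of(nrow(A)), function(g) {
    Bp <- B[g, g]
    cor(A[ut], Bp[ut])
  }, numeric(1))
  extreme <- switch(alternative,
                    greater = stats >= r_obs - 1e-12,
                    less = stats <= r_obs + 1e-12,
                    two.sided = abs(stats) >= abs(r_obs) - 1e-12)
  mean(extreme)
}

oracle_partial_exact <- function(A, B, C, alternative = "greater") {
  ut <- upper.tri(A)
  pr <- function(Am) {
    rab <- cor(Am[ut], B[ut]); rac <- cor(Am[ut], C[ut])
    rbc <- cor(B[ut], C[ut])
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  }
  r_obs <- pr(A)
  stats <- vapply(perms_of(nrow(A)), function(g) pr(A[g, g]), numeric(1))
  extreme <- switch(alternative,
                    greater = stats >= r_obs - 1e-12,
                    less = stats <= r_obs + 1e-12,
                    two.sided = abs(stats) >= abs(r_obs) - 1e-12)
  mean(extreme)
}

# small simulated dataset used by several structural tests
quick_dataset <- function(seed = 11, ...) {
  simulate_metapopulation(sim_config(seed = seed, ...))
}
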