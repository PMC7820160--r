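#' Configuration for the island-metapopulation simulator
#'
#' Defines a chain of island populations evolving under a forward
#' Wright-Fisher model with distance-scaled stepping-stone migration,
#' plus the phenotype-count layer in which each island's equilibrium mimic
#' ratio is set by the local abundance of the unpalatable model species.
#' Defaults emulate a five-island north-south archipelago sampled at
#' realistic field sizes: 11-46 diploids per island genotyped at a few
#' hundred biallelic loci, patchy missingness (a minority of loci and a
#' couple of individuals with heavy dropout), and model abundance rising
#' from north to south.
#'
#' @param n_islands number of islands (>= 2).
#' @param island_positions strictly increasing coordinates (km) along the
#'   chain; geographic distance is the absolute coordinate difference.
#' @param n_diploids_per_island individuals sampled per island at the final
#'   generation (each <= `effective_size`).
#' @param n_loci unlinked biallelic loci.
#' @param n_generations Wright-Fisher generations.
#' @param effective_size diploid effective size N per island.
#' @param migration_rate_per_km per-generation migration fraction between
#'   islands i and j is `migration_rate_per_km / distance(i, j)`; off-diagonal
#'   row sums must not exceed 1.
#' @param mutation_rate symmetric per-locus per-generation mutation rate.
#' @param missing_locus_rates per-locus missingness probabilities (length
#'   `n_loci`); default: 0.03 everywhere, 0.30 for every 10th locus.
#' @param missing_individual_rates per-individual missingness probabilities;
#'   default: 0.02 everywhere, 0.45 for two individuals.
#' @param model_abundance per-island count of model-species individuals.
#' @param females_per_island per-island female counts for the phenotype
#'   survey layer.
#' @param nfds_noise_sd SD of logit-scale noise around the equilibrium
#'   mimic ratio, default 0.1.
#' @param ancestral_freq `"half"` (all loci start at frequency 0.5) or
#'   `"beta"` (frequencies drawn from Beta(0.8, 0.8)).
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_islands = 5,
                       island_positions = c(0, 150, 450, 750, 765),
                       n_diploids_per_island = c(11, 46, 12, 14, 12),
                       n_loci = 240,
                       n_generations = 400,
                       effective_size = 100,
                       migration_rate_per_km = 0.5,
                       mutation_rate = 1e-5,
                       missing_locus_rates = NULL,
                       missing_individual_rates = NULL,
                       model_abundance = c(350, 10, 40, 300, 150),
                       females_per_island = c(100, 400, 120, 150, 110),
                       nfds_noise_sd = 0.1,
                       ancestral_freq = c("half", "beta"),
                       seed = 1L) {
  ancestral_freq <- match.arg(ancestral_freq)
  if (n_islands < 2) stop("invalid config: n_islands must be >= 2")
  stopifnot(length(island_positions) == n_islands,
            length(n_diploids_per_island) == n_islands,
            length(model_abundance) == n_islands,
            length(females_per_island) == n_islands)
  if (any(diff(island_positions) <= 0)) {
    stop("invalid config: island positions must be strictly increasing")
  }
  if (any(n_diploids_per_island > effective_size)) {
    stop("invalid config: cannot sample more diploids than the effective size")
  }
  d <- abs(outer(island_positions, island_positions, "-"))
  if (any(d[upper.tri(d)] == 0)) {
    stop("invalid config: zero inter-island distance")
  }
  mig <- ifelse(d > 0, migration_rate_per_km / d, 0)
  diag(mig) <- 0
  if (any(rowSums(mig) > 1)) {
    stop("invalid config: migration fractions exceed 1 for some island; ",
         "reduce migration_rate_per_km")
  }
  n_ind <- sum(n_diploids_per_island)
  if (is.null(missing_locus_rates)) {
    missing_locus_rates <- rep(0.03, n_loci)
    missing_locus_rates[seq(10, n_loci, by = 10)] <- 0.30
  }
  if (is.null(missing_individual_rates)) {
    missing_individual_rates <- rep(0.02, n_ind)
    missing_individual_rates[c(5L, min(20L, n_ind))] <- 0.45
  }
  stopifnot(length(missing_locus_rates) == n_loci,
            length(missing_individual_rates) == n_ind)
  if (any(missing_locus_rates < 0 | missing_locus_rates > 1) ||
      any(missing_individual_rates < 0 | missing_individual_rates > 1) ||
      mutation_rate < 0 || mutation_rate > 1 || nfds_noise_sd < 0) {
    stop("invalid config: rates must lie in [0, 1]")
  }
  structure(list(n_islands = n_islands, island_positions = island_positions,
                 n_diploids_per_island = n_diploids_per_island,
                 n_loci = n_loci, n_generations = n_generations,
                 effective_size = effective_size,
                 migration_rate_per_km = migration_rate_per_km,
                 migration_matrix = mig, mutation_rate = mutation_rate,
                 missing_locus_rates = missing_locus_rates,
                 missing_individual_rates = missing_individual_rates,
                 model_abundance = model_abundance,
                 females_per_island = females_per_island,
                 nfds_noise_sd = nfds_noise_sd,
                 ancestral_freq = ancestral_freq, seed = as.integer(seed)),
            class = "sim_config")
}

#' Equilibrium mimic ratios from model-species abundance
#'
#' Under negative frequency-dependent selection the mimic-ratio equilibrium
#' tracks the advantage index AI = M / (m + M) (model count over mimic plus
#' model count). The equilibrium is the self-consistent solution of
#' `qlogis(MR) = qlogis(AI(MR)) + e` with `AI(MR) = M / (F * MR + M)` and
#' logit-scale noise `e ~ N(0, noise_sd)`: mimic ratio and advantage index
#' are logit-linearly linked at the realized equilibrium, islands richer in
#' models (relative to their female numbers) equilibrating at higher MR and
#' higher AI. The left side is increasing and the right side decreasing in
#' MR, so the root is unique; it is found numerically.
#'
#' @param model_abundance per-island model-species counts.
#' @param females_per_island per-island female counts (>= 1).
#' @param noise_sd logit-scale noise SD.
#' @param seed optional integer seed.
#' @return vector of equilibrium mimic ratios in (0, 1).
#' @export
equilibrium_mr <- function(model_abundance, females_per_island,
                           noise_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(length(model_abundance), sd = noise_sd)
  vapply(seq_along(model_abundance), function(i) {
    M <- model_abundance[i]; F_ <- females_per_island[i]
    if (M == 0) return(1e-6)
    gap <- function(mr) {
      ai <- max(min(M / (F_ * mr + M), 1 - 1e-12), 1e-12)
      stats::qlogis(mr) - stats::qlogis(ai) - eps[i]
    }
    stats::uniroot(gap, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  }, numeric(1))
}

#' Draw per-island phenotype counts from true mimic ratios
#'
#' Mimic counts are Binomial(females, MR) draws; model counts are copied
#' through unchanged.
#'
#' @param truth_mr per-island true mimic ratios in \[0, 1\].
#' @param females_per_island per-island female counts (>= 0).
#' @param model_abundance per-island model-species counts.
#' @param island_labels island names.
#' @param seed optional integer seed.
#' @return [count_table()]
#' @export
assign_phenotypes <- function(truth_mr, females_per_island, model_abundance,
                              island_labels = NULL, seed = NULL) {
  if (any(truth_mr < 0 | truth_mr > 1)) stop("truth_mr must lie in [0, 1]")
  if (any(females_per_island < 0)) stop("female counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(island_labels)) {
    island_labels <- sprintf("isl%d", seq_along(truth_mr))
  }
  m <- stats::rbinom(length(truth_mr), females_per_island, truth_mr)
  count_table(island_labels, m, females_per_island - m, model_abundance)
}

#' Inject missing calls into a genotype matrix
#'
#' Call (i, l) is set missing independently with probability
#' `1 - (1 - locus_rate_l) * (1 - individual_rate_i)`; all other calls are
#' preserved.
#'
#' @param x [snp_matrix()]
#' @param locus_rates per-site missingness rates (length `ncol(x)`).
#' @param individual_rates per-individual rates (length `nrow(x)`).
#' @param seed optional integer seed.
#' @export
inject_missingness <- function(x, locus_rates, individual_rates, seed = NULL) {
  if (length(locus_rates) != ncol(x) || length(individual_rates) != nrow(x)) {
    stop("rate vectors must match matrix dimensions")
  }
  if (any(c(locus_rates, individual_rates) < 0) ||
      any(c(locus_rates, individual_rates) > 1)) {
    stop("rates must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  p_miss <- 1 - outer(1 - individual_rates, 1 - locus_rates)
  mask <- matrix(stats::runif(length(p_miss)) < p_miss, nrow(x))
  out <- unclass(x)
  out[mask] <- NA_integer_
  snp_matrix(out, loci = attr(x, "loci"), site_class = attr(x, "site_class"))
}

#' Simulate an island metapopulation
#'
#' Forward Wright-Fisher simulation of unlinked biallelic loci in
#' `n_islands` demes of diploid size N. Each generation: allele frequencies
#' are mixed by the distance-scaled migration matrix, perturbed by
#' symmetric mutation, then resampled binomially (2N copies per deme).
#' At the final generation, `n_diploids_per_island` individuals are sampled
#' per island without replacement (hypergeometric draw of allele copies,
#' paired at random into diploids), missingness is injected, and phenotype
#' counts are drawn with the equilibrium mimic ratio set by local model
#' abundance. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `simulated_dataset` with elements `genotypes`
#'   ([snp_matrix()] with missingness), `genotypes_complete` (pre-dropout),
#'   `islands` ([island_table()]), `counts` ([count_table()]), `geography`
#'   (km distance matrix), `truth` (final per-island allele frequencies,
#'   per-generation metapopulation mean frequency, equilibrium mimic
#'   ratios) and `config`.
#' @export
simulate_metapopulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k_isl <- config$n_islands
  L <- config$n_loci
  N <- config$effective_size
  M <- config$migration_matrix
  diag(M) <- 1 - rowSums(M)
  mu <- config$mutation_rate
  labs <- sprintf("isl%d", seq_len(k_isl))

  p0 <- switch(config$ancestral_freq,
               half = matrix(0.5, k_isl, L),
               beta = matrix(rep(stats::rbeta(L, 0.8, 0.8), each = k_isl),
                             k_isl, L))
  K <- matrix(as.integer(round(2 * N * p0)), k_isl, L)
  traj <- numeric(config$n_generations)
  for (g in seq_len(config$n_generations)) {
    p <- M %*% (K / (2 * N))
    p <- p * (1 - mu) + (1 - p) * mu
    K <- matrix(stats::rbinom(k_isl * L, 2L * N, as.vector(p)), k_isl, L)
    traj[g] <- mean(K) / (2 * N)
  }

  n_i <- config$n_diploids_per_island
  geno <- matrix(NA_integer_, sum(n_i), L)
  ind_labels <- unlist(lapply(seq_len(k_isl), function(i) {
    sprintf("%s_i%02d", labs[i], seq_len(n_i[i]))
  }))
  row0 <- cumsum(c(0, n_i))
  for (i in seq_len(k_isl)) {
    drawn <- stats::rhyper(L, K[i, ], 2 * N - K[i, ], 2 * n_i[i])
    for (l in seq_len(L)) {
      copies <- sample(c(rep(1L, drawn[l]), rep(0L, 2 * n_i[i] - drawn[l])))
      geno[row0[i] + seq_len(n_i[i]), l] <-
        copies[seq(1, 2 * n_i[i], by = 2)] + copies[seq(2, 2 * n_i[i], by = 2)]
    }
  }
  rownames(geno) <- ind_labels
  colnames(geno) <- sprintf("locus%04d", seq_len(L))
  # SNPs carry known ref/alt bases in real call sets; emulate the usual
  # transition bias (~2:1) so K2P distances downstream are class-aware
  site_class <- ifelse(stats::runif(L) < 2 / 3, "ts", "tv")
  complete <- snp_matrix(geno, site_class = site_class)

  mr <- equilibrium_mr(config$model_abundance, config$females_per_island,
                       config$nfds_noise_sd)
  counts <- assign_phenotypes(mr, config$females_per_island,
                              config$model_abundance, labs)
  pheno <- unlist(lapply(seq_len(k_isl), function(i) {
    ifelse(stats::rbinom(n_i[i], 1, mr[i]) == 1, "mimic", "nonmimic")
  }))
  islands <- island_table(ind_labels, rep(labs, n_i), pheno)

  withmiss <- inject_missingness(complete, config$missing_locus_rates,
                                 config$missing_individual_rates)
  geography <- abs(outer(config$island_positions, config$island_positions, "-"))
  dimnames(geography) <- list(labs, labs)
  attr(geography, "kind") <- "geographic_km"
  dimnames(K) <- list(labs, colnames(geno))

  structure(list(genotypes = withmiss, genotypes_complete = complete,
                 islands = islands, counts = counts, geography = geography,
                 truth = list(allele_freq_final = K / (2 * N),
                              mean_freq_trajectory = traj,
                              equilibrium_mr = stats::setNames(mr, labs)),
                 config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated island metapopulation: %d islands, %d individuals, %d loci\n",
    x$config$n_islands, nrow(x$genotypes), ncol(x$genotypes)))
  cat("equilibrium mimic ratios:",
      paste(sprintf("%s=%.2f", names(x$truth$equilibrium_mr),
                    x$truth$equilibrium_mr), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @param genotype_format `"vcf"`, `"structure"` or `"tsv"`.
#' @return invisible named vector of file paths.
#' @export
write_simulated_dataset <- function(dataset, dir, genotype_format = "vcf") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- switch(genotype_format, vcf = "vcf", structure = "str", tsv = "tsv")
  paths <- c(genotypes = file.path(dir, paste0("genotypes.", ext)),
             islands = file.path(dir, "islands.csv"),
             counts = file.path(dir, "counts.csv"),
             geography = file.path(dir, "geography.tsv"))
  write_genotypes(dataset$genotypes, paths["genotypes"], genotype_format)
  write_island_table(dataset$islands, paths["islands"])
  write_count_table(dataset$counts, paths["counts"])
  write_distance_matrix(dataset$geography, paths["geography"], "tsv")
  invisible(paths)
}
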