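#' Run the full mimicry population-genetics pipeline
#'
#' Stages, in order: read inputs (or accept in-memory objects), optional
#' one-SNP-per-locus thinning, staged missingness + Hardy-Weinberg
#' filtering, per-island diversity summary, pairwise differences / net
#' divergence / differentiation matrices, neighbor-joining trees
#' (population-level from net divergence; individual-level from K2P
#' distances on randomly phased allele concatenations, with optional
#' bootstrap), mimic-ratio and advantage-index tables and their difference
#' matrices, and the Mantel / partial-Mantel battery linking geography,
#' genetics, mimic ratios and advantage indices. Identical config and seed
#' give an identical report.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{genotypes/islands/counts/geography}{input file paths, or
#'       in-memory objects (`snp_matrix`, data.frames, matrix).}
#'     \item{genotype_format}{`"auto"`, `"vcf"`, `"structure"` or `"tsv"`.}
#'     \item{environment}{optional named list of additional distance
#'       matrices (paths or matrices) tested against mimic-ratio
#'       differences.}
#'     \item{locus_missing, individual_missing, hwe_alpha,
#'       usable_locus_missing_max}{filter thresholds (defaults 0.2, 0.3,
#'       0.05, 0.05).}
#'     \item{one_snp_per_locus}{thin to one site per locus when a grouping
#'       is present (default TRUE).}
#'     \item{n_permutations}{Mantel permutations (default 10000; exact
#'       enumeration is used automatically for <= 7 islands).}
#'     \item{alternative}{Mantel alternative (default `"greater"`).}
#'     \item{bootstrap_reps}{bootstrap replicates for the individual-level
#'       tree (default 0 = skip).}
#'     \item{seed}{integer master seed (default 1).}
#'     \item{out_dir}{optional output directory for report and artifacts.}
#'   }
#' @return list of class `analysis_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(genotype_format = "auto", locus_missing = 0.2,
                   individual_missing = 0.3, hwe_alpha = 0.05,
                   usable_locus_missing_max = 0.05, one_snp_per_locus = TRUE,
                   n_permutations = 10000, alternative = "greater",
                   bootstrap_reps = 0, seed = 1L, out_dir = NULL,
                   environment = NULL)
  config <- utils::modifyList(defaults, config)
  seed <- as.integer(config$seed)

  as_input <- function(obj, reader, ...) {
    if (is.character(obj) && length(obj) == 1) reader(obj, ...) else obj
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  geno <- stage("input", as_input(config$genotypes, read_genotypes,
                                  config$genotype_format))
  islands <- stage("input", as_input(config$islands, read_island_table))
  counts <- stage("input", as_input(config$counts, read_count_table))
  geography <- stage("input", as_input(config$geography, read_distance_matrix))
  env_mats <- lapply(config$environment, as_input, read_distance_matrix)

  if (config$one_snp_per_locus && !is.null(attr(geno, "loci"))) {
    geno <- stage("thin", select_one_snp_per_locus(geno, seed = seed + 1L))
  }
  filt <- stage("filter", filter_genotypes(
    geno, islands, locus_threshold = config$locus_missing,
    individual_threshold = config$individual_missing,
    alpha = config$hwe_alpha))
  x <- filt$matrix
  isl <- filt$islands

  diversity <- stage("diversity",
                     diversity_summary(x, isl, config$usable_locus_missing_max))
  pi <- stage("distances", pairwise_pi(x, isl))
  da <- nei_DA(pi)
  phist <- phi_st(pi)
  fst <- slatkin_fst(pi)

  island_order <- rownames(geography)
  if (!setequal(island_order, rownames(da))) {
    stop("island labels of geography and genotype data disagree")
  }
  da <- da[island_order, island_order]
  phist <- phist[island_order, island_order]
  fst <- fst[island_order, island_order]

  pop_tree <- stage("trees", neighbor_joining(da))
  builder <- function(m) neighbor_joining(k2p_matrix(
    concatenate_random_alleles(m)))
  set.seed(seed + 2L)
  ind_tree <- stage("trees", builder(x))
  boot <- NULL
  if (config$bootstrap_reps > 0) {
    boot <- stage("trees", bootstrap_support(x, builder,
                                             n_reps = config$bootstrap_reps,
                                             seed = seed + 3L))
  }

  counts <- counts[match(island_order, counts$island), ]
  if (anyNA(counts$island)) stop("count table does not cover all islands")
  idx <- stage("indices", mimicry_indices(counts))
  mrd <- difference_matrix(stats::setNames(idx$mr, idx$island), "mr_difference")
  aid <- difference_matrix(stats::setNames(idx$ai, idx$island), "ai_difference")
  aiud <- difference_matrix(stats::setNames(idx$ai_uesugi, idx$island),
                            "ai_uesugi_difference")

  np <- config$n_permutations
  alt <- config$alternative
  mantel <- stage("mantel", list(
    gd_agd = mantel_test(geography, da, np, alt, seed = seed + 10L),
    agd_mrd = mantel_test(da, mrd, np, alt, seed = seed + 11L),
    gd_mrd = mantel_test(geography, mrd, np, alt, seed = seed + 12L),
    mr_ai_given_agd = partial_mantel_test(mrd, aid, da, np, alt,
                                          seed = seed + 13L),
    mr_ai_given_gd = partial_mantel_test(mrd, aid, geography, np, alt,
                                         seed = seed + 14L),
    mr_ai_uesugi_given_agd = partial_mantel_test(mrd, aiud, da, np, alt,
                                                 seed = seed + 15L),
    mr_ai_uesugi_given_gd = partial_mantel_test(mrd, aiud, geography, np, alt,
                                                seed = seed + 16L)))
  if (length(env_mats)) {
    for (nm in names(env_mats)) {
      ed <- env_mats[[nm]][island_order, island_order]
      mantel[[paste0(nm, "_mrd")]] <-
        mantel_test(ed, mrd, np, alt, seed = seed + 20L)
      mantel[[paste0("mr_ai_given_", nm)]] <-
        partial_mantel_test(mrd, aid, ed, np, alt, seed = seed + 21L)
    }
  }

  report <- structure(list(
    version = as.character(utils::packageVersion("polymimic")),
    seed = seed,
    filter = filt$report,
    diversity = diversity,
    distances = list(geography = geography, pi_between = pi$between,
                     D_A = da, phi_st = phist, slatkin_fst = fst,
                     mr_difference = mrd, ai_difference = aid,
                     ai_uesugi_difference = aiud),
    trees = list(population = ape::write.tree(pop_tree),
                 individual = ape::write.tree(ind_tree),
                 individual_bootstrap = if (!is.null(boot))
                   ape::write.tree(boot$tree),
                 bootstrap_failed = if (!is.null(boot)) boot$n_failed),
    indices = idx,
    mantel = mantel,
    config = config[setdiff(names(config),
                            c("genotypes", "islands", "counts", "geography",
                              "environment"))]),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis report (seed", x$seed, ")\n")
  cat(sprintf("  %d loci retained, %d islands\n", x$filter$loci_final,
              nrow(x$diversity)))
  cat("  Mantel battery:\n")
  for (nm in names(x$mantel)) {
    m <- x$mantel[[nm]]
    cat(sprintf("    %-24s r = %+.3f  p = %.4g\n", nm, m$statistic,
                m$p_value))
  }
  invisible(x)
}

#' Write an analysis report and its artifacts
#'
#' Writes `report.json` plus TSV distance matrices, the diversity and index
#' tables, and Newick trees under `dir`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$distances)) {
    m <- report$distances[[nm]]
    write_distance_matrix(m, file.path(dir, paste0(nm, ".tsv")))
  }
  utils::write.table(report$diversity, file.path(dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$indices, file.path(dir, "indices.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$trees$population, file.path(dir, "population_tree.nwk"))
  writeLines(report$trees$individual, file.path(dir, "individual_tree.nwk"))
  if (!is.null(report$trees$individual_bootstrap)) {
    writeLines(report$trees$individual_bootstrap,
               file.path(dir, "individual_tree_bootstrap.nwk"))
  }
  json <- rapply(unclass(report), function(v) v, how = "replace")
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(file.path(dir, "report.json"))
}
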