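## population SD (divisor n) used for the summary tables
sd_pop <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  sqrt(mean((v - mean(v))^2))
}

## per-island per-site allele frequency, het fraction and diploid counts
island_site_stats <- function(x, islands) {
  rows <- island_rows(x, islands)
  m <- unclass(x)
  lapply(rows, function(ix) {
    sub <- m[ix, , drop = FALSE]
    n <- colSums(!is.na(sub))
    p <- ifelse(n > 0, colSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
    het <- ifelse(n > 0, colSums(sub == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, het = het, n_ind = length(ix))
  })
}

#' Observed and expected heterozygosity per island
#'
#' Summaries are taken over the sites polymorphic within each island
#' (both alleles observed among that island's non-missing calls). Per site,
#' observed heterozygosity is the fraction of heterozygotes among
#' non-missing individuals; expected heterozygosity is the small-sample
#' unbiased form `2n/(2n-1) * 2*p*q` with `n` non-missing diploids.
#' Reported SDs are population SDs (divisor n) across polymorphic sites.
#'
#' @param x filtered [snp_matrix()]
#' @param islands [island_table()]
#' @return data.frame, one row per island: `island`, `n_individuals`,
#'   `n_polymorphic_sites`, `ho_mean`, `ho_sd`, `he_mean`, `he_sd`.
#' @export
heterozygosities <- function(x, islands) {
  st <- island_site_stats(x, islands)
  out <- lapply(names(st), function(isl) {
    s <- st[[isl]]
    if (all(s$n == 0)) stop("island ", isl, " has no non-missing calls")
    poly <- s$n > 0 & s$p > 0 & s$p < 1
    ho <- s$het[poly]
    he <- (2 * s$n[poly] / (2 * s$n[poly] - 1)) * 2 * s$p[poly] * (1 - s$p[poly])
    data.frame(island = isl, n_individuals = s$n_ind,
               n_polymorphic_sites = sum(poly),
               ho_mean = if (any(poly)) mean(ho) else NA_real_,
               ho_sd = sd_pop(ho),
               he_mean = if (any(poly)) mean(he) else NA_real_,
               he_sd = sd_pop(he), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Average gene diversity over usable loci, per island
#'
#' Gene diversity of a locus is the probability that two randomly chosen
#' distinct allele copies differ: `h = 2N/(2N-1) * (1 - sum p_a^2)` with
#' `2N` the non-missing allele copies in the island. Only "usable" loci --
#' within-island missing fraction strictly below `usable_locus_missing_max`
#' -- enter the average; monomorphic usable loci contribute 0.
#'
#' @param x filtered [snp_matrix()]
#' @param islands [island_table()]
#' @param usable_locus_missing_max usable-locus cutoff, default 0.05.
#' @return data.frame: `island`, `n_usable_loci`, `gene_diversity_mean`,
#'   `gene_diversity_sd`.
#' @export
gene_diversity <- function(x, islands, usable_locus_missing_max = 0.05) {
  rows <- island_rows(x, islands)
  m <- unclass(x)
  out <- lapply(names(rows), function(isl) {
    sub <- m[rows[[isl]], , drop = FALSE]
    usable <- colMeans(is.na(sub)) < usable_locus_missing_max
    if (!any(usable)) stop("island ", isl, " has no usable loci")
    sub <- sub[, usable, drop = FALSE]
    n2 <- 2 * colSums(!is.na(sub))          # allele copies
    p <- colSums(sub, na.rm = TRUE) / n2
    h <- ifelse(n2 > 1, (n2 / (n2 - 1)) * (1 - p^2 - (1 - p)^2), 0)
    data.frame(island = isl, n_usable_loci = sum(usable),
               gene_diversity_mean = mean(h), gene_diversity_sd = sd_pop(h),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Polymorphic-site and private-allele-site counts per island
#'
#' A site is polymorphic within an island when both alleles are observed
#' among its non-missing calls; an island has a private allele at a site
#' when it carries an allele observed in no other island. Sites with no
#' non-missing calls in an island are excluded from that island's tallies.
#'
#' @param x filtered [snp_matrix()]
#' @param islands [island_table()]
#' @return data.frame: `island`, `n_polymorphic_sites`,
#'   `n_private_allele_sites`.
#' @export
polymorphic_and_private_sites <- function(x, islands) {
  st <- island_site_stats(x, islands)
  # presence[allele 0/1, island, site]
  has_ref <- vapply(st, function(s) s$n > 0 & s$p < 1, logical(ncol(x)))
  has_alt <- vapply(st, function(s) s$n > 0 & s$p > 0, logical(ncol(x)))
  if (is.null(dim(has_ref))) {  # single-site matrix
    has_ref <- matrix(has_ref, nrow = 1); has_alt <- matrix(has_alt, nrow = 1)
  }
  out <- lapply(seq_along(st), function(k) {
    s <- st[[k]]
    poly <- sum(s$n > 0 & s$p > 0 & s$p < 1)
    ref_priv <- has_ref[, k] & rowSums(has_ref[, -k, drop = FALSE]) == 0
    alt_priv <- has_alt[, k] & rowSums(has_alt[, -k, drop = FALSE]) == 0
    data.frame(island = names(st)[k], n_polymorphic_sites = poly,
               n_private_allele_sites = sum(ref_priv | alt_priv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-island diversity summary table
#'
#' Combines [heterozygosities()], [gene_diversity()] and
#' [polymorphic_and_private_sites()] into one table of per-island
#' population-genetic diversity statistics.
#'
#' @inheritParams gene_diversity
#' @export
diversity_summary <- function(x, islands, usable_locus_missing_max = 0.05) {
  h <- heterozygosities(x, islands)
  g <- gene_diversity(x, islands, usable_locus_missing_max)
  p <- polymorphic_and_private_sites(x, islands)
  out <- merge(merge(h, p, by = c("island", "n_polymorphic_sites")), g,
               by = "island", sort = FALSE)
  out$n_loci <- ncol(x)
  out[, c("island", "n_individuals", "n_loci", "n_usable_loci",
          "n_polymorphic_sites", "n_private_allele_sites",
          "ho_mean", "ho_sd", "he_mean", "he_sd",
          "gene_diversity_mean", "gene_diversity_sd")]
}
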