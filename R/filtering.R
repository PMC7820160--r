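#' Select one SNP site per locus at random
#'
#' Reduced-representation loci often carry several SNP sites that are
#' tightly linked; downstream statistics treat sites as independent, so a
#' single site is retained per locus, chosen uniformly at random.
#'
#' @param x [snp_matrix()] with a locus grouping.
#' @param seed optional integer seed for the random draw.
#' @return [snp_matrix()] with one site per locus and no grouping.
#' @export
select_one_snp_per_locus <- function(x, seed = NULL) {
  loci <- attr(x, "loci")
  if (is.null(loci)) stop("matrix has no locus grouping")
  if (!is.null(seed)) set.seed(seed)
  groups <- split(seq_len(ncol(x)), loci)
  if (any(lengths(groups) == 0)) stop("empty locus group")
  keep <- vapply(groups, function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }, integer(1))
  keep <- sort(unname(keep))
  out <- x[, keep]
  attr(out, "loci") <- NULL
  out
}

#' Staged missing-data filter
#'
#' Three passes, in order: (1) keep sites whose missing fraction across all
#' individuals is strictly below `locus_threshold`; (2) drop individuals
#' whose missing fraction across the kept sites is strictly above
#' `individual_threshold`; (3) recompute site missingness over the remaining
#' individuals and again keep sites strictly below `locus_threshold`.
#'
#' @param x [snp_matrix()]
#' @param locus_threshold maximum tolerated per-site missing fraction
#'   (strict `<`), default 0.20.
#' @param individual_threshold per-individual missing fraction above which
#'   (strict `>`) the individual is dropped, default 0.30.
#' @return list with `matrix` (filtered [snp_matrix()]) and `report`
#'   (a `filter_report`).
#' @export
staged_missingness_filter <- function(x, locus_threshold = 0.20,
                                      individual_threshold = 0.30) {
  stopifnot(locus_threshold > 0, locus_threshold <= 1,
            individual_threshold > 0, individual_threshold <= 1)
  loci_in <- ncol(x)
  keep1 <- missing_by_site(x) < locus_threshold
  if (!any(keep1)) stop("no sites pass the first missingness pass")
  x1 <- x[, which(keep1)]
  drop_ind <- missing_by_individual(x1) > individual_threshold
  if (all(drop_ind)) stop("all individuals removed by missingness filter")
  x2 <- x1[which(!drop_ind), ]
  keep3 <- missing_by_site(x2) < locus_threshold
  if (!any(keep3)) stop("no sites pass the recomputed missingness pass")
  x3 <- x2[, which(keep3)]
  report <- filter_report(
    loci_in = loci_in,
    loci_after_locus_filter = ncol(x1),
    individuals_in = nrow(x),
    individuals_removed = rownames(x1)[drop_ind],
    loci_after_refilter = ncol(x3),
    removed_loci_pass1 = colnames(x)[!keep1],
    removed_loci_pass3 = colnames(x2)[!keep3],
    locus_threshold = locus_threshold,
    individual_threshold = individual_threshold)
  list(matrix = x3, report = report)
}

filter_report <- function(...) {
  structure(list(...), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter report\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) > 6) v <- c(utils::head(v, 6), "...")
    cat(sprintf("  %-26s %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Hardy-Weinberg chi-squared test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit test of the three diploid genotype
#' classes against Hardy-Weinberg proportions computed from the sample
#' allele frequencies; no continuity correction, no minimum expected count.
#' Monomorphic samples give `chi2 = 0, p = 1` by convention.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return list with `chi2` and `p`.
#' @export
hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  o <- c(n_AA, n_Aa, n_aa)
  if (length(o) != 3 || anyNA(o)) stop("three genotype counts required")
  if (any(o < 0)) stop("negative genotype counts")
  n <- sum(o)
  if (n < 1) stop("total genotype count must be >= 1")
  p <- (2 * o[1] + o[2]) / (2 * n)
  if (p == 0 || p == 1) return(list(chi2 = 0, p = 1))
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((o - e)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Hardy-Weinberg equilibrium locus filter
#'
#' Removes every site whose genotype counts (non-missing calls only) deviate
#' from Hardy-Weinberg proportions at `p < alpha` in at least one island
#' population. Raw per-site p-values are used, with no multiple-testing
#' correction, matching common practice for HWE-based genotyping-artifact
#' screens.
#'
#' @param x filtered [snp_matrix()]
#' @param islands [island_table()] covering every individual.
#' @param alpha significance level, default 0.05.
#' @return list with `matrix`, `report` (`filter_report` with per-island
#'   violation counts) and `p_values` (island x site matrix).
#' @export
hwe_filter <- function(x, islands, alpha = 0.05) {
  rows <- island_rows(x, islands)
  if (any(lengths(rows) == 0)) stop("island with no individuals")
  m <- unclass(x)
  pmat <- matrix(NA_real_, length(rows), ncol(m),
                 dimnames = list(names(rows), colnames(m)))
  for (k in seq_along(rows)) {
    sub <- m[rows[[k]], , drop = FALSE]
    n0 <- colSums(sub == 0L, na.rm = TRUE)
    n1 <- colSums(sub == 1L, na.rm = TRUE)
    n2 <- colSums(sub == 2L, na.rm = TRUE)
    for (j in seq_len(ncol(m))) {
      if (n0[j] + n1[j] + n2[j] >= 1) {
        pmat[k, j] <- hwe_chisq(n0[j], n1[j], n2[j])$p
      }
    }
  }
  viol <- apply(pmat, 2, function(p) any(!is.na(p) & p < alpha))
  out <- x[, which(!viol)]
  report <- filter_report(
    loci_in = ncol(x),
    loci_removed_hwe = sum(viol),
    loci_final = ncol(out),
    removed_loci_hwe = colnames(x)[viol],
    hwe_alpha = alpha)
  list(matrix = out, report = report, p_values = pmat)
}

#' Full genotype filtering stage
#'
#' Staged missingness filter followed by the per-island Hardy-Weinberg
#' filter; reports are merged so locus counts reconcile across passes.
#'
#' @inheritParams staged_missingness_filter
#' @inheritParams hwe_filter
#' @export
filter_genotypes <- function(x, islands, locus_threshold = 0.20,
                             individual_threshold = 0.30, alpha = 0.05) {
  s1 <- staged_missingness_filter(x, locus_threshold, individual_threshold)
  isl <- islands[islands$individual %in% rownames(s1$matrix), , drop = FALSE]
  s2 <- hwe_filter(s1$matrix, isl, alpha)
  rep <- s1$report
  rep$loci_removed_hwe <- s2$report$loci_removed_hwe
  rep$removed_loci_hwe <- s2$report$removed_loci_hwe
  rep$loci_final <- s2$report$loci_final
  rep$hwe_alpha <- alpha
  list(matrix = s2$matrix, islands = isl, report = rep)
}
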