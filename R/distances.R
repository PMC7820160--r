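#' Average pairwise differences within and between island populations
#'
#' Each diploid is treated as two allele copies per site. Between islands X
#' and Y, the per-site contribution is the probability that one random copy
#' from X and one from Y differ, `p_X(1-p_Y) + p_Y(1-p_X)`; within an
#' island the unbiased two-distinct-copies form `2n/(2n-1) * 2pq` (with
#' `2n` non-missing copies) is used. Contributions are summed over sites,
#' so values are in units of differing SNP sites; `per_site = TRUE` divides
#' by the number of sites used. For every island pair, sites without
#' coverage in either member are dropped for that pair (pairwise deletion),
#' and the within-island sums entering net divergence for that pair are
#' restricted to the same site set.
#'
#' @param x filtered [snp_matrix()]
#' @param islands [island_table()]
#' @param per_site report per-site averages instead of sums over sites.
#' @return object of class `pairwise_pi`: list with `labels`, `between`
#'   (matrix of pi_XY, diagonal = within-island pi), `within_pair` (matrix:
#'   entry (i,j) is island i's within-pi over the sites shared with j),
#'   `n_sites` (sites used per pair) and `n_dropped` (sites dropped per
#'   pair).
#' @export
pairwise_pi <- function(x, islands, per_site = FALSE) {
  st <- island_site_stats(x, islands)
  k <- length(st)
  labs <- names(st)
  between <- matrix(0, k, k, dimnames = list(labs, labs))
  within_pair <- matrix(0, k, k, dimnames = list(labs, labs))
  n_sites <- matrix(0L, k, k, dimnames = list(labs, labs))
  pi_within_site <- lapply(st, function(s) {
    ifelse(s$n > 0,
           (2 * s$n / pmax(2 * s$n - 1, 1)) * 2 * s$p * (1 - s$p), NA_real_)
  })
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- st[[i]]$n > 0 & st[[j]]$n > 0
      ns <- sum(ok)
      if (ns == 0) stop("islands ", labs[i], " and ", labs[j],
                        " share no covered sites")
      scale <- if (per_site) ns else 1
      if (i == j) {
        between[i, i] <- sum(pi_within_site[[i]][ok]) / scale
      } else {
        pi_b <- sum(st[[i]]$p[ok] * (1 - st[[j]]$p[ok]) +
                    st[[j]]$p[ok] * (1 - st[[i]]$p[ok])) / scale
        between[i, j] <- between[j, i] <- pi_b
        within_pair[i, j] <- sum(pi_within_site[[i]][ok]) / scale
        within_pair[j, i] <- sum(pi_within_site[[j]][ok]) / scale
      }
      n_sites[i, j] <- n_sites[j, i] <- ns
    }
    within_pair[i, i] <- between[i, i]
  }
  structure(list(labels = labs, between = between, within_pair = within_pair,
                 n_sites = n_sites,
                 n_dropped = ncol(x) - n_sites, per_site = per_site),
            class = "pairwise_pi")
}

#' @export
print.pairwise_pi <- function(x, ...) {
  cat("pairwise average differences (diagonal: within-island)\n")
  print(round(x$between, 4))
  invisible(x)
}

#' Nei's net nucleotide divergence D_A between island populations
#'
#' `D_A(X,Y) = pi_XY - (pi_X + pi_Y)/2`: the between-population average
#' pairwise difference net of the mean within-population diversity. For
#' each pair the within terms are computed over the pair's shared site set.
#'
#' @param pi a [pairwise_pi()] object.
#' @return symmetric matrix with zero diagonal (attribute `kind = "D_A"`).
#' @export
nei_DA <- function(pi) {
  stopifnot(inherits(pi, "pairwise_pi"))
  da <- pi$between - (pi$within_pair + t(pi$within_pair)) / 2
  diag(da) <- 0
  attr(da, "kind") <- "D_A"
  da
}

#' Phi_ST: net divergence scaled by between-population diversity
#'
#' `Phi_ST(X,Y) = D_A(X,Y) / pi_XY`. Pairs with `pi_XY = 0` (identical
#' monomorphic populations, where D_A is also 0) are set to 0 by
#' convention.
#'
#' @param pi a [pairwise_pi()] object.
#' @return symmetric matrix, zero diagonal (attribute `kind = "phi_st"`).
#' @export
phi_st <- function(pi) {
  da <- nei_DA(pi)
  out <- ifelse(pi$between > 0, da / pi$between, 0)
  diag(out) <- 0
  dimnames(out) <- dimnames(da)
  attr(out, "kind") <- "phi_st"
  out
}

#' Pairwise F_ST from average pairwise differences
#'
#' Hudson-style ratio `F_ST = (pi_XY - (pi_X + pi_Y)/2) / pi_XY`, computed
#' from allele frequencies with pairwise deletion. With `linearize = TRUE`
#' the divergence-time standardization `D = F_ST / (1 - F_ST)` is applied;
#' pairs at `F_ST = 1` then become `Inf` with a warning. Negative estimates
#' are reported as computed, not clamped.
#'
#' @param pi a [pairwise_pi()] object.
#' @param linearize apply `F/(1-F)` standardization.
#' @return symmetric matrix, zero diagonal (attribute `kind`
#'   `"slatkin_fst"` or `"linearized_fst"`).
#' @export
slatkin_fst <- function(pi, linearize = FALSE) {
  f <- phi_st(pi)
  attr(f, "kind") <- "slatkin_fst"
  if (!linearize) return(f)
  if (any(f == 1)) warning("F_ST = 1: linearized distance is infinite")
  out <- f / (1 - f)
  diag(out) <- 0
  attr(out, "kind") <- "linearized_fst"
  out
}
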