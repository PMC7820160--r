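upper_entries <- function(M) M[upper.tri(M)]

## all n! permutations of 1..n as rows (used for exact nulls, n <= 7)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

## correlation of each row of M with y
row_cor <- function(M, y) {
  k <- length(y)
  My <- as.vector(M %*% y)
  sM <- rowSums(M); sM2 <- rowSums(M^2)
  num <- My - sM * sum(y) / k
  den <- sqrt((sM2 - sM^2 / k) * (sum(y^2) - sum(y)^2 / k))
  ifelse(den > 0, num / den, NA_real_)
}

## upper-triangle entries of M[g, g] for every permutation row g of perms
permuted_upper <- function(M, perms) {
  n <- nrow(M)
  ij <- which(upper.tri(M), arr.ind = TRUE)
  gi <- perms[, ij[, 1], drop = FALSE]
  gj <- perms[, ij[, 2], drop = FALSE]
  matrix(M[(gj - 1L) * n + gi], nrow(perms))
}

check_mantel_input <- function(...) {
  ms <- list(...)
  lapply(ms, check_distance_matrix)
  labs <- rownames(ms[[1]])
  if (length(labs) < 3) stop("Mantel tests need >= 3 labels")
  for (m in ms[-1]) {
    if (!identical(rownames(m), labs)) {
      stop("distance matrices must share labels in the same order")
    }
  }
  for (m in ms) {
    if (stats::sd(upper_entries(m)) == 0) {
      stop("Mantel statistic undefined: zero variance in off-diagonal entries")
    }
  }
  invisible(labs)
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation over the n(n-1)/2 upper-off-diagonal entries.
#'
#' @param A,B labeled symmetric matrices with identical labels in identical
#'   order, n >= 3, nonzero off-diagonal variance.
#' @return correlation in \[-1, 1\].
#' @export
mantel_r <- function(A, B) {
  check_mantel_input(A, B)
  stats::cor(upper_entries(A), upper_entries(B))
}

make_perms <- function(n, n_perm, method) {
  if (method == "exact") {
    all_permutations(n)
  } else {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  }
}

count_extreme <- function(null_stats, observed, alternative, tol = 1e-12) {
  switch(alternative,
         greater = sum(null_stats >= observed - tol, na.rm = TRUE),
         less = sum(null_stats <= observed + tol, na.rm = TRUE),
         two.sided = sum(abs(null_stats) >= abs(observed) - tol, na.rm = TRUE))
}

mantel_result <- function(statistic, p_value, null_stats, n_perm, method,
                          scheme, alternative, seed, n_labels) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_permutations = n_perm, method = method, scheme = scheme,
                 alternative = alternative, seed = seed, n_labels = n_labels,
                 null_quantiles = stats::quantile(
                   null_stats, c(0.025, 0.5, 0.975), na.rm = TRUE,
                   names = FALSE)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test (%s, %s): r = %.4f, p = %.4g (%d %s)\n",
              if (x$scheme == "partial") "partial" else "simple",
              x$method, x$alternative, x$statistic, x$p_value,
              x$n_permutations,
              if (x$method == "exact") "enumerated permutations"
              else "random permutations"))
  invisible(x)
}

#' Mantel permutation test
#'
#' The null distribution is built by simultaneous random row/column
#' permutations of `B` while `A` stays fixed. For `n <= 7` labels all `n!`
#' permutations are enumerated (exact p-value: the fraction of
#' permutations, identity included, at least as extreme as the observed
#' statistic); otherwise `n_perm` random permutations are drawn and
#' `p = (1 + #extreme) / (1 + n_perm)`. Ties with the observed statistic
#' count as extreme.
#'
#' @inheritParams mantel_r
#' @param n_perm Monte-Carlo permutation count, default 10000.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param seed optional integer seed (Monte-Carlo mode).
#' @param method `"auto"` (exact when n <= 7), `"exact"` or
#'   `"monte-carlo"`.
#' @return object of class `mantel_result`.
#' @export
mantel_test <- function(A, B, n_perm = 10000,
                        alternative = c("greater", "less", "two.sided"),
                        seed = NULL, method = c("auto", "exact", "monte-carlo")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  labs <- check_mantel_input(A, B)
  n <- length(labs)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (method == "auto") method <- if (n <= 7) "exact" else "monte-carlo"
  if (method == "exact" && n > 9) stop("exact enumeration infeasible for n > 9")
  if (!is.null(seed)) set.seed(seed)
  a <- upper_entries(A)
  r_obs <- stats::cor(a, upper_entries(B))
  perms <- make_perms(n, n_perm, method)
  null_stats <- row_cor(permuted_upper(B, perms), a)
  k <- count_extreme(null_stats, r_obs, alternative)
  p <- if (method == "exact") k / nrow(perms) else (1 + k) / (1 + n_perm)
  mantel_result(r_obs, p, null_stats, nrow(perms), method, "simple",
                alternative, seed, n)
}

partial_r <- function(r_ab, r_ac, r_bc) {
  den2 <- (1 - r_ac^2) * (1 - r_bc^2)
  ifelse(den2 > 0, (r_ab - r_ac * r_bc) / sqrt(den2), NA_real_)
}

#' Partial Mantel permutation test
#'
#' Observed statistic: the first-order partial correlation
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))` over
#' upper-off-diagonal entries. The null permutes the rows/columns of the
#' raw matrix `A` while `B` and `C` stay fixed, recomputing the full
#' partial statistic each draw (Legendre's Method 1; residual-permutation
#' variants are deliberately not implemented). Exact enumeration and the
#' p-value conventions are as in [mantel_test()].
#'
#' @param A,B,C labeled symmetric matrices, identical labels and order;
#'   `A` is the response-side matrix that gets permuted.
#' @inheritParams mantel_test
#' @return object of class `mantel_result`.
#' @export
partial_mantel_test <- function(A, B, C, n_perm = 10000,
                                alternative = c("greater", "less", "two.sided"),
                                seed = NULL,
                                method = c("auto", "exact", "monte-carlo")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  labs <- check_mantel_input(A, B, C)
  n <- length(labs)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (method == "auto") method <- if (n <= 7) "exact" else "monte-carlo"
  if (method == "exact" && n > 9) stop("exact enumeration infeasible for n > 9")
  if (!is.null(seed)) set.seed(seed)
  b <- upper_entries(B); cc <- upper_entries(C)
  r_bc <- stats::cor(b, cc)
  a <- upper_entries(A)
  r_ab <- stats::cor(a, b); r_ac <- stats::cor(a, cc)
  if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12) {
    stop("degenerate control: a correlation with C has magnitude 1")
  }
  r_obs <- partial_r(r_ab, r_ac, r_bc)
  perms <- make_perms(n, n_perm, method)
  ap <- permuted_upper(A, perms)
  null_stats <- partial_r(row_cor(ap, b), row_cor(ap, cc), r_bc)
  k <- count_extreme(null_stats, r_obs, alternative)
  p <- if (method == "exact") k / nrow(perms) else (1 + k) / (1 + n_perm)
  mantel_result(r_obs, p, null_stats, nrow(perms), method, "partial",
                alternative, seed, n)
}
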