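#' Concatenate diploid calls into pseudo-haplotype allele sequences
#'
#' Gametic phase is unknown for unlinked reduced-representation loci, so
#' each individual's two allele copies per site are emitted in random order
#' into a concatenated allele sequence: site s occupies columns 2s-1 and 2s
#' of the output, each holding 0 (reference) or 1 (alternate); missing calls
#' become NA at both positions. Homozygous calls are unaffected by the
#' ordering; for heterozygotes the copy order is an independent fair coin
#' flip per individual and site.
#'
#' @param x filtered [snp_matrix()]
#' @param seed optional integer seed making the concatenation reproducible.
#' @return integer matrix, individuals x (2 * sites), values 0/1/NA, with
#'   attribute `site` mapping each column to its source site index.
#' @export
concatenate_random_alleles <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(x)
  n <- nrow(m); L <- ncol(m)
  ref_first <- matrix(stats::runif(n * L) < 0.5, n, L)
  half <- m %/% 2L                       # 0 for 0/1, 1 for 2
  first <- ifelse(m == 1L, ifelse(ref_first, 0L, 1L), half)
  second <- ifelse(m == 1L, ifelse(ref_first, 1L, 0L), half)
  out <- matrix(NA_integer_, n, 2L * L)
  out[, seq(1L, 2L * L, by = 2L)] <- first
  out[, seq(2L, 2L * L, by = 2L)] <- second
  rownames(out) <- rownames(m)
  colnames(out) <- paste0(rep(colnames(m), each = 2), c(".a", ".b"))
  attr(out, "site") <- rep(seq_len(L), each = 2)
  cls <- attr(x, "site_class")
  if (!is.null(cls)) attr(out, "class") <- rep(cls, each = 2)
  out
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with P and Q the
#' transition and transversion proportions over pairwise-complete positions.
#' Biallelic 0/1 pseudo-sequences carry no nucleotide identities, so each
#' position is assigned a substitution class via `classes`; the default
#' treats every difference as a transition (Q = 0), making the distance a
#' monotone transform of the p-distance.
#'
#' @param seq_i,seq_j equal-length vectors (0/1 integer or character);
#'   NA marks a gap/unknown position.
#' @param classes per-position substitution class, `"ts"` (transition) or
#'   `"tv"` (transversion); recycled; default all `"ts"`.
#' @return distance in substitutions per site.
#' @export
k2p_distance <- function(seq_i, seq_j, classes = "ts") {
  if (length(seq_i) != length(seq_j)) stop("sequences must have equal length")
  classes <- rep_len(classes, length(seq_i))
  if (!all(classes %in% c("ts", "tv"))) stop("classes must be 'ts' or 'tv'")
  ok <- !is.na(seq_i) & !is.na(seq_j)
  n <- sum(ok)
  if (n < 1) stop("no pairwise-complete positions")
  diff <- ok & (seq_i != seq_j)
  P <- sum(diff & classes == "ts") / n
  Q <- sum(diff & classes == "tv") / n
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0) {
    stop("K2P distance undefined (saturation): 1-2P-Q = ", signif(a, 4),
         ", 1-2Q = ", signif(b, 4))
  }
  -0.5 * log(a * sqrt(b))
}

#' Pairwise K2P distance matrix over a set of sequences
#'
#' @param seqs matrix of aligned sequences in rows (e.g. from
#'   [concatenate_random_alleles()]).
#' @param classes per-position substitution classes, as in
#'   [k2p_distance()]; defaults to the matrix's `class` attribute when
#'   present (carried over from recorded ref/alt bases), else all
#'   transitions.
#' @return labeled symmetric distance matrix (attribute `kind = "k2p"`).
#' @details All pairs are computed at once from cross-products of the 0/1
#'   allele matrix split by substitution class; results are identical to
#'   calling [k2p_distance()] on every pair, and a saturated pair raises
#'   the same error.
#' @export
k2p_matrix <- function(seqs, classes = NULL) {
  if (is.null(classes)) {
    classes <- attr(seqs, "class")
    if (is.null(classes)) classes <- "ts"
  }
  classes <- rep_len(classes, ncol(seqs))
  if (!all(classes %in% c("ts", "tv"))) stop("classes must be 'ts' or 'tv'")
  n <- nrow(seqs)
  V <- matrix(as.numeric(!is.na(seqs)), n)          # validity mask
  M <- matrix(as.numeric(seqs == 1L), n)            # alt-allele indicator
  M[V == 0] <- 0
  n_complete <- V %*% t(V)
  if (any(n_complete[upper.tri(n_complete)] < 1)) {
    stop("no pairwise-complete positions for some sequence pair")
  }
  mismatches <- function(cols) {
    if (!length(cols)) return(matrix(0, n, n))
    A <- M[, cols, drop = FALSE]
    B <- (1 - M[, cols, drop = FALSE]) * V[, cols, drop = FALSE]
    A %*% t(B) + B %*% t(A)
  }
  P <- mismatches(which(classes == "ts")) / n_complete
  Q <- mismatches(which(classes == "tv")) / n_complete
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  bad <- (a <= 0 | b <= 0) & upper.tri(a)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("K2P distance undefined (saturation): 1-2P-Q = ",
         signif(a[w[1], w[2]], 4), ", 1-2Q = ", signif(b[w[1], w[2]], 4))
  }
  d <- -0.5 * log(a * sqrt(b))
  diag(d) <- 0
  dimnames(d) <- list(rownames(seqs), rownames(seqs))
  attr(d, "kind") <- "k2p"
  d
}
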