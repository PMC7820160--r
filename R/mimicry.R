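#' Mimic ratio
#'
#' Fraction of females displaying the mimetic phenotype:
#' `MR = n_mimic / (n_mimic + n_nonmimic)`.
#'
#' @param n_mimic,n_nonmimic nonnegative counts (vectorized).
#' @return proportion in \[0, 1\].
#' @export
mimic_ratio <- function(n_mimic, n_nonmimic) {
  check_counts(n_mimic, n_nonmimic)
  tot <- n_mimic + n_nonmimic
  if (any(tot < 1)) stop("mimic ratio undefined: no females counted")
  n_mimic / tot
}

#' Advantage index of Batesian mimicry
#'
#' The advantage index is the local abundance of the unpalatable model
#' species relative to model plus mimic abundance,
#' `AI = n_model / (n_mimic + n_model)`: the higher the model share, the
#' greater the protective benefit per mimic, and under negative
#' frequency-dependent selection the mimic-ratio equilibrium tracks it.
#' The variant `advantage_index_uesugi()` keeps nonmimetic females in the
#' denominator, `AI_U = n_model / (n_mimic + n_nonmimic + n_model)`;
#' `AI >= AI_U` always, with equality iff `n_nonmimic = 0`.
#'
#' @param n_model,n_mimic,n_nonmimic nonnegative counts (vectorized).
#' @return proportion in \[0, 1\].
#' @export
advantage_index <- function(n_model, n_mimic) {
  check_counts(n_model, n_mimic)
  den <- n_mimic + n_model
  if (any(den < 1)) stop("advantage index undefined: empty denominator")
  n_model / den
}

#' @rdname advantage_index
#' @export
advantage_index_uesugi <- function(n_model, n_mimic, n_nonmimic) {
  check_counts(n_model, n_mimic, n_nonmimic)
  den <- n_mimic + n_nonmimic + n_model
  if (any(den < 1)) stop("advantage index undefined: empty denominator")
  n_model / den
}

check_counts <- function(...) {
  for (v in list(...)) {
    if (anyNA(v) || any(v < 0)) stop("counts must be nonnegative and non-NA")
  }
  invisible(NULL)
}

#' Absolute pairwise-difference matrix of per-island scalars
#'
#' Turns per-island values (mimic ratios, advantage indices) into the
#' symmetric distance matrix `|v_i - v_j|` consumed by Mantel tests.
#'
#' @param values named numeric vector, one value per island (>= 2).
#' @param kind optional tag stored as attribute `kind`.
#' @return symmetric matrix with zero diagonal.
#' @export
difference_matrix <- function(values, kind = "difference") {
  if (is.null(names(values))) stop("values must be named by island")
  if (length(values) < 2) stop("need >= 2 islands")
  if (anyNA(values)) stop("missing island value")
  m <- abs(outer(values, values, "-"))
  dimnames(m) <- list(names(values), names(values))
  attr(m, "kind") <- kind
  m
}

#' Per-island mimicry index table
#'
#' @param counts [count_table()]
#' @return data.frame with `island`, `mr`, `ai`, `ai_uesugi`.
#' @export
mimicry_indices <- function(counts) {
  data.frame(island = counts$island,
             mr = mimic_ratio(counts$n_mimic, counts$n_nonmimic),
             ai = advantage_index(counts$n_model, counts$n_mimic),
             ai_uesugi = advantage_index_uesugi(counts$n_model,
                                               counts$n_mimic,
                                               counts$n_nonmimic),
             stringsAsFactors = FALSE)
}
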