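#' Neighbor-joining tree from a distance matrix
#'
#' Canonical agglomeration: at each step the pair (i, j) minimizing
#' `Q_ij = (r-2) d_ij - R_i - R_j` (r active nodes, R the row sums) is
#' joined, with branch lengths `l_i = d_ij/2 + (R_i - R_j)/(2(r-2))`,
#' `l_j = d_ij - l_i`, and distances to the new node
#' `(d_ik + d_jk - d_ij)/2`. Ties in Q are broken deterministically by the
#' smallest (row, column) pair in the current node order (input label order,
#' then creation order of joined nodes). The last three nodes are connected
#' through a single internal node by the three-point formulas, giving the
#' usual unrooted representation with a basal trifurcation. The method is
#' exact on additive matrices. Negative branch lengths are retained as
#' computed unless `clamp_negative` is set.
#'
#' @param D labeled symmetric distance matrix with at least 3 labels.
#' @param clamp_negative replace negative branch lengths by zero.
#' @return unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(D, clamp_negative = FALSE) {
  check_distance_matrix(D)
  if (nrow(D) < 3) stop("neighbor joining needs >= 3 labels")
  if (any(!is.finite(D))) stop("non-finite distances")
  fmt <- function(x) sprintf("%.12g", if (clamp_negative) max(x, 0) else x)
  nodes <- as.list(rownames(D))
  d <- unname(as.matrix(D))
  while (length(nodes) > 3) {
    r <- length(nodes)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    frag <- paste0("(", nodes[[i]], ":", fmt(li), ",",
                   nodes[[j]], ":", fmt(lj), ")")
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    nodes <- c(nodes[keep], frag)
  }
  x1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  x2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  x3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", nodes[[1]], ":", fmt(x1), ",", nodes[[2]], ":", fmt(x2),
                ",", nodes[[3]], ":", fmt(x3), ");")
  ape::read.tree(text = nwk)
}

## canonical bipartition keys of a tree's internal edges; the side not
## containing the alphabetically first tip label is sorted and pasted.
bipartition_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- sort(labs)[1]
  vapply(pp, function(ix) {
    side <- labs[ix]
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, character(1))
}

#' Site-resampling bootstrap support for a tree
#'
#' Columns of `x` (SNP sites or alignment positions) are resampled with
#' replacement `n_reps` times; `tree_builder` is rerun on each replicate
#' and every internal edge of the point-estimate tree is annotated with the
#' percentage of successful replicates containing the same bipartition.
#' Replicates on which the builder fails (e.g. saturated distances) are
#' dropped and counted; supports are percentages of the successful
#' replicates.
#'
#' @param x matrix whose columns are the resampling unit ([snp_matrix()] of
#'   SNP sites, or site-level sequences).
#' @param tree_builder function mapping such a matrix to a `phylo` tree,
#'   e.g. `function(m) neighbor_joining(k2p_matrix(concatenate_random_alleles(m)))`.
#' @param n_reps bootstrap replicates, default 1000.
#' @param seed optional integer seed.
#' @param consensus also return the majority-rule consensus of the
#'   replicate trees (the point-estimate tree with supports remains the
#'   primary output).
#' @return list of class `bootstrap_tree`: `tree` (point-estimate `phylo`
#'   with node labels holding supports, root unlabeled), `supports`
#'   (percent, one per internal node), `n_success`, `n_failed`, and
#'   `consensus` (majority-rule `phylo`, or NULL).
#' @export
bootstrap_support <- function(x, tree_builder, n_reps = 1000, seed = NULL,
                              consensus = FALSE) {
  if (ncol(x) < 2) stop("need >= 2 sites to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  point <- tree_builder(x)
  keys <- bipartition_keys(point)
  counts <- integer(length(keys))
  n_failed <- 0L
  kept <- if (consensus) vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(x), replace = TRUE)
    tr <- tryCatch(tree_builder(x[, cols, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(tr)) {
      n_failed <- n_failed + 1L
    } else {
      counts <- counts + as.integer(keys %in% bipartition_keys(tr))
      if (consensus) kept[[b]] <- tr
    }
  }
  n_success <- n_reps - n_failed
  if (n_success == 0) stop("all bootstrap replicates failed")
  supports <- 100 * counts / n_success
  supports[keys == ""] <- NA_real_     # root: trivial bipartition
  point$node.label <- ifelse(is.na(supports), "",
                             sprintf("%.4g", supports))
  cons <- NULL
  if (consensus) {
    kept <- kept[!vapply(kept, is.null, logical(1))]
    cons <- ape::consensus(kept, p = 0.5)
  }
  structure(list(tree = point, supports = supports,
                 n_success = n_success, n_failed = n_failed,
                 consensus = cons),
            class = "bootstrap_tree")
}

#' @export
print.bootstrap_tree <- function(x, ...) {
  cat(sprintf("bootstrap NJ tree: %d tips, %d/%d successful replicates\n",
              length(x$tree$tip.label), x$n_success,
              x$n_success + x$n_failed))
  cat("supports:", paste(stats::na.omit(round(x$supports, 1)),
                         collapse = ", "), "\n")
  invisible(x)
}
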