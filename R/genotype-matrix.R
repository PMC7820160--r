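#' SNP genotype matrix
#'
#' Container for diploid biallelic SNP calls: an integer matrix with
#' individuals in rows and SNP sites in columns. Each call is the count of
#' the alternate allele (0, 1 or 2); missing calls are `NA`. An optional
#' locus grouping maps each site to the sequenced locus it came from, for
#' reduced-representation data where one locus may carry several SNP sites.
#'
#' @param calls matrix coercible to integer with values in `{0, 1, 2, NA}`.
#'   Row names label individuals, column names label sites; defaults are
#'   generated when absent.
#' @param loci optional character vector, one entry per site, naming the
#'   locus each site belongs to.
#' @param site_class optional per-site substitution class (`"ts"`
#'   transition / `"tv"` transversion), known when ref/alt nucleotides are
#'   recorded; used by K2P distances downstream.
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(calls, loci = NULL, site_class = NULL) {
  calls <- as.matrix(calls)
  if (is.data.frame(calls)) calls <- data.matrix(calls)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    stop("genotype calls must be 0, 1, 2 or NA; found ",
         paste(unique(calls[bad]), collapse = ", "))
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("ind%03d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("site%04d", seq_len(ncol(calls)))
  }
  if (anyDuplicated(rownames(calls))) stop("duplicated individual labels")
  if (anyDuplicated(colnames(calls))) stop("duplicated site labels")
  if (!is.null(loci)) {
    if (length(loci) != ncol(calls)) {
      stop("'loci' must have one entry per site (", ncol(calls), "), got ",
           length(loci))
    }
    loci <- as.character(loci)
  }
  if (!is.null(site_class)) {
    site_class <- rep_len(as.character(site_class), ncol(calls))
    if (!all(site_class %in% c("ts", "tv"))) {
      stop("site_class entries must be 'ts' or 'tv'")
    }
  }
  structure(calls, loci = loci, site_class = site_class,
            class = c("snp_matrix", "matrix", "array"))
}

#' @export
`[.snp_matrix` <- function(x, i, j, drop = FALSE) {
  loci <- attr(x, "loci")
  cls <- attr(x, "site_class")
  m <- unclass(x)
  attr(m, "loci") <- NULL
  attr(m, "site_class") <- NULL
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  out <- m[i, j, drop = FALSE]
  if (!is.null(loci)) {
    names(loci) <- colnames(m)
    loci <- unname(loci[j])
  }
  if (!is.null(cls)) {
    names(cls) <- colnames(m)
    cls <- unname(cls[j])
  }
  # resampling with replacement (bootstrap) duplicates labels: disambiguate
  if (anyDuplicated(rownames(out))) rownames(out) <- make.unique(rownames(out))
  if (anyDuplicated(colnames(out))) colnames(out) <- make.unique(colnames(out))
  snp_matrix(out, loci = loci, site_class = cls)
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d individuals x %d sites (%.1f%% missing)%s\n",
              nrow(x), ncol(x), 100 * mean(is.na(x)),
              if (!is.null(attr(x, "loci"))) {
                sprintf(", %d loci", length(unique(attr(x, "loci"))))
              } else ""))
  n <- min(nrow(x), 6L); p <- min(ncol(x), 8L)
  print(unclass(x)[seq_len(n), seq_len(p), drop = FALSE])
  if (nrow(x) > n || ncol(x) > p) cat("...\n")
  invisible(x)
}

#' @export
is_snp_matrix <- function(x) inherits(x, "snp_matrix")

## fraction of missing calls per site / per individual
missing_by_site <- function(x) colMeans(is.na(x))
missing_by_individual <- function(x) rowMeans(is.na(x))

## alternate-allele sample frequency per site (pairwise deletion)
alt_freq <- function(x) colMeans(unclass(x), na.rm = TRUE) / 2

## non-missing diploid count per site
site_n <- function(x) colSums(!is.na(x))

#' Per-individual island and phenotype table
#'
#' @param individual,island character vectors of equal length.
#' @param phenotype optional phenotype per individual, one of `"mimic"`,
#'   `"nonmimic"` or `NA` (males / unscored).
#' @return data.frame with columns `individual`, `island`, `phenotype`.
#' @export
island_table <- function(individual, island, phenotype = NULL) {
  individual <- as.character(individual)
  island <- as.character(island)
  if (length(individual) != length(island)) {
    stop("individual and island must have equal length")
  }
  if (anyDuplicated(individual)) stop("duplicated individual labels")
  if (is.null(phenotype)) phenotype <- rep(NA_character_, length(individual))
  phenotype <- as.character(phenotype)
  ok <- is.na(phenotype) | phenotype %in% c("mimic", "nonmimic")
  if (!all(ok)) stop("phenotype must be 'mimic', 'nonmimic' or NA")
  data.frame(individual = individual, island = island,
             phenotype = phenotype, stringsAsFactors = FALSE)
}

## split row indices of a genotype matrix by island, checking coverage
island_rows <- function(x, islands) {
  stopifnot(is.data.frame(islands),
            all(c("individual", "island") %in% names(islands)))
  miss <- setdiff(rownames(x), islands$individual)
  if (length(miss)) {
    stop("individuals absent from island table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  isl <- islands$island[match(rownames(x), islands$individual)]
  split(seq_len(nrow(x)), isl)
}
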