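#' Read a genotype matrix
#'
#' Supported formats:
#' \describe{
#'   \item{`vcf`}{biallelic SNP records of a VCF with GT fields; `./.` (or
#'     `.`) maps to missing. Non-biallelic records are skipped with a
#'     warning reporting the count. The locus grouping is taken from the
#'     CHROM column (reduced-representation loci are commonly encoded as one
#'     "chromosome" per locus), site labels from the ID column when present.}
#'   \item{`structure`}{Structure-like tabular dialect: a header row of site
#'     labels, then one row per individual holding the individual label
#'     followed by two allele columns (0/1) per site; -9 encodes a missing
#'     allele, and a genotype with any missing allele is missing.}
#'   \item{`tsv`}{plain table of 0/1/2 alternate-allele counts, individuals
#'     in rows (first column = label), sites in columns, NA for missing.}
#' }
#'
#' @param path file path.
#' @param format `"vcf"`, `"structure"`, `"tsv"`, or `"auto"` (by extension).
#' @return [snp_matrix()]
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "structure", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     vcf = "vcf", str = "structure", stru = "structure",
                     "tsv")
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         structure = read_genotypes_structure(path),
         tsv = read_genotypes_tsv(path))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warning(sum(!bi), " non-biallelic VCF record(s) skipped")
    v <- v[bi, ]
  }
  if (nrow(v@fix) == 0) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- v@fix
  ids <- fix[, "ID"]
  lab <- ifelse(is.na(ids) | ids == ".",
                paste(fix[, "CHROM"], fix[, "POS"], sep = "_"), ids)
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    out
  }
  calls <- apply(gt, 2, code)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1,
                                           dimnames = list(NULL, colnames(gt)))
  rownames(calls) <- lab
  purine <- c("A", "G")
  cls <- ifelse((fix[, "REF"] %in% purine) == (fix[, "ALT"] %in% purine),
                "ts", "tv")
  snp_matrix(t(calls), loci = fix[, "CHROM"], site_class = cls)
}

#' Write a genotype matrix
#'
#' Writing then reading any format is the identity on calls and labels.
#' The VCF writer emits minimal plain-text VCFv4.2; REF is fixed at A and
#' ALT encodes the site's substitution class (G for transitions, C for
#' transversions, defaulting to transition when no class is recorded), since
#' the matrices handled here carry allele counts, not nucleotide identities.
#'
#' @param x [snp_matrix()]
#' @param path output file path.
#' @param format one of `"vcf"`, `"structure"`, `"tsv"`.
#' @export
write_genotypes <- function(x, path, format = c("vcf", "structure", "tsv")) {
  format <- match.arg(format)
  switch(format,
         vcf = write_genotypes_vcf(x, path),
         structure = write_genotypes_structure(x, path),
         tsv = write_genotypes_tsv(x, path))
  invisible(path)
}

write_genotypes_vcf <- function(x, path) {
  loci <- attr(x, "loci")
  chrom <- if (is.null(loci)) colnames(x) else loci
  pos <- stats::ave(seq_len(ncol(x)), chrom, FUN = seq_along)
  cls <- attr(x, "site_class")
  if (is.null(cls)) cls <- rep("ts", ncol(x))
  alt <- ifelse(cls == "ts", "G", "C")   # REF fixed at A: A/G ts, A/C tv
  gt_str <- matrix("./.", ncol(x), nrow(x))
  m <- t(unclass(x))  # sites x individuals
  gt_str[!is.na(m) & m == 0L] <- "0/0"
  gt_str[!is.na(m) & m == 1L] <- "0/1"
  gt_str[!is.na(m) & m == 2L] <- "1/1"
  body <- paste(chrom, pos, colnames(x), "A", alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(x)), collapse = "\t"))
  writeLines(c(header, body), path)
}

read_genotypes_structure <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("structure file needs a header and >= 1 row")
  sites <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  L <- length(sites)
  n <- length(lines) - 1L
  calls <- matrix(NA_integer_, n, L)
  labs <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
    if (length(f) != 2L * L + 1L) {
      stop("malformed structure row at line ", i + 1L, ": expected ",
           2L * L + 1L, " fields, got ", length(f))
    }
    labs[i] <- f[1]
    al <- suppressWarnings(as.integer(f[-1]))
    if (anyNA(al)) stop("non-numeric allele at line ", i + 1L)
    a1 <- al[seq(1L, 2L * L, by = 2L)]
    a2 <- al[seq(2L, 2L * L, by = 2L)]
    g <- a1 + a2
    g[a1 == -9L | a2 == -9L] <- NA_integer_
    if (any(!is.na(g) & !(g %in% 0:2))) {
      stop("allele codes must be 0/1 (or -9) at line ", i + 1L)
    }
    calls[i, ] <- g
  }
  rownames(calls) <- labs
  colnames(calls) <- sites
  snp_matrix(calls)
}

write_genotypes_structure <- function(x, path) {
  m <- unclass(x)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    g <- m[i, ]
    a1 <- ifelse(is.na(g), -9L, as.integer(g >= 1L))
    a2 <- ifelse(is.na(g), -9L, as.integer(g == 2L))
    paste(c(rownames(m)[i], as.vector(rbind(a1, a2))), collapse = "\t")
  }, character(1))
  writeLines(c(paste(colnames(m), collapse = "\t"), rows), path)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  snp_matrix(as.matrix(df))
}

write_genotypes_tsv <- function(x, path) {
  df <- as.data.frame(unclass(x), check.names = FALSE)
  utils::write.table(cbind(individual = rownames(x), df), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write per-individual island metadata
#'
#' CSV with columns `individual,island,phenotype`.
#' @param path file path.
#' @export
read_island_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "island")
  if (!all(need %in% names(df))) {
    stop("island table needs columns individual,island")
  }
  island_table(df$individual, df$island,
               if ("phenotype" %in% names(df)) df$phenotype else NULL)
}

#' @rdname read_island_table
#' @param islands data.frame as returned by [island_table()].
#' @export
write_island_table <- function(islands, path) {
  utils::write.csv(islands, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-island phenotype count tables
#'
#' CSV with columns `island,n_mimic,n_nonmimic,n_model`.
#' @param path file path.
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("island", "n_mimic", "n_nonmimic", "n_model")
  if (!all(need %in% names(df))) {
    stop("count table needs columns ", paste(need, collapse = ","))
  }
  count_table(df$island, df$n_mimic, df$n_nonmimic, df$n_model)
}

#' @rdname read_count_table
#' @param counts data.frame as returned by [count_table()].
#' @export
write_count_table <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-island count table of mimics, nonmimics and model-species individuals
#'
#' @param island island labels.
#' @param n_mimic,n_nonmimic counts of mimetic and nonmimetic females.
#' @param n_model counts of model-species individuals.
#' @export
count_table <- function(island, n_mimic, n_nonmimic, n_model) {
  df <- data.frame(island = as.character(island),
                   n_mimic = as.integer(n_mimic),
                   n_nonmimic = as.integer(n_nonmimic),
                   n_model = as.integer(n_model),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$island)) stop("duplicated island labels")
  if (any(df$n_mimic < 0 | df$n_nonmimic < 0 | df$n_model < 0, na.rm = TRUE)) {
    stop("counts must be nonnegative")
  }
  df
}

#' Read / write a labeled symmetric distance matrix
#'
#' Two on-disk forms: `"tsv"` (header of labels, rows `label<TAB>values`) and
#' `"phylip"` (square PHYLIP: first line n, then `label value...`).
#'
#' @param path file path.
#' @param format `"tsv"` or `"phylip"` (`"auto"` picks by extension,
#'   `.phy`/`.dist` meaning phylip).
#' @export
read_distance_matrix <- function(path, format = c("auto", "tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("phy", "dist"))
      "phylip" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
  } else {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1]))
    f <- lapply(lines[1 + seq_len(n)], function(l) strsplit(trimws(l), "[ \t]+")[[1]])
    labs <- vapply(f, `[`, character(1), 1)
    m <- t(vapply(f, function(v) as.numeric(v[-1]), numeric(n)))
    dimnames(m) <- list(labs, labs)
  }
  check_distance_matrix(m)
  m
}

#' @rdname read_distance_matrix
#' @param m labeled symmetric numeric matrix.
#' @export
write_distance_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  check_distance_matrix(m)
  if (format == "tsv") {
    df <- as.data.frame(m, check.names = FALSE)
    utils::write.table(cbind(label = rownames(m), df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    rows <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], sprintf("%.10g", m[i, ])), collapse = "  ")
    }, character(1))
    writeLines(c(as.character(nrow(m)), rows), path)
  }
  invisible(path)
}

check_distance_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("not a square matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) stop("matrix must be labeled")
  if (!identical(rownames(m), colnames(m))) stop("row/column labels differ")
  if (max(abs(m - t(m)), na.rm = TRUE) > tol) stop("matrix not symmetric")
  invisible(m)
}
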