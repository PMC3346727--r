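#' Construct a genotype matrix with a binary phenotype
#'
#' The central data container of the package: additive minor-allele dosages
#' (0, 1 or 2 copies, `NA` for missing) for samples by SNPs, plus a binary
#' case-control phenotype.  All pathway tests operate on this object.
#'
#' @param dosages Integer-like matrix (samples x SNPs) with values 0, 1, 2 or
#'   `NA`.
#' @param phenotype Vector of 0 (control) / 1 (case), one value per sample.
#' @param sample_ids,snp_ids Optional identifier vectors; default to the
#'   `dimnames` of `dosages` or generated identifiers.
#' @return An object of class `genotype_matrix` with elements `dosages`
#'   (integer matrix with dimnames), `phenotype` (integer vector),
#'   `sample_ids` and `snp_ids`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 2L, 1L, 0L), 2, 2), phenotype = c(1, 0))
#' gm
#' @export
genotype_matrix <- function(dosages, phenotype, sample_ids = NULL,
                            snp_ids = NULL) {
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix")
  mode(dosages) <- "integer"
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) {
    abort(sprintf("dosages must be 0, 1, 2 or NA (%d offending cells)",
                  sum(bad)))
  }
  if (length(phenotype) != nrow(dosages)) {
    abort("`phenotype` must have one value per sample (matrix row)")
  }
  phenotype <- as.integer(phenotype)
  if (anyNA(phenotype) || !all(phenotype %in% c(0L, 1L))) {
    abort("`phenotype` must be coded 0 (control) / 1 (case)")
  }
  sample_ids <- as.character(sample_ids %||% rownames(dosages) %||%
                               sprintf("sample%04d", seq_len(nrow(dosages))))
  snp_ids <- as.character(snp_ids %||% colnames(dosages) %||%
                            sprintf("snp%04d", seq_len(ncol(dosages))))
  if (length(sample_ids) != nrow(dosages) || length(snp_ids) != ncol(dosages)) {
    abort("identifier lengths do not match the dosage matrix dimensions")
  }
  if (anyDuplicated(snp_ids)) abort("SNP identifiers must be unique")
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(
    list(dosages = dosages, phenotype = phenotype,
         sample_ids = sample_ids, snp_ids = snp_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmis <- n_missing(x)
  cat(sprintf(
    "<genotype_matrix> %d samples x %d SNPs (%d cases / %d controls)%s\n",
    nrow(x$dosages), ncol(x$dosages), sum(x$phenotype == 1L),
    sum(x$phenotype == 0L),
    if (nmis > 0) sprintf(", %d missing dosages", nmis) else ""
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of missing dosage cells
#' @param x A [genotype_matrix()].
#' @return Integer count of `NA` dosage cells.
#' @export
n_missing <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  sum(is.na(x$dosages))
}

# resolve a SNP selection (NULL / integer indices / character ids /
# pathway_snp_set) to integer column indices of a genotype matrix
resolve_snp_subset <- function(x, snps) {
  if (is.null(snps)) return(seq_len(ncol(x$dosages)))
  if (inherits(snps, "pathway_snp_set")) snps <- snps$snp_ids
  if (is.character(snps)) {
    idx <- match(snps, x$snp_ids)
    if (anyNA(idx)) {
      abort(sprintf("SNPs not present in the genotype matrix: %s",
                    paste(utils::head(snps[is.na(idx)], 5), collapse = ", ")))
    }
    return(idx)
  }
  idx <- as.integer(snps)
  if (length(idx) == 0) abort("empty SNP subset")
  if (anyNA(idx) || any(idx < 1 | idx > ncol(x$dosages)) || anyDuplicated(idx)) {
    abort("SNP indices must be unique and within bounds")
  }
  idx
}

#' Impute missing genotypes by the per-SNP mode
#'
#' Replaces every missing dosage by the most frequent observed dosage of that
#' SNP.  Ties are broken deterministically toward the smaller dosage value.
#' This is a simple, deterministic stand-in for haplotype-based imputation,
#' adequate here because the tests treat genotypes as exchangeable predictors
#' rather than reconstructing haplotypes.
#'
#' @param x A [genotype_matrix()], possibly with `NA` dosages.
#' @return The genotype matrix with no missing values.  Idempotent.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 0L, 2L, NA), 4, 1), rep(c(0, 1), 2))
#' impute_missing(gm)$dosages
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosages
  miss_cols <- which(colSums(is.na(d)) > 0)
  for (j in miss_cols) {
    col <- d[, j]
    obs <- col[!is.na(col)]
    if (length(obs) == 0) {
      abort(sprintf("SNP '%s' has no observed genotypes; cannot impute",
                    x$snp_ids[j]))
    }
    counts <- tabulate(obs + 1L, nbins = 3L)
    mode_val <- which.max(counts) - 1L  # which.max takes the first (smallest) on ties
    col[is.na(col)] <- mode_val
    d[, j] <- col
  }
  x$dosages <- d
  x
}

#' Read a PLINK additive-dosage text file
#'
#' Parses the text layout produced by PLINK's `--recodeA` option: a header row
#' `FID IID PAT MAT SEX PHENOTYPE <snp> ...` followed by one row per sample
#' with dosages in 0/1/2/NA.  SNP header tokens of the form `rs123_A` yield
#' the SNP id `rs123` with counted allele `A` (stored in the
#' `counted_allele` attribute).
#'
#' @param path Path to the file.
#' @param phenotype_coding `"auto"` (default), `"0/1"`, or `"1/2"` (PLINK
#'   case-control coding, 2 = case).  Auto-detection errors on files whose
#'   phenotype column is ambiguous (e.g. mixes 0, 1 and 2).
#' @return A [genotype_matrix()]; missing dosages are retained as `NA` and
#'   should be resolved with [impute_missing()] before testing.
#' @export
read_additive_genotypes <- function(path,
                                    phenotype_coding = c("auto", "0/1", "1/2")) {
  phenotype_coding <- match.arg(phenotype_coding)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) abort("empty genotype file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  header <- toks[[1]]
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 7 || !identical(toupper(header[1:6]), lead)) {
    abort(paste("malformed header: expected the six leading sample columns",
                "FID IID PAT MAT SEX PHENOTYPE followed by SNP columns"))
  }
  snp_tokens <- header[-(1:6)]
  p <- length(snp_tokens)
  body <- toks[-1]
  n <- length(body)
  if (n == 0) abort("genotype file contains no sample rows")
  widths <- lengths(body)
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1]
    abort(sprintf("parse error at line %d: %d fields, expected %d",
                  bad + 1L, widths[bad], length(header)))
  }
  m <- matrix(unlist(body, use.names = FALSE), nrow = n, byrow = TRUE)
  sample_ids <- m[, 2]
  phen_raw <- m[, 6]
  dosage_chr <- m[, -(1:6), drop = FALSE]
  ok <- matrix(dosage_chr %in% c("0", "1", "2", "NA", "na"),
               nrow = nrow(dosage_chr))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    abort(sprintf("parse error at line %d: invalid dosage '%s'",
                  bad[1] + 1L, dosage_chr[bad[1], bad[2]]))
  }
  dosages <- matrix(suppressWarnings(as.integer(dosage_chr)), nrow = n)

  phen_num <- suppressWarnings(as.integer(phen_raw))
  if (anyNA(phen_num)) {
    abort(sprintf("phenotype value outside coding: '%s'",
                  phen_raw[which(is.na(phen_num))[1]]))
  }
  vals <- sort(unique(phen_num))
  coding <- phenotype_coding
  if (coding == "auto") {
    if (all(vals %in% c(0L, 1L))) coding <- "0/1"
    else if (all(vals %in% c(1L, 2L))) coding <- "1/2"
    else abort(sprintf(
      "ambiguous phenotype coding (values %s); pass `phenotype_coding`",
      paste(vals, collapse = ", ")))
  }
  phenotype <- switch(coding,
    "0/1" = {
      if (!all(vals %in% c(0L, 1L))) {
        abort("phenotype value outside the 0/1 coding")
      }
      phen_num
    },
    "1/2" = {
      if (!all(vals %in% c(1L, 2L))) {
        abort("phenotype value outside the 1/2 coding")
      }
      phen_num - 1L
    }
  )

  # split "<id>_<allele>" SNP tokens (PLINK --recodeA appends the counted allele)
  has_allele <- grepl("_[ACGT]$", snp_tokens)
  snp_ids <- ifelse(has_allele, sub("_[ACGT]$", "", snp_tokens), snp_tokens)
  counted <- ifelse(has_allele, sub("^.*_([ACGT])$", "\\1", snp_tokens),
                    NA_character_)
  gm <- genotype_matrix(dosages, phenotype, sample_ids = sample_ids,
                        snp_ids = snp_ids)
  attr(gm, "counted_allele") <- stats::setNames(counted, snp_ids)
  gm
}

#' Write / read a plain sample-by-SNP dosage table
#'
#' A simple TSV interchange format: columns `sample_id`, `phenotype` (0/1),
#' then one column per SNP with dosages 0/1/2/NA.  The round trip through
#' [write_genotype_tsv()] and [read_genotype_tsv()] preserves dosages,
#' identifiers and phenotype exactly.
#'
#' @param x A [genotype_matrix()].
#' @param path Output (input) file path.
#' @return `write_genotype_tsv()` returns `path` invisibly;
#'   `read_genotype_tsv()` returns a [genotype_matrix()].
#' @export
write_genotype_tsv <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  df <- data.frame(sample_id = x$sample_ids, phenotype = x$phenotype,
                   x$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = NA)
  if (ncol(df) < 3 || !identical(names(df)[1:2], c("sample_id", "phenotype"))) {
    abort("expected columns sample_id, phenotype, then SNP dosage columns")
  }
  dos <- as.matrix(df[, -(1:2), drop = FALSE])
  genotype_matrix(dos, df$phenotype, sample_ids = as.character(df$sample_id),
                  snp_ids = colnames(dos))
}

#' Write genotypes in the PLINK additive (`--recodeA`) text layout
#'
#' Inverse of [read_additive_genotypes()]: emits the
#' `FID IID PAT MAT SEX PHENOTYPE <snp> ...` header and one row per sample,
#' with the phenotype in PLINK 1/2 case-control coding.
#'
#' @inheritParams write_genotype_tsv
#' @return `path`, invisibly.
#' @export
write_additive_genotypes <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE", x$snp_ids)
  dos <- x$dosages
  dos_chr <- matrix(as.character(dos), nrow = nrow(dos))
  dos_chr[is.na(dos_chr)] <- "NA"
  rows <- cbind(x$sample_ids, x$sample_ids, "0", "0", "0",
                as.character(x$phenotype + 1L), dos_chr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = " "), con)
  writeLines(apply(rows, 1, paste, collapse = " "), con)
  invisible(path)
}
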