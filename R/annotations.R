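#' Read gene-set definitions in GMT format
#'
#' One tab-separated line per pathway: identifier, description, then gene
#' identifiers.  Duplicate genes within a line are dropped (first occurrence
#' kept).
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `pathway_id`, `name`, `gene_ids`
#'   (list-column of character vectors) and `n_genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(pathway_id = character(), name = character(),
                  gene_ids = list(), n_genes = integer()))
  }
  toks <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(toks) < 3)
  if (length(bad)) {
    abort(sprintf("parse error at GMT line %d: fewer than 3 tab-separated fields",
                  bad[1]))
  }
  tibble(
    pathway_id = vapply(toks, `[`, "", 1),
    name = vapply(toks, `[`, "", 2),
    gene_ids = lapply(toks, function(t) unique(t[-(1:2)])),
  ) |>
    dplyr::mutate(n_genes = lengths(.data$gene_ids))
}

#' Read SNP positions from a PLINK MAP file
#'
#' Accepts the 4-column layout (chromosome, SNP id, genetic distance,
#' base-pair position) or the 3-column layout without the genetic distance.
#'
#' @param path Path to a `.map` file (whitespace-separated, no header).
#' @return A tibble with columns `snp_id`, `chromosome`, `position` (1-based
#'   bp).
#' @export
read_snp_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (!ncol(df) %in% c(3, 4)) {
    abort("MAP file must have 3 or 4 columns (chrom, id[, cM], position)")
  }
  pos <- suppressWarnings(as.integer(df[[ncol(df)]]))
  if (anyNA(pos) || any(pos < 1)) {
    abort("MAP positions must be positive integers")
  }
  out <- tibble(snp_id = df[[2]], chromosome = df[[1]], position = pos)
  if (anyDuplicated(out$snp_id)) abort("duplicate SNP ids in MAP file")
  out
}

#' Read gene annotations from a 4-column TSV or a BED file
#'
#' The TSV layout is `gene_id`, `chromosome`, `start`, `end` with 1-based
#' inclusive coordinates (a header row naming those columns is recognised and
#' may be omitted).  BED input (`chrom`, `start`, `end`, `name`) is converted
#' from 0-based half-open to the internal 1-based inclusive convention.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by file extension), `"tsv"` or `"bed"`.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`.
#' @export
read_gene_annotations <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "bed") "bed" else "tsv"
  }
  df <- utils::read.table(path, header = FALSE, colClasses = "character",
                          sep = "", stringsAsFactors = FALSE)
  if (ncol(df) < 4) abort("gene annotation requires 4 columns")
  if (format == "tsv" &&
      identical(tolower(unlist(df[1, 1:4])),
                c("gene_id", "chromosome", "start", "end"))) {
    df <- df[-1, , drop = FALSE]
  }
  if (format == "bed") {
    out <- tibble(gene_id = df[[4]], chromosome = df[[1]],
                  start = suppressWarnings(as.integer(df[[2]])) + 1L,
                  end = suppressWarnings(as.integer(df[[3]])))
  } else {
    out <- tibble(gene_id = df[[1]], chromosome = df[[2]],
                  start = suppressWarnings(as.integer(df[[3]])),
                  end = suppressWarnings(as.integer(df[[4]])))
  }
  if (anyNA(out$start) || anyNA(out$end)) abort("non-numeric gene coordinates")
  if (any(out$start > out$end)) abort("gene start must not exceed end")
  if (any(out$start < 1)) abort("gene coordinates must be 1-based (start >= 1)")
  out
}

#' Map SNPs to a pathway through gene proximity
#'
#' A SNP belongs to a pathway when it lies on the same chromosome as one of
#' the pathway's genes and within `window_kb` kilobases of the gene body
#' (boundaries inclusive, `window = round(window_kb * 1000)` base pairs).
#' Each SNP is included once however many genes it hits; pathway genes absent
#' from the annotation are skipped and reported through `n_genes_matched`.
#'
#' @param pathway A one-row slice of a [read_gmt()] tibble, a list with
#'   elements `pathway_id` and `gene_ids`, or a plain character vector of gene
#'   ids.
#' @param genes Gene annotation tibble ([read_gene_annotations()]).
#' @param snps SNP annotation tibble ([read_snp_map()]).
#' @param window_kb Flanking distance in kilobases (default 20).
#' @return An object of class `pathway_snp_set`: `pathway_id`, `snp_ids`,
#'   `snp_indices` (row positions in `snps`, in annotation order),
#'   `n_genes_matched`, `window_kb`.
#' @export
map_snps_to_pathway <- function(pathway, genes, snps, window_kb = 20) {
  stopifnot(is.numeric(window_kb), length(window_kb) == 1, window_kb >= 0)
  if (is.character(pathway)) {
    pathway <- list(pathway_id = "pathway", gene_ids = pathway)
  }
  if (is.data.frame(pathway)) {
    stopifnot(nrow(pathway) == 1)
    pathway <- list(pathway_id = pathway$pathway_id[[1]],
                    gene_ids = pathway$gene_ids[[1]])
  }
  gene_ids <- unique(unlist(pathway$gene_ids))
  if (length(gene_ids) == 0) abort("pathway has no genes")
  window <- round(window_kb * 1000)
  g <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  hit <- logical(nrow(snps))
  for (i in seq_len(nrow(g))) {
    hit <- hit | (snps$chromosome == g$chromosome[i] &
                    snps$position >= g$start[i] - window &
                    snps$position <= g$end[i] + window)
  }
  idx <- which(hit)
  structure(
    list(pathway_id = pathway$pathway_id %||% "pathway",
         snp_ids = snps$snp_id[idx],
         snp_indices = idx,
         n_genes_matched = length(unique(g$gene_id)),
         window_kb = window_kb),
    class = "pathway_snp_set"
  )
}

#' @export
print.pathway_snp_set <- function(x, ...) {
  cat(sprintf("<pathway_snp_set> %s: %d SNPs via %d annotated genes (window %g kb)\n",
              x$pathway_id, length(x$snp_indices), x$n_genes_matched,
              x$window_kb))
  invisible(x)
}
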