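# Containers and file formats.
#
# Genotypes travel either as standard VCF (GT subfield, unphased) or as a
# plain TSV dialect: rows = individuals, columns = SNPs, cells 0/1/2/NA
# counting alternate alleles, with a sidecar SNP map (snp, chrom, pos).

#' Construct a genotype matrix container
#'
#' @param calls integer matrix, individuals x SNPs, values in `{0, 1, 2, NA}`
#'   counting alternate alleles; dimnames give animal and SNP ids.
#' @param map data frame with columns `snp`, `chrom` (character; `1`-`29`,
#'   `X`, `Y`), `pos` (1-based), one row per column of `calls`.
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("ind%04d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("snp%05d", seq_len(ncol(calls)))
  if (missing(map) || is.null(map)) {
    map <- data.frame(snp = colnames(calls),
                      chrom = as.character(rep_len(1:29, ncol(calls))),
                      pos = seq_len(ncol(calls)), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(map), nrow(map) == ncol(calls),
            all(c("snp", "chrom", "pos") %in% names(map)))
  if (anyDuplicated(rownames(calls)) || anyDuplicated(colnames(calls)))
    stop("individual and SNP ids must be unique", call. = FALSE)
  if (any(map$pos <= 0)) stop("SNP positions must be positive", call. = FALSE)
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad)) stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  map$snp <- as.character(map$snp)
  map$chrom <- as.character(map$chrom)
  if (!identical(map$snp, colnames(calls))) {
    stopifnot(setequal(map$snp, colnames(calls)))
    map <- map[match(colnames(calls), map$snp), , drop = FALSE]
  }
  rownames(map) <- NULL
  structure(list(calls = calls, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Write / read the TSV genotype dialect
#'
#' `write_genotypes_tsv()` writes two files: `<path>` with the call matrix
#' (first column `animal`, then one column per SNP) and `<path>.map` with the
#' SNP map. `read_genotypes_tsv()` reads them back.
#'
#' @param g a [genotype_matrix()].
#' @param path output TSV path.
#' @return `read_genotypes_tsv()` returns a [genotype_matrix()];
#'   `write_genotypes_tsv()` returns `path` invisibly.
#' @export
write_genotypes_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(animal = rownames(g$calls), g$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(g$map, paste0(path, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- df[[1]]
  map_path <- paste0(path, ".map")
  map <- if (file.exists(map_path)) {
    read.table(map_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else NULL
  genotype_matrix(calls, map)
}

#' Write / read genotypes as VCF
#'
#' Writes a minimal VCF 4.2 with unphased GT genotypes (the coded alternate
#' allele is the VCF ALT allele, so dosage 0/1/2 round-trips). Reading uses
#' the vcfR package.
#'
#' @param g a [genotype_matrix()].
#' @param path VCF file path (uncompressed).
#' @return `read_genotypes_vcf()` returns a [genotype_matrix()];
#'   `write_genotypes_vcf()` returns `path` invisibly.
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  calls <- t(g$calls)  # SNP x individual
  gt <- matrix("./.", nrow(calls), ncol(calls))
  ok <- !is.na(calls)
  gt[ok] <- gt_code[as.character(calls[ok])]
  body <- cbind(g$map$chrom, g$map$pos, g$map$snp, "A", "G", ".", "PASS",
                ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$calls)), collapse = "\t")),
             con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # count alternate alleles irrespective of phasing separator
  count_alt <- function(s) {
    ifelse(is.na(s) | s %in% c("./.", ".|.", "."), NA_integer_,
           vapply(strsplit(s, "[/|]"), function(a)
             sum(a != "." & a != "0"), integer(1)))
  }
  calls <- t(apply(gt, 1L, count_alt))
  dimnames(calls) <- dimnames(gt)
  fix <- vcfR::getFIX(v)
  map <- data.frame(snp = fix[, "ID"], chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  genotype_matrix(t(calls), map)
}

#' Read or write a genotype matrix, dispatching on file extension
#'
#' @param path file path; `.vcf` dispatches to the VCF reader/writer,
#'   anything else to the TSV dialect.
#' @param g a [genotype_matrix()] (writing only).
#' @return A [genotype_matrix()] (reading) or `path` invisibly (writing).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) read_genotypes_vcf(path)
  else read_genotypes_tsv(path)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(g, path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) write_genotypes_vcf(g, path)
  else write_genotypes_tsv(g, path)
}

#' Write / read an abundance table as TSV
#'
#' Rows are samples, columns are taxa; the first column holds sample ids.
#'
#' @param tab numeric matrix, samples x taxa.
#' @param path TSV path.
#' @return Reading returns the matrix; writing returns `path` invisibly.
#' @export
write_abundance_tsv <- function(tab, path) {
  df <- data.frame(sample = rownames(tab), tab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tab <- as.matrix(df[, -1, drop = FALSE])
  rownames(tab) <- df[[1]]
  tab
}

#' Write / read sample metadata as CSV
#'
#' Columns follow the generator: `animal`, `breed_group`, `brahman_fraction`,
#' `sex`, `age`, `stage`, body weights, `WG*`, `IgG1`.
#'
#' @param meta metadata data frame.
#' @param path CSV path.
#' @return Reading returns the data frame; writing returns `path` invisibly.
#' @export
write_metadata_csv <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a square matrix (distance or relationship) as TSV with header
#'
#' @param m square numeric matrix with dimnames.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_square_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
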