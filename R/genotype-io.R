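#' Read genotypes from VCF or dosage TSV
#'
#' VCF: biallelic SNP records only; GT `0/0`, `0/1`, `1/1` (or phased
#' equivalents) become dosages 0, 1, 2 and `./.` becomes missing. Multiallelic
#' or non-SNP records are skipped with a warning. Dosage TSV: one row per
#' variant with columns `id`, `chrom`, `pos`, `ref`, `alt` followed by one
#' numeric column per individual (empty cells = missing).
#'
#' @param path Input file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_tsv <- function(path) {
  tab <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("failed to parse dosage TSV ", path, ": ",
                             conditionMessage(e)))
  meta_cols <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(tab)))
    stop("dosage TSV must start with columns ", paste(meta_cols, collapse = ", "))
  ind <- setdiff(names(tab), meta_cols)
  if (length(ind) == 0 || nrow(tab) == 0) stop("empty genotype matrix in ", path)
  dos <- t(as.matrix(tab[, ind]))
  variants <- dplyr::mutate(tab[, meta_cols], chrom = as.character(.data$chrom))
  genotype_matrix(dos, variants, ind)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF ", path, ": ",
                                         conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("empty genotype matrix in ", path)
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!is_snp))
    warning(sum(!is_snp), " multiallelic/non-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  if (nrow(fix) == 0) stop("empty genotype matrix in ", path)
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  variants <- tibble::tibble(id = ids, chrom = fix$CHROM,
                             pos = as.integer(fix$POS),
                             ref = fix$REF, alt = fix$ALT)
  genotype_matrix(t(dos), variants, colnames(gt))
}

gt_to_dosage <- function(gt) {
  if (is.na(gt)) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(as.numeric(alleles))
}

#' Write genotypes to VCF or dosage TSV
#'
#' The VCF writer emits GT calls and therefore requires integer dosages
#' (kNN-imputed fractional dosages belong in the TSV format). Column order
#' is deterministic.
#'
#' @param G A [genotype_matrix()].
#' @param path Output file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    tab <- dplyr::bind_cols(G$variants,
                            tibble::as_tibble(t(G$dosages), .name_repair = "minimal"))
    names(tab) <- c(names(G$variants), G$individuals)
    readr::write_tsv(tab, path, na = "")
  } else {
    d <- G$dosages
    if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE))
      stop("VCF output requires integer dosages; use dosage_tsv for fractional values")
    gt_codes <- c("0/0", "0/1", "1/1")
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$individuals), collapse = "\t"))
    body <- vapply(seq_len(nrow(G$variants)), function(j) {
      v <- G$variants[j, ]
      calls <- ifelse(is.na(d[, j]), "./.", gt_codes[round(d[, j]) + 1])
      paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
              calls), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' Read / write a gene coordinate table
#'
#' TSV with columns `gene_id`, `chrom`, `start`, `end`; coordinates are
#' 1-based inclusive.
#'
#' @param path File path.
#' @return A tibble of gene models.
#' @export
read_gene_table <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(g)))
  if (any(g$start > g$end)) stop("gene models must satisfy start <= end")
  dplyr::mutate(g, chrom = as.character(.data$chrom))
}

#' @rdname read_gene_table
#' @param genes Gene table.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes[, c("gene_id", "chrom", "start", "end")], path)
  invisible(path)
}

#' Read / write a per-tissue expression matrix
#'
#' TSV with rows = genes (first column `gene_id`), columns = individuals.
#' Returned in the package's internal orientation (individuals x genes).
#'
#' @param path File path.
#' @return A numeric matrix, individuals in rows, genes in columns.
#' @export
read_expression_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(names(tab)[1] == "gene_id")
  m <- t(as.matrix(tab[, -1]))
  colnames(m) <- tab$gene_id
  m
}

#' Read / write an imputed gene-tissue feature matrix
#'
#' TSV with one row per individual (first column `individual`) and one
#' numeric column per gene-tissue pair, named `"gene|tissue"`.
#'
#' @param path File path.
#' @return An [imputed_features()] object.
#' @export
read_imputed_features <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(names(tab)[1] == "individual")
  keys <- names(tab)[-1]
  parts <- strsplit(keys, "|", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("feature columns must be named 'gene|tissue'")
  m <- as.matrix(tab[, -1])
  imputed_features(
    m,
    tibble::tibble(gene_id = vapply(parts, `[`, "", 1),
                   tissue = vapply(parts, `[`, "", 2)),
    tab$individual)
}

#' @rdname read_imputed_features
#' @param features An [imputed_features()] object.
#' @export
write_imputed_features <- function(features, path) {
  tab <- dplyr::bind_cols(
    tibble::tibble(individual = features$individuals),
    tibble::as_tibble(features$values, .name_repair = "minimal"))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname read_expression_matrix
#' @param expr Individuals x genes matrix.
#' @export
write_expression_matrix <- function(expr, path) {
  tab <- dplyr::bind_cols(tibble::tibble(gene_id = colnames(expr)),
                          tibble::as_tibble(t(expr), .name_repair = "minimal"))
  names(tab) <- c("gene_id", rownames(expr))
  readr::write_tsv(tab, path)
  invisible(path)
}
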