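# Plain-text (TSV) interchange for cohorts, panels and summary statistics.

#' Write / read a cohort table
#' @param cohort data.frame from [generate_cohort()] (possibly augmented).
#' @param path TSV path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a genotype panel as dosage + variant-map TSVs
#'
#' The dosage matrix is written subjects x SNPs with a header of SNP ids;
#' the variant map with columns CHR, SNP, BP, MAF, BLOCK.
#'
#' @param panel A `genotype_panel`.
#' @param dosage_path,map_path Output TSV paths.
#' @export
write_panel_tsv <- function(panel, dosage_path, map_path) {
  utils::write.table(panel$dosages, dosage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  map <- data.frame(CHR = panel$map$chrom, SNP = panel$map$snp,
                    BP = panel$map$pos, MAF = panel$map$maf,
                    BLOCK = panel$map$block)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dosage_path, map_path))
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(dosage_path, map_path) {
  D <- as.matrix(utils::read.delim(dosage_path, check.names = FALSE))
  m <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  map <- data.frame(chrom = m$CHR, snp = m$SNP, pos = m$BP, maf = m$MAF,
                    block = m$BLOCK, stringsAsFactors = FALSE)
  structure(list(dosages = D, map = map, n_subjects = nrow(D),
                 n_snps = ncol(D)),
            class = "genotype_panel")
}

#' Write association summary statistics in PLINK-flavoured TSV
#'
#' Columns CHR, SNP, BP, A1, BETA, SE, P (A1 is always the simulated minor
#' allele, reported as "A").
#' @param results An `assoc_result`.
#' @param path Output TSV.
#' @export
write_sumstats_tsv <- function(results, path) {
  out <- data.frame(CHR = results$chrom, SNP = results$snp, BP = results$pos,
                    A1 = "A", BETA = results$beta, SE = results$se,
                    P = results$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
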