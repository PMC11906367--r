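#' Write a synthetic cohort to disk
#'
#' Emits covariates TSV, local ancestry as an RFMix MSP-like TSV, germline
#' variants as VCF v4.2 with GT and per-variant INFO fields (per-ancestry
#' allele frequencies, REVEL, MTR, consequence class), somatic calls TSV,
#' and the generating truth parameters as JSON.
#'
#' @param cohort a `synthetic_cohort` from [simulate_full_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t")
  write_msp(cohort$mosaic, file.path(dir, "local_ancestry.msp.tsv"))
  if (!is.null(cohort$genotypes))
    write_genotype_vcf(cohort$genotypes, cohort$variant_meta,
                       file.path(dir, "germline.vcf"))
  if (!is.null(cohort$somatic))
    data.table::fwrite(cohort$somatic, file.path(dir, "somatic_calls.tsv"),
                       sep = "\t")
  cfg <- cohort$truth$config
  truth <- list(seed = cfg$seed, n_individuals = cfg$n_individuals,
                ch_logit = as.list(cfg$ch_logit),
                smoking_logit = as.list(cfg$smoking_logit),
                gene_weights = as.list(cfg$gene_weights),
                ltl_model = cfg$ltl_model,
                ancestry_dirichlet = as.list(cfg$ancestry_dirichlet),
                switch_rate = cfg$switch_rate)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write hard-call genotypes as a VCF v4.2 file
#'
#' @param geno dosage matrix (individuals x variants).
#' @param meta `VariantMeta` table aligned with the columns.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(geno, meta, path) {
  meta <- data.table::as.data.table(meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANC_AF_AMR,Number=1,Type=Float,Description=\"Allele frequency, Indigenous American ancestry\">",
    "##INFO=<ID=ANC_AF_EUR,Number=1,Type=Float,Description=\"Allele frequency, European ancestry\">",
    "##INFO=<ID=ANC_AF_AFR,Number=1,Type=Float,Description=\"Allele frequency, African ancestry\">",
    "##INFO=<ID=REVEL,Number=1,Type=Float,Description=\"REVEL score\">",
    "##INFO=<ID=MTR,Number=1,Type=Float,Description=\"Missense tolerance ratio\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")), con)
  gt_of <- c("0/0", "0/1", "1/1")
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE))
  for (j in seq_len(ncol(geno))) {
    m <- meta[j]
    info <- sprintf("ANC_AF_AMR=%s;ANC_AF_EUR=%s;ANC_AF_AFR=%s;REVEL=%s;MTR=%s;CSQ=%s",
                    fmt_num(m$maf_AMR), fmt_num(m$maf_EUR), fmt_num(m$maf_AFR),
                    fmt_num(m$revel), fmt_num(m$mtr), m$consequence)
    writeLines(paste(c(m$chrom, m$pos, m$variant_id, m$ref, m$alt, ".",
                       "PASS", info, "GT", gt_of[geno[, j] + 1L]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read hard-call genotypes from a VCF file
#'
#' Inverse of [write_genotype_vcf()]: returns the dosage matrix
#' (individuals x variants) and the variant table. Requires the `vcfR`
#' package.
#'
#' @param path VCF path.
#' @return list: `geno` (dosage matrix), `meta` (`data.table` with
#'   variant_id, chrom, pos, ref, alt).
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotype_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- matrix(c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
                  "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)[gt],
                nrow = nrow(gt), dimnames = dimnames(gt))
  meta <- data.table::data.table(
    variant_id = vcfR::getID(v), chrom = vcfR::getCHROM(v),
    pos = vcfR::getPOS(v), ref = vcfR::getREF(v), alt = vcfR::getALT(v))
  list(geno = t(dos), meta = meta)
}

#' Read somatic calls from TSV
#'
#' Expects the `SomaticVariantCall` columns (sample_id, gene, chrom, pos,
#' ref, alt, consequence, exon_number, protein_change, alt_reads, depth;
#' vaf computed when absent). Positions are 1-based.
#'
#' @param path TSV path.
#' @return `data.table`.
#' @export
read_somatic_tsv <- function(path) {
  d <- data.table::fread(path)
  if (!"vaf" %in% names(d)) d$vaf <- d$alt_reads / d$depth
  d
}

#' Write an association summary-statistics TSV
#'
#' @param results table from [gwas_scan()] / [fisher_allelic_test()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(results, path) {
  data.table::fwrite(results, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read an association summary-statistics TSV
#' @param path TSV path.
#' @return `data.table`.
#' @export
read_sumstats <- function(path) data.table::fread(path)
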