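#!/usr/bin/env Rscript
# Step 5: rare-variant gene collapsing and cross-cohort meta-analysis.
#
# Simulates a second, European-ancestry-weighted cohort, runs the
# 11-model gene collapsing in both, meta-analyses the per-gene carrier
# tables with Cochran-Mantel-Haenszel, and meta-analyses the common-variant
# summary statistics with IVW + the sample-size-weighted P-value method.

suppressMessages({library(chancestry); library(data.table)})

# extend the default panel with rare PTVs so the collapsing models have
# qualifying variants: two risk PTVs in one gene, two neutral ones in another
rare_ptvs <- function(n_windows) {
  data.table(
    id = paste0("ptv", 1:4), gene = c("GERM1", "GERM1", "GERM2", "GERM2"),
    window = pmax(1L, as.integer(round(n_windows * c(0.2, 0.4, 0.6, 0.8)))),
    pos_offset = 900L, ref = "G", alt = "A",
    af_AMR = 0.002, af_EUR = 0.002, af_AFR = 0.002,
    consequence = c("nonsense", "frameshift", "nonsense", "splice_site"),
    revel = NA_real_, mtr = NA_real_, mtr_centile = NA_real_,
    beta_dnmt3a = c(0.5, 0.5, 0, 0), beta_other = c(0.5, 0.5, 0, 0),
    beta_ltl = 0)
}

build <- function(seed, dirichlet) {
  nw <- 60L
  panel <- rbind(default_variant_panel(nw), rare_ptvs(nw))
  cfg <- sim_config(n_individuals = 20000L, n_windows = nw,
                    ancestry_dirichlet = dirichlet, variant_panel = panel,
                    seed = seed)
  co <- assign_ch_status(simulate_genetic_data(simulate_cohort(cfg), cfg), cfg)
  list(cfg = cfg, co = co)
}
a <- build(11L, c(6.6, 3.1, 0.3))          # admixed cohort
b <- build(77L, c(0.5, 9.0, 0.5))          # European-weighted cohort

registry <- qv_models()
meta_ann <- function(x) x$co$variant_meta
collapse_one <- function(x)
  collapse_genes(x$co$genotypes, meta_ann(x), x$co$covariates$ch,
                 models = c("ptv5pcnt", "flexdmg", "rec", "syn"))
ca <- collapse_one(a); cb <- collapse_one(b)
fwrite(ca, "results/collapsing_cohort_a.tsv", sep = "\t")
fwrite(cb, "results/collapsing_cohort_b.tsv", sep = "\t")
cat(sprintf("collapsing: %d gene-model rows (cohort A), %d (cohort B)\n",
            nrow(ca), nrow(cb)))

# CMH meta for genes present in both cohorts under a shared model
shared <- intersect(ca[model == "ptv5pcnt"]$gene, cb[model == "ptv5pcnt"]$gene)
meta_rows <- rbindlist(lapply(shared, function(g) {
  tab <- function(x) {
    r <- x[model == "ptv5pcnt" & gene == g]
    rbind(c(r$carriers_cases, r$n_cases - r$carriers_cases),
          c(r$carriers_controls, r$n_controls - r$carriers_controls))
  }
  cbind(gene = g, cmh_meta(list(t(tab(ca)), t(tab(cb)))))
}))
fwrite(meta_rows, "results/collapsing_cmh_meta.tsv", sep = "\t")
print(meta_rows)

# per-variant IVW + P-value-method meta of the two cohorts' common variants
scan_one <- function(x) {
  covars <- cbind(age = x$co$covariates$age,
                  smoking = as.numeric(x$co$covariates$ever_smoker))
  res <- gwas_scan(x$co$genotypes, x$co$covariates$ch, covars)
  res$effect_allele <- "ALT"; res$other_allele <- "REF"
  res
}
sa <- scan_one(a); sb <- scan_one(b)
mm <- meta_analyse(list(admixed = sa, european = sb), threshold = 5e-8)
fwrite(mm, "results/gwas_meta.tsv", sep = "\t")
cat("\ncross-cohort meta (IVW + sample-size-weighted):\n")
print(mm[, .(variant_id, beta_meta, p_ivw, p_pvalue, q_p, directions, significant)])
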