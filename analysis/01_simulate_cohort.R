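#!/usr/bin/env Rscript
# Step 1: build the synthetic admixed discovery cohort.
#
# One cohort of 20,000 individuals with three-way admixture (mean fractions
# 66% Indigenous American / 31% European / 3% African), ancestry-dependent
# smoking, age- ancestry- smoking- and telomere-dependent CH risk, a small
# germline panel with ancestry-specific allele frequencies, and somatic
# driver calls with 10% decoy records. All files land in results/cohort/.

suppressMessages({library(chancestry); library(data.table)})

cfg <- sim_config(n_individuals = 20000L, seed = 11L)
cohort <- simulate_full_cohort(cfg)
write_cohort(cohort, "results/cohort")

cov <- cohort$covariates
cat(sprintf("cohort: %d individuals, CH prevalence %.2f%%\n",
            nrow(cov), 100 * mean(cov$ch)))
cat(sprintf("mean ancestry fractions: AMR %.3f EUR %.3f AFR %.3f\n",
            mean(cov$frac_AMR), mean(cov$frac_EUR), mean(cov$frac_AFR)))
cat(sprintf("somatic records: %d (%d decoys)\n",
            nrow(cohort$somatic), sum(cohort$somatic$decoy)))
cat("wrote results/cohort/{covariates.tsv,local_ancestry.msp.tsv,germline.vcf,somatic_calls.tsv,truth.json}\n")
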