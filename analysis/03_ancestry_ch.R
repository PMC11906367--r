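#!/usr/bin/env Rscript
# Step 3: local-ancestry aggregation and the ancestry-CH risk models.
#
# Summarizes the window mosaics to global fractions, fits CH risk on the
# continuous European fraction (adjusted for age, sex-free generator uses
# smoking) and on 10%-wide ancestry bins, and runs the diplotype additive
# model at the locus of the ancestry-differentiated rare variant.

suppressMessages({library(chancestry); library(data.table)})

mosaic <- read_msp("results/cohort/local_ancestry.msp.tsv")
cov <- fread("results/cohort/covariates.tsv")
status <- fread("results/ch_status.tsv")

gf <- global_ancestry_fractions(mosaic)
fwrite(gf, "results/ancestry_fractions.tsv", sep = "\t")
d <- merge(cov[, .(sample_id, age, ever_smoker, ltl_std)],
           gf, by = "sample_id")
d <- merge(d, status[, .(sample_id, overall_ch, DNMT3A)], by = "sample_id")

cont <- cohort_risk_model(d, "overall_ch", "frac_EUR",
                          covariates = c("age", "ever_smoker"))
fwrite(cont, "results/ancestry_risk_continuous.tsv", sep = "\t")
eur <- cont[term == "frac_EUR"]
cat(sprintf("CH ~ European fraction (mosaic-derived): beta %.2f [%.2f, %.2f], P %.2g\n",
            eur$estimate, log(eur$ci_low), log(eur$ci_high), eur$p))

binned <- cohort_risk_model(d, "overall_ch", "frac_EUR",
                            covariates = c("age", "ever_smoker"),
                            binned = TRUE)
fwrite(binned, "results/ancestry_risk_binned.tsv", sep = "\t")

# diplotype additive model at the rare-variant locus (gene-level interval)
truth <- jsonlite::read_json("results/cohort/truth.json")
win <- mosaic$windows[4]                      # window holding the rare variant
fr <- interval_ancestry(mosaic, win$chrom, win$spos, win$epos, "EUR")
dip <- categorize_diplotype(fr[, 1], fr[, 2])
dd <- data.table(sample_id = rownames(fr), code = dip$code)
dd <- merge(dd, d, by = "sample_id")
dd <- dd[!is.na(code)]
cat(sprintf("diplotype categories at the test locus: %s (unassigned excluded: %d)\n",
            paste(table(dip$category), collapse = "/"),
            sum(is.na(dip$code))))
addv <- cohort_risk_model(dd, "overall_ch", "code",
                          covariates = c("age", "ever_smoker"))
fwrite(addv, "results/ancestry_risk_diplotype.tsv", sep = "\t")
print(addv[term == "code"])
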