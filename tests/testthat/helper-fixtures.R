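# Shared fixtures and independent oracles, built in code at test time.

# Brute-force two-sided Fisher P: enumerate every table with the observed
# margins via the hypergeometric pmf and sum the probabilities of tables no
# more probable than the observed one. Independent of stats::fisher.test.
enum_fisher_p <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  lo <- max(0, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  pr <- exp(lgamma(m1 + 1) - lgamma(xs + 1) - lgamma(m1 - xs + 1) +
            lgamma(m2 + 1) - lgamma(k - xs + 1) - lgamma(m2 - k + xs + 1) -
            (lgamma(m1 + m2 + 1) - lgamma(k + 1) - lgamma(m1 + m2 - k + 1)))
  p_obs <- pr[xs == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Random variant annotation table with per-ancestry MAFs whose weighted mean
# is the global MAF (so that a zero global MAF implies zero everywhere).
random_annotation <- function(n, seed) {
  set.seed(seed)
  conseq <- sample(c("synonymous", "missense", "nonsense", "frameshift",
                     "splice_site", "inframe_indel", "other"), n, replace = TRUE)
  anc <- matrix(stats::rexp(3 * n, rate = 400), ncol = 3)
  anc[sample(n, n %/% 10), ] <- 0                 # some absent-everywhere
  anc[sample(n, n %/% 5), ] <- stats::runif(n %/% 5, 0, 0.1)  # some common
  w <- c(0.4, 0.35, 0.25)
  data.table::data.table(
    variant_id = sprintf("v%04d", seq_len(n)),
    gene = sample(paste0("G", 1:8), n, replace = TRUE),
    consequence = conseq,
    maf_global = as.numeric(anc %*% w),
    maf_AMR = anc[, 1], maf_EUR = anc[, 2], maf_AFR = anc[, 3],
    revel = ifelse(stats::runif(n) < 0.15, NA, stats::runif(n)),
    mtr = ifelse(stats::runif(n) < 0.15, NA, stats::runif(n, 0.4, 1.2)),
    mtr_centile = ifelse(stats::runif(n) < 0.15, NA, stats::runif(n, 0, 100)))
}

# Small mosaic with unequal window lengths for aggregation arithmetic.
toy_mosaic <- function(codes_h0, codes_h1, lens = NULL,
                       labels = c("AMR", "EUR", "AFR")) {
  w <- length(codes_h0)
  if (is.null(lens)) lens <- rep(1000L, w)
  spos <- cumsum(c(0L, lens[-w]))
  la_mosaic(windows = data.frame(chrom = "chr1", spos = spos,
                                 epos = spos + lens),
            hap = cbind(codes_h0, codes_h1), labels = labels, ids = "I1")
}

# One somatic record with qualifying defaults, overridable per field.
somatic_record <- function(...) {
  rec <- list(sample_id = "S1", gene = "DNMT3A", chrom = "chr2", pos = 100L,
              ref = "C", alt = "T", consequence = "nonsense", exon_number = 5L,
              protein_change = NA_character_, alt_reads = 6L, depth = 60L,
              vaf = 0.10)
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}
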