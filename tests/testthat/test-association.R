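test_that("allelic Fisher P matches exhaustive hypergeometric enumeration", {
  # cases 8 effect / 12 other alleles; controls 2 / 18
  dosage <- c(rep(2, 3), rep(1, 2), rep(0, 5), rep(1, 2), rep(0, 8))
  outcome <- c(rep(1, 10), rep(0, 10))
  r <- fisher_allelic_test(dosage, outcome)
  expect_equal(r$mac_cases, 8)
  expect_equal(r$mac_controls, 2)
  expect_equal(r$p, enum_fisher_p(8, 12, 2, 18), tolerance = 1e-12)
  # symmetric table: OR 1, P 1
  r2 <- fisher_allelic_test(c(rep(1, 10), rep(1, 10)),
                            c(rep(1, 10), rep(0, 10)))
  expect_equal(r2$or, 1)
  expect_equal(r2$p, 1)
  # zero effect alleles in controls: Haldane correction keeps OR finite
  r3 <- fisher_allelic_test(c(rep(1, 4), rep(0, 6), rep(0, 10)),
                            c(rep(1, 10), rep(0, 10)))
  expect_true(is.finite(r3$or) && r3$or > 1)
  # monomorphic: untestable
  r4 <- fisher_allelic_test(rep(0, 20), c(rep(1, 10), rep(0, 10)))
  expect_true(r4$untestable)
})

test_that("random small allele tables agree exactly with the enumeration oracle", {
  set.seed(9)
  for (i in 1:200) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + c_) == 0 || (b + d) == 0 || (a + b) == 0 || (c_ + d) == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, enum_fisher_p(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("Hardy-Weinberg exact test behaves at equilibrium and extremes", {
  expect_equal(hwe_exact_p(25, 50, 25), 1, tolerance = 1e-9)
  # hand-enumerable case: 2 minor alleles in 2 diploids
  # possible het counts {0, 2}: P(h=2) = 2/3, P(h=0) = 1/3
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_p(0, 2, 0), 1, tolerance = 1e-12)
  # gross heterozygote excess is rejected
  expect_lt(hwe_exact_p(0, 1000, 0), 1e-6)
  # symmetric in allele labels
  expect_equal(hwe_exact_p(10, 40, 300), hwe_exact_p(300, 40, 10))
})

test_that("variant QC reports the first failed gate per variant", {
  set.seed(2)
  n <- 400
  mk <- function(maf) stats::rbinom(n, 2, maf)
  geno <- cbind(
    ok1 = mk(0.3), ok2 = mk(0.2),
    lowmaf = stats::rbinom(n, 2, 0.002),
    hwe_bad = rep(1L, n),                      # all heterozygous
    info_bad = mk(0.25),
    mac_bad = c(rep(1L, 3), rep(0L, n - 3)))   # MAC 3 overall
  meta <- data.table::data.table(
    variant_id = colnames(geno),
    info = c(1, 1, 1, 1, 0.4, 1),
    ref = "A", alt = "C")
  y <- rep(c(1, 0), n / 2)
  qc <- variant_qc(geno, meta, outcome = y, ld_r2 = NULL)
  rs <- qc$reasons$reason
  names(rs) <- qc$reasons$variant_id
  expect_true(all(is.na(rs[c("ok1", "ok2")])))
  expect_equal(unname(rs["lowmaf"]), "maf")
  expect_equal(unname(rs["hwe_bad"]), "hwe")
  expect_equal(unname(rs["info_bad"]), "info")
  expect_equal(unname(rs["mac_bad"]), "maf")  # MAF gate fires first
  qc2 <- variant_qc(geno, meta, outcome = y, maf_min = NULL, ld_r2 = NULL)
  expect_equal(qc2$reasons$reason[qc2$reasons$variant_id == "mac_bad"], "mac")
})

test_that("MAF and INFO gates commute; LD pruning drops duplicated columns", {
  set.seed(3)
  n <- 300
  geno <- sapply(stats::runif(30, 0.005, 0.4), function(f) stats::rbinom(n, 2, f))
  colnames(geno) <- paste0("v", 1:30)
  meta <- data.table::data.table(variant_id = colnames(geno),
                                 info = stats::runif(30, 0.3, 1))
  a <- variant_qc(geno, meta, maf_min = 0.05, hwe_min = NULL, info_min = NULL,
                  mac_min = NULL, ld_r2 = NULL)
  a2 <- variant_qc(geno[, a$keep], meta[meta$variant_id %in% a$keep],
                   maf_min = NULL, hwe_min = NULL, info_min = 0.6,
                   mac_min = NULL, ld_r2 = NULL)
  b <- variant_qc(geno, meta, maf_min = NULL, hwe_min = NULL, info_min = 0.6,
                  mac_min = NULL, ld_r2 = NULL)
  b2 <- variant_qc(geno[, b$keep], meta[meta$variant_id %in% b$keep],
                   maf_min = 0.05, hwe_min = NULL, info_min = NULL,
                   mac_min = NULL, ld_r2 = NULL)
  expect_setequal(a2$keep, b2$keep)
  # duplicated column pruned
  g2 <- cbind(geno[, 1:3], dup = geno[, 3])
  meta2 <- data.table::data.table(variant_id = colnames(g2), info = 1)
  qc <- variant_qc(g2, meta2, maf_min = NULL, hwe_min = NULL, info_min = NULL,
                   mac_min = NULL, ld_r2 = 0.1)
  expect_true(xor("v3" %in% qc$keep, "dup" %in% qc$keep))
  expect_equal(qc$reasons$reason[qc$reasons$variant_id == "dup"], "ld_prune")
})

test_that("LD statistics reproduce hand arithmetic and boundary patterns", {
  # variant against itself
  g <- stats::rbinom(500, 2, 0.3)
  self <- ld_stats(g, g)
  expect_equal(self$r2, 1, tolerance = 1e-6)
  expect_equal(self$d_prime, 1, tolerance = 1e-6)
  # phased toy: AB 40, Ab 10, aB 10, ab 40
  hapA <- c(rep(1, 50), rep(0, 50))
  hapB <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  ld <- ld_stats(matrix(hapA, ncol = 1), matrix(hapB, ncol = 1), phased = TRUE)
  expect_equal(ld$d, 0.15)
  expect_equal(ld$d_prime, 0.6)
  expect_equal(ld$r2, 0.36)
  # rare allele exclusively on the major background: D' ~ 1, r2 small
  n_hap <- 2000
  common <- stats::rbinom(n_hap, 1, 0.3)
  rare <- ifelse(common == 0, stats::rbinom(n_hap, 1, 0.02), 0)
  ldr <- ld_stats(matrix(common, ncol = 2), matrix(rare, ncol = 2),
                  phased = TRUE)
  expect_gte(ldr$d_prime, 0.95)
  expect_lt(ldr$r2, 0.05)
  # EM on the unphased collapse matches phased counting
  gc_ <- common[seq(1, n_hap, 2)] + common[seq(2, n_hap, 2)]
  gr <- rare[seq(1, n_hap, 2)] + rare[seq(2, n_hap, 2)]
  em <- ld_stats(gc_, gr)
  expect_equal(em$r2, ldr$r2, tolerance = 1e-6)
  # monomorphic variant flagged
  expect_true(ld_stats(rep(0, 100), stats::rbinom(100, 2, 0.3))$flagged)
})

test_that("genomic inflation is definitional and responds to scaled statistics", {
  expect_equal(genomic_inflation(rep(0.5, 1000)),
               stats::qchisq(0.5, 1) / 0.456, tolerance = 1e-9)
  set.seed(10)
  chi <- stats::rchisq(5000, 1)
  p_infl <- stats::pchisq(chi * 1.2, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p_infl), 1.2, tolerance = 0.05)
  expect_error(genomic_inflation(c(0.5, 0)), "\\(0, 1\\]")
  expect_warning(genomic_inflation(rep(0.4, 10)), "unstable")
})

test_that("loci are seeded by ascending P and the novelty window is inclusive +-1 Mb", {
  res <- data.table::data.table(
    variant_id = c("a", "b", "c"),
    chrom = c("1", "1", "1"),
    pos = c(1e6, 1.5e6, 4.5e6),
    p = c(1e-10, 1e-9, 1e-9))
  loci <- define_loci(res, threshold = 5e-8)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$lead_variant, c("a", "c"))
  expect_equal(loci$n_members, c(2L, 1L))
  # row order invariance
  loci2 <- define_loci(res[c(3, 1, 2)], threshold = 5e-8)
  expect_equal(loci, loci2)
  # novelty boundary
  known <- data.frame(chrom = "1", pos = 1e6 + 9e5)
  expect_false(define_loci(res[1], known = known)$novel)
  known2 <- data.frame(chrom = "1", pos = 1e6 + 1.1e6)
  expect_true(define_loci(res[1], known = known2)$novel)
  # nothing significant
  expect_equal(nrow(define_loci(res, threshold = 1e-12)), 0)
})

test_that("conditioning on the causal variant removes its proxy's signal", {
  set.seed(55)
  n <- 20000
  h1 <- stats::rbinom(2 * n, 1, 0.3)
  flip <- stats::runif(2 * n) < 0.055
  h2 <- ifelse(flip, 1 - h1, h1)           # strong LD proxy (r2 ~ 0.86 scale)
  causal <- h1[seq(1, 2 * n, 2)] + h1[seq(2, 2 * n, 2)]
  proxy <- h2[seq(1, 2 * n, 2)] + h2[seq(2, 2 * n, 2)]
  y <- as.numeric(stats::runif(n) < stats::plogis(-3.3 + 0.5 * causal))
  geno <- cbind(causal = causal, proxy = proxy)
  marg <- gwas_scan(geno, y)
  expect_lt(marg$p[marg$variant_id == "proxy"], 5e-8)
  cond <- gwas_scan(geno, y, condition = "causal")
  expect_gt(cond$p[cond$variant_id == "proxy"], 5e-8)
  r2 <- ld_stats(causal, proxy)$r2
  expect_gt(r2, 0.7)
})
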