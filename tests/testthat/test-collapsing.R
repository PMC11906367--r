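registry <- qv_models()

test_that("the registry enforces the dominant/recessive convention", {
  expect_equal(names(registry)[vapply(registry, function(m)
    m$genetic_model == "recessive", logical(1))], "rec")
  expect_equal(length(registry), 11)
})

test_that("threshold bands qualify variants as the model definitions force", {
  meta <- data.table::data.table(
    variant_id = c("syn_rare", "mis_absent", "ptv_common", "ptv_rare"),
    gene = "G1",
    consequence = c("synonymous", "missense", "nonsense", "frameshift"),
    maf_global = c(0.00004, 0, 0.02, 0.0005),
    maf_AMR = c(0.00004, 0, 0.02, 0.0005),
    maf_EUR = c(0.00004, 0, 0.02, 0.0005),
    maf_AFR = c(0.00004, 0, 0.02, 0.0005),
    revel = c(NA, 0.3, NA, NA),
    mtr = c(NA, 0.5, NA, NA), mtr_centile = c(NA, 30, NA, NA))
  # synonymous rare variant qualifies under syn and nothing else
  per_model <- lapply(registry, function(m) qualify_variants(meta, m, registry))
  has_syn <- vapply(per_model, function(v) "syn_rare" %in% v, logical(1))
  expect_identical(unname(has_syn), names(registry) == "syn")
  # absent missense with REVEL 0.3 qualifies under UR hence flexdmg
  expect_true("mis_absent" %in% per_model$UR)
  expect_true("mis_absent" %in% per_model$flexdmg)
  # PTV at 2% fails ptv but passes ptv5pcnt
  expect_false("ptv_common" %in% per_model$ptv)
  expect_true("ptv_common" %in% per_model$ptv5pcnt)
  expect_true("ptv_rare" %in% per_model$ptv)
})

test_that("qualifying-set identities hold on randomized annotation tables", {
  for (seed in c(1, 2, 3)) {
    meta <- random_annotation(600, seed)
    q <- lapply(registry, function(m) qualify_variants(meta, m, registry))
    expect_true(all(q$UR %in% q$flexdmg))
    expect_true(all(q$URmtr %in% q$UR))
    expect_true(all(q$raredmgmtr %in% q$raredmg))
    expect_true(all(q$ptv %in% q$ptv5pcnt))
    expect_setequal(q$ptvraredmg, union(q$ptv, q$raredmg))
    # consequence-class exclusions
    syn_cons <- meta$consequence[meta$variant_id %in% q$syn]
    expect_true(all(syn_cons == "synonymous"))
    ptv_cons <- meta$consequence[meta$variant_id %in% q$ptv5pcnt]
    expect_false(any(ptv_cons %in% c("synonymous", "missense")))
  }
})

test_that("dominant carrier counts grow monotonically with the MAF ceiling", {
  meta <- random_annotation(500, 7)
  geno <- sapply(pmin(pmax(meta$maf_global, 0.001), 0.5),
                 function(f) stats::rbinom(150, 2, f))
  colnames(geno) <- meta$variant_id
  counts <- sapply(c(0.0005, 0.005, 0.05, 0.5), function(ceil) {
    m <- registry$ptv5pcnt
    m$maf_global_max <- ceil; m$maf_ancestry_max <- ceil
    q <- qualify_variants(meta, m, registry)
    if (length(q) == 0) return(0)
    sum(carrier_status(geno, meta, q, "dominant"))
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("carrier status distinguishes dominant from recessive aggregation", {
  meta <- data.table::data.table(variant_id = c("v1", "v2"), gene = "G1")
  geno <- rbind(het1 = c(1, 0), hom = c(2, 0), twohet = c(1, 1),
                none = c(0, 0), missing = c(NA, 1))
  colnames(geno) <- meta$variant_id
  dom <- carrier_status(geno, meta, c("v1", "v2"), "dominant")
  rec <- carrier_status(geno, meta, c("v1", "v2"), "recessive")
  expect_equal(unname(dom[, "G1"]), c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(unname(rec[, "G1"]), c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("collapsing P values match the enumeration oracle", {
  carriers <- matrix(c(rep(TRUE, 30), rep(FALSE, 970),
                       rep(TRUE, 50), rep(FALSE, 8950)),
                     ncol = 1)
  rownames(carriers) <- NULL; colnames(carriers) <- "G1"
  pheno <- c(rep(1, 1000), rep(0, 9000))
  r <- collapsing_test(carriers, pheno)
  expect_equal(r$p, enum_fisher_p(30, 970, 50, 8950), tolerance = 1e-9)
  expect_equal(r$carriers_cases, 30)
  # zero carriers: untestable
  r0 <- collapsing_test(matrix(FALSE, 100, 1, dimnames = list(NULL, "G")),
                        rep(c(0, 1), 50))
  expect_true(r0$untestable)
})

test_that("CMH reduces to the single-stratum test and matches hand arithmetic", {
  t1 <- rbind(c(12, 88), c(30, 870))
  # single stratum: MH chi-square = (n-1)/n times the Pearson chi-square
  single <- cmh_meta(list(t1))
  pear <- suppressWarnings(stats::chisq.test(t1, correct = FALSE)$statistic)
  expect_equal(single$chisq, unname(pear) * (sum(t1) - 1) / sum(t1),
               tolerance = 1e-12)
  # k >= 2: statistic, P and CI agree with stats::mantelhaen.test
  t2b <- rbind(c(5, 45), c(10, 440))
  arr <- array(c(t1, t2b), c(2, 2, 2))
  mh <- stats::mantelhaen.test(arr, correct = FALSE)
  ours <- cmh_meta(list(t1, t2b))
  expect_equal(ours$chisq, unname(mh$statistic), tolerance = 1e-9)
  expect_equal(ours$p, mh$p.value, tolerance = 1e-9)
  expect_equal(ours$or_mh, unname(mh$estimate), tolerance = 1e-9)
  # two identical strata: common OR equals the stratum OR
  two <- cmh_meta(list(t1, t1))
  or1 <- (12 * 870) / (88 * 30)
  expect_equal(two$or_mh, or1, tolerance = 1e-12)
  # hand-built two-stratum MH formula
  t2 <- rbind(c(5, 45), c(10, 440))
  both <- cmh_meta(list(t1, t2))
  num <- 12 * 870 / sum(t1) + 5 * 440 / sum(t2)
  den <- 88 * 30 / sum(t1) + 45 * 10 / sum(t2)
  expect_equal(both$or_mh, num / den, tolerance = 1e-12)
  # replicating a stratum K times inflates the statistic monotonically
  chis <- sapply(1:4, function(k) cmh_meta(rep(list(t1), k))$chisq)
  expect_true(all(diff(chis) > 0))
  # degenerate strata contribute nothing
  zero <- rbind(c(0, 0), c(0, 0))
  expect_equal(cmh_meta(list(t1, zero))$n_strata, 1L)
  expect_true(cmh_meta(list(zero))$untestable)
})

test_that("collapse_genes recovers an injected carrier effect", {
  set.seed(23)
  n <- 12000
  meta <- data.table::data.table(
    variant_id = c("r1", "r2"), gene = c("CHEK2L", "NULLG"),
    consequence = c("nonsense", "nonsense"),
    maf_global = c(0.004, 0.004), maf_AMR = c(0.004, 0.004),
    maf_EUR = c(0.004, 0.004), maf_AFR = c(0.004, 0.004),
    revel = NA_real_, mtr = NA_real_, mtr_centile = NA_real_)
  g1 <- stats::rbinom(n, 2, 0.004)
  g2 <- stats::rbinom(n, 2, 0.004)
  eta <- -2.2 + log(1.62) * (g1 >= 1)
  y <- as.numeric(stats::runif(n) < stats::plogis(eta))
  geno <- cbind(r1 = g1, r2 = g2)
  res <- collapse_genes(geno, meta, y, models = "ptv5pcnt")
  row <- res[res$gene == "CHEK2L"]
  expect_true(row$ci_low < 1.62 && 1.62 < row$ci_high)
  expect_gt(res[res$gene == "NULLG"]$p, 0.001)
})
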