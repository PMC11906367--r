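rules15 <- ch_rules("panel15")
rules58 <- ch_rules("panel58")

test_that("classify_variant applies the gates in fixed order with reason codes", {
  expect_equal(classify_variant(somatic_record(), rules15),
               list(qualified = TRUE, reason = "ok"))
  # below the 3% VAF floor
  v <- classify_variant(somatic_record(gene = "TET2", consequence = "frameshift",
                                       alt_reads = 6L, depth = 300L, vaf = 0.02),
                        rules15)
  expect_equal(v, list(qualified = FALSE, reason = "vaf"))
  # VAF bounds are inclusive at both ends
  expect_true(classify_variant(somatic_record(vaf = 0.03, alt_reads = 3L,
                                              depth = 100L), rules15)$qualified)
  expect_true(classify_variant(somatic_record(vaf = 0.40, alt_reads = 40L,
                                              depth = 100L), rules15)$qualified)
  expect_false(classify_variant(somatic_record(vaf = 0.401, alt_reads = 41L,
                                               depth = 100L), rules15)$qualified)
  # hotspot-only gene rejects a non-hotspot missense
  v <- classify_variant(somatic_record(gene = "JAK2", consequence = "missense",
                                       protein_change = "V617G", vaf = 0.2,
                                       alt_reads = 10L, depth = 50L), rules15)
  expect_equal(v$reason, "consequence")
  expect_true(classify_variant(somatic_record(gene = "JAK2",
                                              consequence = "missense",
                                              protein_change = "V617F",
                                              vaf = 0.2, alt_reads = 10L,
                                              depth = 50L), rules15)$qualified)
  # exon restriction for ASXL1/PPM1D-style rules
  expect_true(classify_variant(somatic_record(gene = "ASXL1",
                                              consequence = "nonsense",
                                              exon_number = 12L), rules15)$qualified)
  expect_equal(classify_variant(somatic_record(gene = "ASXL1",
                                               consequence = "nonsense",
                                               exon_number = 3L),
                                rules15)$reason, "consequence")
  # gate order: panel before reads before VAF before consequence
  expect_equal(classify_variant(somatic_record(gene = "NOTAGENE",
                                               alt_reads = 1L, vaf = 0.9),
                                rules15)$reason, "panel")
  expect_equal(classify_variant(somatic_record(alt_reads = 2L, vaf = 0.5),
                                rules15)$reason, "reads")
  expect_equal(classify_variant(somatic_record(consequence = "synonymous",
                                               alt_reads = 5L, vaf = 0.5),
                                rules15)$reason, "vaf")
  expect_error(classify_variant(somatic_record(depth = 0L), rules15),
               "malformed")
})

test_that("call_ch emits one complete row per cohort member and deduplicates", {
  calls <- data.table::rbindlist(list(
    somatic_record(sample_id = "S1", pos = 100L),
    somatic_record(sample_id = "S1", pos = 200L),
    somatic_record(sample_id = "S2", gene = "JAK2", consequence = "missense",
                   protein_change = "V617F", pos = 300L),
    somatic_record(sample_id = "S3", gene = "TP53", consequence = "frameshift",
                   pos = 400L),
    somatic_record(sample_id = "S4", consequence = "synonymous", pos = 500L)))
  ids <- paste0("S", 1:10)
  st <- call_ch(calls, rules15, ids)
  expect_equal(nrow(st), 10)
  expect_true(st$overall_ch[st$sample_id == "S1"])
  expect_true(st$DNMT3A[st$sample_id == "S1"])
  expect_equal(sum(attr(st, "audit")$qualified[attr(st, "audit")$sample_id == "S1"]), 2)
  expect_true(st$JAK2[st$sample_id == "S2"])
  expect_true(st$TP53[st$sample_id == "S3"])
  expect_false(st$overall_ch[st$sample_id == "S4"])   # synonymous never qualifies
  expect_equal(sum(!st$overall_ch), 7)
  # overall flag is the OR of the gene flags
  gene_or <- Reduce(`|`, as.list(st[, setdiff(names(st), c("sample_id", "overall_ch")), with = FALSE]))
  expect_identical(st$overall_ch, gene_or)
  # duplicates collapse with a warning
  expect_warning(st2 <- call_ch(rbind(calls, calls[1]), rules15, ids),
                 "duplicate")
  expect_identical(st2$overall_ch, st$overall_ch)
  expect_error(call_ch(calls, rules15, c("S1", "S2")), "absent")
})

test_that("tightening the VAF floor never adds CH-positive individuals", {
  cfg <- sim_config(n_individuals = 2000, n_windows = 30, decoy_fraction = 0.2,
                    seed = 17)
  co <- simulate_full_cohort(cfg)
  counts <- sapply(c(0.03, 0.05, 0.10, 0.20), function(t) {
    sub <- co$somatic[co$somatic$vaf >= t]
    sum(call_ch(sub, cfg$rules, co$covariates$sample_id)$overall_ch)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("panel15 positivity implies panel58 positivity on the same calls", {
  cfg <- sim_config(n_individuals = 3000, n_windows = 30, decoy_fraction = 0.2,
                    seed = 19)
  co <- simulate_full_cohort(cfg)
  st15 <- call_ch(co$somatic, rules15, co$covariates$sample_id)
  st58 <- call_ch(co$somatic, rules58, co$covariates$sample_id)
  expect_true(all(st58$overall_ch[st15$overall_ch]))
})

test_that("age screen recovers a generating age effect and skips sparse genes", {
  set.seed(101)
  n <- 20000
  age <- stats::runif(n, 35, 90)
  p <- stats::plogis(-9 + 0.08 * age)
  flag <- stats::runif(n) < p
  st <- data.table::data.table(sample_id = as.character(1:n),
                               overall_ch = flag, DNMT3A = flag,
                               RAREG = c(TRUE, rep(FALSE, n - 1)))
  cov <- data.table::data.table(sample_id = as.character(1:n), age = age)
  expect_message(res <- age_association_screen(st, cov,
                                               genes = c("DNMT3A", "RAREG")),
                 "skipped")
  expect_equal(nrow(res), 1)
  expect_true(res$age_associated)
  expect_true(res$ci_low < exp(0.08) && exp(0.08) < res$ci_high)
})

test_that("frequencies and Wilson intervals follow the closed forms", {
  st <- data.table::data.table(
    sample_id = seq_len(1000),
    overall_ch = c(rep(TRUE, 50), rep(FALSE, 950)),
    grp = rep(c("a", "b"), each = 500))
  f <- ch_frequency(st)
  expect_equal(f$freq_pct, 5)
  expect_equal(c(f$ci_low_pct, f$ci_high_pct) / 100,
               as.numeric(stats::prop.test(50, 1000, correct = FALSE)$conf.int))
  # zero cases: frequency 0, Wilson lower bound 0
  f0 <- ch_frequency(data.table::data.table(sample_id = 1:100,
                                            overall_ch = rep(FALSE, 100)))
  expect_equal(f0$freq_pct, 0)
  expect_equal(f0$ci_low_pct, 0)
  # grouped + chi-square between two groups
  fg <- ch_frequency(st, by = "grp", compare = list("a", "b"))
  expect_equal(nrow(fg), 2)
  expect_s3_class(attr(fg, "chisq"), "htest")
})
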