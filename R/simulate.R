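#' Configuration for the synthetic admixed-cohort generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: three-way admixture (Indigenous American / European / African)
#' laid out as window mosaics along two haplotypes, ancestry-dependent
#' smoking prevalence, age-, ancestry-, smoking- and telomere-dependent CH
#' risk split into a DNMT3A and a non-DNMT3A component (so germline variants
#' can carry opposing effects on the two), ancestry-specific allele
#' frequencies, and a heritable leukocyte telomere length (LTL) trait.
#'
#' @param n_individuals cohort size.
#' @param n_windows genomic windows in the simulated segment (default 400).
#' @param window_bp window length in base pairs (default 100000).
#' @param ancestry_dirichlet Dirichlet concentrations (AMR, EUR, AFR);
#'   default `c(6.6, 3.1, 0.3)` gives mean fractions (0.66, 0.31, 0.03).
#' @param switch_rate per-window probability that a haplotype resamples its
#'   ancestry from the individual's global fractions (default 0.1).
#' @param age_range uniform age range in years (default `c(35, 90)`).
#' @param smoking_logit `c(intercept, eur)`: logit of ever-smoking as a
#'   linear function of European fraction.
#' @param ch_logit named vector `c(intercept, age, eur, smoking, ltl)`:
#'   shared log-odds model of the two CH components (age in years, smoking
#'   = ever-smoker indicator, ltl = standardized LTL).
#' @param gene_weights named probabilities of the mutated driver gene given
#'   CH; must be genes of `rules`. The DNMT3A weight splits overall risk
#'   into the DNMT3A and non-DNMT3A components.
#' @param variant_panel data.frame of synthetic germline variants: `id`,
#'   `gene`, `window` (1-based window index), `pos_offset`, `ref`, `alt`,
#'   `af_AMR`, `af_EUR`, `af_AFR`, `consequence`, `revel`, `mtr`,
#'   `mtr_centile`, `beta_dnmt3a` and `beta_other` (log-odds on the two CH
#'   components per allele), `beta_ltl` (LTL units per allele).
#' @param ltl_model list `intercept` (kb), `age_slope` (kb lost per year),
#'   `noise_sd` (kb).
#' @param coverage_mean mean sequencing depth (default 57).
#' @param decoy_fraction fraction of somatic records that are injected
#'   non-qualifying decoys (default 0.1; 1 suppresses true calls).
#' @param rules [ch_rules()] object used to emit qualifying consequences.
#' @param seed integer master seed; each component (covariates, mosaic,
#'   genotypes, LTL, CH, somatic) uses an offset stream so components can
#'   be regenerated independently.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals,
                       n_windows = 400L,
                       window_bp = 100000L,
                       ancestry_dirichlet = c(AMR = 6.6, EUR = 3.1, AFR = 0.3),
                       switch_rate = 0.1,
                       age_range = c(35, 90),
                       smoking_logit = c(intercept = -1.0, eur = 0.8),
                       ch_logit = c(intercept = -9.6, age = 0.08, eur = 0.84,
                                    smoking = 0.35, ltl = 0.15),
                       gene_weights = default_gene_weights(),
                       variant_panel = default_variant_panel(n_windows),
                       ltl_model = list(intercept = 3.9, age_slope = 0.02,
                                        noise_sd = 0.5),
                       coverage_mean = 57,
                       decoy_fraction = 0.1,
                       rules = ch_rules("panel15"),
                       seed = 1L) {
  if (n_individuals <= 0 || n_windows <= 0)
    stop("n_individuals and n_windows must be positive")
  if (any(ancestry_dirichlet <= 0))
    stop("Dirichlet concentrations must be strictly positive")
  if (switch_rate < 0 || switch_rate > 1)
    stop("switch_rate must lie in [0, 1]")
  if (!all(names(gene_weights) %in% names(rules$genes)))
    stop("gene_weights contains genes absent from the rule set: ",
         paste(setdiff(names(gene_weights), names(rules$genes)), collapse = ", "))
  variant_panel <- data.table::as.data.table(variant_panel)
  if (nrow(variant_panel) > 0 &&
      any(variant_panel$window < 1 | variant_panel$window > n_windows))
    stop("variant panel positions outside window span: ",
         paste(variant_panel$id[variant_panel$window < 1 |
                                variant_panel$window > n_windows],
               collapse = ", "))
  structure(list(
    n_individuals = as.integer(n_individuals), n_windows = as.integer(n_windows),
    window_bp = as.integer(window_bp),
    ancestry_dirichlet = ancestry_dirichlet, switch_rate = switch_rate,
    age_range = age_range, smoking_logit = smoking_logit, ch_logit = ch_logit,
    gene_weights = gene_weights / sum(gene_weights),
    variant_panel = variant_panel, ltl_model = ltl_model,
    coverage_mean = coverage_mean, decoy_fraction = decoy_fraction,
    rules = rules, seed = as.integer(seed)), class = "sim_config")
}

#' Default driver-gene weights given CH (ranked as observed in admixed
#' Latin American blood donors: DNMT3A most frequent, then TET2, ASXL1,
#' PPM1D, TP53).
#' @return named numeric vector summing to 1.
#' @export
default_gene_weights <- function() {
  w <- c(DNMT3A = 0.50, TET2 = 0.16, ASXL1 = 0.09, PPM1D = 0.07, TP53 = 0.05,
         SF3B1 = 0.03, SRSF2 = 0.02, GNB1 = 0.02, IDH2 = 0.015, JAK2 = 0.015,
         PRPF8 = 0.01, KRAS = 0.01, NRAS = 0.01, BRAF = 0.005, MPL = 0.005)
  w / sum(w)
}

#' Default synthetic germline variant panel
#'
#' Contains a TCL1B-like rare variant (EUR-enriched, opposing effects on
#' DNMT3A- vs non-DNMT3A-CH), a TERT-like common risk variant, and two
#' LTL-effect variants; frequencies differ by local ancestry. Variants are
#' placed at fixed relative positions along the simulated segment.
#' @param n_windows number of windows in the simulated segment.
#' @return `data.table` in the [sim_config()] `variant_panel` schema.
#' @export
default_variant_panel <- function(n_windows = 400L) {
  data.table::data.table(
    id = c("rs_tcl1b_like", "rs_tert_like", "rs_ltl_1", "rs_ltl_2"),
    gene = c("TCL1B", "TERT", "TERC", "OBFC1"),
    window = pmax(1L, as.integer(round(n_windows * c(0.1, 0.3, 0.5, 0.7)))),
    pos_offset = c(500L, 500L, 500L, 500L),
    ref = c("C", "A", "G", "T"), alt = c("T", "G", "A", "C"),
    af_AMR = c(0.0006, 0.20, 0.25, 0.30),
    af_EUR = c(0.0162, 0.25, 0.30, 0.35),
    af_AFR = c(0.0010, 0.22, 0.28, 0.32),
    consequence = c("missense", "other", "other", "other"),
    revel = c(0.30, NA, NA, NA),
    mtr = c(0.70, NA, NA, NA),
    mtr_centile = c(40, NA, NA, NA),
    beta_dnmt3a = c(-1.2, 0.27, 0, 0),
    beta_other = c(1.5, 0.27, 0, 0),
    beta_ltl = c(0, 0, 0.08, 0.06))
}

sim_seed <- function(config, component) {
  off <- c(covariates = 11L, mosaic = 23L, genotypes = 37L, ltl = 41L,
           ch = 53L, somatic = 67L)[[component]]
  (config$seed %% 100000000L) * 10L + off
}

#' Simulate cohort covariates and local-ancestry mosaics
#'
#' Global ancestry per individual is a Dirichlet draw; each haplotype is a
#' window-wise Markov mosaic whose stationary distribution equals the
#' individual's global fractions (the first window is drawn from them, each
#' subsequent window resamples with probability `switch_rate`). Smoking is
#' logistic in the European fraction; age is uniform; sex is Bernoulli(0.5).
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort`: `covariates` (`data.table`:
#'   sample_id, age, sex, smoking, ever_smoker, cohort, coverage, frac_AMR,
#'   frac_EUR, frac_AFR), `mosaic` (class `la_mosaic`), `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  set.seed(sim_seed(config, "covariates"))
  frac <- rdirichlet(n, config$ancestry_dirichlet)
  colnames(frac) <- c("frac_AMR", "frac_EUR", "frac_AFR")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  ever <- stats::rbinom(n, 1, stats::plogis(
    config$smoking_logit[["intercept"]] +
      config$smoking_logit[["eur"]] * frac[, "frac_EUR"])) == 1
  smoking <- ifelse(!ever, "never",
                    ifelse(stats::runif(n) < 0.5, "previous", "current"))
  coverage <- stats::rnorm(n, config$coverage_mean, 4)
  cov <- data.table::data.table(
    sample_id = sprintf("S%06d", seq_len(n)), age = age, sex = sex,
    smoking = smoking, ever_smoker = ever, cohort = "SYN",
    coverage = pmax(coverage, 10))
  cov <- cbind(cov, frac)
  mosaic <- simulate_mosaic(frac, config)
  structure(list(covariates = cov, mosaic = mosaic,
                 truth = list(config = config)),
            class = "synthetic_cohort")
}

rdirichlet <- function(n, alpha) {
  g <- vapply(alpha, function(a) stats::rgamma(n, shape = a), numeric(n))
  g <- matrix(g, nrow = n)
  g / rowSums(g)
}

# Window-wise Markov mosaic; codes 1=AMR, 2=EUR, 3=AFR.
# Storage: integer matrix [n_windows x 2n], haplotype columns paired.
simulate_mosaic <- function(frac, config) {
  n <- nrow(frac); W <- config$n_windows
  set.seed(sim_seed(config, "mosaic"))
  fr2 <- frac[rep(seq_len(n), each = 2), , drop = FALSE]  # per haplotype
  H <- 2L * n
  m <- matrix(0L, nrow = W, ncol = H)
  draw <- function(idx) {
    u <- stats::runif(length(idx))
    1L + (u > fr2[idx, 1]) + (u > fr2[idx, 1] + fr2[idx, 2])
  }
  m[1, ] <- draw(seq_len(H))
  if (W > 1) {
    for (w in 2:W) {
      sw <- stats::runif(H) < config$switch_rate
      m[w, ] <- m[w - 1, ]
      if (any(sw)) m[w, sw] <- draw(which(sw))
    }
  }
  windows <- data.table::data.table(
    chrom = "chr1",
    spos = (seq_len(W) - 1L) * config$window_bp,
    epos = seq_len(W) * config$window_bp)
  structure(list(windows = windows, hap = m,
                 labels = c("AMR", "EUR", "AFR"),
                 ids = sprintf("S%06d", seq_len(n))),
            class = "la_mosaic")
}

#' Simulate germline genotypes and leukocyte telomere length
#'
#' Each allele at each panel variant is drawn with the allele frequency of
#' the local ancestry of the overlying window on that haplotype. LTL (kb)
#' is `intercept - age_slope * age + sum(dosage * beta_ltl) + N(0, noise_sd)`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config the same [sim_config()].
#' @return the cohort with `genotypes` (n x m dosage matrix),
#'   `variant_meta` (`data.table`) and covariate columns `ltl`, `ltl_std`
#'   added.
#' @export
simulate_genetic_data <- function(cohort, config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  panel <- config$variant_panel
  if (nrow(panel) == 0) stop("variant_panel is empty")
  bad <- panel$window < 1 | panel$window > config$n_windows
  if (any(bad))
    stop("variant position outside window span: ",
         paste(panel$id[bad], collapse = ", "))
  m <- cohort$mosaic$hap
  n <- config$n_individuals
  set.seed(sim_seed(config, "genotypes"))
  G <- matrix(0L, nrow = n, ncol = nrow(panel),
              dimnames = list(cohort$covariates$sample_id, panel$id))
  af_mat <- as.matrix(panel[, c("af_AMR", "af_EUR", "af_AFR")])
  for (j in seq_len(nrow(panel))) {
    anc <- m[panel$window[j], ]                      # per haplotype, length 2n
    af <- af_mat[j, anc]
    alleles <- stats::rbinom(length(af), 1, af)
    G[, j] <- alleles[seq(1, 2 * n, by = 2)] + alleles[seq(2, 2 * n, by = 2)]
  }
  set.seed(sim_seed(config, "ltl"))
  lm_ <- config$ltl_model
  ltl <- lm_$intercept - lm_$age_slope * cohort$covariates$age +
    drop(G %*% panel$beta_ltl) +
    stats::rnorm(n, 0, lm_$noise_sd)
  cohort$genotypes <- G
  cohort$variant_meta <- variant_meta_from_panel(panel, config)
  cohort$covariates$ltl <- ltl
  cohort$covariates$ltl_std <- as.numeric(scale(ltl))
  cohort
}

variant_meta_from_panel <- function(panel, config) {
  pos <- (panel$window - 1L) * config$window_bp + panel$pos_offset
  af_glob <- rowMeans(as.matrix(panel[, c("af_AMR", "af_EUR", "af_AFR")]))
  data.table::data.table(
    variant_id = panel$id, gene = panel$gene, chrom = "chr1", pos = pos,
    ref = panel$ref, alt = panel$alt, effect_allele = panel$alt,
    maf_global = pmin(af_glob, 1 - af_glob),
    maf_AMR = pmin(panel$af_AMR, 1 - panel$af_AMR),
    maf_EUR = pmin(panel$af_EUR, 1 - panel$af_EUR),
    maf_AFR = pmin(panel$af_AFR, 1 - panel$af_AFR),
    info = 1, consequence = panel$consequence, revel = panel$revel,
    mtr = panel$mtr, mtr_centile = panel$mtr_centile)
}

#' Assign true CH status from the generating risk model
#'
#' CH risk is the union of a DNMT3A component and a non-DNMT3A component.
#' Both share the `ch_logit` covariate coefficients; their intercepts are
#' offset by `log(w)` and `log(1 - w)` where `w` is the DNMT3A gene weight,
#' and panel variants contribute `beta_dnmt3a` / `beta_other` respectively,
#' allowing opposing germline effects on the two CH classes.
#'
#' @param cohort cohort with genetic data.
#' @param config the [sim_config()].
#' @return cohort with covariate columns `ch`, `ch_dnmt3a`, `ch_other` and
#'   `ch_gene` (driver gene, `NA` if CH-negative) added.
#' @export
assign_ch_status <- function(cohort, config) {
  cov <- cohort$covariates
  if (is.null(cov$ltl_std)) stop("run simulate_genetic_data() first")
  b <- config$ch_logit
  eta <- b[["intercept"]] + b[["age"]] * cov$age +
    b[["eur"]] * cov$frac_EUR + b[["smoking"]] * as.numeric(cov$ever_smoker) +
    b[["ltl"]] * cov$ltl_std
  G <- cohort$genotypes
  panel <- config$variant_panel
  w_d <- unname(config$gene_weights[["DNMT3A"]])
  eta_d <- eta + log(w_d) + drop(G %*% panel$beta_dnmt3a)
  eta_o <- eta + log(1 - w_d) + drop(G %*% panel$beta_other)
  set.seed(sim_seed(config, "ch"))
  n <- nrow(cov)
  ch_d <- stats::runif(n) < stats::plogis(eta_d)
  ch_o <- stats::runif(n) < stats::plogis(eta_o)
  other_w <- config$gene_weights[names(config$gene_weights) != "DNMT3A"]
  other_gene <- sample(names(other_w), n, replace = TRUE,
                       prob = other_w / sum(other_w))
  cov$ch_dnmt3a <- ch_d
  cov$ch_other <- ch_o
  cov$ch <- ch_d | ch_o
  cov$ch_other_gene <- ifelse(ch_o, other_gene, NA)
  cov$ch_gene <- ifelse(ch_d, "DNMT3A", cov$ch_other_gene)
  cohort$covariates <- cov
  cohort
}

#' Simulate somatic variant records for the generated CH status
#'
#' Every CH-positive individual receives one qualifying somatic call per
#' positive component, drawn from its driver gene's rule class: a PTV for
#' whole-gene or exon-restricted genes (with a valid exon), a hotspot
#' amino-acid change for hotspot-only genes. VAF is uniform on
#' `[0.03, 0.40]`, depth is Poisson around the individual's coverage, and
#' alternate reads are `round(VAF x depth)` floored at 3. A configurable
#' fraction of decoy records violating one gate each (consequence, VAF
#' range, read support, panel membership) is injected.
#'
#' @param cohort cohort with CH status assigned.
#' @param config the [sim_config()].
#' @return cohort with a `somatic` `data.table` added (sample_id, gene,
#'   chrom, pos, ref, alt, consequence, exon_number, protein_change,
#'   alt_reads, depth, vaf, decoy).
#' @export
simulate_somatic_calls <- function(cohort, config) {
  cov <- cohort$covariates
  if (is.null(cov$ch)) stop("run assign_ch_status() first")
  for (g in names(config$gene_weights)) {
    if (is.null(config$rules$genes[[g]]))
      stop("gene_weights gene lacks a rule entry: ", g)
  }
  set.seed(sim_seed(config, "somatic"))
  recs <- list()
  if (config$decoy_fraction < 1) {
    carriers <- data.table::data.table(
      sample_id = c(cov$sample_id[cov$ch_dnmt3a], cov$sample_id[cov$ch_other]),
      gene = c(rep("DNMT3A", sum(cov$ch_dnmt3a)),
               cov$ch_other_gene[cov$ch_other]))
    if (nrow(carriers) > 0) {
      covx <- cov[match(carriers$sample_id, cov$sample_id)]
      recs$true <- make_true_calls(carriers, covx$coverage, config)
    }
  }
  n_true <- if (is.null(recs$true)) 0L else nrow(recs$true)
  n_decoy <- if (config$decoy_fraction >= 1) {
    max(10L, sum(cov$ch))
  } else if (config$decoy_fraction > 0) {
    round(config$decoy_fraction * n_true / (1 - config$decoy_fraction))
  } else 0L
  if (n_decoy > 0) {
    recs$decoy <- make_decoy_calls(n_decoy, cov, config)
  }
  somatic <- data.table::rbindlist(recs, use.names = TRUE)
  if (nrow(somatic) > 0) {
    somatic <- somatic[order(somatic$sample_id, somatic$pos)]
  } else {
    somatic <- data.table::data.table(
      sample_id = character(), gene = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      consequence = character(), exon_number = integer(),
      protein_change = character(), alt_reads = integer(), depth = integer(),
      vaf = numeric(), decoy = logical())
  }
  cohort$somatic <- somatic
  cohort
}

gene_positions <- function(config) {
  genes <- names(config$rules$genes)
  # deterministic fake coordinates, one slot per gene, clear of the panel
  data.table::data.table(gene = genes, chrom = "chr2",
                         base = 1000000L + 50000L * seq_along(genes))
}

qualifying_call_for_gene <- function(gene, rules) {
  g <- rules$genes[[gene]]
  switch(g$rule_class,
    whole_gene_ptv_plus_hotspot = list(
      consequence = sample(PTV_CLASSES, 1), exon_number = 3L,
      protein_change = NA_character_),
    exon_restricted_ptv = list(
      consequence = sample(PTV_CLASSES, 1),
      exon_number = g$allowed_exons[sample.int(length(g$allowed_exons), 1)],
      protein_change = NA_character_),
    hotspot_only = list(
      consequence = "missense", exon_number = 3L,
      protein_change = g$hotspots[sample.int(length(g$hotspots), 1)]))
}

make_true_calls <- function(carriers, coverage, config) {
  k <- nrow(carriers)
  gp <- gene_positions(config)
  det <- lapply(seq_len(k), function(i)
    qualifying_call_for_gene(carriers$gene[i], config$rules))
  vaf <- stats::runif(k, 0.03, 0.40)
  depth <- stats::rpois(k, pmax(coverage, 10))
  depth <- pmax(depth, 10L)
  alt <- as.integer(round(vaf * depth))
  # keep read counts inside the qualifying gates after rounding
  alt <- pmax(alt, 3L, as.integer(ceiling(0.03 * depth)))
  alt <- pmin(alt, as.integer(floor(0.40 * depth)))
  base <- gp$base[match(carriers$gene, gp$gene)]
  data.table::data.table(
    sample_id = carriers$sample_id, gene = carriers$gene, chrom = "chr2",
    pos = base + sample.int(2000L, k, replace = TRUE),
    ref = "C", alt = "T",
    consequence = vapply(det, `[[`, "", "consequence"),
    exon_number = vapply(det, `[[`, 1L, "exon_number"),
    protein_change = vapply(det, `[[`, "", "protein_change"),
    alt_reads = alt, depth = depth, vaf = alt / depth, decoy = FALSE)
}

make_decoy_calls <- function(n_decoy, cov, config) {
  ids <- sample(cov$sample_id, n_decoy, replace = TRUE)
  genes <- names(config$rules$genes)
  kind <- rep_len(c("consequence", "vaf_high", "vaf_low", "reads", "panel"),
                  n_decoy)
  gene <- ifelse(kind == "panel", "NOTDRIVER1",
                 sample(genes, n_decoy, replace = TRUE))
  depth <- pmax(stats::rpois(n_decoy, config$coverage_mean), 30L)
  # deep depth for the low-VAF decoys so >=3 alt reads still sit below 3% VAF
  depth[kind == "vaf_low"] <- 300L
  vaf <- stats::runif(n_decoy, 0.05, 0.35)
  vaf[kind == "vaf_high"] <- stats::runif(sum(kind == "vaf_high"), 0.45, 0.8)
  vaf[kind == "vaf_low"] <- stats::runif(sum(kind == "vaf_low"), 0.012, 0.028)
  alt <- pmax(3L, as.integer(round(vaf * depth)))
  alt[kind == "reads"] <- 2L
  conseq <- rep("synonymous", n_decoy)          # fails every rule class
  conseq[kind != "consequence"] <- "nonsense"   # would pass PTV classes
  # hotspot_only genes reject PTVs anyway; for clean single-gate decoys use
  # whole-gene genes for the non-consequence kinds
  whole <- names(Filter(function(g) g$rule_class != "hotspot_only",
                        config$rules$genes))
  gene[kind %in% c("vaf_high", "vaf_low", "reads")] <-
    sample(whole, sum(kind %in% c("vaf_high", "vaf_low", "reads")), replace = TRUE)
  gp <- gene_positions(config)
  base <- gp$base[match(gene, gp$gene)]
  base[is.na(base)] <- 9000000L
  data.table::data.table(
    sample_id = ids, gene = gene, chrom = "chr2",
    pos = base + 3000L + sample.int(1000L, n_decoy, replace = TRUE),
    ref = "G", alt = "A",
    consequence = conseq, exon_number = 3L, protein_change = NA_character_,
    alt_reads = alt, depth = depth, vaf = alt / depth, decoy = TRUE)
}

#' Run the full synthetic-cohort pipeline
#'
#' Convenience wrapper chaining [simulate_cohort()],
#' [simulate_genetic_data()], [assign_ch_status()] and
#' [simulate_somatic_calls()].
#'
#' @param config a [sim_config()].
#' @return a complete `synthetic_cohort`.
#' @export
simulate_full_cohort <- function(config) {
  cohort <- simulate_cohort(config)
  cohort <- simulate_genetic_data(cohort, config)
  cohort <- assign_ch_status(cohort, config)
  simulate_somatic_calls(cohort, config)
}
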