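#' Allelic Fisher's exact test for one variant
#'
#' Builds the 2x2 allele-count table (effect allele / other allele) x
#' (case / control) from hard-call genotypes and tests it with Fisher's
#' exact two-sided test. The reported OR is the cross-product ratio
#' `(a d) / (b c)` with a Haldane–Anscombe 0.5 correction applied to every
#' cell when any cell is zero (the conditional-MLE OR that `fisher.test`
#' reports is intentionally not used, so ORs remain comparable with the
#' collapsing output).
#'
#' @param dosage hard-call dosages (0/1/2) of the effect allele.
#' @param outcome binary case indicator.
#' @return one-row `data.table`: or, ci_low, ci_high, p, mac_cases,
#'   mac_controls, n, test, untestable.
#' @export
fisher_allelic_test <- function(dosage, outcome) {
  stopifnot(length(dosage) == length(outcome))
  y <- as.numeric(outcome)
  a <- sum(dosage[y == 1])            # effect alleles in cases
  b <- 2 * sum(y == 1) - a
  c_ <- sum(dosage[y == 0])
  d <- 2 * sum(y == 0) - c_
  if (a + c_ == 0 || b + d == 0) {
    return(data.table::data.table(
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
      mac_cases = a, mac_controls = c_, n = length(y), test = "fisher_allelic",
      untestable = TRUE))
  }
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  hc <- if (any(tab == 0)) 0.5 else 0
  or <- ((a + hc) * (d + hc)) / ((b + hc) * (c_ + hc))
  se <- sqrt(sum(1 / (tab + hc)))
  data.table::data.table(
    or = or, ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se), p = p,
    mac_cases = a, mac_controls = c_, n = length(y), test = "fisher_allelic",
    untestable = FALSE)
}

#' Hardy–Weinberg exact test
#'
#' Exact test on genotype counts: the two-sided P value sums the
#' probabilities of all heterozygote counts (given the allele counts) that
#' are no more probable than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom).
#' @return exact P value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_b <- 2 * n_bb + n_ab                 # minor allele count
  if (n_b > n) return(hwe_exact_p(n_bb, n_ab, n_aa))
  hets <- seq(n_b %% 2, n_b, by = 2)
  # log probability of each possible het count given the allele counts
  lp <- vapply(hets, function(h) {
    nbb <- (n_b - h) / 2
    naa <- n - nbb - h
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(n_b + 1) + lgamma(2 * n - n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hets == n_ab] * (1 + 1e-12)])
}

#' Variant quality control
#'
#' Applies any subset of the gates {MAF, HWE, INFO, MAC in cases and
#' controls, strand-ambiguous removal}, each reporting rather than
#' throwing, then LD-prunes the survivors (pruning is order-defined and
#' always last).
#'
#' @param geno dosage matrix (individuals x variants, named columns).
#' @param meta `data.table` with `variant_id` and the annotation columns
#'   used by the active gates (`maf_global` or computable from `geno`,
#'   `info`, `ref`, `alt`).
#' @param outcome binary phenotype, required for the MAC gate.
#' @param maf_min minimum MAF (default 0.01; `NULL` disables).
#' @param hwe_min minimum HWE exact P (default 1e-6; `NULL` disables).
#' @param info_min minimum imputation INFO (default 0.6; `NULL` disables).
#' @param mac_min minimum minor-allele count in cases and in controls
#'   (default 5; `NULL` disables).
#' @param drop_ambiguous remove A/T and C/G variants (default FALSE).
#' @param ld_r2 LD-pruning r-squared threshold (default 0.1; `NULL`
#'   disables), window 50 variants, step 5.
#' @return list: `keep` (variant ids), `reasons` (`data.table` variant_id,
#'   reason; first failed gate, `ld_prune` for pruned survivors).
#' @export
variant_qc <- function(geno, meta, outcome = NULL, maf_min = 0.01,
                       hwe_min = 1e-6, info_min = 0.6, mac_min = 5,
                       drop_ambiguous = FALSE, ld_r2 = 0.1,
                       ld_window = 50L, ld_step = 5L) {
  meta <- data.table::as.data.table(meta)
  ids <- meta$variant_id
  stopifnot(ncol(geno) == nrow(meta))
  af <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  reason <- rep(NA_character_, length(ids))
  fail <- function(which, why) {
    reason[is.na(reason) & which] <<- why
  }
  if (!is.null(maf_min)) fail(maf < maf_min, "maf")
  if (!is.null(hwe_min)) {
    hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
      g <- round(geno[, j])
      hwe_exact_p(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                  sum(g == 2, na.rm = TRUE))
    }, numeric(1))
    fail(hwe_p < hwe_min, "hwe")
  }
  if (!is.null(info_min) && "info" %in% names(meta))
    fail(meta$info <= info_min, "info")
  if (!is.null(mac_min) && !is.null(outcome)) {
    y <- as.numeric(outcome)
    minor_dose <- function(g, af_j) if (af_j <= 0.5) g else 2 - g
    mac_ca <- vapply(seq_len(ncol(geno)), function(j)
      sum(minor_dose(geno[y == 1, j], af[j]), na.rm = TRUE), numeric(1))
    mac_co <- vapply(seq_len(ncol(geno)), function(j)
      sum(minor_dose(geno[y == 0, j], af[j]), na.rm = TRUE), numeric(1))
    fail(mac_ca < mac_min | mac_co < mac_min, "mac")
  }
  if (drop_ambiguous && all(c("ref", "alt") %in% names(meta))) {
    amb <- paste0(meta$ref, meta$alt) %in% c("AT", "TA", "CG", "GC")
    fail(amb, "ambiguous")
  }
  keep <- ids[is.na(reason)]
  if (!is.null(ld_r2) && length(keep) > 1) {
    kept_idx <- match(keep, ids)
    pruned <- ld_prune(geno[, kept_idx, drop = FALSE], maf[kept_idx],
                       r2 = ld_r2, window = ld_window, step = ld_step)
    dropped <- setdiff(keep, keep[pruned])
    reason[match(dropped, ids)] <- "ld_prune"
    keep <- keep[pruned]
  }
  list(keep = keep,
       reasons = data.table::data.table(variant_id = ids, reason = reason))
}

# Sliding-window greedy LD pruning: window of `window` variants advanced by
# `step`; within a window, for any pair with r2 >= threshold the lower-MAF
# member is dropped (ties broken by position in the input order).
# Returns indices of retained variants.
ld_prune <- function(geno, maf, r2 = 0.1, window = 50L, step = 5L) {
  m <- ncol(geno)
  alive <- rep(TRUE, m)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, m)
    idx <- which(alive[start:end]) + start - 1L
    if (length(idx) > 1) {
      cm <- suppressWarnings(stats::cor(geno[, idx, drop = FALSE],
                                        use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      for (i in seq_along(idx)) {
        if (!alive[idx[i]]) next
        for (j in seq_along(idx)) {
          if (j <= i || !alive[idx[j]]) next
          if (cm[i, j]^2 >= r2) {
            drop <- if (maf[idx[i]] < maf[idx[j]] ||
                        (maf[idx[i]] == maf[idx[j]] && i > j)) idx[i] else idx[j]
            alive[drop] <- FALSE
            if (drop == idx[i]) break
          }
        }
      }
    }
    if (end >= m) break
    start <- start + step
  }
  which(alive)
}

#' Per-variant association scan with Firth logistic regression
#'
#' For each variant (optionally after [variant_qc()]), fits the phenotype
#' on dosage plus covariates plus any conditioning dosages by Firth
#' penalized regression and reports the dosage term. The covariate-only
#' reduced fit is shared across variants for the likelihood-ratio P.
#'
#' @param geno dosage matrix (individuals x variants, named columns).
#' @param pheno binary phenotype.
#' @param covars covariate matrix or data.frame (numeric columns).
#' @param meta optional `VariantMeta` table aligned with `geno` columns.
#' @param qc optional result of [variant_qc()]; only `qc$keep` variants are
#'   tested.
#' @param condition character vector of conditioning variant ids (columns
#'   of `geno`); a conditioning variant failing QC is still conditioned on,
#'   with a warning.
#' @param p_method `"lrt"` or `"wald"`.
#' @param threshold significance threshold recorded in the output (GWAS
#'   default 5e-8; use 1e-8 for exome-wide scans).
#' @return `data.table`: variant_id, beta, se, or, ci_low, ci_high, p,
#'   mac_cases, mac_controls, n, test, significant.
#' @export
gwas_scan <- function(geno, pheno, covars = NULL, meta = NULL, qc = NULL,
                      condition = character(), p_method = c("lrt", "wald"),
                      threshold = 5e-8) {
  p_method <- match.arg(p_method)
  y <- as.numeric(pheno)
  ids <- colnames(geno)
  test_ids <- if (!is.null(qc)) intersect(ids, qc$keep) else ids
  if (length(condition) > 0) {
    miss <- setdiff(condition, ids)
    if (length(miss) > 0) stop("conditioning variants absent: ",
                               paste(miss, collapse = ", "))
    if (!is.null(qc) && length(setdiff(condition, qc$keep)) > 0)
      warning("conditioning variant(s) failed QC; conditioning on them anyway")
    test_ids <- setdiff(test_ids, condition)
  }
  C <- if (!is.null(covars)) as.matrix(covars) else NULL
  Z <- if (length(condition) > 0) geno[, condition, drop = FALSE] else NULL
  base <- cbind(C, Z)
  rows <- lapply(test_ids, function(v) {
    g <- geno[, v]
    x <- cbind(dosage = g, base)
    fit <- tryCatch(
      firth_logistic_fit(y, x, p_method = p_method, terms = "dosage"),
      firth_nonconvergence = function(e) NULL)
    if (is.null(fit)) {
      return(data.table::data.table(
        variant_id = v, beta = NA_real_, se = NA_real_, or = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
        mac_cases = NA_real_, mac_controls = NA_real_, n = length(y),
        test = "firth", significant = FALSE))
    }
    b <- fit$coef[["dosage"]]; se <- fit$se[["dosage"]]
    af <- mean(g) / 2
    md <- if (af <= 0.5) g else 2 - g
    data.table::data.table(
      variant_id = v, beta = b, se = se, or = exp(b),
      ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
      p = fit$p[["dosage"]],
      mac_cases = sum(md[y == 1]), mac_controls = sum(md[y == 0]),
      n = length(y), test = "firth", significant = fit$p[["dosage"]] < threshold)
  })
  res <- data.table::rbindlist(rows)
  if (!is.null(meta)) {
    meta <- data.table::as.data.table(meta)
    res <- merge(meta[, intersect(c("variant_id", "chrom", "pos", "ref", "alt",
                                    "effect_allele", "maf_global", "info"),
                                  names(meta)), with = FALSE],
                 res, by = "variant_id", sort = FALSE)
  }
  res[]
}

#' Linkage disequilibrium statistics for a variant pair
#'
#' With phased haplotypes, haplotype frequencies are counted directly;
#' with unphased genotypes they are estimated by EM (tolerance 1e-10).
#' `D = p_AB - p_A p_B`, `D' = D / Dmax`, `r2 = D^2 / (pA qA pB qB)`.
#'
#' @param g1,g2 either phased allele matrices (`n x 2`, 0/1) or unphased
#'   dosage vectors (0/1/2).
#' @param phased are the inputs phased allele matrices?
#' @return list: d, d_prime, r2, p_a, p_b (allele-1 frequencies), flagged
#'   (TRUE when a variant is monomorphic and the statistics are undefined).
#' @export
ld_stats <- function(g1, g2, phased = FALSE) {
  if (phased) {
    a <- as.vector(as.matrix(g1)); b <- as.vector(as.matrix(g2))
    p_ab <- mean(a == 1 & b == 1)
    p_a <- mean(a == 1); p_b <- mean(b == 1)
  } else {
    fr <- em_haplotypes(g1, g2)
    p_ab <- fr[["11"]]
    p_a <- fr[["11"]] + fr[["10"]]
    p_b <- fr[["11"]] + fr[["01"]]
  }
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    return(list(d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                p_a = p_a, p_b = p_b, flagged = TRUE))
  }
  d <- p_ab - p_a * p_b
  dmax <- if (d >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
          else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  list(d = d, d_prime = if (dmax == 0) NA_real_ else abs(d) / dmax,
       r2 = d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)),
       p_a = p_a, p_b = p_b, flagged = FALSE)
}

# Two-locus haplotype-frequency EM on unphased hard calls.
em_haplotypes <- function(g1, g2, tol = 1e-10, max_iter = 1000L) {
  keep <- !(is.na(g1) | is.na(g2))
  g1 <- round(g1[keep]); g2 <- round(g2[keep])
  n <- length(g1)
  cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
  # haplotype frequencies for alleles (1/0) at locus A and B: f11,f10,f01,f00
  p_a <- mean(g1) / 2; p_b <- mean(g2) / 2
  f <- c(`11` = p_a * p_b, `10` = p_a * (1 - p_b),
         `01` = (1 - p_a) * p_b, `00` = (1 - p_a) * (1 - p_b))
  dh <- cnt["1", "1"]                   # double heterozygotes: ambiguous
  repeat {
    # probability the double het is 11/00 rather than 10/01
    denom <- f[["11"]] * f[["00"]] + f[["10"]] * f[["01"]]
    w <- if (denom == 0) 0.5 else f[["11"]] * f[["00"]] / denom
    n11 <- 2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"] + w * dh
    n10 <- 2 * cnt["2", "0"] + cnt["2", "1"] + cnt["1", "0"] + (1 - w) * dh
    n01 <- 2 * cnt["0", "2"] + cnt["1", "2"] + cnt["0", "1"] + (1 - w) * dh
    n00 <- 2 * cnt["0", "0"] + cnt["1", "0"] + cnt["0", "1"] + w * dh
    f_new <- c(`11` = n11, `10` = n10, `01` = n01, `00` = n00) / (2 * n)
    if (max(abs(f_new - f)) < tol) return(f_new)
    f <- f_new
    max_iter <- max_iter - 1L
    if (max_iter <= 0L) return(f)
  }
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - P, 1)) / qchisq(0.5, 1)`; the denominator is
#' fixed at 0.456 (the null median to three decimals) by default.
#'
#' @param p vector of P values in (0, 1].
#' @param denominator null median of the 1-df chi-square (default 0.456).
#' @return lambda.
#' @export
genomic_inflation <- function(p, denominator = 0.456) {
  p <- p[!is.na(p)]
  if (any(p <= 0 | p > 1)) stop("P values must lie in (0, 1]")
  if (length(p) < 100) warning("fewer than 100 P values; lambda is unstable")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) / denominator
}

#' Permutation-based genomic inflation
#'
#' Shuffles the case/control labels with the given seed, re-runs
#' [gwas_scan()], and returns the inflation factor of the permuted scan.
#'
#' @inheritParams gwas_scan
#' @param seed permutation seed.
#' @return lambda under permuted labels.
#' @export
genomic_inflation_permuted <- function(geno, pheno, covars = NULL, seed = 1L,
                                       ...) {
  set.seed(seed)
  perm <- sample(as.numeric(pheno))
  res <- gwas_scan(geno, perm, covars = covars, ...)
  genomic_inflation(res$p)
}

#' Group significant variants into loci and flag novelty
#'
#' Significant variants are visited by ascending P; each unassigned one
#' seeds a locus claiming every significant variant within the window
#' (inclusive) on the same chromosome. A locus is novel iff no known
#' catalog entry lies within the window of its lead.
#'
#' @param results association table with `variant_id`, `chrom`, `pos`, `p`.
#' @param threshold significance threshold (default 5e-8).
#' @param window half-width in bp (default 1e6, i.e. +/- 1 Mb, inclusive).
#' @param known optional data.frame of known loci (`chrom`, `pos`).
#' @return `data.table`: locus, lead_variant, chrom, pos, p, n_members,
#'   members (list column), novel.
#' @export
define_loci <- function(results, threshold = 5e-8, window = 1e6, known = NULL) {
  res <- data.table::as.data.table(results)
  sig <- res[!is.na(res$p) & res$p < threshold]
  if (nrow(sig) == 0) return(data.table::data.table(
    locus = integer(), lead_variant = character(), chrom = character(),
    pos = numeric(), p = numeric(), n_members = integer(),
    members = list(), novel = logical()))
  sig <- sig[order(sig$p, sig$chrom, sig$pos)]
  assigned <- rep(FALSE, nrow(sig))
  out <- list()
  locus <- 0L
  for (i in seq_len(nrow(sig))) {
    if (assigned[i]) next
    locus <- locus + 1L
    lead <- sig[i]
    memb <- !assigned & sig$chrom == lead$chrom &
      abs(sig$pos - lead$pos) <= window
    assigned[memb] <- TRUE
    novel <- TRUE
    if (!is.null(known) && nrow(known) > 0) {
      novel <- !any(known$chrom == lead$chrom &
                      abs(known$pos - lead$pos) <= window)
    }
    out[[locus]] <- data.table::data.table(
      locus = locus, lead_variant = lead$variant_id, chrom = lead$chrom,
      pos = lead$pos, p = lead$p, n_members = sum(memb),
      members = list(sig$variant_id[memb]), novel = novel)
  }
  data.table::rbindlist(out)
}
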