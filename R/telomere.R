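#' Coverage-normalize and standardize leukocyte telomere length
#'
#' Removes the linear dependence of the raw telomere estimate on
#' sequencing coverage by residualizing on centered coverage (the
#' least-squares slope), then standardizes to mean 0, s.d. 1. After
#' normalization the correlation with coverage is 0 by construction. A
#' ratio alternative (`raw * mean(coverage) / coverage`) is available.
#'
#' @param raw raw telomere estimates (kb-scale tool units).
#' @param coverage per-sample sequencing coverage (> 0).
#' @param method `"residual"` (default) or `"ratio"`.
#' @return `data.table`: raw, coverage, normalized, standardized.
#' @export
normalize_ltl <- function(raw, coverage, method = c("residual", "ratio")) {
  method <- match.arg(method)
  stopifnot(length(raw) == length(coverage), all(coverage > 0))
  if (method == "ratio") {
    norm <- raw * mean(coverage) / coverage
  } else if (stats::var(coverage) == 0) {
    message("constant coverage: slope undefined, normalization skipped")
    norm <- raw
  } else {
    b <- stats::cov(raw, coverage) / stats::var(coverage)
    norm <- raw - b * (coverage - mean(coverage))
  }
  std <- if (stats::sd(norm) == 0) rep(0, length(norm)) else
    (norm - mean(norm)) / stats::sd(norm)
  data.table::data.table(raw = raw, coverage = coverage,
                         normalized = norm, standardized = std)
}

#' Trim values beyond k standard deviations
#'
#' Retains values within `mean +/- k * sd`, both computed once on the full
#' input (no re-iteration). With zero spread everything is retained.
#'
#' @param values numeric vector.
#' @param k number of standard deviations (default 3).
#' @return logical vector: retained?
#' @export
trim_outliers <- function(values, k = 3) {
  stopifnot(k > 0)
  s <- stats::sd(values)
  if (is.na(s) || s == 0) return(rep(TRUE, length(values)))
  m <- mean(values)
  values >= m - k * s & values <= m + k * s
}

#' Polygenic score from an effect-size table
#'
#' Raw (non-averaged) score: the sum over overlapping variants of effect-
#' allele dosage times weight. When a genotype column's counted allele is
#' the effect table's other allele the dosage is complemented. Missing
#' dosages are imputed as `2 * eaf` from the effect table.
#'
#' @param geno dosage matrix (individuals x variants, named columns,
#'   dosages count `geno_allele`).
#' @param effects data.frame: `variant_id`, `effect_allele`, `eaf`,
#'   `weight`, and optionally `other_allele`.
#' @param geno_allele optional named character vector giving the allele
#'   counted by each genotype column (defaults to the effect allele, i.e.
#'   already aligned).
#' @return list: `score` (named numeric), `n_overlap`.
#' @export
score_prs <- function(geno, effects, geno_allele = NULL) {
  effects <- data.table::as.data.table(effects)
  overlap <- intersect(colnames(geno), effects$variant_id)
  if (length(overlap) == 0) stop("no overlap between effect table and genotypes")
  score <- numeric(nrow(geno))
  names(score) <- rownames(geno)
  for (v in overlap) {
    e <- effects[effects$variant_id == v][1]
    d <- geno[, v]
    if (!is.null(geno_allele) && !is.na(geno_allele[v]) &&
        geno_allele[v] != e$effect_allele) {
      d <- 2 - d
    }
    d[is.na(d)] <- 2 * e$eaf
    score <- score + d * e$weight
  }
  list(score = score, n_overlap = length(overlap))
}

#' Validate a polygenic score by incremental R-squared
#'
#' Fits the trait on covariates with and without the PRS and reports the
#' PRS effect with its CI, both R-squared values, the absolute difference
#' and the relative (percentage) improvement
#' `100 * (R2_full - R2_base) / R2_base`. With an empty base model the
#' relative improvement is reported as the absolute value with a notice.
#'
#' @param ltl trait values (e.g. standardized LTL).
#' @param prs polygenic score.
#' @param covariates data.frame of adjustment covariates (may be empty).
#' @return list: effect, se, ci, p, r2_full, r2_base, delta_r2_abs,
#'   delta_r2_pct.
#' @export
prs_r2_validation <- function(ltl, prs, covariates = NULL) {
  n <- length(ltl)
  stopifnot(length(prs) == n)
  if (n < 50) stop("at least 50 complete cases required")
  has_cov <- !is.null(covariates) && ncol(as.data.frame(covariates)) > 0
  if (has_cov) {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                    drop = FALSE]
    for (j in seq_len(ncol(C))) {
      r <- suppressWarnings(stats::cor(prs, C[, j]))
      if (!is.na(r) && abs(r) > 0.999)
        warning("PRS is collinear with covariate ", colnames(C)[j])
    }
    base <- stats::lm(ltl ~ C)
    full <- stats::lm(ltl ~ prs + C)
  } else {
    base <- stats::lm(ltl ~ 1)
    full <- stats::lm(ltl ~ prs)
  }
  r2f <- summary(full)$r.squared
  r2b <- summary(base)$r.squared
  sm <- summary(full)$coefficients["prs", ]
  d_abs <- r2f - r2b
  if (r2b == 0) {
    message("base model explains nothing; relative improvement reported as absolute")
    d_pct <- d_abs
  } else {
    d_pct <- 100 * d_abs / r2b
  }
  list(effect = unname(sm["Estimate"]), se = unname(sm["Std. Error"]),
       ci = unname(sm["Estimate"] + c(-1.96, 1.96) * sm["Std. Error"]),
       p = unname(sm["Pr(>|t|)"]),
       r2_full = r2f, r2_base = r2b, delta_r2_abs = d_abs, delta_r2_pct = d_pct)
}
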